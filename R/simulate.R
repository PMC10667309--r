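#' Simulate a synthetic soil community with known phage-host ground truth
#'
#' Generates, per replicate and condition: an entity-level Hi-C link table
#' (phage contigs and host MAGs), within-MAG link counts, metagenome coverage
#' records for every entity, metatranscriptome coverage records for every
#' DNA-present entity, and an argS proxy transcript table for the hosts.
#' Every infection carries a recorded true VPH (viral copies per host cell)
#' so the downstream filtering pipeline can be scored against ground truth.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `truth` (class `sim_truth`: tibbles `hosts`,
#'   `phages`, `infections`) and `data` (class `sim_dataset`: tibbles
#'   `entities`, `samples`, `links`, `intra`, `coverage_dna`, `coverage_rna`,
#'   `transcripts`, plus the `config`).
#' @export
#' @examples
#' sim <- simulate_community(sim_config(n_hosts = 5, n_phages = 8, seed = 42))
#' sim$truth$infections
#' head(sim$data$links)
simulate_community <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_community_impl(config))
}

simulate_community_impl <- function(cfg) {
  conds <- cfg$conditions
  baseline <- conds[1]

  ## --- hosts ---------------------------------------------------------------
  mag_ids <- sprintf("B%03d", seq_len(cfg$n_hosts))
  host_len <- runif(cfg$n_hosts, cfg$host_length_kb[1], cfg$host_length_kb[2])
  base_ab <- rlnorm(cfg$n_hosts, cfg$host_abundance[["meanlog"]],
                    cfg$host_abundance[["sdlog"]])
  hosts <- tidyr::expand_grid(
    tibble(mag_id = mag_ids, length_kb = host_len, .base = base_ab),
    condition = conds
  )
  hosts$abundance <- hosts$.base * ifelse(
    hosts$condition == baseline, 1,
    rlnorm(nrow(hosts), 0, cfg$condition_jitter_sdlog)
  )
  hosts$.base <- NULL

  ## --- phages --------------------------------------------------------------
  phage_ids <- sprintf("P%03d", seq_len(cfg$n_phages))
  phage_len <- runif(cfg$n_phages, cfg$phage_length_kb[1], cfg$phage_length_kb[2])
  lifestyle <- ifelse(runif(cfg$n_phages) < cfg$p_lysogenic,
                      "lysogenic", "lytic")
  is_free <- runif(cfg$n_phages) < cfg$p_no_host
  is_gen <- !is_free & runif(cfg$n_phages) < cfg$p_generalist
  range_vals <- seq(cfg$host_range_size[1], cfg$host_range_size[2])
  range_n <- ifelse(
    is_free, 0L,
    ifelse(
      is_gen,
      range_vals[sample.int(length(range_vals), cfg$n_phages,
                            replace = TRUE)],
      1L
    )
  )
  active_all <- runif(cfg$n_phages) < cfg$p_both_conditions
  solo_cond <- sample(conds, cfg$n_phages, replace = TRUE)

  infections <- purrr::map_dfr(seq_len(cfg$n_phages), function(i) {
    if (is_free[i]) return(NULL)
    k <- min(range_n[i], cfg$n_hosts)
    my_hosts <- sample(mag_ids, k)
    active <- if (active_all[i]) conds else solo_cond[i]
    base_vph <- runif(k, cfg$vph_truth[1], cfg$vph_truth[2])
    tidyr::expand_grid(
      tibble(phage_id = phage_ids[i], mag_id = my_hosts, .base_vph = base_vph),
      condition = active
    )
  })
  infections$true_vph <- infections$.base_vph *
    ifelse(infections$condition == baseline, 1, cfg$post_vph_multiplier) *
    rlnorm(nrow(infections), 0, cfg$vph_condition_jitter_sdlog)
  infections$.base_vph <- NULL
  infections <- infections[, c("phage_id", "mag_id", "condition", "true_vph")]
  infections <- as_tibble(infections)

  # phage abundance tracks the copies it maintains across its hosts, times a
  # free-abundance factor (virions outside cells, recovery variation) that
  # decouples the observed abundance from the host-associated copy number
  phage_ab <- tidyr::expand_grid(phage_id = phage_ids, condition = conds) |>
    left_join(
      infections |>
        left_join(hosts[, c("mag_id", "condition", "abundance")],
                  by = c("mag_id", "condition")) |>
        group_by(.data$phage_id, .data$condition) |>
        summarise(abundance = sum(.data$true_vph * .data$abundance),
                  .groups = "drop"),
      by = c("phage_id", "condition")
    )
  idx <- match(phage_ab$phage_id, phage_ids)
  active <- active_all[idx] | solo_cond[idx] == phage_ab$condition
  free_ab <- rlnorm(nrow(phage_ab), cfg$free_phage_abundance[["meanlog"]],
                    cfg$free_phage_abundance[["sdlog"]])
  phage_ab$abundance <- ifelse(
    !is.na(phage_ab$abundance),
    phage_ab$abundance * rlnorm(nrow(phage_ab), 0,
                                cfg$phage_free_factor_sdlog),
    ifelse(is_free[idx] & active, free_ab, 0)
  )

  phages <- tibble(phage_id = phage_ids, length_kb = phage_len,
                   lifestyle = lifestyle, n_hosts = range_n) |>
    left_join(phage_ab, by = "phage_id")

  truth <- structure(
    list(hosts = hosts, phages = phages, infections = infections),
    class = "sim_truth"
  )

  ## --- per-sample link tables and coverage ---------------------------------
  entities <- bind_rows(
    tibble(entity_id = mag_ids, type = "host", length_kb = host_len),
    tibble(entity_id = phage_ids, type = "phage", length_kb = phage_len)
  )
  samples <- tidyr::expand_grid(condition = conds,
                                replicate = seq_len(cfg$n_replicates)) |>
    mutate(sample_id = paste0(.data$condition, "_", .data$replicate))

  # unordered entity pairs, enumerated once, for background noise
  ent_ids <- entities$entity_id
  noise_pairs <- NULL
  if (cfg$noise_link_rate > 0 && length(ent_ids) >= 2) {
    idx <- utils::combn(length(ent_ids), 2L)
    noise_pairs <- tibble(entity_a = ent_ids[idx[1, ]],
                          entity_b = ent_ids[idx[2, ]])
  }

  inf_lambda <- infections |>
    left_join(hosts |> rename(host_kb = "length_kb", host_ab = "abundance"),
              by = c("mag_id", "condition")) |>
    left_join(tibble(phage_id = phage_ids, phage_kb = phage_len),
              by = "phage_id") |>
    mutate(lambda = cfg$inter_link_efficiency * .data$true_vph *
             .data$host_ab * .data$phage_kb * .data$host_kb)

  host_intra <- hosts |>
    mutate(lambda = cfg$intra_link_rate * .data$abundance * .data$length_kb^2)

  per_sample <- purrr::pmap(samples, function(condition, replicate, sample_id) {
    cond <- condition

    intra <- host_intra |> filter(.data$condition == cond)
    intra_tbl <- tibble(
      condition = cond, replicate = replicate, mag_id = intra$mag_id,
      intra_links = rpois(nrow(intra), intra$lambda)
    )

    lam <- inf_lambda |> filter(.data$condition == cond)
    true_links <- tibble(
      entity_a = pmin(lam$phage_id, lam$mag_id),
      entity_b = pmax(lam$phage_id, lam$mag_id),
      links = rpois(nrow(lam), lam$lambda)
    )
    links <- true_links
    if (!is.null(noise_pairs)) {
      noise <- noise_pairs
      noise$links <- rpois(nrow(noise), cfg$noise_link_rate)
      links <- bind_rows(links, noise)
    }
    links <- links |>
      group_by(.data$entity_a, .data$entity_b) |>
      summarise(links = sum(.data$links), .groups = "drop") |>
      filter(.data$links > 0) |>
      mutate(condition = cond, replicate = replicate, .before = 1)

    ## metagenome coverage
    ab <- bind_rows(
      hosts |> filter(.data$condition == cond) |>
        select(entity_id = "mag_id", abundance = "abundance"),
      phages |> filter(.data$condition == cond) |>
        select(entity_id = "phage_id", abundance = "abundance")
    )
    present <- ab$abundance > 0
    breadth <- ifelse(
      present,
      rbeta(nrow(ab), cfg$breadth_present[1], cfg$breadth_present[2]),
      0.5 * rbeta(nrow(ab), cfg$breadth_absent[1], cfg$breadth_absent[2])
    )
    depth <- ifelse(
      present,
      ab$abundance * (cfg$library_size_dna / 1e6) *
        rlnorm(nrow(ab), 0, cfg$depth_cv),
      0
    )
    cov_dna <- tibble(
      entity_id = ab$entity_id, sample_id = sample_id, condition = cond,
      replicate = replicate, breadth = breadth, mean_depth = depth,
      library_size = cfg$library_size_dna
    )

    ## metatranscriptome coverage, restricted to DNA-present entities
    dna_present <- cov_dna$entity_id[cov_dna$breadth > 0.5]
    rna <- ab |>
      filter(.data$entity_id %in% dna_present) |>
      left_join(phages |> filter(.data$condition == cond) |>
                  select(entity_id = "phage_id", lifestyle = "lifestyle"),
                by = "entity_id")
    act_scale <- ifelse(
      is.na(rna$lifestyle), 1,                                  # hosts
      ifelse(rna$lifestyle == "lysogenic", cfg$lysogenic_activity, 1) *
        ifelse(cond == conds[1], 1, cfg$post_activity_multiplier)
    )
    silent <- !is.na(rna$lifestyle) & runif(nrow(rna)) < cfg$rna_silent_p
    rna_depth <- ifelse(
      silent, 0,
      rna$abundance * act_scale * (cfg$library_size_rna / 1e6) *
        rlnorm(nrow(rna), 0, cfg$depth_cv)
    )
    cov_rna <- tibble(
      entity_id = rna$entity_id, sample_id = sample_id, condition = cond,
      replicate = replicate,
      breadth = ifelse(rna_depth > 0,
                       rbeta(nrow(rna), cfg$breadth_present[1],
                             cfg$breadth_present[2]), 0),
      mean_depth = rna_depth, library_size = cfg$library_size_rna
    )

    list(links = links, intra = intra_tbl, cov_dna = cov_dna,
         cov_rna = cov_rna)
  })

  ## --- argS proxy transcripts ----------------------------------------------
  n_dup <- min(cfg$n_duplicated_proxies, cfg$n_hosts)
  proxy <- tibble(
    node_id = c(mag_ids, if (n_dup > 0) paste0(mag_ids[seq_len(n_dup)], "b")),
    mag_id = c(mag_ids, if (n_dup > 0) mag_ids[seq_len(n_dup)])
  )
  transcripts <- tidyr::expand_grid(samples, proxy) |>
    left_join(hosts[, c("mag_id", "condition", "abundance")],
              by = c("mag_id", "condition"))
  transcripts$abundance <- transcripts$abundance *
    rlnorm(nrow(transcripts), 0, cfg$args_noise_sdlog)
  transcripts <- transcripts[, c("sample_id", "condition", "replicate",
                                 "node_id", "mag_id", "abundance")]

  data <- structure(
    list(
      entities = entities,
      samples = samples,
      links = purrr::map_dfr(per_sample, "links"),
      intra = purrr::map_dfr(per_sample, "intra"),
      coverage_dna = purrr::map_dfr(per_sample, "cov_dna"),
      coverage_rna = purrr::map_dfr(per_sample, "cov_rna"),
      transcripts = transcripts,
      config = cfg
    ),
    class = "sim_dataset"
  )
  list(truth = truth, data = data)
}

#' Ground-truth infection pairs active in a condition
#'
#' Projects the simulator's ground truth onto the set of `(phage_id, mag_id)`
#' pairs active in one condition; this is the oracle used for precision and
#' recall of the link-filtering pipeline.
#'
#' @param truth A `sim_truth` object (from [simulate_community()]).
#' @param condition A condition label present in the truth.
#' @return A tibble with columns `phage_id`, `mag_id` (distinct rows).
#' @export
truth_pair_set <- function(truth, condition) {
  stopifnot(inherits(truth, "sim_truth"))
  known <- unique(truth$hosts$condition)
  if (!condition %in% known) {
    abort(sprintf("Unknown condition '%s'; available: %s.",
                  condition, paste(known, collapse = ", ")))
  }
  truth$infections |>
    filter(.data$condition == !!condition) |>
    distinct(.data$phage_id, .data$mag_id)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset>\n")
  cat(sprintf("  %d entities (%d hosts, %d phages); %d samples\n",
              nrow(x$entities), sum(x$entities$type == "host"),
              sum(x$entities$type == "phage"), nrow(x$samples)))
  cat(sprintf("  %d link-table rows, %d coverage records\n",
              nrow(x$links), nrow(x$coverage_dna)))
  invisible(x)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>\n")
  cat(sprintf("  %d hosts, %d phages, %d infection records\n",
              dplyr::n_distinct(x$hosts$mag_id),
              dplyr::n_distinct(x$phages$phage_id), nrow(x$infections)))
  invisible(x)
}
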