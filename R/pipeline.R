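#' Run the full phage-host inference pipeline
#'
#' Executes catalog -> detection -> linkage -> networks -> statistics on a
#' dataset (a [simulate_community()] result, a `sim_dataset`, or a directory
#' written by [write_sim_dataset()]) and returns a report bundle. The bundle
#' is a pure function of (inputs, parameters, seed); writing it twice
#' produces byte-identical files.
#'
#' @param x Input dataset: the list returned by [simulate_community()], a
#'   bare `sim_dataset`, or a directory path.
#' @param seed Integer seed used by the stochastic network inference.
#' @param outdir Optional directory; when given, [write_report()] is called.
#' @param votu_clusters,mag_derep Optional cluster tables (default: identity
#'   clusters, as appropriate for simulator output where every phage is its
#'   own vOTU and every MAG its own population).
#' @param min_links,min_ratio,min_intra Round-1 thresholds.
#' @param roc_score Score for the second-round threshold scan.
#' @param relative_frac The within-phage relative-count fraction.
#' @param max_host_fraction Promiscuity flagging threshold.
#' @param min_support Replicate support required for the infection network
#'   and downstream summaries.
#' @param breadth_cut Coverage-breadth detection boundary.
#' @param pearson_cutoff,clr_top_edges,rf_top_fraction Co-occurrence network
#'   parameters.
#' @param regression_transform Scale of the VPH-abundance regression.
#' @param var_equal Pooled-variance t-tests instead of Welch.
#' @return A list of class `hic_report`; see Details for elements.
#' @export
run_pipeline <- function(x, seed = 1, outdir = NULL,
                         votu_clusters = NULL, mag_derep = NULL,
                         min_links = 2, min_ratio = 0.1, min_intra = 10,
                         roc_score = "L", relative_frac = 0.8,
                         max_host_fraction = 0.2, min_support = 2,
                         breadth_cut = 0.5, pearson_cutoff = 0.8,
                         clr_top_edges = 200, rf_top_fraction = 0.05,
                         regression_transform = "log10", var_equal = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  ## ---- load ----------------------------------------------------------------
  inp <- stage("load", {
    if (is.character(x)) {
      read_sim_dataset(x)
    } else if (inherits(x, "sim_dataset")) {
      list(truth = NULL, data = x)
    } else if (is.list(x) && inherits(x$data, "sim_dataset")) {
      x
    } else {
      abort("`x` must be a sim_dataset, a simulate_community() result, or a directory.")
    }
  })
  dat <- inp$data
  truth <- inp$truth
  entities <- dat$entities
  viral_ids <- entities$entity_id[entities$type == "phage"]
  host_ids <- entities$entity_id[entities$type == "host"]

  ## ---- catalog -------------------------------------------------------------
  catalog <- stage("catalog", {
    list(
      votu = votu_clusters %||% identity_clusters(viral_ids),
      mag = mag_derep %||% identity_clusters(host_ids)
    )
  })

  ## ---- detect --------------------------------------------------------------
  det <- stage("detect", {
    if (is.null(dat$coverage_dna) || nrow(dat$coverage_dna) == 0) {
      abort("no metagenome coverage table available")
    }
    presence <- call_presence(dat$coverage_dna, breadth_cut = breadth_cut)
    activity <- if (!is.null(dat$coverage_rna) && nrow(dat$coverage_rna)) {
      transcript_activity(dat$coverage_rna, presence)
    }
    abundance <- presence |>
      select("entity_id", "condition", "replicate", "abundance")
    list(presence = presence, activity = activity, abundance = abundance)
  })

  ## ---- link ----------------------------------------------------------------
  link <- stage("link", {
    cands <- build_candidates(dat$links, dat$intra, det$abundance, entities)
    r1 <- round1_filter(cands, min_links = min_links, min_ratio = min_ratio,
                        min_intra = min_intra)
    # the trade-off scan is taken within each Hi-C library (one threshold
    # per replicate sample), matching the per-metagenome filtering unit
    r2 <- r1 |>
      dplyr::group_split(.data$condition, .data$replicate) |>
      purrr::map(function(g) {
        res <- roc_threshold(g, score = roc_score)
        res$survivors |> mutate(roc_threshold = res$threshold)
      }) |>
      bind_rows()
    r3 <- relative_count_filter(r2, frac = relative_frac)
    prom <- promiscuity_adjust(r3, n_mags = length(host_ids),
                               max_host_fraction = max_host_fraction)
    pairs <- collapse_to_pairs(prom$candidates, catalog$votu, catalog$mag)
    list(candidates_all = cands, survivors = prom$candidates,
         promiscuity_report = prom$report, pairs = pairs)
  })

  ## ---- network -------------------------------------------------------------
  net <- stage("network", {
    infection <- build_infection_network(link$pairs,
                                         min_support = min_support)
    mat <- dat$transcripts |>
      select("sample_id", "node_id", "abundance") |>
      tidyr::pivot_wider(names_from = "node_id",
                         values_from = "abundance") |>
      tibble::column_to_rownames("sample_id") |>
      as.matrix()
    node_to_host <- dat$transcripts |>
      distinct(node = .data$node_id, population_id = .data$mag_id)
    hosts_linked <- unique(infection$edges$population_id)
    coocc <- list(
      pearson = pearson_network(mat, cutoff = pearson_cutoff),
      clr = clr_network(mat, top_edges = clr_top_edges),
      rf_importance = rf_importance_network(mat,
                                            top_fraction = rf_top_fraction,
                                            seed = seed)
    )
    cent <- purrr::map(coocc, centrality)
    crossref <- purrr::map(cent, cross_reference_hosts,
                           hosts = hosts_linked,
                           node_to_host = node_to_host)
    list(infection = infection, cooccurrence = coocc, centrality = cent,
         crossref = crossref)
  })

  ## ---- stats ---------------------------------------------------------------
  sts <- stage("stats", {
    conds <- unique(dat$samples$condition)
    supported <- link$pairs |>
      filter(.data$support_count >= min_support)
    host_assoc <- supported |>
      distinct(condition = .data$condition, votu_id = .data$votu_id)
    host_range <- supported |>
      distinct(.data$condition, entity_id = .data$votu_id,
               .data$host_range_class)

    viral_presence <- det$presence |>
      filter(.data$entity_id %in% viral_ids)
    summaries <- purrr::map_dfr(seq_len(nrow(dat$samples)), function(i) {
      s <- dat$samples[i, ]
      pres <- viral_presence |> filter(.data$sample_id == s$sample_id)
      act <- if (!is.null(det$activity)) {
        det$activity |>
          filter(.data$sample_id == s$sample_id,
                 .data$entity_id %in% viral_ids)
      }
      ha <- host_assoc$votu_id[host_assoc$condition == s$condition]
      hr <- host_range |>
        filter(.data$condition == s$condition) |>
        select("entity_id", "host_range_class")
      summarize_sample(pres, act,
                       intersect(ha, pres$entity_id[pres$present]),
                       host_range = hr) |>
        mutate(condition = s$condition, replicate = s$replicate, .before = 1)
    })

    metric_cols <- setdiff(
      names(summaries)[vapply(summaries, is.numeric, TRUE)],
      c("replicate", "n_detected", "n_host_associated", "n_active")
    )
    comparisons <- purrr::map_dfr(metric_cols, function(m) {
      two_group_ttest(
        summaries[[m]][summaries$condition == conds[1]],
        summaries[[m]][summaries$condition == conds[min(2, length(conds))]],
        metric = m, var_equal = var_equal
      )
    })

    vph_tbl <- vph_per_host(link$survivors, catalog$mag) |>
      dplyr::semi_join(
        supported |> distinct(.data$population_id, .data$condition),
        by = c("population_id", "condition")
      )
    vph_by_pop <- vph_tbl |>
      group_by(.data$population_id, .data$condition) |>
      summarise(total_vph = mean(.data$total_vph), .groups = "drop")
    vph_comparison <- two_group_ttest(
      vph_by_pop$total_vph[vph_by_pop$condition == conds[1]],
      vph_by_pop$total_vph[vph_by_pop$condition ==
                             conds[min(2, length(conds))]],
      metric = "total_vph_per_population", var_equal = var_equal
    )

    pop_abund <- det$presence |>
      filter(.data$entity_id %in% host_ids) |>
      left_join(catalog$mag |> select(entity_id = "id",
                                      population_id = "cluster"),
                by = "entity_id") |>
      group_by(.data$population_id, .data$condition) |>
      summarise(abundance = mean(.data$abundance), .groups = "drop")
    reg_data <- vph_by_pop |>
      left_join(pop_abund, by = c("population_id", "condition"))
    regressions <- purrr::map(
      setNames(conds, conds),
      function(cc) {
        sub <- reg_data |> filter(.data$condition == cc, .data$total_vph > 0,
                                  .data$abundance > 0)
        if (nrow(sub) < 3) return(NULL)
        vph_abundance_regression(sub, transform = regression_transform)
      }
    )

    list(summaries = summaries, comparisons = comparisons,
         vph_table = vph_tbl, vph_comparison = vph_comparison,
         regressions = regressions)
  })

  evaluation <- NULL
  if (!is.null(truth)) {
    evaluation <- stage("evaluate", {
      evaluate_against_truth(link$pairs, link$survivors, truth,
                             min_support = min_support)
    })
  }

  manifest <- list(
    package = "phagehic",
    version = as.character(utils::packageVersion("phagehic")),
    seed = seed,
    thresholds = list(
      min_links = min_links, min_ratio = min_ratio, min_intra = min_intra,
      roc_score = roc_score, relative_frac = relative_frac,
      max_host_fraction = max_host_fraction, min_support = min_support,
      breadth_cut = breadth_cut, pearson_cutoff = pearson_cutoff,
      clr_top_edges = clr_top_edges, rf_top_fraction = rf_top_fraction,
      regression_transform = regression_transform,
      t_test = if (var_equal) "pooled" else "welch"
    ),
    n_statistical_tests = nrow(sts$comparisons) + 1
  )

  report <- structure(
    list(manifest = manifest, catalog = catalog,
         presence = det$presence, activity = det$activity,
         candidates = link$candidates_all, survivors = link$survivors,
         promiscuity_report = link$promiscuity_report, pairs = link$pairs,
         infection_network = net$infection,
         cooccurrence = net$cooccurrence, centrality = net$centrality,
         crossref = net$crossref,
         detection_summaries = sts$summaries, comparisons = sts$comparisons,
         vph_table = sts$vph_table, vph_comparison = sts$vph_comparison,
         regressions = sts$regressions, evaluation = evaluation),
    class = "hic_report"
  )
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.hic_report <- function(x, ...) {
  cat("<hic_report>\n")
  cat(sprintf("  %d candidate links -> %d survivors -> %d infection pairs (%d supported)\n",
              nrow(x$candidates), nrow(x$survivors), nrow(x$pairs),
              nrow(x$infection_network$edges)))
  if (!is.null(x$evaluation)) {
    ov <- x$evaluation[x$evaluation$condition == "overall", ]
    cat(sprintf("  vs ground truth: precision %.3f, recall %.3f, Spearman(vph) %.3f\n",
                ov$precision, ov$recall, ov$spearman_vph))
  }
  invisible(x)
}

#' Score detected pairs against simulator ground truth
#'
#' Compares the replicate-supported infection pairs with the ground-truth
#' infection set per condition, and correlates the estimated VPH of true
#' positives with the generative truth. vOTU and population ids must
#' correspond to the truth's phage and MAG ids (the simulator's catalog is
#' the identity, so this holds for simulated data).
#'
#' @param pairs Output of [collapse_to_pairs()].
#' @param cands Surviving candidates (for the VPH estimates).
#' @param truth A `sim_truth`.
#' @param min_support Replicate support defining a detection (default 2).
#' @return A tibble with one row per condition plus an `"overall"` row:
#'   `n_detected`, `n_truth`, `tp`, `precision`, `recall`, `spearman_vph`.
#' @export
evaluate_against_truth <- function(pairs, cands, truth, min_support = 2) {
  conds <- unique(truth$hosts$condition)
  detected <- as_tibble(pairs) |>
    filter(.data$support_count >= min_support) |>
    select(phage_id = "votu_id", mag_id = "population_id", "condition")
  est <- cands |>
    group_by(.data$phage_id, .data$mag_id, .data$condition) |>
    summarise(est_vph = mean(.data$vph), .groups = "drop")

  score_one <- function(det, tru, lab) {
    tp_tbl <- inner_join(det, tru, by = c("phage_id", "mag_id", "condition"))
    tp <- nrow(tp_tbl)
    sp <- NA_real_
    if (tp >= 3) {
      joined <- tp_tbl |>
        left_join(est, by = c("phage_id", "mag_id", "condition")) |>
        left_join(truth$infections,
                  by = c("phage_id", "mag_id", "condition"))
      sp <- suppressWarnings(
        cor(joined$est_vph, joined$true_vph, method = "spearman",
            use = "complete.obs")
      )
    }
    tibble(
      condition = lab, n_detected = nrow(det), n_truth = nrow(tru), tp = tp,
      precision = if (nrow(det)) tp / nrow(det) else NA_real_,
      recall = if (nrow(tru)) tp / nrow(tru) else NA_real_,
      spearman_vph = sp
    )
  }

  per_cond <- purrr::map_dfr(conds, function(cc) {
    score_one(detected |> filter(.data$condition == cc),
              truth_pair_set(truth, cc) |> mutate(condition = cc),
              cc)
  })
  all_truth <- purrr::map_dfr(conds, function(cc) {
    truth_pair_set(truth, cc) |> mutate(condition = cc)
  })
  bind_rows(per_cond, score_one(detected, all_truth, "overall"))
}
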