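#' Write / read a simulated dataset as a directory of TSV files
#'
#' The on-disk layout is plain text and stable:
#' * `links.<condition>.<replicate>.tsv` — columns `entity_a`, `entity_b`,
#'   `links`; rows with `entity_a == entity_b` carry the within-MAG (intra)
#'   link count of that MAG.
#' * `coverage.<sample_id>.tsv` — columns `entity_id`, `assay`
#'   (`dna`/`rna`), `breadth`, `mean_depth`, `library_size`.
#' * `entities.tsv` — `entity_id`, `type`, `length_kb`.
#' * `transcripts.tsv` — long argS proxy table.
#' * `truth.json`, `config.json` — ground truth and generative parameters.
#'
#' @param sim Result of [simulate_community()] (list with `truth` and `data`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim$data, "sim_dataset"))
  dat <- sim$data
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    readr::write_tsv(x, file.path(dir, name), progress = FALSE)
  }
  for (i in seq_len(nrow(dat$samples))) {
    s <- dat$samples[i, ]
    links <- dat$links |>
      filter(.data$condition == s$condition, .data$replicate == s$replicate) |>
      select("entity_a", "entity_b", "links")
    intra <- dat$intra |>
      filter(.data$condition == s$condition, .data$replicate == s$replicate) |>
      dplyr::transmute(entity_a = .data$mag_id, entity_b = .data$mag_id,
                       links = .data$intra_links)
    tsv(bind_rows(links, intra),
        sprintf("links.%s.%d.tsv", s$condition, s$replicate))
    cov <- bind_rows(
      dat$coverage_dna |> filter(.data$sample_id == s$sample_id) |>
        mutate(assay = "dna"),
      dat$coverage_rna |> filter(.data$sample_id == s$sample_id) |>
        mutate(assay = "rna")
    ) |>
      select("entity_id", "assay", "breadth", "mean_depth", "library_size")
    tsv(cov, sprintf("coverage.%s.tsv", s$sample_id))
  }
  tsv(dat$entities, "entities.tsv")
  tsv(dat$transcripts, "transcripts.tsv")
  truth <- sim$truth
  jsonlite::write_json(
    list(hosts = truth$hosts, phages = truth$phages,
         infections = truth$infections),
    file.path(dir, "truth.json"), digits = NA
  )
  cfg <- sim$data$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_sim_dataset
#' @return For `read_sim_dataset()`: a list with `truth` (or `NULL` when no
#'   `truth.json` is present) and `data`, mirroring [simulate_community()].
#' @export
read_sim_dataset <- function(dir) {
  if (!dir.exists(dir)) abort(sprintf("Dataset directory '%s' not found.", dir))
  tsv <- function(name, types) {
    path <- file.path(dir, name)
    if (!file.exists(path)) {
      abort(sprintf("Required table '%s' is missing from '%s'.", name, dir))
    }
    readr::read_tsv(path, col_types = types, progress = FALSE)
  }
  entities <- tsv("entities.tsv", "ccd")
  transcripts <- tsv("transcripts.tsv", "cciccd") |>
    mutate(replicate = as.integer(.data$replicate))

  link_files <- list.files(dir, pattern = "^links\\.")
  if (length(link_files) == 0) {
    abort(sprintf("No link tables (links.*.tsv) found in '%s'.", dir))
  }
  parts <- stringr::str_match(link_files, "^links\\.(.+)\\.(\\d+)\\.tsv$")
  samples <- tibble(condition = parts[, 2],
                    replicate = as.integer(parts[, 3])) |>
    mutate(sample_id = paste0(.data$condition, "_", .data$replicate)) |>
    arrange(match(.data$condition, unique(transcripts$condition)),
            .data$replicate)

  read_one <- function(i) {
    s <- samples[i, ]
    raw <- tsv(sprintf("links.%s.%d.tsv", s$condition, s$replicate), "cci")
    intra <- raw |> filter(.data$entity_a == .data$entity_b)
    links <- raw |> filter(.data$entity_a != .data$entity_b)
    cov <- tsv(sprintf("coverage.%s.tsv", s$sample_id), "ccddd")
    list(
      links = links |> mutate(condition = s$condition, replicate = s$replicate,
                              .before = 1),
      intra = tibble(condition = s$condition, replicate = s$replicate,
                     mag_id = intra$entity_a, intra_links = intra$links),
      cov = cov |> mutate(sample_id = s$sample_id, condition = s$condition,
                          replicate = s$replicate)
    )
  }
  parts_list <- purrr::map(seq_len(nrow(samples)), read_one)
  cov_all <- purrr::map_dfr(parts_list, "cov")
  sel <- c("entity_id", "sample_id", "condition", "replicate",
           "breadth", "mean_depth", "library_size")

  cfg_path <- file.path(dir, "config.json")
  config <- if (file.exists(cfg_path)) {
    jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  }

  data <- structure(
    list(
      entities = entities,
      samples = samples,
      links = purrr::map_dfr(parts_list, "links"),
      intra = purrr::map_dfr(parts_list, "intra"),
      coverage_dna = cov_all |> filter(.data$assay == "dna") |>
        select(dplyr::all_of(sel)),
      coverage_rna = cov_all |> filter(.data$assay == "rna") |>
        select(dplyr::all_of(sel)),
      transcripts = transcripts,
      config = config
    ),
    class = "sim_dataset"
  )

  truth_path <- file.path(dir, "truth.json")
  truth <- NULL
  if (file.exists(truth_path)) {
    raw <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    truth <- structure(
      list(hosts = as_tibble(raw$hosts), phages = as_tibble(raw$phages),
           infections = as_tibble(raw$infections)),
      class = "sim_truth"
    )
  }
  list(truth = truth, data = data)
}
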