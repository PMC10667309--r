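#' Presence calling and normalized abundance from coverage records
#'
#' An entity is positively detected in a sample when more than `breadth_cut`
#' of its genome is covered (strict inequality, so a breadth of exactly 0.50
#' is absent at the default cutoff). Detected entities get a normalized
#' abundance of `mean_depth / library_size * scale`; absent entities get 0.
#'
#' @param records Data frame with one row per (entity, sample) and columns
#'   `entity_id`, `sample_id`, `breadth` (fraction in `[0,1]`), `mean_depth`
#'   (>= 0) and `library_size` (> 0).
#' @param breadth_cut Detection boundary on breadth (default 0.5).
#' @param scale Display constant for the normalized abundance (default 1e6,
#'   i.e. depth per million library reads). All downstream quantities are
#'   ratios and do not depend on it.
#' @return The input tibble with added logical `present` and numeric
#'   `abundance` columns.
#' @export
#' @examples
#' rec <- tibble::tibble(entity_id = c("v1", "v2"), sample_id = "s1",
#'                       breadth = c(0.51, 0.50), mean_depth = c(12, 7),
#'                       library_size = 4e6)
#' call_presence(rec)
call_presence <- function(records, breadth_cut = 0.5, scale = 1e6) {
  records <- as_tibble(records)
  needed <- c("entity_id", "sample_id", "breadth", "mean_depth",
              "library_size")
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    abort(paste0("`records` is missing column(s): ",
                 paste(miss, collapse = ", "), "."))
  }
  if (any(records$breadth < 0 | records$breadth > 1, na.rm = TRUE)) {
    abort("`breadth` must lie in [0, 1].")
  }
  if (any(records$mean_depth < 0, na.rm = TRUE)) {
    abort("`mean_depth` must be non-negative.")
  }
  if (anyDuplicated(records[, c("entity_id", "sample_id")])) {
    abort("Exactly one record per (entity, sample) is required.")
  }
  records |>
    mutate(
      present = .data$breadth > breadth_cut,
      abundance = if_else(
        .data$present,
        normalized_abundance(.data$mean_depth, .data$library_size, scale),
        0
      )
    )
}

#' Normalized abundance of a detected entity
#'
#' `mean_depth / library_size * scale` — mean per-base read depth normalized
#' by the sequencing effort of the sample, scaled for readability.
#'
#' @param mean_depth Mean per-base coverage depth (>= 0).
#' @param library_size Reads in the sample's library (> 0).
#' @param scale Display constant (default 1e6).
#' @return Numeric vector of normalized abundances.
#' @export
#' @examples
#' normalized_abundance(12, 4e6) # 3
normalized_abundance <- function(mean_depth, library_size, scale = 1e6) {
  if (any(library_size <= 0, na.rm = TRUE)) {
    abort("`library_size` must be positive.")
  }
  mean_depth / library_size * scale
}

#' Transcriptional activity from metatranscriptome coverage
#'
#' Restricted to entities already DNA-detected in the same sample (the
#' identity/alignment-fraction read filtering is assumed to have happened
#' upstream of the coverage table). An entity is transcriptionally active
#' when its RNA depth is positive; the activity value is the depth normalized
#' by the metatranscriptome library size.
#'
#' @param records Metatranscriptome coverage records (same columns as
#'   [call_presence()] input).
#' @param dna_presence Output of [call_presence()] on the matching metagenome
#'   records; every RNA record must refer to an entity DNA-present in its
#'   sample.
#' @param scale Display constant (default 1e6).
#' @return The RNA records with added `active` (logical) and `activity`
#'   columns.
#' @export
transcript_activity <- function(records, dna_presence, scale = 1e6) {
  records <- as_tibble(records)
  allowed <- dna_presence |>
    filter(.data$present) |>
    select("entity_id", "sample_id")
  stray <- anti_join(records, allowed, by = c("entity_id", "sample_id"))
  if (nrow(stray) > 0) {
    abort(paste0(
      "RNA coverage supplied for entities not DNA-detected in the same ",
      "sample: ",
      paste(head(paste0(stray$entity_id, "@", stray$sample_id), 5),
            collapse = ", "),
      if (nrow(stray) > 5) sprintf(" (and %d more)", nrow(stray) - 5), "."
    ))
  }
  records |>
    mutate(
      active = .data$mean_depth > 0,
      activity = normalized_abundance(.data$mean_depth, .data$library_size,
                                      scale)
    )
}

#' Per-sample detection summary of host-associated vOTUs
#'
#' Computes, for one sample, the four headline fractions of the detection
#' analysis: relative richness and relative abundance of host-associated
#' vOTUs among all detected vOTUs, the fraction of transcriptionally active
#' vOTUs that are host-associated, and the fraction of transcripts mapping to
#' host-associated vOTUs. When a host-range classification is supplied, the
#' same richness/abundance fractions are also split into multi-host versus
#' one-host vOTUs.
#'
#' Undefined fractions (empty denominators) are explicit `NA`, never 0.
#' Host-associated ids that were not detected in the sample are reported with
#' a warning and excluded from numerators (never silently dropped).
#'
#' @param presence One sample's rows from [call_presence()].
#' @param activity Matching rows from [transcript_activity()], or `NULL` when
#'   no metatranscriptome is available.
#' @param host_associated Character vector of host-associated entity ids.
#' @param host_range Optional data frame `(entity_id, host_range_class)` with
#'   classes `"multiple_hosts"` / `"one_host"`.
#' @return A one-row tibble (class `detection_summary` attributes preserved)
#'   with counts and fractions.
#' @export
summarize_sample <- function(presence, activity = NULL, host_associated,
                             host_range = NULL) {
  presence <- as_tibble(presence)
  sample_id <- unique(presence$sample_id)
  if (length(sample_id) != 1) {
    abort("`presence` must contain exactly one sample.")
  }
  detected <- presence |> filter(.data$present)
  undetected <- setdiff(host_associated, detected$entity_id)
  if (length(undetected) > 0) {
    warn(paste0(
      "Host-associated id(s) not detected in sample ", sample_id, ": ",
      paste(head(undetected, 5), collapse = ", "),
      if (length(undetected) > 5) sprintf(" (and %d more)",
                                          length(undetected) - 5),
      ". They are excluded from the numerators."
    ))
  }
  ha <- intersect(host_associated, detected$entity_id)

  frac <- function(num, den) if (den > 0) num / den else NA_real_

  n_det <- nrow(detected)
  tot_ab <- sum(detected$abundance)
  ha_rows <- detected |> filter(.data$entity_id %in% ha)

  out <- tibble(
    sample_id = sample_id,
    n_detected = n_det,
    n_host_associated = nrow(ha_rows),
    relative_richness = frac(nrow(ha_rows), n_det),
    relative_abundance = frac(sum(ha_rows$abundance), tot_ab)
  )

  if (!is.null(activity)) {
    act <- as_tibble(activity) |> filter(.data$active)
    act_ha <- act |> filter(.data$entity_id %in% ha)
    out$n_active <- nrow(act)
    out$active_fraction_host_associated <- frac(nrow(act_ha), nrow(act))
    out$transcript_fraction_host_associated <-
      frac(sum(act_ha$activity), sum(act$activity))
  }

  if (!is.null(host_range)) {
    hr <- as_tibble(host_range)
    multi <- hr$entity_id[hr$host_range_class == "multiple_hosts"]
    one <- hr$entity_id[hr$host_range_class == "one_host"]
    m_rows <- detected |> filter(.data$entity_id %in% multi)
    o_rows <- detected |> filter(.data$entity_id %in% one)
    out$relative_richness_multi <- frac(nrow(m_rows), n_det)
    out$relative_abundance_multi <- frac(sum(m_rows$abundance), tot_ab)
    out$relative_richness_one <- frac(nrow(o_rows), n_det)
    out$relative_abundance_one <- frac(sum(o_rows$abundance), tot_ab)
  }
  out
}
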