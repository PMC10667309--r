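#' Collapse surviving candidates to unique infection pairs
#'
#' Groups contig-level phage-host candidates into unique
#' (vOTU, dereplicated host population, condition) infection pairs: phage
#' contigs in the same vOTU and host MAGs in the same >= 99%-identity
#' population collapse together. Each pair records the set of replicates in
#' which any member-level candidate was observed, and a host-range class:
#' `"multiple_hosts"` when the vOTU maps to two or more distinct populations
#' in that condition, otherwise `"one_host"`.
#'
#' @param cands Surviving candidate tibble (see [build_candidates()] and the
#'   filter stages).
#' @param votu_clusters Cluster table from [greedy_centroid_cluster()] (or
#'   [identity_clusters()]) assigning every `phage_id`.
#' @param mag_derep Cluster table assigning every `mag_id` to a dereplicated
#'   population.
#' @return A tibble with columns `votu_id`, `population_id`, `condition`,
#'   `replicate_support` (list column of replicate ids), `support_count`,
#'   `host_range_class`.
#' @export
collapse_to_pairs <- function(cands, votu_clusters, mag_derep) {
  vmap <- setNames(votu_clusters$cluster, votu_clusters$id)
  hmap <- setNames(mag_derep$cluster, mag_derep$id)
  miss_v <- setdiff(unique(cands$phage_id), names(vmap))
  miss_h <- setdiff(unique(cands$mag_id), names(hmap))
  if (length(miss_v) || length(miss_h)) {
    abort(paste0(
      "Unassigned id(s): ",
      paste(head(c(miss_v, miss_h), 5), collapse = ", "), "."
    ))
  }
  pairs <- cands |>
    mutate(votu_id = unname(vmap[.data$phage_id]),
           population_id = unname(hmap[.data$mag_id])) |>
    group_by(.data$votu_id, .data$population_id, .data$condition) |>
    summarise(
      replicate_support = list(sort(unique(.data$replicate))),
      support_count = dplyr::n_distinct(.data$replicate),
      .groups = "drop"
    ) |>
    group_by(.data$votu_id, .data$condition) |>
    mutate(host_range_class = if_else(
      dplyr::n_distinct(.data$population_id) >= 2,
      "multiple_hosts", "one_host"
    )) |>
    ungroup() |>
    arrange(.data$condition, .data$votu_id, .data$population_id)
  class(pairs) <- c("infection_pairs", class(pairs))
  pairs
}

#' Total VPH per host population
#'
#' For each dereplicated host population, condition and replicate, sums the
#' estimated VPH over all surviving phages linked to that population's
#' members. Populations with no surviving links are absent from the table
#' (not reported as zero).
#'
#' @param cands Surviving candidate tibble with `vph` computed.
#' @param mag_derep Cluster table assigning every `mag_id` to a population;
#'   defaults to each MAG as its own population.
#' @return A tibble `(population_id, condition, replicate, total_vph,
#'   n_phages)`.
#' @export
vph_per_host <- function(cands, mag_derep = NULL) {
  if (is.null(mag_derep)) {
    mag_derep <- identity_clusters(unique(cands$mag_id))
  }
  hmap <- setNames(mag_derep$cluster, mag_derep$id)
  miss <- setdiff(unique(cands$mag_id), names(hmap))
  if (length(miss)) {
    abort(paste0("Unassigned MAG id(s): ",
                 paste(head(miss, 5), collapse = ", "), "."))
  }
  cands |>
    mutate(population_id = unname(hmap[.data$mag_id])) |>
    group_by(.data$population_id, .data$condition, .data$replicate) |>
    summarise(total_vph = sum(.data$vph),
              n_phages = dplyr::n_distinct(.data$phage_id),
              .groups = "drop")
}
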