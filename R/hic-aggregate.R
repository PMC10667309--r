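#' Aggregate Hi-C read pairs into an entity-level link table
#'
#' Applies the standard proximity-ligation mapping filters — drop PCR
#' duplicates, non-primary/non-unique alignments, pairs with either mapping
#' quality below `min_mapq`, pairs with both ends on the same contig, and
#' contigs at or below `min_contig_kb` — then sums the surviving pairs into
#' entity-level link counts, where an entity is the contig's MAG when binned
#' and the contig itself otherwise (e.g. viral contigs). Pairs joining two
#' *distinct* contigs of the same MAG are counted into that MAG's intra-MAG
#' connectivity instead of the inter-entity table.
#'
#' @param records Data frame with columns `read_id`, `contig_a`, `contig_b`,
#'   `mapq_a`, `mapq_b`, `is_duplicate`, `is_primary_a`, `is_primary_b`.
#' @param contig_meta Data frame with columns `contig_id`, `length_kb` and
#'   `mag_id` (`NA` for unbinned contigs). Every referenced contig must be
#'   present.
#' @param min_mapq Minimum mapping quality on both ends (default 20).
#' @param min_contig_kb Contigs must be strictly longer than this (kb).
#' @return A list with `links` (tibble `entity_a`, `entity_b`, `links`,
#'   unordered pairs stored with `entity_a <= entity_b`) and `intra` (tibble
#'   `mag_id`, `intra_links`).
#' @export
aggregate_read_pairs <- function(records, contig_meta, min_mapq = 20,
                                 min_contig_kb = 1) {
  records <- as_tibble(records)
  contig_meta <- as_tibble(contig_meta)
  used <- unique(c(records$contig_a, records$contig_b))
  unknown <- setdiff(used, contig_meta$contig_id)
  if (length(unknown) > 0) {
    abort(paste0("Contig(s) absent from metadata: ",
                 paste(head(unknown, 5), collapse = ", "), "."))
  }
  meta <- contig_meta |>
    mutate(entity = if_else(is.na(.data$mag_id), .data$contig_id,
                            .data$mag_id))
  look <- function(what, ids) meta[[what]][match(ids, meta$contig_id)]

  kept <- records |>
    filter(
      !.data$is_duplicate,
      .data$is_primary_a, .data$is_primary_b,
      .data$mapq_a >= min_mapq, .data$mapq_b >= min_mapq,
      .data$contig_a != .data$contig_b,
      look("length_kb", .data$contig_a) > min_contig_kb,
      look("length_kb", .data$contig_b) > min_contig_kb
    ) |>
    mutate(entity_a = look("entity", .data$contig_a),
           entity_b = look("entity", .data$contig_b))

  intra_rows <- kept |> filter(.data$entity_a == .data$entity_b)
  inter_rows <- kept |> filter(.data$entity_a != .data$entity_b)

  links <- inter_rows |>
    mutate(a = pmin(.data$entity_a, .data$entity_b),
           b = pmax(.data$entity_a, .data$entity_b)) |>
    dplyr::count(.data$a, .data$b, name = "links") |>
    rename(entity_a = "a", entity_b = "b")

  intra <- intra_rows |>
    dplyr::count(mag_id = .data$entity_a, name = "intra_links")

  list(links = links, intra = intra)
}
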