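#' Call viral contigs by multi-tool voting
#'
#' A contig is classified as viral when at least two of the three detection
#' tools (VirSorter2, VIBRANT, DeepVirFinder) call it viral, or when exactly
#' one tool calls it viral and its CheckV genome quality is complete, high or
#' medium. A tool's sub-threshold score is treated as a "not viral" call.
#'
#' @param votes A data frame with one row per contig and columns `contig_id`,
#'   `virsorter_call`, `vibrant_call`, `deepvirfinder_call` (logical) and
#'   `checkv_quality` (one of `"complete"`, `"high"`, `"medium"`, `"low"`,
#'   `"not-determined"`).
#' @return A tibble with columns `contig_id`, `n_tools` (number of positive
#'   tool calls), `checkv_rescue` (logical) and `viral` (logical). Use
#'   `dplyr::filter(viral)` (or the `$contig_id` of that subset) for the
#'   viral set.
#' @export
#' @examples
#' votes <- tibble::tibble(
#'   contig_id = c("c1", "c2", "c3"),
#'   virsorter_call = c(TRUE, TRUE, FALSE),
#'   vibrant_call = c(TRUE, FALSE, FALSE),
#'   deepvirfinder_call = FALSE,
#'   checkv_quality = c("low", "medium", "complete")
#' )
#' vote_viral_contigs(votes)
vote_viral_contigs <- function(votes) {
  votes <- as_tibble(votes)
  needed <- c("contig_id", "virsorter_call", "vibrant_call",
              "deepvirfinder_call", "checkv_quality")
  missing_cols <- setdiff(needed, names(votes))
  if (length(missing_cols)) {
    abort(paste0("`votes` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (anyDuplicated(votes$contig_id)) {
    dup <- unique(votes$contig_id[duplicated(votes$contig_id)])
    abort(paste0("Duplicate contig_id record(s): ",
                 paste(head(dup, 5), collapse = ", "), "."))
  }
  quality_levels <- c("complete", "high", "medium", "low", "not-determined")
  bad_q <- setdiff(unique(votes$checkv_quality), quality_levels)
  if (length(bad_q)) {
    abort(paste0("Unknown checkv_quality value(s): ",
                 paste(bad_q, collapse = ", "), "."))
  }
  votes |>
    mutate(
      n_tools = as.integer(.data$virsorter_call) +
        as.integer(.data$vibrant_call) + as.integer(.data$deepvirfinder_call),
      checkv_rescue = .data$n_tools == 1L &
        .data$checkv_quality %in% c("complete", "high", "medium"),
      viral = .data$n_tools >= 2L | .data$checkv_rescue
    ) |>
    select("contig_id", "n_tools", "checkv_rescue", "viral")
}
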