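#' Match CRISPR spacers against viral contigs
#'
#' A hit is a full-length, ungapped alignment of a spacer on either strand of
#' a viral contig with at most one mismatch *and* at least 95% identity
#' (so a single mismatch only qualifies for spacers of 20 nt or more). Per
#' spacer only the single best target is reported: fewest mismatches, ties
#' broken by the longest contig, then lexicographically by contig id for
#' determinism.
#'
#' @param spacers Data frame with columns `spacer_id`, `mag_id`, `sequence`
#'   (A/C/G/T only).
#' @param viral_seqs A [Biostrings::DNAStringSet], a named character vector of
#'   sequences, or the path to a FASTA file.
#' @param max_mismatch Maximum mismatches allowed in a hit.
#' @param min_identity Minimum full-length identity (fraction).
#' @param min_spacer_length Spacers shorter than this are rejected.
#' @return A tibble of best hits with columns `mag_id`, `contig_id`,
#'   `spacer_id`, `mismatches`, `identity`, `strand`. Reduce with
#'   `dplyr::distinct(mag_id, contig_id)` for unique phage-host links.
#' @export
#' @examples
#' contigs <- c(v1 = "ACGTACGTACGTACGTACGTACGTACGTACGT")
#' spacers <- tibble::tibble(spacer_id = "s1", mag_id = "B001",
#'                           sequence = "ACGTACGTACGTACGTACGT")
#' match_crispr_spacers(spacers, contigs)
match_crispr_spacers <- function(spacers, viral_seqs, max_mismatch = 1,
                                 min_identity = 0.95,
                                 min_spacer_length = 18) {
  spacers <- as_tibble(spacers)
  if (!all(c("spacer_id", "mag_id", "sequence") %in% names(spacers))) {
    abort("`spacers` needs columns `spacer_id`, `mag_id`, `sequence`.")
  }
  if (is.character(viral_seqs) && length(viral_seqs) == 1 &&
      is.null(names(viral_seqs)) && file.exists(viral_seqs)) {
    viral_seqs <- Biostrings::readDNAStringSet(viral_seqs)
  }
  if (!methods::is(viral_seqs, "DNAStringSet")) {
    viral_seqs <- Biostrings::DNAStringSet(viral_seqs)
  }
  if (length(viral_seqs) == 0) abort("`viral_seqs` must be non-empty.")
  if (is.null(names(viral_seqs)) || any(names(viral_seqs) == "")) {
    abort("All viral sequences must be named (contig ids).")
  }

  if (any(grepl("[^ACGT]", spacers$sequence))) {
    abort("Spacer sequences must be over {A, C, G, T}.")
  }
  too_short <- nchar(spacers$sequence) < min_spacer_length
  if (any(too_short)) {
    abort(sprintf(
      "%d spacer(s) shorter than the %d nt minimum: %s.",
      sum(too_short), min_spacer_length,
      paste(head(spacers$spacer_id[too_short], 5), collapse = ", ")
    ))
  }

  contig_len <- Biostrings::width(viral_seqs)
  names(contig_len) <- names(viral_seqs)

  best_hit <- function(seq) {
    pat_f <- Biostrings::DNAString(seq)
    pat_r <- Biostrings::reverseComplement(pat_f)
    len <- nchar(seq)
    # mismatch budget compatible with both the mismatch cap and the identity
    # floor; for an 18-19 nt spacer this forces an exact match
    budget <- min(max_mismatch, floor((1 - min_identity) * len))
    hits <- purrr::map_dfr(names(viral_seqs), function(cid) {
      subj <- viral_seqs[[cid]]
      mm_at <- function(pat) {
        for (m in 0:budget) {
          if (Biostrings::countPattern(pat, subj, max.mismatch = m) > 0) {
            return(m)
          }
        }
        NA_integer_
      }
      mf <- mm_at(pat_f)
      mr <- mm_at(pat_r)
      if (is.na(mf) && is.na(mr)) return(NULL)
      strand <- if (!is.na(mf) && (is.na(mr) || mf <= mr)) "+" else "-"
      mm <- min(mf, mr, na.rm = TRUE)
      tibble(contig_id = cid, mismatches = as.integer(mm),
             identity = (len - mm) / len, strand = strand,
             contig_length = contig_len[[cid]])
    })
    if (nrow(hits) == 0) return(NULL)
    hits |>
      arrange(.data$mismatches, -.data$contig_length, .data$contig_id) |>
      dplyr::slice(1)
  }

  out <- purrr::map_dfr(seq_len(nrow(spacers)), function(i) {
    hit <- best_hit(spacers$sequence[i])
    if (is.null(hit)) return(NULL)
    bind_cols(spacers[i, c("mag_id", "spacer_id")], hit)
  })
  if (nrow(out) == 0) {
    return(tibble(mag_id = character(), contig_id = character(),
                  spacer_id = character(), mismatches = integer(),
                  identity = double(), strand = character()))
  }
  out |>
    select("mag_id", "contig_id", "spacer_id", "mismatches",
           "identity", "strand")
}

#' Compare two phage-host link sets
#'
#' Set arithmetic over two collections of phage-host pairs keyed at the same
#' level (e.g. Hi-C detected pairs versus CRISPR spacer predictions).
#'
#' @param hic_pairs,crispr_pairs Data frames whose first two columns are the
#'   pair keys; both must carry identical column names (the declared key
#'   level).
#' @return A one-row tibble with `n_hic`, `n_crispr`, `n_overlap`, `jaccard`
#'   (`NA` when both sets are empty).
#' @export
compare_link_sets <- function(hic_pairs, crispr_pairs) {
  a <- as_tibble(hic_pairs)
  b <- as_tibble(crispr_pairs)
  if (ncol(a) < 2 || ncol(b) < 2) {
    abort("Both link sets need at least two key columns.")
  }
  a <- a[, 1:2]
  b <- b[, 1:2]
  if (!identical(names(a), names(b))) {
    abort(sprintf(
      "Mismatched key levels: (%s) vs (%s). Collapse both sets to a common level first.",
      paste(names(a), collapse = ", "), paste(names(b), collapse = ", ")
    ))
  }
  a <- distinct(a)
  b <- distinct(b)
  ov <- nrow(inner_join(a, b, by = names(a)))
  uni <- nrow(distinct(bind_rows(a, b)))
  tibble(
    n_hic = nrow(a), n_crispr = nrow(b), n_overlap = ov,
    jaccard = if (uni == 0) NA_real_ else ov / uni
  )
}
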