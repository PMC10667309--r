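#' Round-1 quality filter on phage-host candidates
#'
#' Keeps candidates with at least `min_links` Hi-C links to the host, a
#' connectivity ratio R' of at least `min_ratio`, and an intra-MAG
#' connectivity of at least `min_intra` links. All three thresholds are
#' inclusive. Counts are never mutated; per-criterion pass flags for every
#' input row are available as the `"audit"` attribute of the result.
#'
#' @param cands Candidate tibble (see [build_candidates()]) with `vph` and
#'   `r_prime` computed.
#' @param min_links,min_ratio,min_intra Inclusive thresholds (defaults 2,
#'   0.1, 10).
#' @return The surviving candidates; `attr(x, "audit")` holds all input rows
#'   with logical `flag_min_links`, `flag_ratio`, `flag_intra` columns.
#' @export
round1_filter <- function(cands, min_links = 2, min_ratio = 0.1,
                          min_intra = 10) {
  # the ratio threshold is inclusive; a hair of floating-point slack keeps
  # candidates that sit exactly on the boundary algebraically
  ratio_tol <- 1e-9 * max(min_ratio, 1)
  audit <- cands |>
    mutate(
      flag_min_links = .data$L >= min_links,
      flag_ratio = !is.na(.data$r_prime) &
        .data$r_prime >= min_ratio - ratio_tol,
      flag_intra = .data$intra >= min_intra
    )
  out <- audit |>
    filter(.data$flag_min_links, .data$flag_ratio, .data$flag_intra) |>
    select(-dplyr::starts_with("flag_"))
  attr(out, "audit") <- audit
  out
}

#' Second-round threshold from a retention/removal trade-off scan
#'
#' Scans every observed score value t as a candidate threshold and evaluates
#' `f(t)`, the fraction of phages that would still retain at least one host
#' at score >= t, and `g(t)`, the fraction of links removed. The selected
#' threshold maximizes `f(t) + g(t)` — the most links removed while keeping
#' the most phages host-assigned; ties (within 1e-9, absorbing floating-point
#' noise in the two fractions) resolve to the smallest threshold.
#'
#' @param cands Non-empty candidate tibble.
#' @param score Column used as the score (default `"r_prime"`, `"L"`
#'   selectable).
#' @return A list of class `roc_threshold` with elements `threshold`,
#'   `survivors` (candidates at score >= threshold), and `scan` (tibble of
#'   `threshold`, `f`, `g`, `objective` over all scanned values).
#' @export
roc_threshold <- function(cands, score = "r_prime") {
  if (nrow(cands) == 0) abort("`cands` must be non-empty.")
  if (!score %in% names(cands)) {
    abort(sprintf("Score column '%s' not found.", score))
  }
  s <- cands[[score]]
  if (any(is.na(s))) abort("Score column contains NA.")
  phage <- cands$phage_id
  n_phage <- dplyr::n_distinct(phage)
  n_links <- length(s)

  ts <- sort(unique(s))
  scan <- purrr::map_dfr(ts, function(t) {
    keep <- s >= t
    tibble(
      threshold = t,
      f = dplyr::n_distinct(phage[keep]) / n_phage,
      g = sum(!keep) / n_links
    )
  }) |>
    mutate(objective = .data$f + .data$g)

  best <- scan$threshold[
    which(scan$objective > max(scan$objective) - 1e-9)[1] # tie -> smallest t
  ]
  out <- list(threshold = best,
              survivors = cands[s >= best, , drop = FALSE],
              scan = scan)
  class(out) <- "roc_threshold"
  out
}

#' @export
print.roc_threshold <- function(x, ...) {
  at <- x$scan[x$scan$threshold == x$threshold, ]
  cat(sprintf(
    "<roc_threshold> t = %g; %d candidate(s) retained (f = %.3f, g = %.3f)\n",
    x$threshold, nrow(x$survivors), at$f, at$g
  ))
  invisible(x)
}

#' Relative link-count filter within each phage (the 80% rule)
#'
#' Within each phage's group of linked hosts, drops the links whose
#' replicate-averaged count is *less than* `frac` times the highest
#' replicate-averaged count of that phage (strict inequality: a link at
#' exactly 80% of the maximum is kept). When a (phage, host) pair appears in
#' several replicates its count is the mean over the replicates in which it
#' appears; groups are formed per condition when a `condition` column is
#' present.
#'
#' @param cands Candidate tibble.
#' @param frac Fraction of the per-phage maximum (default 0.8).
#' @return Surviving candidates; the per-pair averages and keep decisions are
#'   attached as the `"audit"` attribute.
#' @export
relative_count_filter <- function(cands, frac = 0.8) {
  if (nrow(cands) == 0) return(cands)
  grp <- intersect(c("condition", "phage_id"), names(cands))
  pair_grp <- c(grp, "mag_id")
  avg <- cands |>
    group_by(dplyr::across(dplyr::all_of(pair_grp))) |>
    summarise(avg_L = mean(.data$L), .groups = "drop_last") |>
    mutate(keep = .data$avg_L >= frac * max(.data$avg_L)) |>
    ungroup()
  out <- cands |>
    inner_join(avg |> filter(.data$keep) |> select(-"avg_L", -"keep"),
               by = pair_grp)
  attr(out, "audit") <- avg
  out
}

#' Flag and remove promiscuously linked phages
#'
#' Phages linked to more than `max_host_fraction` of all MAGs in a replicate
#' are characteristic of spurious, false-positive-rich sequences (e.g.
#' mobile elements). They are always flagged in the report; under the
#' default policy (`remove = TRUE`) their candidates are also removed.
#'
#' @param cands Candidate tibble.
#' @param n_mags Total number of MAGs per replicate: a single number, or a
#'   tibble `(condition, replicate, n_mags)`.
#' @param max_host_fraction Flagging threshold (default 0.2; 1.0 disables).
#' @param remove Whether flagged phages are removed (default `TRUE`).
#' @return A list with `candidates` (filtered when `remove`) and `report`
#'   (tibble `condition`, `replicate`, `phage_id`, `n_hosts`, `host_fraction`,
#'   `flagged`).
#' @export
promiscuity_adjust <- function(cands, n_mags, max_host_fraction = 0.2,
                               remove = TRUE) {
  if (nrow(cands) == 0) {
    return(list(candidates = cands, report = tibble()))
  }
  rep_grp <- intersect(c("condition", "replicate"), names(cands))
  report <- cands |>
    group_by(dplyr::across(dplyr::all_of(c(rep_grp, "phage_id")))) |>
    summarise(n_hosts = dplyr::n_distinct(.data$mag_id), .groups = "drop")
  if (is.data.frame(n_mags)) {
    report <- report |> left_join(as_tibble(n_mags), by = rep_grp)
  } else {
    report$n_mags <- n_mags
  }
  report <- report |>
    mutate(host_fraction = .data$n_hosts / .data$n_mags,
           flagged = .data$host_fraction > max_host_fraction)
  out <- cands
  if (remove) {
    bad <- report |> filter(.data$flagged) |>
      select(dplyr::all_of(c(rep_grp, "phage_id")))
    out <- anti_join(cands, bad, by = c(rep_grp, "phage_id"))
  }
  list(candidates = out, report = report)
}
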