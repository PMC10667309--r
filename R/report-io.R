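#' Write a pipeline report bundle to disk
#'
#' Emits every result table as TSV, the run manifest (versions, seed,
#' thresholds) as JSON, and a human-readable `summary.txt`. The output is a
#' pure function of the report: re-writing the same report produces
#' byte-identical files (no timestamps).
#'
#' @param report An `hic_report` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "hic_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    if (!is.null(x) && nrow(x) > 0) {
      readr::write_tsv(x, file.path(outdir, name), progress = FALSE)
    }
  }
  tsv(report$candidates, "candidates.tsv")
  tsv(report$survivors, "survivors.tsv")
  tsv(report$promiscuity_report, "promiscuity_report.tsv")
  pairs_flat <- as_tibble(report$pairs) |>
    mutate(replicate_support = purrr::map_chr(
      .data$replicate_support, paste, collapse = ","
    ))
  tsv(pairs_flat, "infection_pairs.tsv")
  tsv(report$infection_network$edges, "infection_network_edges.tsv")
  for (m in names(report$centrality)) {
    tsv(report$centrality[[m]], sprintf("centrality_%s.tsv", m))
    tsv(report$cooccurrence[[m]]$edges, sprintf("network_%s_edges.tsv", m))
  }
  tsv(report$detection_summaries, "detection_summaries.tsv")
  tsv(report$comparisons, "comparisons.tsv")
  tsv(report$vph_table, "vph_per_host.tsv")
  tsv(tidy(report$vph_comparison), "vph_comparison.tsv")
  reg <- purrr::imap_dfr(report$regressions, function(r, cc) {
    if (is.null(r)) return(NULL)
    glance(r) |> mutate(condition = cc, .before = 1)
  })
  tsv(reg, "regressions.tsv")
  if (!is.null(report$evaluation)) tsv(report$evaluation, "evaluation.tsv")
  jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  lines <- c(
    "phage-host Hi-C pipeline report",
    "===============================",
    sprintf("candidates: %d; survivors after filtering: %d",
            nrow(report$candidates), nrow(report$survivors)),
    sprintf("infection pairs: %d (%d with replicate support >= %d)",
            nrow(report$pairs), nrow(report$infection_network$edges),
            report$manifest$thresholds$min_support),
    "",
    "pre/post comparisons (p-values):",
    sprintf("  %-40s p = %s", report$comparisons$metric,
            formatC(report$comparisons$p, digits = 3, format = "g")),
    sprintf("  %-40s p = %s", "total VPH per host population",
            formatC(report$vph_comparison$p, digits = 3, format = "g")),
    "",
    "VPH ~ host abundance regressions:",
    unlist(purrr::imap(report$regressions, function(r, cc) {
      if (is.null(r)) return(sprintf("  %s: insufficient data", cc))
      g <- glance(r)
      sprintf("  %s: slope = %.4g (adj R^2 = %.3f, p = %.3g, n = %d)",
              cc, g$slope, g$adj_r_squared, g$p_value, g$n)
    }))
  )
  if (!is.null(report$evaluation)) {
    ov <- report$evaluation[report$evaluation$condition == "overall", ]
    lines <- c(lines, "",
               sprintf("ground-truth recovery: precision %.3f, recall %.3f, Spearman(VPH) %.3f",
                       ov$precision, ov$recall, ov$spearman_vph))
  }
  writeLines(lines, file.path(outdir, "summary.txt"))
  invisible(outdir)
}
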