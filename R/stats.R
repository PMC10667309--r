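#' Two-sided two-group t-test of a metric between conditions
#'
#' Welch's unequal-variance t-test by default, with a pooled-variance option
#' for sensitivity analyses. Degenerate zero-variance groups are handled
#' explicitly: identical constant groups give `t = 0, p = 1`; separated
#' constant groups give `p = 0`. Groups with fewer than two finite values
#' yield an explicit all-`NA` result rather than an error.
#'
#' @param pre,post Numeric vectors of per-replicate values for the two
#'   groups.
#' @param metric Optional metric name carried into the result.
#' @param var_equal Use the pooled-variance test (default `FALSE` = Welch).
#' @param alpha Significance level for the flag (default 0.05).
#' @return A one-row tibble of class `group_comparison`: `metric`, `n_pre`,
#'   `n_post`, `mean_pre`, `mean_post`, `estimate` (post - pre), `t`, `df`,
#'   `p`, `significant`, `method`.
#' @export
#' @examples
#' two_group_ttest(c(0.10, 0.12, 0.11), c(0.18, 0.21, 0.20), "rel_richness")
two_group_ttest <- function(pre, post, metric = NA_character_,
                            var_equal = FALSE, alpha = 0.05) {
  pre <- pre[is.finite(pre)]
  post <- post[is.finite(post)]
  method <- if (var_equal) "pooled t-test" else "Welch t-test"
  base <- tibble(
    metric = metric, n_pre = length(pre), n_post = length(post),
    mean_pre = if (length(pre)) mean(pre) else NA_real_,
    mean_post = if (length(post)) mean(post) else NA_real_,
    estimate = NA_real_, t = NA_real_, df = NA_real_, p = NA_real_,
    significant = NA, method = method
  )
  if (length(pre) < 2 || length(post) < 2) {
    inform("Fewer than two finite values in a group; returning NA result.")
    class(base) <- c("group_comparison", class(base))
    return(base)
  }
  base$estimate <- mean(post) - mean(pre)
  if (sd(pre) == 0 && sd(post) == 0) {
    # degenerate: no within-group variance at all
    if (mean(pre) == mean(post)) {
      base$t <- 0
      base$p <- 1
    } else {
      base$t <- sign(mean(post) - mean(pre)) * Inf
      base$p <- 0
    }
    base$significant <- base$p < alpha
  } else {
    tt <- t.test(post, pre, var.equal = var_equal,
                 alternative = "two.sided")
    base$t <- unname(tt$statistic)
    base$df <- unname(tt$parameter)
    base$p <- tt$p.value
    base$significant <- tt$p.value < alpha
  }
  class(base) <- c("group_comparison", class(base))
  base
}

#' Regression of VPH on host abundance
#'
#' Ordinary least squares of (transformed) total VPH on (transformed) host
#' abundance, the model behind the lytic-pressure analysis: a significant
#' negative slope before drying indicates that heavier phage burdens depress
#' host abundance. Defaults to log10-log10 axes; the transform is recorded
#' in the result.
#'
#' @param data Data frame of paired observations.
#' @param vph,abundance Column names (strings) of the VPH and host-abundance
#'   variables (defaults `"total_vph"`, `"abundance"`).
#' @param transform `"log10"` (default) or `"identity"`. Non-positive values
#'   under the log transform abort with an itemized report.
#' @param conf_level Confidence level for the slope interval (default 0.95).
#' @return An object of class `vph_regression` wrapping the `lm` fit; use
#'   [tidy()], [glance()] or [autoplot()] on it.
#' @export
vph_abundance_regression <- function(data, vph = "total_vph",
                                     abundance = "abundance",
                                     transform = c("log10", "identity"),
                                     conf_level = 0.95) {
  transform <- match.arg(transform)
  data <- as_tibble(data)
  for (col in c(vph, abundance)) {
    if (!col %in% names(data)) {
      abort(sprintf("Column '%s' not found in `data`.", col))
    }
  }
  y <- data[[vph]]
  x <- data[[abundance]]
  ok <- is.finite(y) & is.finite(x)
  if (transform == "log10") {
    bad <- ok & (y <= 0 | x <= 0)
    if (any(bad)) {
      abort(paste0(
        "log10 transform requires positive values; offending row(s): ",
        paste(head(which(bad), 10), collapse = ", "),
        sprintf(" (%d in total). Use transform = \"identity\" or filter.",
                sum(bad))
      ))
    }
    y <- log10(y)
    x <- log10(x)
  }
  y <- y[ok]
  x <- x[ok]
  if (length(y) < 3) abort("At least 3 finite pairs are required.")
  df <- data.frame(x = x, y = y)
  fit <- lm(y ~ x, data = df)
  structure(
    list(model = fit, transform = transform, n = length(y),
         conf_level = conf_level, data = df,
         vars = c(vph = vph, abundance = abundance)),
    class = "vph_regression"
  )
}

#' @export
print.vph_regression <- function(x, ...) {
  g <- glance(x)
  cat("<vph_regression>", x$transform, "scale,", x$n, "points\n")
  cat(sprintf("  slope = %.4g [%.4g, %.4g], adj R^2 = %.3f, F-test p = %.3g\n",
              g$slope, g$conf_low, g$conf_high, g$adj_r_squared, g$p_value))
  invisible(x)
}
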