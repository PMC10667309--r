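#' Tidy a VPH-abundance regression
#'
#' @param x A `vph_regression` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`, `conf_low`, `conf_high`.
#' @method tidy vph_regression
#' @export
tidy.vph_regression <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  ci <- confint(x$model, level = x$conf_level)
  tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p_value = unname(sm[, "Pr(>|t|)"]),
    conf_low = unname(ci[, 1]),
    conf_high = unname(ci[, 2])
  )
}

#' One-row summary of a VPH-abundance regression
#'
#' @param x A `vph_regression` object.
#' @param ... Unused.
#' @return A one-row tibble: `slope`, `intercept`, `adj_r_squared`,
#'   `r_squared`, `p_value` (overall F-test), `conf_low`/`conf_high` (slope
#'   interval at the object's confidence level), `n`, `transform`.
#' @method glance vph_regression
#' @export
glance.vph_regression <- function(x, ...) {
  sm <- summary(x$model)
  fstat <- sm$fstatistic
  p_f <- if (is.null(fstat)) NA_real_ else
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  ci <- confint(x$model, "x", level = x$conf_level)
  tibble(
    slope = unname(coef(x$model)["x"]),
    intercept = unname(coef(x$model)["(Intercept)"]),
    adj_r_squared = sm$adj.r.squared,
    r_squared = sm$r.squared,
    p_value = p_f,
    conf_low = ci[1, 1],
    conf_high = ci[1, 2],
    n = x$n,
    transform = x$transform
  )
}

#' @rdname tidy.vph_regression
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Scatter plot of a VPH-abundance regression with its confidence band
#'
#' @param object A `vph_regression` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vph_regression
#' @export
autoplot.vph_regression <- function(object, ...) {
  lab <- if (object$transform == "log10") {
    c(x = paste0("log10 ", object$vars[["abundance"]]),
      y = paste0("log10 ", object$vars[["vph"]]))
  } else {
    c(x = object$vars[["abundance"]], y = object$vars[["vph"]])
  }
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                         level = object$conf_level, colour = "steelblue") +
    ggplot2::labs(x = lab[["x"]], y = lab[["y"]]) +
    ggplot2::theme_minimal()
}

#' Bipartite plot of an infection network
#'
#' vOTUs and host populations on two rows, edges weighted by replicate
#' support and coloured by condition.
#'
#' @param object An `infection_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot infection_network
#' @export
autoplot.infection_network <- function(object, ...) {
  nodes <- object$nodes |>
    group_by(.data$type) |>
    mutate(x = seq_len(n()) / (n() + 1),
           y = if_else(.data$type == "votu", 1, 0)) |>
    ungroup()
  pos <- nodes |> select("node", "x", "y")
  edges <- object$edges |>
    left_join(pos, by = c(votu_id = "node")) |>
    rename(x_from = "x", y_from = "y") |>
    left_join(pos, by = c(population_id = "node")) |>
    rename(x_to = "x", y_to = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x_from, y = .data$y_from, xend = .data$x_to,
                   yend = .data$y_to, colour = .data$condition,
                   linewidth = .data$support_count),
      alpha = 0.6
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$type), size = 3
    ) +
    ggplot2::scale_linewidth_continuous(range = c(0.3, 1.5)) +
    ggplot2::scale_y_continuous(breaks = c(0, 1),
                                labels = c("host populations", "vOTUs")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Boxplot of per-host VPH by condition
#'
#' @param vph_table Output of [vph_per_host()].
#' @return A ggplot object.
#' @export
plot_vph_comparison <- function(vph_table) {
  ggplot2::ggplot(vph_table,
                  ggplot2::aes(x = .data$condition, y = .data$total_vph,
                               fill = .data$condition)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "total VPH per host population") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
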