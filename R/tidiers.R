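#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a test result
#'
#' @param x A test-result tibble (as returned by [welch_t()] and friends).
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `p.value`, `method`.
#' @export
tidy.tx_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, method = x$method)
}

#' @rdname tidy.tx_test
#' @export
glance.tx_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, method = x$method,
         n.a = x$n_a, n.b = x$n_b, seed = x$seed, degenerate = x$degenerate)
}

#' Tidy a fitted wave HMM
#'
#' @param x A `wave_hmm` object.
#' @param ... Unused.
#' @return One row per parameter (`term`, `estimate`).
#' @export
tidy.wave_hmm <- function(x, ...) {
  tibble(term = c("lambda_on", "lambda_off", "p_stay_on"),
         estimate = c(x$lambda_on, x$lambda_off, x$p_stay_on))
}

#' @rdname tidy.wave_hmm
#' @export
glance.wave_hmm <- function(x, ...) {
  tibble(logLik = x$loglik[length(x$loglik)], n.iter = x$n_iter,
         converged = x$converged, n.genes = x$n_genes, n.bins = x$n_bins)
}

#' Tidy a wave-speed fit
#'
#' @param x A `wave_speed` object (see [estimate_speed()]).
#' @param ... Unused.
#' @return The `lm` coefficient table as a tibble (`term`, `estimate`,
#'   `std.error`).
#' @export
tidy.wave_speed <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(term = c("intercept_kb", "speed_kb_min"),
         estimate = as.numeric(cf[, 1]), std.error = as.numeric(cf[, 2]))
}

#' @rdname tidy.wave_speed
#' @export
glance.wave_speed <- function(x, ...) {
  tibble(speed = x$speed, intercept = x$intercept,
         n.timepoints = x$n_timepoints, r.squared = summary(x$fit)$r.squared,
         cell_line = x$cell_line, condition = x$condition)
}

#' Plot a Vplot as a filled raster
#'
#' @param object A `vplot` object.
#' @param trans Transformation applied to cell values before plotting
#'   (default `"sqrt"` to tame the dynamic range; use `"identity"` for raw).
#' @param ... Unused.
#' @return A ggplot object: fragment size against midpoint offset, fill =
#'   accumulated signal; the mononucleosome band appears near 147 bp.
#' @export
autoplot.vplot <- function(object, trans = "sqrt", ...) {
  df <- as.data.frame.table(object$matrix, responseName = "value")
  df$size <- as.integer(as.character(df$size))
  df$offset <- as.integer(as.character(df$offset))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$size,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans) +
    ggplot2::labs(x = "midpoint offset from dyad (bp)",
                  y = "fragment size (bp)",
                  fill = object$normalization) +
    ggplot2::theme_minimal()
}

#' Plot per-timepoint wave-front medians with quartile ribbons
#'
#' @param summaries Output of [wave_summary()], optionally with a
#'   `cell_line` column for colouring.
#' @return A ggplot object (front position in kb against time in minutes).
#' @export
plot_wave_progression <- function(summaries) {
  aes_base <- if ("cell_line" %in% names(summaries)) {
    ggplot2::aes(x = .data$timepoint, y = .data$median_bp / 1000,
                 colour = .data$cell_line, fill = .data$cell_line)
  } else {
    ggplot2::aes(x = .data$timepoint, y = .data$median_bp / 1000)
  }
  ggplot2::ggplot(summaries, aes_base) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1_bp / 1000,
                                      ymax = .data$q3_bp / 1000),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time (min)", y = "wave front (kb from TSS)") +
    ggplot2::theme_minimal()
}

#' Boxplot of retention ratios by timepoint and cell line
#'
#' @param retention A tibble with `retention`, `timepoint`, and `cell_line`
#'   columns (e.g. bound rows of [compute_retention()] results).
#' @return A ggplot object.
#' @export
plot_retention <- function(retention) {
  ggplot2::ggplot(retention,
                  ggplot2::aes(x = factor(.data$timepoint),
                               y = .data$retention,
                               fill = .data$cell_line)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::labs(x = "chase time (h)", y = "retention ratio",
                  fill = "cell line") +
    ggplot2::theme_minimal()
}

#' Density plot of per-gene EI values by condition
#'
#' @param ei A tibble with `ei` and a `condition` column (e.g. bound rows of
#'   [compute_ei()] results).
#' @return A ggplot object on a log10 x-axis.
#' @export
plot_ei_distribution <- function(ei) {
  ggplot2::ggplot(ei, ggplot2::aes(x = .data$ei, colour = .data$condition)) +
    ggplot2::geom_density() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "escape index (EI)", y = "density") +
    ggplot2::theme_minimal()
}
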