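#' Tidy a dispersion fit
#'
#' @param x A `"dispersion_fit"`.
#' @param ... Unused.
#' @return One row per parameter (`a`, `b`) with estimate, standard error,
#'   t statistic and p-value from the underlying regression (standard
#'   errors are `NA` for manually specified fits).
#' @export
tidy.dispersion_fit <- function(x, ...) {
  if (is.null(x$lm)) {
    return(tibble(term = c("a", "b"), estimate = c(x$a, x$b),
                  std.error = NA_real_, statistic = NA_real_,
                  p.value = NA_real_))
  }
  cf <- summary(x$lm)$coefficients
  tibble(term = c("a", "b"), estimate = cf[, 1], std.error = cf[, 2],
         statistic = cf[, 3], p.value = cf[, 4])
}

#' @rdname tidy.dispersion_fit
#' @export
glance.dispersion_fit <- function(x, ...) {
  if (is.null(x$lm)) {
    return(tibble(a = x$a, b = x$b, n_snps_used = x$n_snps_used, s = x$s,
                  r.squared = NA_real_, sigma = NA_real_))
  }
  sm <- summary(x$lm)
  tibble(a = x$a, b = x$b, n_snps_used = x$n_snps_used, s = x$s,
         r.squared = sm$r.squared, sigma = sm$sigma)
}

#' @rdname tidy.dispersion_fit
#' @param object A `"dispersion_fit"`.
#' @export
autoplot.dispersion_fit <- function(object, ...) {
  if (!nrow(object$per_snp)) abort("nothing to plot for a manually specified fit.")
  ggplot2::ggplot(object$per_snp, ggplot2::aes(x = .data$x, y = .data$z)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(intercept = object$a, slope = object$b, colour = "red") +
    ggplot2::labs(
      x = "depth regressor ((R - 1)/s scale)",
      y = "per-SNP dispersion statistic",
      title = sprintf("Over-dispersion fit: a = %.3f, b = %.3f", object$a, object$b))
}

#' Tidy an EB1 fit
#'
#' @param x An `"eb1_fit"` from [fit_eb1()].
#' @param ... Unused.
#' @export
tidy.eb1_fit <- function(x, ...) {
  tibble(term = c("phi", "beta_case"), estimate = c(x$phi, x$beta))
}

#' @rdname tidy.eb1_fit
#' @export
glance.eb1_fit <- function(x, ...) {
  tibble(phi = x$phi, X2_full = x$X2_full, X2_null = x$X2_null,
         statistic = x$statistic, df = 1L, p.value = x$p_value,
         iterations = x$iterations, converged = x$converged)
}

#' Tidy a Q-Q summary
#'
#' @param x A `"qq_summary"`.
#' @param ... Unused.
#' @return `tidy()`: the quantile table; `glance()`: one row with slope,
#'   maximum observed value, n and the count of underflow-capped p-values.
#' @export
tidy.qq_summary <- function(x, ...) x$quantiles

#' @rdname tidy.qq_summary
#' @export
glance.qq_summary <- function(x, ...) {
  tibble(slope = x$slope, max_observed = x$max_observed,
         n = x$n, n_capped = x$n_capped)
}

#' @rdname tidy.qq_summary
#' @param object A `"qq_summary"`.
#' @export
autoplot.qq_summary <- function(object, ...) {
  ggplot2::ggplot(object$quantiles, ggplot2::aes(x = .data$expected)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_lo, ymax = .data$band_hi),
                         fill = "grey80") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.8) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = 2) +
    ggplot2::geom_abline(intercept = 0, slope = object$slope, colour = "red") +
    ggplot2::labs(x = "expected chi-square(1) quantile",
                  y = "observed chi-square(1) quantile",
                  title = sprintf("Q-Q: slope = %.3f (n = %d)", object$slope, object$n))
}

#' Plot Type-1 error / power rates
#'
#' @param rates Output of [type1_power_table()] or
#'   [run_simulation_study()].
#' @param alpha Nominal level drawn as a dashed reference line.
#' @return A ggplot: rejection rate vs control MAF, faceted by truth class
#'   (and error rate when present), coloured by method.
#' @export
plot_rejection_rates <- function(rates, alpha = 0.05) {
  p <- ggplot2::ggplot(rates,
                       ggplot2::aes(x = factor(.data$maf_control), y = .data$rate,
                                    colour = .data$method, group = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = alpha, linetype = 2) +
    ggplot2::labs(x = "control MAF", y = "rejection rate", colour = "method")
  if ("error_rate" %in% names(rates)) {
    p + ggplot2::facet_grid(rows = ggplot2::vars(.data$class),
                            cols = ggplot2::vars(.data$error_rate))
  } else {
    p + ggplot2::facet_wrap(ggplot2::vars(.data$class))
  }
}
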