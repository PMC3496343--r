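#' Convert p-values to chi-square(1) quantiles
#'
#' Inverts the upper-tail chi-square(1) survival function, so a p-value is
#' mapped back to the chi-square statistic that would have produced it
#' (`p = 1` maps to 0). Underflowed p-values of exactly 0 are capped at the
#' smallest positive double before inversion; the number of capped values
#' is attached as attribute `n_capped`, since those points sit beyond any
#' plottable boundary.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Chi-square(1)-scale values, with attribute `n_capped`.
#' @examples
#' pvalues_to_chisq(0.05) # 3.8415
#' @export
pvalues_to_chisq <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  n_capped <- sum(p == 0)
  p <- pmax(p, .Machine$double.xmin)
  out <- qchisq(p, df = 1, lower.tail = FALSE)
  attr(out, "n_capped") <- n_capped
  out
}

#' Q-Q summary of a p-value set against chi-square(1)
#'
#' Observed chi-square values are obtained from the p-values with
#' [pvalues_to_chisq()] and sorted against expected chi-square(1) quantiles
#' at the deterministic plotting positions `k/(m+1)`. The slope is the
#' least-squares regression of observed on expected through the origin
#' (the genomic-inflation convention: calibrated p-values give slope 1).
#' The 95% concentration band is pointwise, from the Beta(k, m+1-k) order
#' statistics of uniforms mapped to the chi-square scale.
#'
#' @param p_values At least 10 p-values in \[0, 1\].
#' @return A `"qq_summary"` object: tibble of `expected`, `observed`,
#'   `band_lo`, `band_hi` (ascending) plus fields `slope`, `max_observed`,
#'   `n`, `n_capped`. Methods: [tidy()], [glance()], [autoplot()].
#' @export
qq_summary <- function(p_values) {
  p_values <- p_values[is.finite(p_values)]
  m <- length(p_values)
  if (m < 10) abort("qq_summary needs at least 10 finite p-values.")
  obs_raw <- pvalues_to_chisq(p_values)
  n_capped <- attr(obs_raw, "n_capped")
  obs <- sort(obs_raw)
  k <- seq_len(m)
  expected <- qchisq(k / (m + 1), df = 1)
  band_lo <- qchisq(qbeta(0.025, k, m + 1 - k), df = 1)
  band_hi <- qchisq(qbeta(0.975, k, m + 1 - k), df = 1)
  if (max(obs) - min(obs) < 1e-12) {
    warn("all p-values identical; Q-Q slope is degenerate.")
  }
  slope <- sum(obs * expected) / sum(expected^2)
  structure(list(
    quantiles = tibble(expected = expected, observed = obs,
                       band_lo = band_lo, band_hi = band_hi),
    slope = slope, max_observed = max(obs), n = m, n_capped = n_capped),
    class = "qq_summary")
}

#' @export
print.qq_summary <- function(x, ...) {
  cat(sprintf("<qq_summary> %d p-values, slope = %.3f, max observed chi-square = %.2f%s\n",
              x$n, x$slope, x$max_observed,
              if (x$n_capped > 0) sprintf(" (%d p-values capped at 0)", x$n_capped) else ""))
  invisible(x)
}

#' Type-1 error and power summary
#'
#' Rejection rates at level `alpha` per truth class and control-MAF bin:
#' among `neutral` SNPs the rate estimates Type-1 error, among `disease`
#' SNPs it estimates power. Excluded or degenerate SNPs are counted
#' separately and never as rejections. Confidence intervals are exact
#' binomial (Clopper-Pearson).
#'
#' @param results Association-result tibble (possibly several methods
#'   bound together).
#' @param truth Truth tibble with `snp_id`, `class`, `maf_control` (from
#'   [simulate_dataset()]).
#' @param alpha Significance level in (0, 1).
#' @return Tibble: `method`, `class`, `maf_control`, `n_tested`,
#'   `n_excluded`, `n_rejected`, `rate`, `conf_lo`, `conf_hi`.
#' @export
type1_power_table <- function(results, truth, alpha = 0.05) {
  if (alpha <= 0 || alpha > 1) abort("`alpha` must lie in (0, 1].")
  bins <- dplyr::distinct(truth[c("class", "maf_control")])
  results |>
    dplyr::inner_join(truth, by = "snp_id") |>
    dplyr::group_by(.data$method, .data$class, .data$maf_control) |>
    dplyr::summarise(
      n_tested = sum(.data$status == "tested"),
      n_excluded = sum(.data$status != "tested"),
      n_rejected = sum(.data$status == "tested" & .data$p_value <= alpha),
      .groups = "drop") |>
    tidyr::complete(.data$method, !!bins,
                    fill = list(n_tested = 0L, n_excluded = 0L, n_rejected = 0L)) |>
    dplyr::mutate(
      rate = ifelse(.data$n_tested > 0, .data$n_rejected / .data$n_tested, NA_real_),
      ci = purrr::map2(.data$n_rejected, .data$n_tested, function(x, n) {
        if (n == 0) return(c(NA_real_, NA_real_))
        binom.test(x, n)$conf.int
      }),
      conf_lo = purrr::map_dbl(.data$ci, 1),
      conf_hi = purrr::map_dbl(.data$ci, 2),
      ci = NULL)
}
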