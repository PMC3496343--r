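result_na_row <- function(snp_id, method, status) {
  tibble(snp_id = snp_id, method = method, statistic = NA_real_,
         df = NA_integer_, p_value = NA_real_,
         p_hat_control = NA_real_, p_hat_case = NA_real_,
         major_control = NA_real_, minor_control = NA_real_,
         major_case = NA_real_, minor_case = NA_real_, status = status)
}

join_design <- function(counts, design) {
  counts <- validate_pool_counts(counts, design)
  if (!all(c("major_reads", "depth") %in% names(counts))) {
    abort("`counts` must be oriented first (orient_major_allele()).")
  }
  dplyr::left_join(counts, as_tibble(design)[c("pool_id", "group")], by = "pool_id")
}

#' Fisher's exact test on estimated chromosome counts
#'
#' The naive binomial-model analysis: within each group the major-allele
#' frequency is estimated as the unweighted mean of per-pool read
#' frequencies over valid pools, converted to chromosome counts out of
#' `s x (number of valid pools)` chromosomes (rounded, ties to even), and
#' the resulting 2x2 allele-by-group table is tested with a two-sided
#' Fisher's exact test. Because each pool only holds `s` chromosomes and
#' pools vary, the implied binomial variance understates the truth and the
#' test is anti-conservative on over-dispersed data; it is provided as the
#' comparison baseline.
#'
#' @param counts Oriented count tibble ([orient_major_allele()]); counts may
#'   be real-valued (error-corrected).
#' @param design A [pool_design()].
#' @param valid_pools Optional tibble `snp_id`, `pool_id`, `valid` from
#'   [chromosome_coverage_filter()]; pools with zero depth are always
#'   invalid. A SNP with no valid pool in one group is `excluded`.
#' @return An association-result tibble (one row per SNP; columns as in
#'   [write_results()]). The test is exact, so `df` is `NA`; `statistic`
#'   reports the chi-square(1) equivalent of the exact p-value (the value
#'   [pvalues_to_chisq()] would give), which is invariant to group and
#'   allele relabelling.
#' @export
fisher_test <- function(counts, design, valid_pools = NULL) {
  s <- design_s(design)
  dat <- join_design(counts, design)
  dat$valid <- dat$depth > 0
  if (!is.null(valid_pools)) {
    dat <- dat |>
      dplyr::left_join(dplyr::rename(valid_pools, cov_valid = "valid"),
                       by = c("snp_id", "pool_id")) |>
      dplyr::mutate(valid = .data$valid & dplyr::coalesce(.data$cov_valid, FALSE),
                    cov_valid = NULL)
  }
  wide <- dat |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$snp_id, .data$group) |>
    dplyr::summarise(freq = mean(.data$major_reads / .data$depth),
                     n_chrom = s * dplyr::n(), .groups = "drop") |>
    dplyr::mutate(minor_chrom = round((1 - .data$freq) * .data$n_chrom),
                  major_chrom = .data$n_chrom - .data$minor_chrom) |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("freq", "n_chrom", "minor_chrom", "major_chrom"))
  for (col in c("freq_control", "freq_case", "minor_chrom_control",
                "major_chrom_control", "minor_chrom_case", "major_chrom_case")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  all_ids <- unique(dat$snp_id)
  wide <- dplyr::left_join(tibble(snp_id = all_ids), wide, by = "snp_id")
  ok <- !is.na(wide$freq_control) & !is.na(wide$freq_case)
  pv <- rep(NA_real_, nrow(wide))
  pv[ok] <- mapply(function(a, b, c, d) {
    fisher.test(matrix(c(a, b, c, d), nrow = 2), conf.int = FALSE)$p.value
  }, wide$major_chrom_control[ok], wide$minor_chrom_control[ok],
     wide$major_chrom_case[ok], wide$minor_chrom_case[ok])
  pv <- pmin(pv, 1)
  tibble(snp_id = wide$snp_id, method = "fisher",
         statistic = ifelse(ok, qchisq(pmax(pv, .Machine$double.xmin),
                                       df = 1, lower.tail = FALSE), NA_real_),
         df = NA_integer_, p_value = pv,
         p_hat_control = wide$freq_control, p_hat_case = wide$freq_case,
         major_control = wide$major_chrom_control,
         minor_control = wide$minor_chrom_control,
         major_case = wide$major_chrom_case,
         minor_case = wide$minor_chrom_case,
         status = ifelse(ok, "tested", "excluded"))
}

#' Williams' extra-binomial quasi-likelihood fit for one SNP (EB1)
#'
#' Williams' model keeps binomial variation within a pool but lets the
#' pool-level allele frequency vary with variance `phi * p(1-p)`, giving
#' the unconditional count variance `R p(1-p) [1 + (R-1) phi]` — a
#' heterogeneity factor growing with depth. The major-allele proportion is
#' fitted on the logistic scale (intercept plus case-control factor) by
#' iteratively re-weighted least squares with pool weights
#' `w = 1 / [1 + phi (R-1)]`; `phi` is updated by the moment equation that
#' matches the weighted Pearson chi-square to its expectation (with
#' leverage correction), floored at 0 each step.
#'
#' @param major,depth Numeric vectors of per-pool major-allele reads and
#'   depths (depth-0 pools are dropped).
#' @param group Character vector `"case"`/`"control"` per pool.
#' @param phi Optional fixed dispersion; when supplied no estimation is
#'   done (useful for the pure-binomial reduction `phi = 0`).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on
#'   `phi`.
#' @return An object of class `"eb1_fit"`: list with `phi`, `beta` (the
#'   case effect on the log-odds scale), `X2_full`, `X2_null`, `statistic`
#'   (the chi-square increase when the case-control factor is deleted),
#'   `p_value`, `iterations`, `converged`.
#' @export
fit_eb1 <- function(major, depth, group, phi = NULL, max_iter = 50, tol = 1e-8) {
  keep <- depth > 0
  y <- major[keep]; R <- depth[keep]
  grp <- factor(group[keep], levels = c("control", "case"))
  prop <- y / R
  pearson_x2 <- function(fit, w) {
    mu <- fitted(fit)
    sum(w * R * (prop - mu)^2 / (mu * (1 - mu)))
  }
  fixed <- !is.null(phi)
  phi_hat <- if (fixed) phi else 0
  iter <- 0L; converged <- fixed
  if (!fixed) {
    repeat {
      iter <- iter + 1L
      w <- 1 / (1 + phi_hat * (R - 1))
      fit <- suppressWarnings(glm(prop ~ grp, family = quasibinomial(),
                                  weights = w * R))
      x2 <- pearson_x2(fit, w)
      h <- hatvalues(fit)
      denom <- sum((1 - h) * w * (R - 1))
      phi_new <- if (denom > 0) (x2 - sum((1 - h) * w)) / denom else 0
      phi_new <- max(phi_new, 0)
      if (abs(phi_new - phi_hat) < tol) { phi_hat <- phi_new; converged <- TRUE; break }
      phi_hat <- phi_new
      if (iter >= max_iter) break
    }
  }
  w <- 1 / (1 + phi_hat * (R - 1))
  full <- suppressWarnings(glm(prop ~ grp, family = quasibinomial(), weights = w * R))
  null <- suppressWarnings(glm(prop ~ 1, family = quasibinomial(), weights = w * R))
  X2_full <- pearson_x2(full, w)
  X2_null <- pearson_x2(null, w)
  stat <- X2_null - X2_full
  structure(list(phi = phi_hat, beta = unname(coef(full)[2]),
                 X2_full = X2_full, X2_null = X2_null,
                 statistic = max(stat, 0),
                 p_value = pchisq(max(stat, 0), df = 1, lower.tail = FALSE),
                 fitted_control = unname(fitted(full)[grp == "control"][1]),
                 fitted_case = unname(fitted(full)[grp == "case"][1]),
                 iterations = iter, converged = converged),
            class = "eb1_fit")
}

#' @export
print.eb1_fit <- function(x, ...) {
  cat(sprintf("<eb1_fit> phi = %.4g, dX2 = %.4g (df = 1, p = %.3g), %d iteration(s)%s\n",
              x$phi, x$statistic, x$p_value, x$iterations,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' EB1 association test across SNPs
#'
#' Applies [fit_eb1()] per SNP and tests the case-control factor by the
#' increase in the weighted Pearson chi-square when it is deleted,
#' referred to chi-square with 1 df. SNPs whose total minor-allele count is
#' zero in either group are excluded (the pool variance needed to estimate
#' the dispersion is not identifiable there); non-convergent fits are
#' flagged `degenerate`.
#'
#' @inheritParams fisher_test
#' @inheritParams fit_eb1
#' @return Association-result tibble with extra columns `phi`,
#'   `X2_full`, `X2_null`, `iterations`, `converged`. The 2x2 table columns
#'   hold summed raw major/minor reads per group.
#' @export
eb1_test <- function(counts, design, phi = NULL, max_iter = 50, tol = 1e-8) {
  dat <- join_design(counts, design)
  one <- function(d, id) {
    minor_tot <- tapply(d$minor_reads, factor(d$group, levels = c("control", "case")), sum)
    tabrow <- function(g, col) sum(d[[col]][d$group == g])
    base <- tibble(snp_id = id, method = "eb1",
                   major_control = tabrow("control", "major_reads"),
                   minor_control = tabrow("control", "minor_reads"),
                   major_case = tabrow("case", "major_reads"),
                   minor_case = tabrow("case", "minor_reads"))
    if (anyNA(minor_tot) || any(minor_tot <= 0)) {
      out <- result_na_row(id, "eb1", "excluded")
      return(dplyr::rows_update(out, base, by = "snp_id"))
    }
    f <- fit_eb1(d$major_reads, d$depth, d$group, phi = phi,
                 max_iter = max_iter, tol = tol)
    dplyr::bind_cols(base[c("snp_id", "method")],
                     tibble(statistic = f$statistic, df = 1L, p_value = f$p_value,
                            p_hat_control = f$fitted_control,
                            p_hat_case = f$fitted_case),
                     base[c("major_control", "minor_control", "major_case", "minor_case")],
                     tibble(status = if (f$converged) "tested" else "degenerate",
                            phi = f$phi, X2_full = f$X2_full, X2_null = f$X2_null,
                            iterations = f$iterations, converged = f$converged))
  }
  dat |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::group_map(~ one(.x, .y$snp_id)) |>
    dplyr::bind_rows()
}

#' Fit the global over-dispersion parameters (a, b)
#'
#' The EB2 variance law states that the per-pool major-allele count has
#' variance `R p(1-p) [a + b (R-1)/s]`, with `a` and `b` shared by all
#' SNPs. Under pure two-stage sampling (s chromosomes drawn into the pool,
#' then reads drawn from them) `a = b = 1`; sequencing and library noise
#' push the parameters away from that ideal. For each SNP the normalized
#' dispersion statistic
#' `z_i = sum_j R_ij (p_ij - p_g(j))^2 / [p_i (1 - p_i)] / (n_i - 2)`
#' (deviations about the group means, overall frequency `p_i` in the
#' denominator, `n_i - 2` residual degrees of freedom) has expectation
#' `a + b x_i` where the depth regressor `x_i` reduces to `(R - 1)/s` for
#' equal depths; `a` and `b` are estimated as intercept and slope of the
#' ordinary least-squares regression of `z_i` on `x_i` across SNPs.
#'
#' @inheritParams fisher_test
#' @param min_pools Minimum pools with positive depth for a SNP to enter
#'   the regression (needs `n_i - 2 >= 1`; default 4).
#' @return A `"dispersion_fit"` object: fields `a`, `b`, `s`,
#'   `n_snps_used`, `per_snp` (tibble `snp_id`, `z`, `x`, `mean_depth`),
#'   and the underlying `lm` fit. Methods: [tidy()], [glance()],
#'   [autoplot()].
#' @export
fit_dispersion <- function(counts, design, min_pools = 4) {
  s <- design_s(design)
  dat <- join_design(counts, design) |> dplyr::filter(.data$depth > 0)
  per_snp <- dat |>
    dplyr::group_by(.data$snp_id, .data$group) |>
    dplyr::mutate(p_grp = sum(.data$major_reads) / sum(.data$depth)) |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(
      n_pools = dplyr::n(),
      n_groups = dplyr::n_distinct(.data$group),
      p_bar = sum(.data$major_reads) / sum(.data$depth),
      ss = sum(.data$depth * (.data$major_reads / .data$depth - .data$p_grp)^2),
      sum_R = sum(.data$depth),
      sum_R2_over_Rg = sum(tapply(.data$depth, .data$group,
                                  function(r) sum(r^2) / sum(r))),
      mean_depth = mean(.data$depth),
      .groups = "drop") |>
    dplyr::filter(.data$n_pools >= max(min_pools, 3), .data$n_groups == 2,
                  .data$p_bar > 0, .data$p_bar < 1) |>
    dplyr::mutate(
      z = .data$ss / (.data$p_bar * (1 - .data$p_bar)) / (.data$n_pools - 2),
      x = ((.data$sum_R - .data$sum_R2_over_Rg) / (.data$n_pools - 2) - 1) / s)
  if (nrow(per_snp) < 2) {
    abort("fit_dispersion needs at least 2 usable SNPs (pooled frequency strictly inside (0,1)).")
  }
  fit <- lm(z ~ x, data = per_snp)
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  if (a + b * (max(per_snp$mean_depth) - 1) / s <= 0 ||
      a + b * (min(per_snp$mean_depth) - 1) / s <= 0) {
    warn("fitted variance function is non-positive at some observed depths; affected pools will be dropped downstream.")
  }
  structure(list(a = a, b = b, s = s, n_snps_used = nrow(per_snp),
                 per_snp = per_snp[c("snp_id", "z", "x", "mean_depth")],
                 lm = fit),
            class = "dispersion_fit")
}

#' @rdname fit_dispersion
#' @param a,b Over-dispersion parameters for a manually specified fit
#'   (e.g. imported from file, or `a = 1, b = 0` for the identity
#'   adjustment).
#' @param s Chromosomes per pool.
#' @export
dispersion_fit <- function(a, b, s) {
  structure(list(a = a, b = b, s = as.integer(s), n_snps_used = 0L,
                 per_snp = tibble(snp_id = character(), z = numeric(),
                                  x = numeric(), mean_depth = numeric()),
                 lm = NULL),
            class = "dispersion_fit")
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat(sprintf("<dispersion_fit> a = %.4g, b = %.4g (s = %d, %d SNPs)\n",
              x$a, x$b, x$s, x$n_snps_used))
  invisible(x)
}

#' @rdname fit_dispersion
#' @param fit A `dispersion_fit`.
#' @param R Read depth(s).
#' @return `adjusted_depth()`: the EB2 effective depth
#'   `R* = R / [a + b (R-1)/s]` — the number of binomial observations a
#'   pool is really worth once over-dispersion is accounted for.
#' @export
adjusted_depth <- function(fit, R) {
  R / (fit$a + fit$b * (R - 1) / fit$s)
}

#' EB2 association test with globally adjusted depths
#'
#' Each pool's depth is shrunk to the adjusted depth
#' `R* = R / [a + b (R-1)/s]` implied by the fitted variance law, so the
#' per-pool frequency estimate `p = y/R` behaves like a binomial
#' proportion out of `R*` trials. Adjusted allele counts `p R*` and
#' `(1-p) R*` are summed over case and control pools into a 2x2 table and
#' tested with a Pearson chi-square (1 df, no continuity correction;
#' fractional entries are expected since the table is model-adjusted, not
#' raw data). Pools with non-positive adjusted depth are dropped; a SNP
#' losing all pools of one group is excluded.
#'
#' @inheritParams fisher_test
#' @param fit A `"dispersion_fit"` from [fit_dispersion()] or
#'   [dispersion_fit()].
#' @return Association-result tibble; the table columns hold the adjusted
#'   (real-valued) allele counts per group.
#' @export
eb2_test <- function(counts, design, fit) {
  if (!inherits(fit, "dispersion_fit")) abort("`fit` must be a dispersion_fit.")
  dat <- join_design(counts, design) |> dplyr::filter(.data$depth > 0)
  dat$h <- fit$a + fit$b * (dat$depth - 1) / fit$s
  n_bad <- sum(dat$h <= 0)
  if (n_bad > 0) {
    inform(sprintf("EB2: dropped %d pool(s) with non-positive adjusted depth.", n_bad))
    dat <- dat[dat$h > 0, ]
  }
  dat$rstar <- dat$depth / dat$h
  dat$adj_major <- (dat$major_reads / dat$depth) * dat$rstar
  dat$adj_minor <- dat$rstar - dat$adj_major
  out <- dat |>
    dplyr::group_by(.data$snp_id, .data$group) |>
    dplyr::summarise(M = sum(.data$adj_major), m = sum(.data$adj_minor),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = c("M", "m"))
  for (col in c("M_control", "m_control", "M_case", "m_case")) {
    if (!col %in% names(out)) out[[col]] <- NA_real_
  }
  out |>
    dplyr::mutate(
      n1 = .data$M_control + .data$m_control,
      n2 = .data$M_case + .data$m_case,
      cM = .data$M_control + .data$M_case,
      cm = .data$m_control + .data$m_case,
      N = .data$n1 + .data$n2,
      statistic = ifelse(.data$n1 > 0 & .data$n2 > 0 & .data$cM > 0 & .data$cm > 0,
                         .data$N * (.data$M_control * .data$m_case -
                                    .data$M_case * .data$m_control)^2 /
                           (.data$n1 * .data$n2 * .data$cM * .data$cm),
                         0),
      excluded = is.na(.data$n1) | is.na(.data$n2) | .data$n1 <= 0 | .data$n2 <= 0,
      method = "eb2", df = 1L,
      p_value = ifelse(.data$excluded, NA_real_,
                       pchisq(.data$statistic, df = 1, lower.tail = FALSE)),
      statistic = ifelse(.data$excluded, NA_real_, .data$statistic),
      p_hat_control = .data$M_control / .data$n1,
      p_hat_case = .data$M_case / .data$n2,
      status = ifelse(.data$excluded, "excluded", "tested")) |>
    dplyr::transmute(
      snp_id = .data$snp_id, method = .data$method, statistic = .data$statistic,
      df = .data$df, p_value = .data$p_value,
      p_hat_control = .data$p_hat_control, p_hat_case = .data$p_hat_case,
      major_control = .data$M_control, minor_control = .data$m_control,
      major_case = .data$M_case, minor_case = .data$m_case,
      status = .data$status)
}

#' Odds ratio of the minor allele from group MAFs
#'
#' @param maf_control,maf_case Minor-allele frequencies in controls and
#'   cases, strictly inside (0, 1); vectorised.
#' @return `[maf_case/(1-maf_case)] / [maf_control/(1-maf_control)]`.
#' @examples
#' odds_ratio(0.5, 0.6) # 1.5
#' @export
odds_ratio <- function(maf_control, maf_case) {
  if (any(maf_control <= 0 | maf_control >= 1 | maf_case <= 0 | maf_case >= 1)) {
    abort("MAFs must lie strictly inside (0, 1) for an odds ratio.")
  }
  (maf_case / (1 - maf_case)) / (maf_control / (1 - maf_control))
}

#' Append a Benjamini-Hochberg adjusted p-value column
#'
#' p-values are reported raw throughout the package (the analysis style is
#' diagnostic, via Q-Q calibration, rather than per-SNP decision making);
#' this helper adds an FDR-adjusted column for workflows that do want
#' per-SNP significance calls. Only rows with `status == "tested"` enter
#' the adjustment.
#'
#' @param results Association-result tibble.
#' @return `results` with a `p_bh` column (NA for untested rows).
#' @export
add_bh <- function(results) {
  tested <- results$status == "tested" & !is.na(results$p_value)
  p_bh <- rep(NA_real_, nrow(results))
  p_bh[tested] <- p.adjust(results$p_value[tested], method = "BH")
  dplyr::mutate(results, p_bh = p_bh)
}
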