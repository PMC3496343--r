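#' Estimate base-specific sequencing error rates
#'
#' For each ordered base substitution a -> a' (12 classes), the error rate
#' is the fraction of reads showing a' among all reads at positions whose
#' reference base is a and whose observed alternative is a', summed over
#' every position that was *not* called (and kept) as a SNP. Positions that
#' carry genuine variation would inflate the rates, hence the exclusion.
#'
#' @param site_counts Tibble of per-position read totals with columns
#'   `chrom`, `pos`, `ref`, `alt`, `ref_reads`, `alt_reads` (summed over
#'   pools).
#' @param snp_positions Tibble with columns `chrom`, `pos` identifying
#'   positions called and retained as SNPs; these are excluded from the
#'   estimate.
#' @return An `error_rates` tibble with columns `ref`, `alt`, `alt_reads`,
#'   `total_reads`, `rate` — one row per ordered substitution. Classes with
#'   no eligible reads get rate 0 with a warning.
#' @export
estimate_error_rates <- function(site_counts, snp_positions = NULL) {
  need <- c("chrom", "pos", "ref", "alt", "ref_reads", "alt_reads")
  if (!all(need %in% names(site_counts))) {
    abort(paste0("`site_counts` needs columns ", paste(need, collapse = ", ")))
  }
  sites <- as_tibble(site_counts)
  if (!is.null(snp_positions) && nrow(snp_positions)) {
    sites <- dplyr::anti_join(sites, snp_positions[c("chrom", "pos")],
                              by = c("chrom", "pos"))
  }
  bases <- c("A", "C", "G", "T")
  classes <- tidyr::expand_grid(ref = bases, alt = bases) |>
    dplyr::filter(.data$ref != .data$alt)
  agg <- sites |>
    dplyr::group_by(.data$ref, .data$alt) |>
    dplyr::summarise(alt_reads = sum(.data$alt_reads),
                     total_reads = sum(.data$ref_reads) + sum(.data$alt_reads),
                     .groups = "drop")
  out <- classes |>
    dplyr::left_join(agg, by = c("ref", "alt")) |>
    dplyr::mutate(alt_reads = dplyr::coalesce(.data$alt_reads, 0),
                  total_reads = dplyr::coalesce(.data$total_reads, 0),
                  rate = ifelse(.data$total_reads > 0,
                                .data$alt_reads / .data$total_reads, 0))
  if (any(out$total_reads == 0)) {
    warn(paste0("no eligible reads for substitution class(es) ",
                paste(paste0(out$ref[out$total_reads == 0], ">",
                             out$alt[out$total_reads == 0]), collapse = ", "),
                "; their rates are set to 0."))
  }
  class(out) <- c("error_rates", class(out))
  out
}

# Look up rate for an ordered substitution, treating negligible rates as 0.
lookup_rate <- function(rates, from, to, floor = 1e-8) {
  r <- rates$rate[match(paste(from, to), paste(rates$ref, rates$alt))]
  r[is.na(r)] <- 0
  r[r < floor] <- 0
  r
}

#' Correct read counts for sequencing error
#'
#' With per-base error rates `e_Mm` (major allele misread as minor) and
#' `e_mM` (minor misread as major), the observed major count satisfies
#' `E[y_obs] = y (1 - e_Mm) + (R - y) e_mM`. The correction inverts this
#' relationship, `y* = (y_obs - R e_mM) / (1 - e_Mm - e_mM)`, so that the
#' corrected count is unbiased for the error-free count. Corrected counts
#' are real-valued and are clamped to `[0, depth]` (clamping is flagged);
#' depths are unchanged. For each SNP only the rates of its own ref/alt
#' substitution pair apply.
#'
#' @param counts Oriented count tibble (see [orient_major_allele()]).
#' @param rates An `error_rates` table from [estimate_error_rates()].
#' @param rate_scale Sensitivity-analysis multiplier applied to every rate
#'   before correcting (default 1). Estimated error rates are uncertain;
#'   re-running the analysis with the rates halved and doubled
#'   (`rate_scale = 0.5, 2`) shows whether findings are robust to their
#'   misspecification.
#' @return `counts` with `major_reads`/`minor_reads` replaced by corrected
#'   real values and a logical `clamped` column added.
#' @export
correct_counts <- function(counts, rates, rate_scale = 1) {
  if (rate_scale < 0) abort("`rate_scale` must be non-negative.")
  rates <- dplyr::mutate(rates, rate = .data$rate * rate_scale)
  counts <- validate_pool_counts(counts)
  if (!all(c("major_reads", "depth") %in% names(counts))) {
    abort("`counts` must be oriented first (orient_major_allele()).")
  }
  e_Mm <- lookup_rate(rates, counts$major_allele, counts$minor_allele)
  e_mM <- lookup_rate(rates, counts$minor_allele, counts$major_allele)
  denom <- 1 - e_Mm - e_mM
  if (any(denom <= 0)) abort("error rates sum to >= 1 for some SNP; cannot correct.")
  y <- (counts$major_reads - counts$depth * e_mM) / denom
  clamped <- y < 0 | y > counts$depth
  y <- pmin(pmax(y, 0), counts$depth)
  if (any(clamped)) {
    inform(sprintf("error correction clamped %d pool count(s) to [0, depth].",
                   sum(clamped)))
  }
  counts |>
    dplyr::mutate(major_reads = y,
                  minor_reads = .data$depth - y,
                  clamped = clamped)
}
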