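#' Minimum read-depth filter
#'
#' A SNP passes when the summed read depth in each group (case and control)
#' reaches `min_depth`; with `per_pool = TRUE` every single pool must reach
#' it instead. Site-level depth filtering mirrors what variant callers apply
#' before a SNP is reported at all.
#'
#' @param counts Oriented count tibble (see [orient_major_allele()]).
#' @param design A [pool_design()].
#' @param min_depth Non-negative depth threshold; default 8.
#' @param per_pool Require the threshold per pool rather than per group sum.
#' @return Tibble with columns `snp_id`, `passed_depth`.
#' @export
min_depth_filter <- function(counts, design, min_depth = 8, per_pool = FALSE) {
  if (min_depth < 0) abort("`min_depth` must be >= 0.")
  counts |>
    dplyr::left_join(design, by = "pool_id") |>
    dplyr::group_by(.data$snp_id, .data$group) |>
    dplyr::summarise(ok = if (per_pool) all(.data$depth >= min_depth)
                     else sum(.data$depth) >= min_depth,
                     .groups = "drop") |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(passed_depth = all(.data$ok), .groups = "drop")
}

#' Partition SNPs into common and rare by pooled MAF
#'
#' The overall minor-allele frequency is the ratio of total minor reads to
#' total depth pooled over all pools. A SNP is `common` when its MAF is at
#' or above `maf_threshold` (boundary inclusive), `rare` below it; a SNP
#' with zero total depth is flagged `degenerate` (class `NA`).
#'
#' @inheritParams min_depth_filter
#' @param maf_threshold MAF cutoff in (0, 0.5); default 0.05.
#' @return Tibble with columns `snp_id`, `maf`, `maf_class`.
#' @export
maf_partition <- function(counts, maf_threshold = 0.05) {
  if (maf_threshold <= 0 || maf_threshold >= 0.5) {
    abort("`maf_threshold` must lie in (0, 0.5).")
  }
  counts |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(maf = sum(.data$minor_reads) / sum(.data$depth),
                     .groups = "drop") |>
    dplyr::mutate(maf_class = dplyr::case_when(
      !is.finite(.data$maf) ~ NA_character_,
      .data$maf >= maf_threshold ~ "common",
      TRUE ~ "rare"))
}

#' Screen rare variants against a random-error null
#'
#' Sequencing errors scatter minor-allele reads across pools in proportion
#' to pool depth, whereas a genuine rare variant concentrates them in the
#' few pools containing carriers. For each SNP the minor-read counts across
#' pools are compared to depth-proportional expectation with a Pearson
#' chi-square statistic whose null distribution is obtained by Monte-Carlo
#' multinomial resampling (the total minor count thrown onto pools with
#' probabilities proportional to depth). A SNP is called a true rare SNP
#' when the Monte-Carlo p-value falls below the Bonferroni-corrected level
#' `alpha / n_tests` *and* at least one pool holds more than two minor
#' reads.
#'
#' @inheritParams min_depth_filter
#' @param n_tests Bonferroni denominator: the number of rare candidate
#'   variants screened in this run.
#' @param alpha Prior significance level before correction; default 0.05.
#' @param n_perm Monte-Carlo resamples; default 10000. The smallest
#'   attainable p-value is `1/(n_perm + 1)`, so `n_perm` must exceed
#'   `n_tests/alpha` for any SNP to clear the Bonferroni threshold (a
#'   warning is raised otherwise). Sampling is adaptive: a first batch of
#'   500 resamples settles clearly unremarkable SNPs, and only candidates
#'   with fewer than 10 exceedances go on to the full `n_perm`.
#' @param method `"montecarlo"` (default) resolves the tail by multinomial
#'   resampling; `"chisq"` uses the asymptotic chi-square tail of the same
#'   statistic (df = informative pools - 1). The asymptotic tail has no
#'   granularity floor, which matters when the Bonferroni threshold falls
#'   below `1/(n_perm + 1)` — e.g. screening many hundreds of candidates —
#'   and is accurate when expected minor reads per pool are not tiny.
#' @return Tibble with columns `snp_id`, `error_screen_p`, `called_true_snp`.
#'   Uses the current RNG stream; seed beforehand for reproducibility.
#' @export
random_error_screen <- function(counts, n_tests, alpha = 0.05, n_perm = 10000,
                                method = c("montecarlo", "chisq")) {
  method <- match.arg(method)
  if (n_tests < 1) abort("`n_tests` must be >= 1.")
  thr <- alpha / n_tests
  if (method == "montecarlo" && 1 / (n_perm + 1) >= thr) {
    warn(sprintf(paste0("Monte-Carlo resolution 1/%d cannot fall below the ",
                        "Bonferroni threshold %.3g; no SNP can be called. ",
                        "Increase `n_perm` or use method = 'chisq'."), n_perm + 1, thr))
  }
  b1 <- min(500L, n_perm)
  one_snp <- function(minor, depth) {
    keep <- depth > 0
    minor <- minor[keep]; depth <- depth[keep]
    total <- sum(minor)
    if (total == 0 || length(depth) < 2) {
      return(c(p = 1, called = 0))
    }
    expd <- total * depth / sum(depth)
    stat <- sum((minor - expd)^2 / expd)
    if (method == "chisq") {
      p <- pchisq(stat, df = length(depth) - 1, lower.tail = FALSE)
    } else {
      sim_stat <- colSums((rmultinom(b1, size = total, prob = depth) - expd)^2 / expd)
      hits <- sum(sim_stat >= stat - 1e-9)
      b <- b1
      if (hits < 10 && n_perm > b1) {
        sim_stat <- colSums((rmultinom(n_perm - b1, size = total, prob = depth) - expd)^2 / expd)
        hits <- hits + sum(sim_stat >= stat - 1e-9)
        b <- n_perm
      }
      p <- (1 + hits) / (b + 1)
    }
    c(p = p, called = as.numeric(p < thr && max(minor) > 2))
  }
  counts |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(res = list(one_snp(.data$minor_reads, .data$depth)),
                     .groups = "drop") |>
    dplyr::mutate(error_screen_p = purrr::map_dbl(.data$res, "p"),
                  called_true_snp = purrr::map_dbl(.data$res, "called") > 0,
                  res = NULL)
}

#' Occupancy probability: reads covering distinct chromosomes
#'
#' If `R` reads land uniformly and independently on `s` chromosomes, the
#' number of distinct chromosomes hit follows the classical occupancy
#' distribution. `occupancy_dist` returns the exact probability mass over
#' `0..min(R, s)` by dynamic programming over reads; `coverage_probability`
#' returns `P(distinct chromosomes hit >= k)`.
#'
#' @param R Number of reads (non-negative integer; vectorised in
#'   `coverage_probability`).
#' @param s Number of chromosomes in the pool.
#' @param k Coverage target, `1 <= k <= s`.
#' @return `occupancy_dist`: numeric vector of length `min(R, s) + 1`
#'   (probabilities of hitting `0, 1, ..., min(R, s)` chromosomes).
#'   `coverage_probability`: numeric vector like `R`.
#' @examples
#' coverage_probability(3, s = 4, k = 3) # 24/64
#' @export
occupancy_dist <- function(R, s) {
  R <- as.integer(R)
  if (R < 0 || s < 1) abort("need R >= 0 and s >= 1.")
  m_max <- min(R, s)
  probs <- c(1, numeric(m_max))
  m <- 0:m_max
  stay <- m / s
  for (r in seq_len(R)) {
    new <- probs * stay
    new[-1] <- new[-1] + probs[-(m_max + 1)] * (1 - stay[-(m_max + 1)])
    probs <- new
  }
  probs
}

#' @rdname occupancy_dist
#' @export
coverage_probability <- function(R, s, k) {
  if (k < 1 || k > s) abort("need 1 <= k <= s.")
  R <- as.integer(R)
  if (any(R < 0)) abort("need R >= 0.")
  curve <- coverage_prob_curve(max(R, 0L), s, k)
  curve[R + 1L]
}

# P(>= k of s chromosomes hit) for every R in 0..max_R, one DP sweep.
coverage_prob_curve <- function(max_R, s, k) {
  m_max <- min(max_R, s)
  probs <- c(1, numeric(m_max))
  m <- 0:m_max
  stay <- m / s
  out <- numeric(max_R + 1)
  out[1] <- if (k == 0) 1 else 0
  tail_idx <- if (k <= m_max) (k + 1):(m_max + 1) else integer()
  for (r in seq_len(max_R)) {
    new <- probs * stay
    new[-1] <- new[-1] + probs[-(m_max + 1)] * (1 - stay[-(m_max + 1)])
    probs <- new
    out[r + 1] <- sum(probs[tail_idx])
  }
  out
}

#' Chromosome-coverage filter for the binomial test path
#'
#' For Fisher's test on estimated chromosome counts, a pool is informative
#' only if its reads plausibly sampled most chromosomes in the pool: pool
#' `j` is valid at a SNP iff its depth gives strictly more than `prob`
#' probability of covering at least `k` of the `s` chromosomes
#' ([coverage_probability()]). A SNP is dropped when one group retains no
#' valid pool. This filter applies to the Fisher/binomial path only.
#'
#' @inheritParams min_depth_filter
#' @param k Minimum chromosomes to cover (default 80).
#' @param prob Required coverage probability (strict `>`; default 0.8).
#' @return List with `valid_pools` (tibble `snp_id`, `pool_id`, `valid`) and
#'   `dropped_snps` (character vector of SNPs with an empty group).
#' @export
chromosome_coverage_filter <- function(counts, design, k = 80, prob = 0.8) {
  s <- design_s(design)
  if (s < k) abort("design s must be >= k.")
  depths <- sort(unique(counts$depth))
  pcov <- coverage_probability(depths, s, k)
  valid <- counts |>
    dplyr::mutate(valid = pcov[match(.data$depth, depths)] > prob) |>
    dplyr::select(dplyr::all_of(c("snp_id", "pool_id", "valid")))
  drop <- valid |>
    dplyr::left_join(design, by = "pool_id") |>
    dplyr::group_by(.data$snp_id, .data$group) |>
    dplyr::summarise(any_valid = any(.data$valid), .groups = "drop") |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(drop = !all(.data$any_valid), .groups = "drop")
  list(valid_pools = valid, dropped_snps = drop$snp_id[drop$drop])
}

#' Run the full pre-test filtering pipeline
#'
#' Applies, in order: the minimum-depth filter, the common/rare MAF
#' partition, and (rare SNPs only) the random-error screen with Bonferroni
#' denominator equal to the number of rare candidates screened. A SNP is
#' called a true SNP if it is common, or rare and passing the screen.
#'
#' @inheritParams min_depth_filter
#' @inheritParams maf_partition
#' @inheritParams random_error_screen
#' @param screen_method Passed to [random_error_screen()] as `method`.
#' @return A `FilterReport` tibble: `snp_id`, `passed_depth`, `maf`,
#'   `maf_class`, `error_screen_p`, `called_true_snp`, `reason`.
#' @export
filter_pipeline <- function(counts, design, min_depth = 8, maf_threshold = 0.05,
                            alpha = 0.05, n_perm = 10000, per_pool = FALSE,
                            screen_method = c("montecarlo", "chisq")) {
  rep1 <- min_depth_filter(counts, design, min_depth, per_pool)
  rep2 <- maf_partition(counts, maf_threshold)
  report <- dplyr::left_join(rep1, rep2, by = "snp_id")
  rare_ids <- report$snp_id[report$passed_depth & !is.na(report$maf_class) &
                              report$maf_class == "rare"]
  if (length(rare_ids)) {
    screen <- random_error_screen(
      dplyr::filter(counts, .data$snp_id %in% rare_ids),
      n_tests = length(rare_ids), alpha = alpha, n_perm = n_perm,
      method = match.arg(screen_method))
  } else {
    screen <- tibble(snp_id = character(), error_screen_p = numeric(),
                     called_true_snp = logical())
  }
  report |>
    dplyr::left_join(screen, by = "snp_id") |>
    dplyr::mutate(
      called_true_snp = dplyr::case_when(
        !.data$passed_depth ~ FALSE,
        is.na(.data$maf_class) ~ FALSE,
        .data$maf_class == "common" ~ TRUE,
        TRUE ~ !is.na(.data$called_true_snp) & .data$called_true_snp),
      reason = dplyr::case_when(
        !.data$passed_depth ~ "below minimum depth",
        is.na(.data$maf_class) ~ "zero total depth",
        .data$maf_class == "common" ~ "common variant",
        .data$called_true_snp ~ "rare variant passing error screen",
        TRUE ~ "consistent with random errors"))
}
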