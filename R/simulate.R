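#' Simulation configuration for a pooled case-control study
#'
#' Defaults reproduce the reference study design: 500 cases and 500
#' controls in 20 pools of 50 persons (so `s = 100` chromosomes per pool),
#' nominal per-person coverage 40x with gamma-distributed per-person depth,
#' three equally sized SNP classes — `null` (MAF 0, pure error), `neutral`
#' (equal case/control MAF spanning 0.005-0.5) and `disease` (case MAF
#' derived from the control MAF under a multiplicative per-allele relative
#' risk, default 1.5) — and a symmetric base-calling error rate between 0
#' and 5%. The per-person depth gamma is strongly right-skewed (shape about
#' 0.13): capture and amplification are very uneven, so about half the
#' persons contribute no reads at a site and pool depths vary widely
#' (CV about 40%), which is what drives the large between-pool variance in
#' allele frequency that the extra-binomial tests exist for. Shape and
#' scale are calibrated so that at 40x nominal coverage the per-person
#' depth has mean 39 (pool mean 1950) and variance 12026.
#'
#' @param n_cases,n_controls Persons per arm.
#' @param pools_per_group Pools per arm (person counts must divide evenly).
#' @param avg_coverage Nominal average reads per person.
#' @param gamma_shape Shape of the per-person depth gamma.
#' @param gamma_scale Scale of the per-person depth gamma; default
#'   `7.70897 * avg_coverage`.
#' @param n_null,n_neutral,n_disease SNPs per truth class.
#' @param maf_grid Control MAFs cycled over neutral and disease SNPs.
#' @param rr Per-allele relative risk for disease SNPs.
#' @param error_rate Symmetric per-read error probability in \[0, 1\].
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_cases = 500, n_controls = 500, pools_per_group = 10,
                       avg_coverage = 40,
                       gamma_shape = 0.126475,
                       gamma_scale = 7.70897 * avg_coverage,
                       n_null = 700, n_neutral = 700, n_disease = 700,
                       maf_grid = c(0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.3, 0.5),
                       rr = 1.5, error_rate = 0, seed = NULL) {
  cfg <- list(n_cases = n_cases, n_controls = n_controls,
              pools_per_group = pools_per_group, avg_coverage = avg_coverage,
              gamma_shape = gamma_shape, gamma_scale = gamma_scale,
              n_null = n_null, n_neutral = n_neutral, n_disease = n_disease,
              maf_grid = maf_grid, rr = rr, error_rate = error_rate, seed = seed)
  with(cfg, {
    if (n_cases < 1 || n_controls < 1 || pools_per_group < 1) {
      abort("person and pool counts must be positive.")
    }
    if (n_cases %% pools_per_group != 0 || n_controls %% pools_per_group != 0) {
      abort("persons per arm must divide evenly into pools.")
    }
    if (n_cases / pools_per_group != n_controls / pools_per_group) {
      abort("case and control pools must hold the same number of persons.")
    }
    if (avg_coverage <= 0 || gamma_shape <= 0 || gamma_scale <= 0) {
      abort("coverage and gamma parameters must be positive.")
    }
    if (n_null < 0 || n_neutral < 0 || n_disease < 0 ||
        n_null + n_neutral + n_disease < 1) {
      abort("SNP class counts must be non-negative with at least one SNP.")
    }
    if (any(maf_grid <= 0 | maf_grid > 0.5)) abort("`maf_grid` must lie in (0, 0.5].")
    if (rr <= 0) abort("`rr` must be positive.")
    if (error_rate < 0 || error_rate > 1) abort("`error_rate` must lie in [0, 1].")
  })
  structure(cfg, class = "sim_config")
}

#' Case MAF under a multiplicative per-allele risk model
#'
#' With per-allele relative risk `rr`, the case-chromosome minor allele
#' frequency is `q rr / (q rr + 1 - q)` for control MAF `q` — the
#' rare-disease odds form, under which the case-vs-control allele odds
#' ratio equals `rr` exactly.
#'
#' @param maf_control Control MAF in (0, 1); vectorised.
#' @param rr Per-allele relative risk (> 0).
#' @return Case MAF.
#' @examples
#' case_maf(0.5, 1.5) # 0.6
#' @export
case_maf <- function(maf_control, rr) {
  if (any(maf_control <= 0 | maf_control >= 1)) {
    abort("`maf_control` must lie strictly inside (0, 1).")
  }
  if (any(rr <= 0)) abort("`rr` must be positive.")
  maf_control * rr / (maf_control * rr + 1 - maf_control)
}

#' Simulate a pooled case-control sequencing dataset
#'
#' Per SNP, pool and person: the person's minor-allele genotype is drawn
#' binomially (2 chromosomes at the group MAF); the person's read depth is
#' gamma-distributed (rounded half-up to an integer, zero allowed); minor
#' reads are binomial in the personal allele fraction; each read is then
#' flipped to the other allele with probability `error_rate`
#' (symmetrically, in both directions). Pool counts are sums over the 50
#' persons. This person-level two-stage structure is what induces the
#' `1/s` between-pool variance component the EB2 model targets. The
#' population-major allele is written as `ref`, so counts feed straight
#' into [orient_major_allele()].
#'
#' @param config A [sim_config()].
#' @return List with `counts` (raw long count tibble), `design`
#'   ([pool_design()] with `s = 2 x` persons per pool) and `truth` (tibble
#'   `snp_id`, `class`, `maf_control`, `maf_case`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (!is.null(config$seed)) set.seed(config$seed)
  persons <- config$n_cases / config$pools_per_group
  n_pools <- 2L * config$pools_per_group
  pool_id <- sprintf("pool%02d", seq_len(n_pools))
  group <- rep(c("control", "case"), each = config$pools_per_group)
  design <- pool_design(pool_id, group, s = 2L * persons)

  n_snp <- config$n_null + config$n_neutral + config$n_disease
  cls <- rep(c("null", "neutral", "disease"),
             c(config$n_null, config$n_neutral, config$n_disease))
  maf_ctl <- numeric(n_snp)
  maf_ctl[cls != "null"] <- rep_len(config$maf_grid, sum(cls != "null"))
  maf_case_v <- maf_ctl
  maf_case_v[cls == "disease"] <- case_maf(maf_ctl[cls == "disease"], config$rr)
  snp_id <- sprintf("snp%05d", seq_len(n_snp))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_snp, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  truth <- tibble(snp_id = snp_id, class = cls,
                  maf_control = maf_ctl, maf_case = maf_case_v)

  # one long vector over (snp x pool x person); column-major: person fastest
  cell_snp <- rep(seq_len(n_snp), each = n_pools * persons)
  cell_pool <- rep(rep(seq_len(n_pools), each = persons), times = n_snp)
  maf_person <- ifelse(group[cell_pool] == "case",
                       maf_case_v[cell_snp], maf_ctl[cell_snp])
  n_cells <- length(cell_snp)
  geno <- rbinom(n_cells, 2L, maf_person)
  dep <- floor(rgamma(n_cells, shape = config$gamma_shape,
                      scale = config$gamma_scale) + 0.5)
  minor_true <- rbinom(n_cells, dep, geno / 2)
  e <- config$error_rate
  minor_obs <- if (e > 0) {
    rbinom(n_cells, minor_true, 1 - e) + rbinom(n_cells, dep - minor_true, e)
  } else minor_true
  idx <- (cell_snp - 1L) * n_pools + cell_pool
  pool_minor <- rowsum(minor_obs, idx)[, 1]
  pool_depth <- rowsum(dep, idx)[, 1]
  counts <- tibble(
    snp_id = snp_id[rep(seq_len(n_snp), each = n_pools)],
    chrom = "sim", pos = rep(seq_len(n_snp), each = n_pools),
    ref = ref[rep(seq_len(n_snp), each = n_pools)],
    alt = alt[rep(seq_len(n_snp), each = n_pools)],
    pool_id = pool_id[rep(seq_len(n_pools), times = n_snp)],
    ref_reads = as.numeric(pool_depth - pool_minor),
    alt_reads = as.numeric(pool_minor))
  list(counts = counts, design = design, truth = truth)
}

#' Run a blinded Type-1-error / power simulation study
#'
#' For each replicate and error rate: simulate a dataset, run the blinded
#' pipeline exactly as it would be run on real data — depth filter, MAF
#' partition, random-error screen of rare candidates (Bonferroni
#' denominator = number screened), error-rate estimation from the SNPs the
#' screen rejected, count correction of the surviving SNPs — then apply
#' the requested tests (chromosome-coverage filter on the Fisher path
#' only). Rejection rates at level `alpha` among `neutral` SNPs estimate
#' Type-1 error and among `disease` SNPs estimate power, reported per
#' method x error rate x control-MAF bin with binomial standard errors.
#'
#' @param config A [sim_config()] template; its `error_rate` is overridden
#'   by each element of `error_rates` in turn, and its `seed` seeds the
#'   per-replicate substreams.
#' @param methods Subset of `c("fisher", "eb1", "eb2")`.
#' @param alpha Significance level.
#' @param n_reps Replicates per error rate.
#' @param error_rates Symmetric error rates to scan.
#' @param n_perm Monte-Carlo resamples for the error screen (must exceed
#'   the rare-candidate count divided by `alpha` for the screen to have
#'   any resolution).
#' @param min_depth,maf_threshold,coverage_k,coverage_prob Pipeline
#'   parameters (see [filter_pipeline()], [chromosome_coverage_filter()]).
#' @param screen_method Tail computation for the error screen; the study
#'   defaults to the asymptotic `"chisq"` tail because at realistic
#'   candidate counts the Bonferroni threshold `alpha/n_tests` lies below
#'   the Monte-Carlo granularity floor `1/(n_perm + 1)`, and read totals in
#'   this regime are large enough for the asymptotic tail to be accurate.
#' @return Tibble: `method`, `error_rate`, `class`, `maf_control`,
#'   `n_tested`, `n_rejected`, `rate`, `se` (binomial), plus `n_excluded`
#'   counted separately.
#' @export
run_simulation_study <- function(config = sim_config(), methods = c("fisher", "eb2"),
                                 alpha = 0.05, n_reps = 10,
                                 error_rates = c(0, 0.01, 0.05),
                                 n_perm = 10000, min_depth = 8,
                                 maf_threshold = 0.05,
                                 coverage_k = 80, coverage_prob = 0.8,
                                 screen_method = c("chisq", "montecarlo")) {
  methods <- match.arg(methods, c("fisher", "eb1", "eb2"), several.ok = TRUE)
  screen_method <- match.arg(screen_method)
  if (n_reps < 1) abort("`n_reps` must be >= 1.")
  base_seed <- config$seed %||% sample.int(.Machine$integer.max, 1)
  grid <- tidyr::expand_grid(error_rate = error_rates, rep = seq_len(n_reps))
  res <- purrr::pmap(grid, function(error_rate, rep) {
    cfg <- config
    cfg$error_rate <- error_rate
    cfg$seed <- (base_seed + 7919L * rep + round(1e6 * error_rate)) %% 2147483647L
    sim <- simulate_dataset(cfg)
    oc <- orient_major_allele(sim$counts)
    report <- filter_pipeline(oc, sim$design, min_depth = min_depth,
                              maf_threshold = maf_threshold, n_perm = n_perm,
                              screen_method = screen_method)
    kept <- report$snp_id[report$called_true_snp]
    site_totals <- oc |>
      dplyr::group_by(.data$snp_id, .data$chrom, .data$pos, .data$ref, .data$alt) |>
      dplyr::summarise(ref_reads = sum(.data$ref_reads),
                       alt_reads = sum(.data$alt_reads), .groups = "drop")
    rates <- suppressWarnings(estimate_error_rates(
      site_totals, site_totals[site_totals$snp_id %in% kept, c("chrom", "pos")]))
    tested <- oc |> dplyr::filter(.data$snp_id %in% kept)
    corrected <- suppressMessages(correct_counts(tested, rates))
    out <- list()
    if ("fisher" %in% methods) {
      cov <- chromosome_coverage_filter(corrected, sim$design,
                                        k = coverage_k, prob = coverage_prob)
      out$fisher <- fisher_test(corrected, sim$design, cov$valid_pools)
    }
    if ("eb2" %in% methods) {
      fit <- fit_dispersion(corrected, sim$design)
      out$eb2 <- suppressMessages(eb2_test(corrected, sim$design, fit))
    }
    if ("eb1" %in% methods) out$eb1 <- eb1_test(corrected, sim$design)
    dplyr::bind_rows(out) |>
      dplyr::left_join(sim$truth, by = "snp_id") |>
      dplyr::mutate(error_rate = error_rate, rep = rep)
  })
  dplyr::bind_rows(res) |>
    dplyr::filter(.data$class %in% c("neutral", "disease")) |>
    dplyr::group_by(.data$method, .data$error_rate, .data$class, .data$maf_control) |>
    dplyr::summarise(
      n_tested = sum(.data$status == "tested"),
      n_excluded = sum(.data$status != "tested"),
      n_rejected = sum(.data$status == "tested" & .data$p_value <= alpha),
      .groups = "drop") |>
    dplyr::mutate(rate = ifelse(.data$n_tested > 0,
                                .data$n_rejected / .data$n_tested, NA_real_),
                  se = sqrt(.data$rate * (1 - .data$rate) / .data$n_tested),
                  alpha = alpha)
}
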