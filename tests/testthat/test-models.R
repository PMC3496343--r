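# independent two-sided Fisher oracle: sum of hypergeometric point masses
# no more probable than the observed table
hyper_two_sided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  dens <- dhyper(support, m, n, k)
  sum(dens[dens <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

test_that("fisher test builds chromosome-count tables and matches the hypergeometric oracle", {
  design <- pool_design(c("P1", "P2"), c("control", "case"), s = 96)
  counts <- make_counts(major = c(90, 96), depth = c(96, 96), design)
  res <- fisher_test(counts, design)
  expect_equal(res$major_control, 90)
  expect_equal(res$minor_control, 6)
  expect_equal(res$major_case, 96)
  expect_equal(res$minor_case, 0)
  expect_equal(res$p_value, hyper_two_sided(90, 6, 96, 0), tolerance = 1e-12)
  expect_equal(res$status, "tested")
})

test_that("fisher is symmetric: identical groups give p = 1, label swaps change nothing", {
  design <- make_design(4, s = 96)
  counts <- make_counts(major = c(900, 800, 900, 800), depth = rep(1000, 4), design)
  res <- fisher_test(counts, design)
  expect_equal(res$p_value, 1)
  # swap case/control labels
  design2 <- pool_design(design$pool_id, rev(design$group), s = 96)
  counts2 <- make_counts(major = c(850, 700, 920, 780), depth = rep(1000, 4), design)
  r1 <- fisher_test(counts2, design)
  r2 <- fisher_test(counts2, design2)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-9)
  # swap major/minor orientation
  flipped <- dplyr::mutate(counts2,
    major_reads = depth - major_reads, minor_reads = depth - minor_reads,
    major_allele = "G", minor_allele = "A",
    ref_reads = major_reads, alt_reads = minor_reads, ref = "G", alt = "A")
  r3 <- fisher_test(flipped, design)
  expect_equal(r1$p_value, r3$p_value, tolerance = 1e-12)
  expect_equal(r1$statistic, r3$statistic, tolerance = 1e-9)
})

test_that("fisher excludes SNPs with no valid pool in a group", {
  design <- make_design(4, s = 96)
  counts <- make_counts(major = c(900, 900, 0, 0), depth = c(1000, 1000, 0, 0),
                        design)
  res <- fisher_test(counts, design)
  expect_equal(res$status, "excluded")
  expect_true(is.na(res$p_value))
})

test_that("EB1 excludes zero-minor groups and reduces to the plain GLM at phi = 0", {
  design <- make_design(6, s = 96)
  # zero minor reads among controls -> excluded
  z <- make_counts(major = c(100, 100, 100, 95, 96, 97), depth = rep(100, 6), design)
  expect_equal(eb1_test(z, design)$status, "excluded")
  # phi fixed at 0: delta-X2 equals the Pearson X2 drop computed from two
  # ordinary logistic fits (independent route via stats::glm)
  y <- c(90, 85, 88, 70, 75, 72); R <- rep(100, 6)
  counts <- make_counts(y, R, design)
  res <- eb1_test(counts, design, phi = 0)
  grp <- factor(rep(c("control", "case"), each = 3), levels = c("control", "case"))
  g_full <- glm(cbind(y, R - y) ~ grp, family = binomial())
  g_null <- glm(cbind(y, R - y) ~ 1, family = binomial())
  px2 <- function(g) sum(residuals(g, type = "pearson")^2)
  expect_equal(res$statistic, px2(g_null) - px2(g_full), tolerance = 1e-8)
  expect_equal(res$df, 1L)
  expect_equal(res$p_value, pchisq(res$statistic, 1, lower.tail = FALSE))
})

test_that("EB1 dispersion estimate is near zero on pure binomial data and dX2 >= 0", {
  design <- pool_design(sprintf("P%02d", 1:20),
                        rep(c("control", "case"), each = 10), s = 96)
  n_snp <- 400
  withr::with_seed(51, {
    R <- rpois(n_snp * 20, 400)
    y <- rbinom(n_snp * 20, R, 0.85)
  })
  counts <- make_counts(y, R, design, snp_id = sprintf("b%04d", seq_len(n_snp)))
  res <- eb1_test(counts, design)
  tested <- res[res$status == "tested", ]
  expect_gt(nrow(tested), 350)
  # phi floored at zero, so its mean under a binomial truth is small but positive
  expect_lt(mean(tested$phi), 0.002)
  expect_true(all(tested$statistic >= 0))
  # the IRLS maximizes the quasi-likelihood, not the Pearson X2, so deleting
  # the factor can lower X2 by a small amount; the statistic floors at 0
  expect_true(all(tested$X2_null >= tested$X2_full - 0.05))
  # Type-1 error at nominal level, within Monte-Carlo error
  rej <- mean(tested$p_value <= 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(tested)))
})

test_that("EB1 estimates a positive phi on over-dispersed pools", {
  design <- pool_design(sprintf("P%02d", 1:20),
                        rep(c("control", "case"), each = 10), s = 96)
  withr::with_seed(52, {
    pj <- rbeta(20, 0.9 * 50, 0.1 * 50) # phi = 1/(50+1) ~ 0.0196
    y <- rbinom(20, 2000, pj)
  })
  counts <- make_counts(y, rep(2000, 20), design)
  fit <- fit_eb1(counts$major_reads, counts$depth,
                 rep(c("control", "case"), each = 10))
  expect_true(fit$converged)
  expect_gt(fit$phi, 0.005)
  expect_lt(fit$phi, 0.08)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$statistic, fit$statistic)
})

test_that("dispersion fit recovers generating (a, b) and the two-stage ideal", {
  design <- pool_design(sprintf("P%02d", 1:20),
                        rep(c("control", "case"), each = 10), s = 96)
  # generating values equal to the study's real-data estimates
  a <- 0.40; b <- 13.66
  withr::with_seed(61, {
    depths <- sample(200:4000, 2000 * 20, replace = TRUE)
    p_major <- runif(2000, 0.55, 0.95)
    counts <- simulate_under_law(2000, a, b, 96, design, depths, p_major)
  })
  fit <- fit_dispersion(counts, design)
  td <- tidy(fit)
  expect_lt(abs(fit$a - a), 3 * td$std.error[td$term == "a"])
  expect_lt(abs(fit$b - b), 3 * td$std.error[td$term == "b"])
  # no extra over-dispersion beyond two-stage sampling: a = b = 1
  withr::with_seed(62, {
    depths2 <- sample(200:4000, 1500 * 20, replace = TRUE)
    p2 <- runif(1500, 0.55, 0.95)
    pool_p <- rbinom(1500 * 20, 96, rep(p2, each = 20)) / 96
    y2 <- rbinom(1500 * 20, depths2, pool_p)
  })
  counts2 <- make_counts(y2, depths2, design, snp_id = sprintf("t%04d", seq_len(1500)))
  fit2 <- fit_dispersion(counts2, design)
  td2 <- tidy(fit2)
  expect_lt(abs(fit2$a - 1), 3 * td2$std.error[td2$term == "a"])
  expect_lt(abs(fit2$b - 1), 3 * td2$std.error[td2$term == "b"])
  # under-determined with a single SNP
  expect_error(fit_dispersion(counts[1:20, ], design), "at least 2")
})

test_that("EB2 with the identity adjustment is the Pearson chi-square on raw counts", {
  design <- make_design(6, s = 96)
  withr::with_seed(71, {
    for (i in 1:20) {
      R <- sample(50:500, 6)
      y <- rbinom(6, R, runif(1, 0.6, 0.95))
      counts <- make_counts(y, R, design)
      idfit <- dispersion_fit(a = 1, b = 0, s = 96) # R* = R
      res <- eb2_test(counts, design, idfit)
      tab <- rbind(control = c(sum(y[1:3]), sum(R[1:3] - y[1:3])),
                   case = c(sum(y[4:6]), sum(R[4:6] - y[4:6])))
      if (any(colSums(tab) == 0)) {
        expect_equal(res$statistic, 0)
      } else {
        oracle <- suppressWarnings(chisq.test(tab, correct = FALSE))
        expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-10)
        expect_equal(res$p_value, oracle$p.value, tolerance = 1e-10)
      }
    }
  })
})

test_that("EB2 matches a hand-computed adjusted table on a 4-pool toy", {
  design <- make_design(4, s = 96)
  a <- 2; b <- 5
  y <- c(180, 150, 110, 140); R <- c(200, 180, 130, 160)
  counts <- make_counts(y, R, design)
  res <- eb2_test(counts, design, dispersion_fit(a, b, 96))
  # explicit arithmetic, step by step
  h <- a + b * (R - 1) / 96
  rstar <- R / h
  adjM <- (y / R) * rstar
  adjm <- rstar - adjM
  M1 <- adjM[1] + adjM[2]; m1 <- adjm[1] + adjm[2]
  M2 <- adjM[3] + adjM[4]; m2 <- adjm[3] + adjm[4]
  N <- M1 + m1 + M2 + m2
  stat <- N * (M1 * m2 - M2 * m1)^2 /
    ((M1 + m1) * (M2 + m2) * (M1 + M2) * (m1 + m2))
  expect_equal(res$statistic, stat, tolerance = 1e-10)
  expect_equal(res$p_value, pchisq(stat, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(res$major_control, M1, tolerance = 1e-12)
  expect_equal(res$minor_case, m2, tolerance = 1e-12)
})

test_that("EB2 null identity, swap invariance and monotonicity in b", {
  design <- make_design(4, s = 96)
  same <- make_counts(major = rep(c(90, 80), 2), depth = rep(100, 4), design)
  res <- eb2_test(same, design, dispersion_fit(1.2, 3, 96))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  diff <- make_counts(major = c(95, 93, 80, 78), depth = rep(100, 4), design)
  r1 <- eb2_test(diff, design, dispersion_fit(1.2, 3, 96))
  design2 <- pool_design(design$pool_id, rev(design$group), s = 96)
  r2 <- eb2_test(diff, design2, dispersion_fit(1.2, 3, 96))
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  flipped <- dplyr::mutate(diff, major_reads = depth - major_reads,
                           minor_reads = depth - minor_reads)
  r3 <- eb2_test(flipped, design, dispersion_fit(1.2, 3, 96))
  expect_equal(r1$statistic, r3$statistic, tolerance = 1e-12)
  # growing b shrinks adjusted depths: statistic non-increasing
  stats <- vapply(c(0.5, 2, 8, 30), function(bb) {
    eb2_test(diff, design, dispersion_fit(1, bb, 96))$statistic
  }, numeric(1))
  expect_true(all(diff(stats) <= 1e-9))
})

test_that("EB2 drops non-positive adjusted depths and excludes emptied groups", {
  design <- make_design(4, s = 96)
  counts <- make_counts(major = c(90, 85, 80, 75),
                        depth = c(100, 100, 2000, 2000), design)
  # b < 0 makes h negative for deep pools: the whole case group is lost
  expect_message(res <- eb2_test(counts, design, dispersion_fit(1.5, -0.1, 96)),
                 "non-positive")
  expect_equal(res$status, "excluded")
})

test_that("odds ratio reproduces published values and basic identities", {
  expect_equal(round(odds_ratio(0.53, 0.41), 2), 0.62)
  expect_equal(round(odds_ratio(0.093, 0.15), 2), 1.72)
  expect_equal(odds_ratio(0.3, 0.3), 1)
  expect_equal(odds_ratio(c(0.1, 0.2), c(0.2, 0.1)), c(2.25, 1 / 2.25))
  expect_error(odds_ratio(0, 0.5), "strictly inside")
  expect_error(odds_ratio(0.5, 1), "strictly inside")
})

test_that("optional Benjamini-Hochberg column adjusts tested rows only", {
  res <- tibble::tibble(
    snp_id = paste0("s", 1:5), method = "eb2", statistic = 1, df = 1L,
    p_value = c(0.01, 0.02, 0.04, NA, 0.5),
    p_hat_control = 0.5, p_hat_case = 0.5, major_control = 1, minor_control = 1,
    major_case = 1, minor_case = 1,
    status = c("tested", "tested", "tested", "excluded", "tested"))
  out <- add_bh(res)
  tested <- !is.na(res$p_value)
  expect_equal(out$p_bh[tested], p.adjust(res$p_value[tested], "BH"))
  expect_true(is.na(out$p_bh[4]))
})
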