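# Small in-code fixtures shared across test files.

make_design <- function(n_pools = 4, s = 8) {
  pool_design(sprintf("P%d", seq_len(n_pools)),
              rep(c("control", "case"), each = n_pools / 2), s = s)
}

# Oriented counts for one or more SNPs from per-pool (major, depth) vectors.
make_counts <- function(major, depth, design, snp_id = "snp1",
                        ref = "A", alt = "G") {
  n <- nrow(design)
  stopifnot(length(major) %% n == 0)
  n_snp <- length(major) / n
  ids <- rep(if (length(snp_id) == n_snp) snp_id else paste0("snp", seq_len(n_snp)),
             each = n)
  tibble::tibble(
    snp_id = ids, chrom = "chr1", pos = rep(seq_len(n_snp), each = n),
    ref = ref, alt = alt, pool_id = rep(design$pool_id, n_snp),
    ref_reads = major, alt_reads = depth - major,
    major_allele = ref, minor_allele = alt,
    major_reads = major, minor_reads = depth - major, depth = depth)
}

# Raw (unoriented) counts tibble from ref/alt read vectors.
make_raw_counts <- function(ref_reads, alt_reads, design, snp_id = "snp1",
                            ref = "A", alt = "G") {
  n <- nrow(design)
  n_snp <- length(ref_reads) / n
  ids <- rep(if (length(snp_id) == n_snp) snp_id else paste0("snp", seq_len(n_snp)),
             each = n)
  tibble::tibble(
    snp_id = ids, chrom = "chr1", pos = rep(seq_len(n_snp), each = n),
    ref = ref, alt = alt, pool_id = rep(design$pool_id, n_snp),
    ref_reads = ref_reads, alt_reads = alt_reads)
}

# Symmetric 12-class error-rate table at a single rate.
flat_rates <- function(rate) {
  bases <- c("A", "C", "G", "T")
  out <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  out <- out[out$ref != out$alt, ]
  tibble::as_tibble(cbind(out, rate = rate))
}

# Pool counts drawn under the EB2 variance law Var(y) = R p (1-p) [a + b(R-1)/s]:
# per-pool frequency from a beta with variance c p(1-p), c = (a-1)/(R-1) + b/s,
# then binomial reads.
simulate_under_law <- function(n_snp, a, b, s, design, depths, p_major) {
  n <- nrow(design)
  out <- vector("list", n_snp)
  for (i in seq_len(n_snp)) {
    R <- depths[((i - 1) * n + 1):(i * n)]
    p <- p_major[i]
    cc <- (a - 1) / (R - 1) + b / s
    stopifnot(all(cc > 0 & cc < 1))
    nu <- 1 / cc - 1
    pj <- rbeta(n, p * nu, (1 - p) * nu)
    y <- rbinom(n, R, pj)
    out[[i]] <- make_counts(y, R, design, snp_id = sprintf("law%04d", i))
  }
  dplyr::bind_rows(out)
}
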