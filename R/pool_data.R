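#' Describe a pooled sequencing design
#'
#' A pooled case-control design is a set of `n` pools, each containing DNA
#' from the same number of individuals, so that every pool samples `s`
#' distinct chromosomes (`s = 2 *` individuals per pool for diploids).
#' `s` bounds the allele-frequency resolution of a pool from below: no pool
#' can show a true frequency finer than `1/s`.
#'
#' @param pool_id Character vector of unique pool identifiers.
#' @param group Character vector the same length as `pool_id`, each element
#'   `"case"` or `"control"`.
#' @param s Number of distinct chromosomes per pool. Must be an even integer
#'   `>= 2`.
#'
#' @return A tibble of class `"pool_design"` with columns `pool_id` and
#'   `group`, carrying `s` as an attribute (retrieve it with [design_s()]).
#' @examples
#' pool_design(paste0("P", 1:4), rep(c("control", "case"), each = 2), s = 96)
#' @export
pool_design <- function(pool_id, group, s) {
  pool_id <- as.character(pool_id)
  group <- as.character(group)
  if (length(pool_id) != length(group)) {
    abort("`pool_id` and `group` must have the same length.")
  }
  if (anyDuplicated(pool_id)) {
    abort("pool ids must be unique.")
  }
  bad <- setdiff(unique(group), c("case", "control"))
  if (length(bad)) {
    abort(paste0("unknown group label(s): ", paste(bad, collapse = ", "),
                 " (expected 'case' or 'control')."))
  }
  n <- length(pool_id)
  if (n < 2 || !all(c("case", "control") %in% group)) {
    abort("a design needs at least 2 pools with at least one case and one control pool.")
  }
  s <- as.integer(s)
  if (length(s) != 1 || is.na(s) || s < 2 || s %% 2 != 0) {
    abort("`s` must be a single even integer >= 2 (distinct chromosomes per pool).")
  }
  out <- tibble(pool_id = pool_id, group = group)
  attr(out, "s") <- s
  class(out) <- c("pool_design", class(out))
  out
}

#' @rdname pool_design
#' @param design A `pool_design`.
#' @export
design_s <- function(design) {
  s <- attr(design, "s", exact = TRUE)
  if (is.null(s)) abort("`design` carries no `s` attribute; build it with pool_design().")
  s
}

#' @export
print.pool_design <- function(x, ...) {
  cat(sprintf("<pool_design> %d pools (%d case, %d control), s = %d chromosomes/pool\n",
              nrow(x), sum(x$group == "case"), sum(x$group == "control"), design_s(x)))
  NextMethod()
}

raw_count_cols <- c("snp_id", "chrom", "pos", "ref", "alt",
                    "pool_id", "ref_reads", "alt_reads")

#' Validate a long table of per-SNP, per-pool allele read counts
#'
#' The canonical count layout is long: one row per SNP x pool with columns
#' `snp_id`, `chrom`, `pos`, `ref`, `alt`, `pool_id`, `ref_reads`,
#' `alt_reads`. After [orient_major_allele()] the table additionally carries
#' `major_allele`, `minor_allele`, `major_reads`, `minor_reads` and `depth`
#' (`major_reads + minor_reads`). A pool with no reads at a SNP is kept with
#' depth 0 rather than dropped.
#'
#' @param counts A data frame in the layout above.
#' @param design Optional [pool_design()]; when given, every SNP must have a
#'   row for every pool in the design.
#' @return `counts` as a tibble, invisibly unchanged, or an error naming the
#'   offending SNP/pool.
#' @export
validate_pool_counts <- function(counts, design = NULL) {
  counts <- as_tibble(counts)
  missing_cols <- setdiff(raw_count_cols, names(counts))
  if (length(missing_cols)) {
    abort(paste0("count table is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  bad_allele <- !grepl("^[ACGT]$", counts$ref) | !grepl("^[ACGT]$", counts$alt) |
    counts$ref == counts$alt
  if (any(bad_allele)) {
    abort(paste0("only bi-allelic SNVs are supported; offending SNP(s): ",
                 paste(unique(counts$snp_id[bad_allele]), collapse = ", ")))
  }
  for (col in c("ref_reads", "alt_reads")) {
    v <- counts[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0)) {
      i <- which(!is.finite(counts[[col]]) | counts[[col]] < 0)[1]
      abort(sprintf("invalid %s at SNP %s, pool %s (must be a non-negative number).",
                    col, counts$snp_id[i], counts$pool_id[i]))
    }
  }
  if (all(c("major_reads", "depth") %in% names(counts))) {
    bad <- counts$major_reads > counts$depth + 1e-9 | counts$major_reads < -1e-9
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf("major_reads > depth at SNP %s, pool %s.",
                    counts$snp_id[i], counts$pool_id[i]))
    }
  }
  if (anyDuplicated(counts[c("snp_id", "pool_id")])) {
    abort("duplicated (snp_id, pool_id) rows in count table.")
  }
  if (!is.null(design)) {
    extra <- setdiff(unique(counts$pool_id), design$pool_id)
    if (length(extra)) {
      abort(paste0("count table has pools absent from the design: ",
                   paste(extra, collapse = ", ")))
    }
    tab <- table(counts$snp_id)
    if (any(tab != nrow(design))) {
      abort(paste0("SNP(s) without a row for every design pool (encode missing pools as depth 0): ",
                   paste(names(tab)[tab != nrow(design)], collapse = ", ")))
    }
  }
  counts
}

#' Read a pooled allele-count table
#'
#' Two plain-text dialects are supported. `"generic"` is a wide TSV with
#' columns `snp_id`, `chrom`, `pos`, `ref`, `alt` followed by one
#' `<pool>_ref` / `<pool>_alt` pair of read-count columns per pool.
#' `"varscan"` reads one VarScan-style SNP call file per pool (columns
#' `chrom`, `position`, `ref`, `var`, `reads1`, `reads2`), with the files
#' named by a `file` column in the design sidecar; a SNP absent from a
#' pool's file gets depth 0 in that pool.
#'
#' @param path Path to the count TSV (`generic`) ; ignored entries other than
#'   the design's `file` column for `varscan` (pass `path = NULL`).
#' @param format `"generic"` or `"varscan"`.
#' @param design A [pool_design()], or the path of a design sidecar TSV with
#'   columns `pool_id`, `group`, optionally `s` (constant) and, for
#'   `varscan`, `file`.
#' @param s Chromosomes per pool, required if the design sidecar lacks an
#'   `s` column.
#' @return A list with elements `counts` (long tibble, see
#'   [validate_pool_counts()]) and `design` (a `pool_design`).
#' @export
read_count_table <- function(path, format = c("generic", "varscan"),
                             design = NULL, s = NULL) {
  format <- match.arg(format)
  if (is.character(design)) design <- read_design(design, s = s)
  if (!inherits(design, "pool_design")) {
    abort("`design` must be a pool_design or the path of a design sidecar TSV.")
  }
  if (format == "generic") {
    if (!file.exists(path)) abort(paste0("count file not found: ", path))
    wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                            col_types = readr::cols(snp_id = "c", chrom = "c",
                                                    pos = "i", ref = "c",
                                                    alt = "c", .default = "d"))
    prob <- readr::problems(wide)
    if (nrow(prob)) {
      abort(sprintf("malformed count table %s: parse problem at line %d (%s).",
                    path, prob$row[1] + 1L, prob$expected[1]))
    }
    need <- c("snp_id", "chrom", "pos", "ref", "alt")
    if (!all(need %in% names(wide))) {
      abort(paste0("generic count table must start with columns ",
                   paste(need, collapse = ", ")))
    }
    for (p in design$pool_id) {
      if (!all(paste0(p, c("_ref", "_alt")) %in% names(wide))) {
        abort(paste0("count table lacks columns for pool ", p, "."))
      }
    }
    counts <- purrr::map_dfr(design$pool_id, function(p) {
      dplyr::bind_cols(wide[need],
                       tibble(pool_id = p,
                              ref_reads = as.numeric(wide[[paste0(p, "_ref")]]),
                              alt_reads = as.numeric(wide[[paste0(p, "_alt")]])))
    })
  } else {
    files <- attr(design, "files", exact = TRUE)
    if (is.null(files)) {
      abort("varscan format needs a design sidecar with a `file` column.")
    }
    per_pool <- purrr::map2(design$pool_id, files, function(p, f) {
      if (!file.exists(f)) abort(paste0("varscan file not found for pool ", p, ": ", f))
      v <- readr::read_tsv(f, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(chrom = "c", position = "i",
                                                   ref = "c", var = "c",
                                                   reads1 = "d", reads2 = "d",
                                                   .default = "?"))
      need <- c("chrom", "position", "ref", "var", "reads1", "reads2")
      if (!all(need %in% names(v))) {
        abort(paste0("varscan file ", f, " must have columns ",
                     paste(need, collapse = ", ")))
      }
      tibble(snp_id = paste0(v$chrom, ":", v$position),
             chrom = as.character(v$chrom), pos = as.integer(v$position),
             ref = v$ref, alt = v$var, pool_id = p,
             ref_reads = as.numeric(v$reads1), alt_reads = as.numeric(v$reads2))
    })
    counts <- dplyr::bind_rows(per_pool) |>
      tidyr::complete(tidyr::nesting(!!!rlang::syms(c("snp_id", "chrom", "pos", "ref", "alt"))),
                      pool_id = design$pool_id,
                      fill = list(ref_reads = 0, alt_reads = 0))
  }
  counts <- validate_pool_counts(counts, design)
  counts <- counts |> dplyr::arrange(.data$snp_id, match(.data$pool_id, design$pool_id))
  list(counts = counts, design = design)
}

#' @rdname read_count_table
#' @export
read_design <- function(path, s = NULL) {
  if (!file.exists(path)) abort(paste0("design file not found: ", path))
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("pool_id", "group") %in% names(d))) {
    abort("design sidecar must have columns pool_id and group.")
  }
  if ("s" %in% names(d)) {
    sv <- unique(d$s)
    if (length(sv) != 1) abort("design sidecar column `s` must be constant.")
    s <- sv
  }
  if (is.null(s)) abort("supply `s` or include an `s` column in the design sidecar.")
  out <- pool_design(d$pool_id, d$group, s)
  if ("file" %in% names(d)) attr(out, "files") <- d$file
  out
}

#' Orient counts to the major allele
#'
#' An observation is treated as a success when it carries the major allele:
#' the allele with the larger total read count summed over all pools at that
#' SNP. On an exact tie the reference allele is taken as major, so the
#' operation is deterministic and idempotent.
#'
#' @inheritParams validate_pool_counts
#' @return The count tibble with columns `major_allele`, `minor_allele`,
#'   `major_reads`, `minor_reads` and `depth` added (recomputed if present).
#' @export
orient_major_allele <- function(counts) {
  counts <- validate_pool_counts(counts)
  counts |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::mutate(major_is_ref = sum(.data$ref_reads) >= sum(.data$alt_reads)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      major_allele = ifelse(.data$major_is_ref, .data$ref, .data$alt),
      minor_allele = ifelse(.data$major_is_ref, .data$alt, .data$ref),
      major_reads = ifelse(.data$major_is_ref, .data$ref_reads, .data$alt_reads),
      minor_reads = ifelse(.data$major_is_ref, .data$alt_reads, .data$ref_reads),
      depth = .data$ref_reads + .data$alt_reads,
      major_is_ref = NULL
    )
}

#' Write / re-read a count table in the generic wide dialect
#'
#' @inheritParams validate_pool_counts
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, design, path) {
  counts <- validate_pool_counts(counts, design)
  wide <- counts |>
    dplyr::select(dplyr::all_of(raw_count_cols)) |>
    tidyr::pivot_wider(names_from = "pool_id",
                       values_from = c("ref_reads", "alt_reads"),
                       names_glue = "{pool_id}_{ifelse(.value == 'ref_reads', 'ref', 'alt')}")
  ord <- c("snp_id", "chrom", "pos", "ref", "alt",
           as.vector(rbind(paste0(design$pool_id, "_ref"), paste0(design$pool_id, "_alt"))))
  readr::write_tsv(wide[ord], path, progress = FALSE)
  invisible(path)
}

result_cols <- c("snp_id", "method", "statistic", "df", "p_value",
                 "p_hat_control", "p_hat_case",
                 "major_control", "minor_control", "major_case", "minor_case",
                 "status")

#' Write association results to TSV
#'
#' One row per SNP with the method, test statistic, degrees of freedom,
#' p-value, estimated group major-allele frequencies, the 2x2 table that was
#' tested and a status flag (`tested`, `excluded` or `degenerate`). Excluded
#' SNPs keep their row with an empty p-value. Column order is fixed so files
#' round-trip byte-stably.
#'
#' @param results Tibble of association results (from [fisher_test()],
#'   [eb1_test()] or [eb2_test()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (!nrow(results)) abort("no results to write.")
  missing_cols <- setdiff(result_cols, names(results))
  if (length(missing_cols)) {
    abort(paste0("results are missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  readr::write_tsv(results[result_cols], path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort(paste0("results file not found: ", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    snp_id = "c", method = "c", statistic = "d", df = "i",
                    p_value = "d", p_hat_control = "d", p_hat_case = "d",
                    major_control = "d", minor_control = "d",
                    major_case = "d", minor_case = "d", status = "c"))
}
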