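#' Read an ASV count table
#'
#' Reads a TSV count table with samples in rows (first column = sample id)
#' and ASVs in columns, or a BIOM file (features x samples, transposed on
#' read; requires the biomformat package), returning a numeric matrix
#' with sample ids as row names.
#'
#' @param path Path to the TSV or `.biom` file.
#' @return Counts matrix, samples x ASVs.
#' @export
read_asv_table <- function(path) {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("reading BIOM files requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))
    if (any(m < 0)) abort("counts must be non-negative")
    return(m)
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  if (any(m < 0)) abort("counts must be non-negative")
  m
}

#' Filter samples by sequencing depth
#'
#' Removes samples whose total count is strictly lower than `min_total`
#' (a sample at exactly the threshold is retained).
#'
#' @param counts Counts matrix, samples x ASVs.
#' @param min_total Minimum total count per sample. Default 700.
#' @return Filtered counts matrix; removed sample ids in attribute
#'   `"removed_samples"`.
#' @export
filter_samples_by_depth <- function(counts, min_total = 700) {
  totals <- rowSums(counts)
  keep <- totals >= min_total
  if (!any(keep)) abort("all samples fall below the depth threshold")
  out <- counts[keep, , drop = FALSE]
  attr(out, "removed_samples") <- rownames(counts)[!keep]
  out
}

#' Filter ASVs by prevalence
#'
#' Removes ASVs present (count > 0) in strictly less than `min_prev` of the
#' retained samples.
#'
#' @param counts Depth-filtered counts matrix.
#' @param min_prev Minimum prevalence fraction. Default 0.05.
#' @return Filtered counts matrix; removed ASV ids in attribute
#'   `"removed_asvs"`.
#' @export
filter_asvs_by_prevalence <- function(counts, min_prev = 0.05) {
  prev <- colMeans(counts > 0)
  keep <- prev >= min_prev
  out <- counts[, keep, drop = FALSE]
  attr(out, "removed_asvs") <- colnames(counts)[!keep]
  out
}

#' Centred log-ratio transform with constant zero imputation
#'
#' Replaces zeros by a constant pseudo-value (the "const" approach:
#' by default 0.65 times the smallest non-zero count of the whole table)
#' and maps each sample row \eqn{x} to \eqn{\ln x - \mathrm{mean}(\ln x)}.
#'
#' @param counts Filtered counts matrix, samples x ASVs.
#' @param zero_const Pseudo-value replacing zeros; `NULL` (default) uses
#'   `0.65 * min(counts[counts > 0])`.
#' @return CLR matrix (rows sum to 0) with attribute `"zero_const"`.
#' @export
clr_transform <- function(counts, zero_const = NULL) {
  zero_rows <- rowSums(counts) == 0
  if (any(zero_rows)) {
    abort(sprintf("sample(s) with all-zero counts: %s",
                  paste(rownames(counts)[zero_rows], collapse = ", ")))
  }
  if (is.null(zero_const)) zero_const <- 0.65 * min(counts[counts > 0])
  x <- counts
  x[x == 0] <- zero_const
  lx <- log(x)
  clr <- lx - rowMeans(lx)
  attr(clr, "zero_const") <- zero_const
  clr
}

#' Aitchison distance between samples
#'
#' Pairwise Euclidean distance between CLR-transformed sample rows.
#'
#' @param clr CLR matrix from [clr_transform()].
#' @return A [stats::dist] object.
#' @export
aitchison_distance <- function(clr) {
  stats::dist(clr, method = "euclidean")
}

#' Per-sample alpha diversity
#'
#' Shannon entropy (nats) and inverse Simpson index, computed on the raw
#' (unfiltered) counts as in the source analyses.
#'
#' @param counts Counts matrix, samples x ASVs.
#' @return Tibble `sample_id, shannon, inv_simpson`; zero-total samples get
#'   `NA`.
#' @export
alpha_diversity <- function(counts) {
  totals <- rowSums(counts)
  sh <- rep(NA_real_, nrow(counts))
  inv <- rep(NA_real_, nrow(counts))
  ok <- totals > 0
  if (any(ok)) {
    sh[ok] <- vegan::diversity(counts[ok, , drop = FALSE], index = "shannon")
    inv[ok] <- vegan::diversity(counts[ok, , drop = FALSE],
                                index = "invsimpson")
  }
  tibble::tibble(sample_id = rownames(counts) %||%
                   as.character(seq_len(nrow(counts))),
                 shannon = sh, inv_simpson = inv)
}

#' Remove alpha-diversity outliers by Tukey fences
#'
#' Drops rows whose `metric` value lies beyond 1.5 interquartile ranges
#' above the third or below the first quartile (single pass; values exactly
#' at a fence are kept).
#'
#' @param diversity Tibble from [alpha_diversity()] (or any tibble).
#' @param metric Column name to screen. Default `"shannon"`.
#' @return Filtered tibble; removed ids in attribute `"removed_samples"`.
#' @export
remove_diversity_outliers <- function(diversity, metric = "shannon") {
  assert_cols(diversity, metric, "diversity")
  x <- diversity[[metric]]
  if (sum(!is.na(x)) < 4) abort("need at least 4 non-missing values")
  out_flag <- tukey_outliers(x)
  out <- diversity[!out_flag, , drop = FALSE]
  removed <- if ("sample_id" %in% names(diversity)) {
    diversity$sample_id[out_flag]
  } else which(out_flag)
  attr(out, "removed_samples") <- removed
  out
}

#' Microbial similarity kernel
#'
#' Column-standardises the CLR matrix (zero-variance columns are dropped
#' with a warning) and forms the inner-product kernel
#' \eqn{K = XX^\top / p} with \eqn{p} the number of retained ASVs, so the
#' mean diagonal is close to 1 (the usual relationship-matrix scaling).
#'
#' @param clr CLR matrix on the depth- and prevalence-filtered table.
#' @return Symmetric positive semi-definite kernel matrix with attribute
#'   `"n_features"`.
#' @export
build_kernel <- function(clr) {
  sds <- apply(clr, 2, sd)
  zero_var <- sds == 0 | is.na(sds)
  if (any(zero_var)) {
    warn(sprintf("dropping %d zero-variance column(s) before scaling",
                 sum(zero_var)))
    clr <- clr[, !zero_var, drop = FALSE]
  }
  x <- scale(clr)
  p <- ncol(x)
  k <- tcrossprod(x) / p
  k <- (k + t(k)) / 2
  attr(k, "n_features") <- p
  k
}
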