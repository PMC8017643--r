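#' Construct a count matrix with sample annotations
#'
#' The basic container for the pipeline: an integer gene-by-sample count
#' matrix plus a per-sample metadata table. Genotype/age/region columns in
#' `meta` define the strata the differential-expression stage fits within.
#'
#' @param counts integer matrix, genes in rows (rownames = gene IDs),
#'   samples in columns (colnames = sample IDs). All entries must be
#'   non-negative integers.
#' @param meta data frame with one row per sample; must contain a
#'   `sample_id` column matching `colnames(counts)` in order or by name.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (integer matrix) and `meta` (data frame, rows aligned to
#'   columns of `counts`).
#' @export
count_matrix <- function(counts, meta) {
  if (!is.matrix(counts)) .fail("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    .fail("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    .fail("duplicate gene IDs: ",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts))) .fail("duplicate sample IDs")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    .fail("non-integer or negative count at gene ", rownames(counts)[bad[1, 1]],
          ", sample ", colnames(counts)[bad[1, 2]])
  if (!is.data.frame(meta) || is.null(meta$sample_id))
    .fail("meta must be a data frame with a sample_id column")
  missing <- setdiff(colnames(counts), meta$sample_id)
  extra   <- setdiff(meta$sample_id, colnames(counts))
  if (length(missing) || length(extra))
    .fail("sample mismatch between counts and metadata; ",
          "missing from metadata: [", paste(missing, collapse = ", "),
          "]; absent from counts: [", paste(extra, collapse = ", "), "]")
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  ann <- intersect(c("genotype", "age", "region"), names(x$meta))
  if (length(ann))
    cat("annotations:", paste(ann, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Load a count matrix and its sample metadata from TSV files
#'
#' The counts file has gene IDs in the first column and one column per
#' sample; the metadata file has one row per sample with a `sample_id`
#' column. Ordering is preserved from the files.
#'
#' @param counts_path path to the counts TSV.
#' @param meta_path path to the metadata TSV.
#' @return A [count_matrix].
#' @export
load_experiment <- function(counts_path, meta_path) {
  ctab <- .read_tsv(counts_path)
  meta <- .read_tsv(meta_path)
  if (ncol(ctab) < 2) .fail("counts file needs a gene column plus samples")
  genes <- as.character(ctab[[1]])
  m <- as.matrix(ctab[, -1, drop = FALSE])
  if (!is.numeric(m)) .fail("non-numeric entries in counts file")
  rownames(m) <- genes
  count_matrix(m, meta)
}

#' Remove genes with too many low counts
#'
#' A gene is excluded when the number of samples in which its count is
#' below `min_count` reaches `min_samples`. With the defaults this is the
#' rule "exclude genes having less than 10 counts in at least 10 samples",
#' read literally per sample. Samples are never removed.
#'
#' @param cm a [count_matrix].
#' @param min_count counts below this are "low" (default 10).
#' @param min_samples number of low samples at which a gene is dropped
#'   (default 10). Must not exceed the number of samples, otherwise the
#'   rule could never trigger.
#' @return A [count_matrix] with the failing genes removed.
#' @export
filter_low_counts <- function(cm, min_count = 10L, min_samples = 10L) {
  stopifnot(inherits(cm, "count_matrix"))
  min_count <- .check_count(min_count, "min_count", min = 0L)
  min_samples <- .check_count(min_samples, "min_samples", min = 1L)
  if (min_samples > ncol(cm$counts))
    .fail("min_samples (", min_samples, ") exceeds number of samples (",
          ncol(cm$counts), "); the filter could never trigger")
  n_low <- rowSums(cm$counts < min_count)
  keep <- n_low < min_samples
  out <- cm
  out$counts <- cm$counts[keep, , drop = FALSE]
  out
}

# Reference sample for TMM: the one whose upper-quartile CPM is closest to
# the mean upper-quartile, as in the published definition.
.tmm_ref <- function(counts, lib) {
  f75 <- apply(counts, 2, function(y) stats::quantile(y / sum(y), 0.75))
  if (median(f75) < 1e-20) return(which.max(colSums(sqrt(counts))))
  which.min(abs(f75 - mean(f75)))
}

# One pairwise TMM factor (log2 scale), sample obs vs sample ref.
.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim, a_cutoff) {
  pos <- obs > 0 & ref > 0
  obs <- obs[pos]; ref <- ref[pos]
  if (!length(obs)) .fail("no genes shared with the reference sample")
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  # delta-method (binomial) asymptotic variance of M
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a) & a > a_cutoff
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (!length(m)) .fail("no usable genes after A-value cutoff")
  if (max(abs(m)) < 1e-6) return(0)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abs_trim) + 1;      hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m & rank(a) >= lo_a & rank(a) <= hi_a
  sum(m[keep] / v[keep]) / sum(1 / v[keep])
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: each sample is compared to a reference sample
#' (the one whose 75th-percentile CPM is closest to the mean of those
#' percentiles). Over genes with positive counts in both samples, M-values
#' (log2 ratio of library-size-normalized counts) and A-values (average
#' log2 abundance) are computed; the most extreme `logratio_trim` fraction
#' of M and `abs_trim` fraction of A are trimmed from each tail, and the
#' factor is the inverse-variance-weighted mean of the remaining M-values
#' (delta-method weights). Factors are rescaled to geometric mean 1.
#'
#' @param cm a [count_matrix]; every sample must have positive library size.
#' @param logratio_trim fraction of M-values trimmed from each tail
#'   (default 0.3).
#' @param abs_trim fraction of A-values trimmed from each tail
#'   (default 0.05).
#' @param a_cutoff genes with A-value at or below this are discarded
#'   before trimming (default -1e10, i.e. effectively off).
#' @return A data frame of class `norm_factors` with columns `sample_id`,
#'   `lib_size`, `tmm_factor` and `effective_lib` (= lib_size * tmm_factor).
#' @references Robinson MD, Oshlack A (2010). A scaling normalization
#'   method for differential expression analysis of RNA-seq data.
#'   Genome Biology 11:R25.
#' @export
tmm_factors <- function(cm, logratio_trim = 0.3, abs_trim = 0.05,
                        a_cutoff = -1e10) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  lib <- colSums(counts)
  if (any(lib <= 0))
    .fail("zero library size for sample(s): ",
          paste(colnames(counts)[lib <= 0], collapse = ", "))
  r <- .tmm_ref(counts, lib)
  logf <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == r) return(0)
    .tmm_pair(counts[, j], counts[, r], lib[j], lib[r],
              logratio_trim, abs_trim, a_cutoff)
  }, numeric(1))
  f <- 2^logf
  f <- f / .geomean(f)
  structure(data.frame(sample_id = colnames(counts), lib_size = lib,
                       tmm_factor = f, effective_lib = lib * f,
                       row.names = NULL),
            class = c("norm_factors", "data.frame"), ref_sample = r)
}

#' log2 counts per million
#'
#' `log2((count + prior_count) / (effective_lib + 2 * prior_count) * 1e6)`,
#' with the effective library size from TMM normalization.
#'
#' @param cm a [count_matrix].
#' @param nf normalization factors from [tmm_factors()], aligned with the
#'   samples of `cm`.
#' @param prior_count pseudo-count stabilising the log at zero counts
#'   (default 0.5).
#' @return Numeric matrix of logCPM values, genes x samples.
#' @export
logcpm <- function(cm, nf, prior_count = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!identical(as.character(nf$sample_id), colnames(cm$counts)))
    .fail("normalization factors not aligned with count matrix samples")
  .check_scalar_num(prior_count, "prior_count", lower = 0)
  el <- nf$effective_lib
  log2(sweep(cm$counts + prior_count, 2, el + 2 * prior_count, "/") * 1e6)
}
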