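#' Construct a qPCR Ct table
#'
#' Genes x samples matrix of threshold-cycle values with per-sample
#' condition annotations. Undetermined reactions are encoded as `NA`,
#' never as 0; any non-missing Ct must be finite and positive.
#'
#' @param ct numeric matrix with gene rownames and sample colnames.
#' @param meta data frame with `sample_id` and `condition` columns.
#' @param candidate_endogenous character vector of candidate reference
#'   genes (subset of the table's genes).
#' @return A list of class `ct_table`: `ct`, `meta`,
#'   `candidate_endogenous`.
#' @export
ct_table <- function(ct, meta, candidate_endogenous = character(0)) {
  if (!is.matrix(ct) || !is.numeric(ct)) .fail("ct must be a numeric matrix")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    .fail("ct needs gene rownames and sample colnames")
  bad <- !is.na(ct) & (!is.finite(ct) | ct <= 0)
  if (any(bad)) .fail("Ct values must be positive and finite (or NA)")
  if (!is.data.frame(meta) || !all(c("sample_id", "condition") %in% names(meta)))
    .fail("meta needs sample_id and condition columns")
  if (!setequal(meta$sample_id, colnames(ct)))
    .fail("metadata samples do not match Ct columns")
  meta <- meta[match(colnames(ct), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (!all(candidate_endogenous %in% rownames(ct)))
    .fail("candidate endogenous genes missing from the table")
  structure(list(ct = ct, meta = meta,
                 candidate_endogenous = as.character(candidate_endogenous)),
            class = "ct_table")
}

#' Read a Ct table and sample metadata from TSV files
#'
#' @param ct_path TSV with gene IDs in the first column and one column per
#'   sample; empty cells are undetermined reactions (`NA`).
#' @param meta_path TSV with `sample_id` and `condition` columns.
#' @param candidates optional candidate endogenous gene names.
#' @return A [ct_table].
#' @export
read_ct_table <- function(ct_path, meta_path, candidates = character(0)) {
  tab <- .read_tsv(ct_path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  ct_table(m, .read_tsv(meta_path), candidate_endogenous = candidates)
}

#' Rank candidate endogenous controls by stability
#'
#' Stability is the standard deviation of a candidate's raw Ct across all
#' samples (all tissues and conditions pooled), ranked ascending; the mean
#' Ct is reported alongside. Candidates with more than 50% missing values
#' are excluded with a warning. The top `k` candidates are selected.
#'
#' @param ct a [ct_table]; its `candidate_endogenous` slot (or
#'   `candidates`) names the candidates.
#' @param k number of controls to select (default 2).
#' @param candidates optional override of the candidate list.
#' @param metric `"sd"` (default) or `"cv"` (coefficient of variation).
#' @return A list: `report` (data frame: `gene`, `mean_ct`, `sd_ct`,
#'   `n_missing`, ranked by stability) and `selected` (character vector,
#'   length `k`).
#' @export
select_endogenous <- function(ct, k = 2L, candidates = NULL, metric = c("sd", "cv")) {
  stopifnot(inherits(ct, "ct_table"))
  metric <- match.arg(metric)
  k <- .check_count(k, "k", min = 1L)
  cand <- if (is.null(candidates)) ct$candidate_endogenous else candidates
  if (!length(cand)) .fail("no candidate endogenous genes")
  if (!all(cand %in% rownames(ct$ct))) .fail("candidates missing from table")
  n <- ncol(ct$ct)
  miss <- rowSums(is.na(ct$ct[cand, , drop = FALSE]))
  usable <- miss <= n / 2
  if (any(!usable))
    warning("excluding candidates with >50% missing Ct: ",
            paste(cand[!usable], collapse = ", "))
  cand <- cand[usable]
  if (length(cand) < k) .fail("fewer than k usable candidates")
  mu <- rowMeans(ct$ct[cand, , drop = FALSE], na.rm = TRUE)
  sdv <- apply(ct$ct[cand, , drop = FALSE], 1, stats::sd, na.rm = TRUE)
  stat <- if (metric == "sd") sdv else sdv / mu
  ord <- order(stat, cand)
  report <- data.frame(gene = cand[ord], mean_ct = mu[ord], sd_ct = sdv[ord],
                       n_missing = miss[usable][ord], row.names = NULL,
                       stringsAsFactors = FALSE)
  list(report = report, selected = report$gene[seq_len(k)])
}

#' Per-sample reference Ct from endogenous controls
#'
#' Geometric mean of the endogenous genes' Ct values per sample (of the Ct
#' values themselves, the convention stated for combined reference genes).
#' Samples in which any endogenous Ct is missing get `NA` and are excluded
#' downstream.
#'
#' @param ct a [ct_table].
#' @param endogenous character vector of selected control genes.
#' @return Named numeric vector, one reference Ct per sample.
#' @export
reference_ct <- function(ct, endogenous) {
  stopifnot(inherits(ct, "ct_table"))
  if (!all(endogenous %in% rownames(ct$ct)))
    .fail("endogenous genes missing from table")
  m <- ct$ct[endogenous, , drop = FALSE]
  ref <- apply(m, 2, function(v) if (anyNA(v)) NA_real_ else .geomean(v))
  if (anyNA(ref))
    warning("missing endogenous Ct; samples excluded: ",
            paste(names(ref)[is.na(ref)], collapse = ", "))
  ref
}

#' Delta-Ct normalization
#'
#' `delta_Ct = Ct(gene) - Ct(reference)` per sample; missing gene Ct or
#' missing reference propagates to `NA`.
#'
#' @param ct a [ct_table].
#' @param reference per-sample reference Ct from [reference_ct()].
#' @return Numeric matrix of delta-Ct values, genes x samples.
#' @export
delta_ct <- function(ct, reference) {
  stopifnot(inherits(ct, "ct_table"))
  if (!identical(names(reference), colnames(ct$ct)))
    .fail("reference not aligned with Ct samples")
  sweep(ct$ct, 2, reference, "-")
}

#' Compare delta-Ct values between two conditions
#'
#' Per gene: two-sided equal-variance Student's t-test on delta-Ct
#' (`welch = TRUE` switches to Welch), with
#' `ddct = mean dCt(second level) - mean dCt(first level)`; a planted
#' 2-fold expression increase in the second condition gives ddct near -1.
#' p-values are BH-adjusted across genes. Genes with fewer than 2 usable
#' samples in a group are skipped with a warning.
#'
#' @param dct delta-Ct matrix from [delta_ct()].
#' @param groups per-sample condition labels (two levels; the first
#'   factor level is the baseline).
#' @param welch use Welch's unequal-variance t-test (default FALSE).
#' @return A data frame of class `dct_result`: `gene`, `mean_dct_<A>`,
#'   `mean_dct_<B>`, `ddct`, `p`, `adj_p`.
#' @export
compare_groups <- function(dct, groups, welch = FALSE) {
  g <- factor(groups)
  if (nlevels(g) != 2L) .fail("exactly two conditions required")
  if (length(g) != ncol(dct)) .fail("groups must match samples")
  a <- levels(g)[1]; b <- levels(g)[2]
  res <- lapply(rownames(dct), function(gene) {
    va <- dct[gene, g == a]; vb <- dct[gene, g == b]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (length(va) < 2 || length(vb) < 2) {
      warning("gene ", gene, " skipped: <2 usable samples in a group")
      return(NULL)
    }
    p <- if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
      if (mean(va) == mean(vb)) 1 else .Machine$double.xmin
    } else stats::t.test(vb, va, var.equal = !welch)$p.value
    data.frame(gene = gene, mean_a = mean(va), mean_b = mean(vb),
               ddct = mean(vb) - mean(va), p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) .fail("no gene with enough samples in both groups")
  res$adj_p <- bh_adjust(res$p)
  names(res)[names(res) == "mean_a"] <- paste0("mean_dct_", a)
  names(res)[names(res) == "mean_b"] <- paste0("mean_dct_", b)
  structure(res, class = c("dct_result", "data.frame"),
            baseline = a, comparison = b)
}

#' qPCR validation in one call
#'
#' Stability-based endogenous-control selection, geometric-mean reference,
#' delta-Ct and group comparison with FDR correction.
#'
#' @param ct a [ct_table].
#' @param k number of endogenous controls (default 2).
#' @param exclude genes reported but never tested (e.g. an
#'   overall-expression check gene); they are excluded from the
#'   comparison, not from the stability report.
#' @return A list of class `qpcr_fit`: `endogenous` (selection report),
#'   `reference` (per-sample Ct), `results` (the [compare_groups()]
#'   table over non-control, non-excluded genes).
#' @export
qpcr_validate <- function(ct, k = 2L, exclude = character(0)) {
  sel <- select_endogenous(ct, k = k)
  ref <- reference_ct(ct, sel$selected)
  dct <- delta_ct(ct, ref)
  targets <- setdiff(rownames(dct), c(sel$selected, exclude))
  res <- compare_groups(dct[targets, , drop = FALSE], ct$meta$condition)
  structure(list(endogenous = sel, reference = ref, results = res),
            class = "qpcr_fit")
}

#' @export
print.qpcr_fit <- function(x, ...) {
  cat("qpcr_fit: controls =", paste(x$endogenous$selected, collapse = ", "),
      ";", nrow(x$results), "target genes,",
      sum(x$results$adj_p < 0.05), "with adj_p < 0.05\n")
  invisible(x)
}
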