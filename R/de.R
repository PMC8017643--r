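#' Precision weights from the mean-variance trend of logCPM
#'
#' Implements the voom idea: fit an ordinary per-gene linear model on
#' logCPM, take the square root of each gene's residual standard deviation
#' (a quarter-root variance, which makes the trend nearly symmetric), smooth
#' it against average log-expression with `lowess`, predict the trend at
#' every observation's fitted value, and set the observation weight to the
#' predicted value to the power -4 (an inverse predicted variance).
#' Counting noise shrinks with abundance, so weights typically increase
#' with expression.
#'
#' @param logcpm numeric matrix of log2-CPM values, genes x samples.
#' @param design design matrix (samples x coefficients), full column rank,
#'   with at least 2 residual degrees of freedom.
#' @param span lowess smoother span (default 0.5).
#' @return A list of class `weighted_expression`: `E` (the logCPM matrix),
#'   `weights` (positive finite matrix, same shape), `design`.
#' @references Law CW, Chen Y, Shi W, Smyth GK (2014). voom: precision
#'   weights unlock linear model analysis tools for RNA-seq read counts.
#'   Genome Biology 15:R29.
#' @export
voom_weights <- function(logcpm, design, span = 0.5) {
  if (!is.matrix(logcpm) || !is.numeric(logcpm)) .fail("logcpm must be a numeric matrix")
  design <- as.matrix(design)
  n <- ncol(logcpm)
  if (nrow(design) != n) .fail("design rows must match samples")
  r <- qr(design)$rank
  if (r < ncol(design)) .fail("design matrix is rank-deficient")
  if (n - r < 2) .fail("need at least 2 residual degrees of freedom")
  fit <- stats::lm.fit(design, t(logcpm))
  res <- t(fit$residuals)                       # genes x samples
  sigma <- sqrt(rowSums(res^2) / (n - r))
  sqrt_sd <- sqrt(sigma)
  avg <- rowMeans(logcpm)
  lo <- stats::lowess(avg, sqrt_sd, f = span)
  fitted <- t(design %*% fit$coefficients)      # genes x samples
  pred <- stats::approx(lo$x, lo$y, xout = fitted, rule = 2, ties = mean)$y
  pred <- pmax(pred, 1e-4)                      # keep weights finite
  w <- matrix(pred^(-4), nrow = nrow(logcpm), ncol = n,
              dimnames = dimnames(logcpm))
  structure(list(E = logcpm, weights = w, design = design),
            class = "weighted_expression")
}

#' Per-gene weighted least squares for one contrast
#'
#' Fits a weighted linear model per gene and extracts the contrast
#' estimate (the log2 fold change), its unscaled standard deviation, the
#' weighted residual standard deviation and the residual degrees of
#' freedom. Weights are used relatively, so rescaling all weights by a
#' constant leaves estimates and t-statistics unchanged.
#'
#' @param we a [voom_weights()] result (or any list with `E`, `weights`,
#'   `design`).
#' @param contrast numeric contrast vector over the design coefficients;
#'   default selects the last coefficient (the group effect in an
#'   intercept + group design).
#' @return A data frame of class `gene_fit`: `gene`, `logFC`,
#'   `stdev_unscaled`, `sigma`, `df_residual`.
#' @export
fit_contrast <- function(we, contrast = NULL) {
  stopifnot(inherits(we, "weighted_expression") ||
              all(c("E", "weights", "design") %in% names(we)))
  X <- as.matrix(we$design)
  p <- ncol(X); n <- nrow(X)
  if (qr(X)$rank < p) .fail("design matrix is rank-deficient")
  if (n <= p) .fail("fewer samples than coefficients")
  if (is.null(contrast)) contrast <- c(rep(0, p - 1), 1)
  if (length(contrast) != p) .fail("contrast length must match coefficients")
  E <- we$E; W <- we$weights
  if (any(!is.finite(W)) || any(W <= 0)) .fail("weights must be positive and finite")
  ng <- nrow(E)
  beta <- su <- sg <- numeric(ng)
  df <- n - p
  for (g in seq_len(ng)) {
    w <- W[g, ]
    Xw <- X * w
    XtWX <- crossprod(X, Xw)
    V <- chol2inv(chol(XtWX))
    b <- V %*% crossprod(Xw, E[g, ])
    r2 <- sum(w * (E[g, ] - X %*% b)^2)
    beta[g] <- sum(contrast * b)
    su[g] <- sqrt(drop(t(contrast) %*% V %*% contrast))
    sg[g] <- sqrt(r2 / df)
  }
  structure(data.frame(gene = rownames(E), logFC = beta, stdev_unscaled = su,
                       sigma = sg, df_residual = df, stringsAsFactors = FALSE),
            class = c("gene_fit", "data.frame"))
}

# Inverse of the trigamma function by Newton iteration (monotone on (0, Inf))
.trigamma_inverse <- function(y, tol = 1e-8, max_iter = 50L) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(max_iter)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < tol) break
  }
  x
}

#' Empirical-Bayes moderated t-statistics
#'
#' Shrinks gene-wise residual variances toward a common prior estimated by
#' matching the first two moments of `log(sigma^2)` to a scaled-F model:
#' the prior degrees of freedom `d0` solve a trigamma equation (Newton
#' iteration, tolerance 1e-8) and the prior variance `s0^2` follows from a
#' digamma identity. The posterior variance is the df-weighted average
#' `(d0 s0^2 + df sigma^2) / (d0 + df)`; when the gene-wise variances show
#' no excess variability beyond sampling (`d0` infinite) every posterior
#' variance equals `s0^2`. Moderated t = logFC / (posterior SD x unscaled
#' SD), with two-sided p from a t distribution on `d0 + df` degrees of
#' freedom. p-values are Benjamini-Hochberg adjusted across genes.
#'
#' @param fit a [fit_contrast()] result; needs at least 2 genes with
#'   positive residual degrees of freedom.
#' @return A data frame of class `gene_stats`: `gene`, `logFC`, `t_mod`,
#'   `p`, `adj_p`, `s2_post`, `df_total`. Attributes `d0` and `s02` hold
#'   the prior.
#' @references Smyth GK (2004). Linear models and empirical Bayes methods
#'   for assessing differential expression in microarray experiments.
#'   Stat Appl Genet Mol Biol 3:Article 3.
#' @export
moderated_stats <- function(fit) {
  stopifnot(is.data.frame(fit),
            all(c("gene", "logFC", "stdev_unscaled", "sigma", "df_residual")
                %in% names(fit)))
  s2 <- fit$sigma^2
  df <- fit$df_residual
  ok <- df > 0 & is.finite(s2) & s2 > 0
  if (sum(ok) < 2) .fail("need at least 2 genes with positive residual variance")
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s02 + df * s2) / (d0 + df)
  } else {
    # no excess variability beyond sampling: common variance, plain mean
    d0 <- Inf
    s02 <- mean(s2[ok])
    s2_post <- rep(s02, length(s2))
  }
  df_total <- d0 + df
  t_mod <- fit$logFC / (sqrt(s2_post) * fit$stdev_unscaled)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p <- pmax(p, .Machine$double.xmin)            # keep p in (0, 1]
  structure(data.frame(gene = fit$gene, logFC = fit$logFC, t_mod = t_mod,
                       p = p, adj_p = bh_adjust(p), s2_post = s2_post,
                       df_total = df_total, stringsAsFactors = FALSE),
            class = c("gene_stats", "data.frame"), d0 = d0, s02 = s02)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper over the standard step-up procedure:
#' `adj_(i) = min over j >= i of min(1, m p_(j) / j)`, returned in input
#' order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, elementwise at least `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    .fail("p-values must be in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is DE iff `|logFC| > lfc_threshold` and `adj_p < alpha`, both
#' strict. The default 0.585 corresponds to a 1.5-fold change.
#'
#' @param stats a [moderated_stats()] table.
#' @param lfc_threshold absolute log2 fold-change threshold (default 0.585).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return `stats` with a logical `is_de` column added.
#' @export
call_de <- function(stats, lfc_threshold = 0.585, alpha = 0.05) {
  stopifnot(is.data.frame(stats),
            all(c("logFC", "adj_p") %in% names(stats)))
  stats$is_de <- abs(stats$logFC) > lfc_threshold & stats$adj_p < alpha
  stats
}

#' Rank genes by signed -log(p)
#'
#' Score = `-log(max(p, p_floor)) * sign(logFC)` (log base 10 by default;
#' `sign(0)` is 0), sorted descending with ties broken by gene identifier,
#' so the ordering is stable and platform-independent. This is the input
#' for pre-ranked GSEA.
#'
#' @param stats a table with `gene`, `p` and `logFC` columns.
#' @param log_base 10 or `exp(1)`; the base does not change the ordering.
#' @param p_floor underflow floor applied to p before the log
#'   (default 1e-300).
#' @return A data frame of class `ranked_list`: `gene`, `score`,
#'   descending.
#' @export
rank_genes <- function(stats, log_base = 10, p_floor = 1e-300) {
  stopifnot(is.data.frame(stats))
  if (is.null(stats$p) || anyNA(stats$p)) .fail("missing p-values")
  if (is.null(stats$logFC)) .fail("missing logFC")
  score <- -log(pmax(stats$p, p_floor), base = log_base) * sign(stats$logFC)
  ord <- order(-score, stats$gene)
  structure(data.frame(gene = stats$gene[ord], score = score[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

#' Write a ranked list in RNK format
#'
#' Two tab-separated columns (gene, score), no header, descending score.
#'
#' @param ranked a [rank_genes()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(ranked, path) {
  utils::write.table(ranked[, c("gene", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an RNK file
#' @param path two-column tab-separated file (gene, score), no header.
#' @return A `ranked_list` data frame, re-sorted descending with gene-name
#'   tie-breaking.
#' @export
read_rnk <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          col.names = c("gene", "score"),
                          stringsAsFactors = FALSE)
  ord <- order(-df$score, df$gene)
  structure(df[ord, , drop = FALSE], class = c("ranked_list", "data.frame"))
}

#' Differential expression for one two-group stratum
#'
#' Convenience wrapper running the whole DE stage on a (filtered) count
#' matrix: TMM normalization, logCPM, precision weights, weighted linear
#' fit of the group contrast, empirical-Bayes moderation, BH adjustment
#' and DE calling.
#'
#' @param cm a [count_matrix]; `group_col` of its metadata must have
#'   exactly two levels. The first level (factor order) is the baseline,
#'   so positive logFC means higher in the second level.
#' @param group_col metadata column defining the comparison
#'   (default "genotype").
#' @param lfc_threshold,alpha DE thresholds, see [call_de()].
#' @param prior_count,span passed to [logcpm()] and [voom_weights()].
#' @return An object of class `de_fit`: list with `stats` (the
#'   [call_de()] table), `ranked` (the [rank_genes()] list), `norm`
#'   (TMM factors), `group_col`, `levels`.
#' @export
de_fit <- function(cm, group_col = "genotype", lfc_threshold = 0.585,
                   alpha = 0.05, prior_count = 0.5, span = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  g <- cm$meta[[group_col]]
  if (is.null(g)) .fail("metadata has no column '", group_col, "'")
  g <- factor(g)
  if (nlevels(g) != 2L) .fail("group column must have exactly two levels")
  nf <- tmm_factors(cm)
  E <- logcpm(cm, nf, prior_count = prior_count)
  design <- stats::model.matrix(~g)
  we <- voom_weights(E, design, span = span)
  stats <- call_de(moderated_stats(fit_contrast(we)),
                   lfc_threshold = lfc_threshold, alpha = alpha)
  structure(list(stats = stats, ranked = rank_genes(stats), norm = nf,
                 group_col = group_col, levels = levels(g)),
            class = "de_fit")
}

#' @export
print.de_fit <- function(x, ...) {
  up <- sum(x$stats$is_de & x$stats$logFC > 0)
  dn <- sum(x$stats$is_de & x$stats$logFC < 0)
  cat("de_fit:", nrow(x$stats), "genes;",
      x$levels[2], "vs", x$levels[1], "->", up, "up,", dn, "down\n")
  invisible(x)
}

#' @export
summary.de_fit <- function(object, n = 10L, ...) {
  s <- object$stats[order(object$stats$p), ]
  cat("Top", min(n, nrow(s)), "genes by p-value:\n")
  print(utils::head(s[, c("gene", "logFC", "t_mod", "p", "adj_p", "is_de")], n),
        row.names = FALSE)
  invisible(s)
}

#' @export
coef.de_fit <- function(object, ...) {
  stats::setNames(object$stats$logFC, object$stats$gene)
}
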