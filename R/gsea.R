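#' Configuration for pre-ranked GSEA
#'
#' @param weight_exponent 0, 1 or 2; exponent on |score| in the running
#'   sum. 0 gives the unweighted Kolmogorov-Smirnov statistic, 1 the
#'   classic weighted form (default).
#' @param n_perm number of gene permutations for the null (>= 100,
#'   default 1000).
#' @param min_size,max_size set-size bounds applied after intersection
#'   with the ranked universe (defaults 10 and 500).
#' @param seed integer seed for the permutation null.
#' @param nes_threshold,q_threshold selection rule: a set is selected iff
#'   `fdr_q < q_threshold` and `|NES| > nes_threshold` (defaults 0.05
#'   and 1.4).
#' @return A list of class `gsea_config`.
#' @export
gsea_config <- function(weight_exponent = 1L, n_perm = 1000L,
                        min_size = 10L, max_size = 500L, seed = 1L,
                        nes_threshold = 1.4, q_threshold = 0.05) {
  if (!weight_exponent %in% c(0L, 1L, 2L))
    .fail("weight_exponent must be 0, 1 or 2")
  n_perm <- .check_count(n_perm, "n_perm", min = 100L)
  min_size <- .check_count(min_size, "min_size", min = 1L)
  max_size <- .check_count(max_size, "max_size", min = min_size)
  .check_scalar_num(nes_threshold, "nes_threshold", lower = 0)
  .check_scalar_num(q_threshold, "q_threshold", lower = 0, upper = 1)
  structure(list(weight_exponent = as.integer(weight_exponent),
                 n_perm = n_perm, min_size = min_size, max_size = max_size,
                 seed = .check_count(seed, "seed", min = 0L),
                 nes_threshold = nes_threshold, q_threshold = q_threshold),
            class = "gsea_config")
}

# Streaming enrichment score. pos: sorted hit positions (1-based); w: the
# corresponding |score|^q values; N: universe size. Walks only the hits:
# between hits the running sum decreases linearly, so its extrema lie at
# the hit steps (just after a hit for the maximum, just before one for the
# minimum) or at the endpoints. Returns ES and the position of its
# extremum. O(k) given sorted positions.
.es_stream <- function(pos, w, N) {
  k <- length(pos)
  nr <- sum(w)
  if (nr == 0) { w <- rep(1, k); nr <- k }      # all-zero scores: KS limit
  miss <- 1 / (N - k)
  h <- cumsum(w) / nr
  idx <- seq_len(k)
  after <- h - (pos - idx) * miss               # running sum at hit i
  before <- c(0, h[-k]) - (pos - idx) * miss    # just before hit i
  up <- max(after, 0)
  dn <- min(before, 0)
  # a tie between the positive and negative extrema resolves to the
  # positive side; compared with a tolerance because exact ties are
  # common at weight 0 and float summation order must not flip the sign
  if (up + dn >= -1e-9) {
    i <- if (up > 0) pos[which.max(after)] else N
    list(es = up, extremum = i)
  } else {
    j <- which.min(before)
    list(es = dn, extremum = pos[j] - 1L)
  }
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list: at each in-set gene (hit) the running sum rises
#' by `|score|^weight_exponent / NR` (NR = sum of those values over all
#' hits); at each miss it falls by `1 / (N - Nh)`. The enrichment score is
#' the running-sum value of maximal absolute deviation from zero (a tie
#' between equal positive and negative deviations resolves to the
#' positive one). The leading edge contains the in-set genes at or before
#' the extremum for a positive ES, and at or after it for a negative ES.
#'
#' @param ranked a [rank_genes()] result (or data frame with `gene`,
#'   `score`, already ordered).
#' @param members character vector of set members; must intersect the
#'   ranked universe but not cover it entirely.
#' @param weight_exponent 0, 1 or 2 (default 1).
#' @return A list: `es`, `running_sum` (length N), `leading_edge`,
#'   `size_used`.
#' @export
enrichment_score <- function(ranked, members, weight_exponent = 1L) {
  genes <- ranked$gene
  N <- length(genes)
  hit <- genes %in% members
  k <- sum(hit)
  if (k == 0) .fail("set absent from universe")
  if (k == N) .fail("set equals the ranked universe")
  pos <- which(hit)
  w <- abs(ranked$score[pos])^weight_exponent
  st <- .es_stream(pos, w, N)
  nr <- sum(w)
  if (nr == 0) { w <- rep(1, k); nr <- k }
  steps <- rep(-1 / (N - k), N)
  steps[pos] <- w / nr
  running <- cumsum(steps)
  le <- if (st$es > 0) genes[pos[pos <= st$extremum]]
        else if (st$es < 0) genes[pos[pos >= st$extremum]]
        else character(0)
  list(es = st$es, running_sum = running, leading_edge = le, size_used = k)
}

#' Permutation null distribution of the enrichment score
#'
#' Draws gene sets of the given size uniformly without replacement from
#' the ranked universe and returns their enrichment scores. Draws come in
#' antithetic pairs: each sampled position set is scored together with its
#' rank-mirrored counterpart (positions `N + 1 - p`). This halves the
#' sampling cost of a symmetric null and makes the null exactly
#' equivariant under negation of the ranking, so NES and p values flip
#' sign exactly. `cfg$n_perm` is rounded up to an even count. Seeded
#' deterministically from `cfg$seed` and the set size, so per-size caching
#' and recomputation agree.
#'
#' @param ranked a ranked list.
#' @param set_size size of the permuted sets (1 <= size < N).
#' @param cfg a [gsea_config()].
#' @return Numeric vector of length `cfg$n_perm` rounded up to even.
#' @export
null_distribution <- function(ranked, set_size, cfg) {
  stopifnot(inherits(cfg, "gsea_config"))
  N <- nrow(ranked)
  set_size <- .check_count(set_size, "set_size", min = 1L)
  if (set_size >= N) .fail("set_size must be smaller than the universe")
  asq <- abs(ranked$score)^cfg$weight_exponent
  set.seed(.derive_seed(cfg$seed, set_size))
  pairs <- ceiling(cfg$n_perm / 2)
  out <- numeric(2L * pairs)
  for (i in seq_len(pairs)) {
    pos <- sort.int(sample.int(N, set_size))
    mir <- rev(N + 1L - pos)
    out[2L * i - 1L] <- .es_stream(pos, asq[pos], N)$es
    out[2L * i] <- .es_stream(mir, asq[mir], N)$es
  }
  out
}

#' Normalize an enrichment score against its permutation null
#'
#' NES divides the ES by the mean magnitude of the same-sign null scores
#' (so the sign is preserved); the nominal p is the fraction of same-sign
#' null scores at least as extreme, with a (r+1)/(n+1) continuity floor.
#' With no same-sign null values the NES is undefined and returned as NA.
#'
#' @param es observed enrichment score.
#' @param null numeric vector of null enrichment scores (non-empty).
#' @return A list: `nes`, `p_nominal` (both NA when undefined).
#' @export
normalize_es <- function(es, null) {
  if (!length(null)) .fail("empty null distribution")
  same <- null[sign(null) == sign(es) & null != 0]
  if (es == 0 || !length(same)) return(list(nes = NA_real_, p_nominal = NA_real_))
  r <- sum(abs(same) >= abs(es))
  list(nes = es / mean(abs(same)),
       p_nominal = (r + 1) / (length(same) + 1))
}

#' Sign-stratified permutation FDR q values
#'
#' For a positive NES*, q is the fraction of positive null NES values at
#' least NES* divided by the fraction of positive observed NES values at
#' least NES*, clipped to \[0, 1\]; mirrored for negative scores. Within
#' each sign, q values are then monotone-adjusted BH-style: a set's q is
#' the minimum raw q over all sets no more extreme than it, so q never
#' decreases as |NES| grows less extreme.
#'
#' @param observed_nes numeric vector of observed NES (NA allowed).
#' @param null_nes pooled vector of normalized null scores.
#' @return Numeric vector of q values aligned with `observed_nes`.
#' @export
fdr_q <- function(observed_nes, null_nes) {
  if (!length(observed_nes) || !length(null_nes))
    .fail("need at least one observed and one null NES")
  q <- rep(NA_real_, length(observed_nes))
  for (s in c(1, -1)) {
    io <- which(!is.na(observed_nes) & sign(observed_nes) == s)
    if (!length(io)) next
    null_s <- null_nes[!is.na(null_nes) & sign(null_nes) == s]
    obs_s <- observed_nes[io]
    if (!length(null_s)) {
      warning("no null NES with sign ", s, "; q set to 1")
      q[io] <- 1
      next
    }
    raw <- vapply(obs_s, function(v) {
      num <- mean(abs(null_s) >= abs(v))
      den <- mean(abs(obs_s) >= abs(v))
      min(1, max(0, num / den))
    }, numeric(1))
    # monotone: q(v) = min raw q over sets at least as extreme as ... the
    # suffix over decreasing |NES|, BH-style
    ord <- order(-abs(obs_s))
    adj <- rev(cummin(rev(raw[ord])))
    q[io[ord]] <- adj
  }
  q
}

#' Pre-ranked gene set enrichment analysis
#'
#' From-scratch pre-ranked GSEA: per-set weighted running-sum enrichment
#' score, gene-permutation null (cached per set size), sign-preserving
#' NES, nominal p with continuity correction, sign-stratified FDR q over
#' the pooled normalized null, and the selection rule
#' `fdr_q < q_threshold & |NES| > nes_threshold`.
#'
#' @param ranked a [rank_genes()] result.
#' @param collection a [gene_set_collection].
#' @param cfg a [gsea_config()].
#' @return A data frame of class `gsea_result`, sorted by NES descending
#'   (undefined NES last): `set_name`, `source`, `size_used`, `ES`,
#'   `NES`, `p_nominal`, `fdr_q`, `selected`, `leading_edge`
#'   (comma-joined). Sets outside the size bounds are reported in the
#'   `skipped` attribute.
#' @export
run_gsea <- function(ranked, collection, cfg = gsea_config()) {
  stopifnot(inherits(cfg, "gsea_config"),
            inherits(collection, "gene_set_collection"))
  universe <- ranked$gene
  sizes <- vapply(collection, function(g) sum(g %in% universe), integer(1))
  keep <- sizes >= cfg$min_size & sizes <= cfg$max_size
  skipped <- data.frame(set_name = names(collection)[!keep],
                        size_used = sizes[!keep], stringsAsFactors = FALSE)
  if (!any(keep)) .fail("no gene set within the size bounds")
  coll <- collection[names(collection)[keep]]
  src <- attr(collection, "source")

  es <- lapply(names(coll), function(nm)
    enrichment_score(ranked, coll[[nm]], cfg$weight_exponent))
  names(es) <- names(coll)

  nulls <- list()                               # per-size cache
  for (k in unique(sizes[keep]))
    nulls[[as.character(k)]] <- null_distribution(ranked, k, cfg)

  nes <- p_nom <- rep(NA_real_, length(coll))
  for (i in seq_along(coll)) {
    nd <- nulls[[as.character(es[[i]]$size_used)]]
    nz <- normalize_es(es[[i]]$es, nd)
    nes[i] <- nz$nes; p_nom[i] <- nz$p_nominal
  }

  # normalize the null scores themselves (per size, same-sign mean), pool
  null_nes <- unlist(lapply(nulls, function(nd) {
    mp <- mean(abs(nd[nd > 0])); mn <- mean(abs(nd[nd < 0]))
    out <- rep(NA_real_, length(nd))
    out[nd > 0] <- nd[nd > 0] / mp
    out[nd < 0] <- nd[nd < 0] / mn
    out
  }), use.names = FALSE)
  q <- fdr_q(nes, null_nes)

  res <- data.frame(
    set_name = names(coll),
    source = unname(src[names(coll)]),
    size_used = vapply(es, `[[`, integer(1), "size_used"),
    ES = vapply(es, `[[`, numeric(1), "es"),
    NES = nes, p_nominal = p_nom, fdr_q = q,
    selected = !is.na(nes) & !is.na(q) &
      q < cfg$q_threshold & abs(nes) > cfg$nes_threshold,
    leading_edge = vapply(es, function(e)
      paste(e$leading_edge, collapse = ","), ""),
    stringsAsFactors = FALSE)
  res <- res[order(-res$NES, res$set_name, na.last = TRUE), ]
  rownames(res) <- NULL
  structure(res, class = c("gsea_result", "data.frame"),
            skipped = skipped, config = cfg)
}

#' @export
print.gsea_result <- function(x, ...) {
  cat("gsea_result:", nrow(x), "sets tested,", sum(x$selected),
      "selected (q <", attr(x, "config")$q_threshold, ", |NES| >",
      attr(x, "config")$nes_threshold, ")\n")
  print.data.frame(utils::head(x[, c("set_name", "size_used", "ES", "NES",
                                     "p_nominal", "fdr_q", "selected")], 10),
                   row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot the running enrichment sum for one gene set
#'
#' Base-graphics diagnostic: the running sum along the ranked list, hit
#' positions as rug marks, and the extremum (the ES) highlighted.
#'
#' @param ranked a ranked list.
#' @param members gene-set members.
#' @param weight_exponent see [enrichment_score()].
#' @param ... passed to [plot()].
#' @return The [enrichment_score()] result, invisibly.
#' @export
plot_enrichment <- function(ranked, members, weight_exponent = 1L, ...) {
  es <- enrichment_score(ranked, members, weight_exponent)
  plot(es$running_sum, type = "l", xlab = "rank", ylab = "running sum", ...)
  graphics::abline(h = 0, col = "grey")
  graphics::rug(which(ranked$gene %in% members))
  i <- which.min(abs(es$running_sum - es$es))
  graphics::points(i, es$es, pch = 19, col = "red")
  invisible(es)
}
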