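# Independent brute-force oracles. These deliberately re-derive each
# quantity with naive code paths (explicit loops, full enumeration) so the
# package implementation is checked against something it shares nothing
# with.

# Full running-sum enumeration of the enrichment score. Same tie rule as
# the streaming path: ties between the extrema (within 1e-9) go positive.
oracle_es <- function(scores, hit, q) {
  N <- length(scores)
  k <- sum(hit)
  w <- abs(scores)^q
  nr <- sum(w[hit])
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hit[i]) {
      if (nr > 0) cur + w[i] / nr else cur + 1 / k
    } else cur - 1 / (N - k)
    run[i] <- cur
  }
  up <- max(c(run, 0)); dn <- min(c(run, 0))
  if (up + dn >= -1e-9) up else dn
}

# Quadratic-time TMM: explicit per-sample loops, trimming by rank bounds.
oracle_tmm <- function(counts) {
  lib <- colSums(counts)
  p75 <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts)))
    p75[j] <- quantile(counts[, j] / lib[j], 0.75)
  ref <- which.min(abs(p75 - mean(p75)))
  lf <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    if (j == ref) next
    ms <- as <- vs <- numeric(0)
    for (g in seq_len(nrow(counts))) {
      yo <- counts[g, j]; yr <- counts[g, ref]
      if (yo > 0 && yr > 0) {
        ms <- c(ms, log2((yo / lib[j]) / (yr / lib[ref])))
        as <- c(as, 0.5 * log2((yo / lib[j]) * (yr / lib[ref])))
        vs <- c(vs, (lib[j] - yo) / (lib[j] * yo) +
                  (lib[ref] - yr) / (lib[ref] * yr))
      }
    }
    if (max(abs(ms)) < 1e-6) { lf[j] <- 0; next }
    n <- length(ms)
    lo_m <- floor(n * 0.3) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * 0.05) + 1; hi_a <- n + 1 - lo_a
    rm_ <- rank(ms); ra <- rank(as)
    num <- den <- 0
    for (i in seq_len(n)) {
      if (rm_[i] >= lo_m && rm_[i] <= hi_m && ra[i] >= lo_a && ra[i] <= hi_a) {
        num <- num + ms[i] / vs[i]
        den <- den + 1 / vs[i]
      }
    }
    lf[j] <- num / den
  }
  f <- 2^lf
  f / exp(mean(log(f)))
}

# Quadratic-time BH step-up: adj_(i) = min over j >= i of min(1, m p_(j)/j)
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    best <- 1
    for (j in i:m) best <- min(best, m * p[ord[j]] / j)
    adj_sorted[i] <- best
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# Direct enumeration of the redundancy-filter rule
oracle_survivors <- function(sets, threshold = 0.8) {
  nms <- names(sets)[order(-lengths(sets), names(sets))]
  kept <- character(0)
  for (nm in nms) {
    redundant <- FALSE
    for (kp in kept) {
      a <- unique(sets[[nm]]); b <- unique(sets[[kp]])
      if (length(intersect(a, b)) / length(union(a, b)) > threshold) {
        redundant <- TRUE; break
      }
    }
    if (!redundant) kept <- c(kept, nm)
  }
  kept
}

# Per-gene WLS through explicit normal equations
oracle_wls <- function(y, X, w, contrast) {
  W <- diag(w)
  V <- solve(t(X) %*% W %*% X)
  b <- V %*% t(X) %*% W %*% y
  r <- y - X %*% b
  df <- nrow(X) - ncol(X)
  list(beta = drop(t(contrast) %*% b),
       stdev_unscaled = sqrt(drop(t(contrast) %*% V %*% contrast)),
       sigma = sqrt(drop(t(r) %*% W %*% r) / df))
}

# small helper: a ranked list straight from scores
make_ranked <- function(scores, genes = sprintf("G%03d", seq_along(scores))) {
  ord <- order(-scores, genes)
  structure(data.frame(gene = genes[ord], score = scores[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

toy_count_matrix <- function(m, groups = rep(c("control", "transgenic"),
                                             each = ncol(m) / 2)) {
  count_matrix(m, data.frame(sample_id = colnames(m), genotype = groups,
                             stringsAsFactors = FALSE))
}
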