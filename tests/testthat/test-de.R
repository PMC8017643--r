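two_group_design <- function(n_per_group) {
  stats::model.matrix(~rep(c(0, 1), each = n_per_group))
}

test_that("precision weights are flat for homoscedastic data and rise with NB abundance", {
  set.seed(21)
  ng <- 2000; n <- 12
  E <- matrix(rnorm(ng * n, mean = rep(runif(ng, 0, 10), n), sd = 0.5),
              ng, n, dimnames = list(sprintf("g%04d", 1:ng), paste0("s", 1:n)))
  design <- two_group_design(6)
  we <- voom_weights(E, design)
  expect_true(all(is.finite(we$weights)) && all(we$weights > 0))
  avg <- rowMeans(E)
  terc <- cut(avg, quantile(avg, c(0, 1/3, 2/3, 1)), include.lowest = TRUE)
  ratio <- mean(we$weights[terc == levels(terc)[3], ]) /
    mean(we$weights[terc == levels(terc)[1], ])
  expect_gt(ratio, 0.8); expect_lt(ratio, 1.25)

  # counting noise: weights grow with abundance on NB counts
  sim <- simulate_counts(sim_spec(n_genes = 2000, de_fraction = 0, seed = 22))
  cm <- filter_low_counts(sim$cm, min_samples = 10)
  nf <- tmm_factors(cm)
  En <- logcpm(cm, nf)
  wn <- voom_weights(En, design)$weights
  avg_n <- rowMeans(En)
  hi <- avg_n >= quantile(avg_n, 2/3); lo <- avg_n <= quantile(avg_n, 1/3)
  expect_gt(mean(wn[hi, ]), mean(wn[lo, ]))

  # identical rows get identical weights
  E2 <- rbind(a = E[1, ], b = E[1, ], E[2:50, ])
  w2 <- voom_weights(E2, design)$weights
  expect_identical(w2["a", ], w2["b", ])

  expect_error(voom_weights(E, cbind(design, design[, 2])), "rank")
  expect_error(voom_weights(E[, 1:3], two_group_design(1)[1:2, , drop = FALSE]),
               "design rows|residual")
})

test_that("weighted fit reduces to group-mean difference and matches normal equations", {
  set.seed(23)
  ng <- 40; n <- 10
  E <- matrix(rnorm(ng * n), ng, n,
              dimnames = list(sprintf("g%02d", 1:ng), paste0("s", 1:n)))
  design <- two_group_design(5)
  eq <- list(E = E, weights = matrix(1, ng, n), design = design)
  ft <- fit_contrast(eq)
  expect_equal(ft$logFC, rowMeans(E[, 6:10]) - rowMeans(E[, 1:5]),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(ft$df_residual, rep(n - 2, ng))

  # uniform weight scaling changes nothing
  sc <- eq; sc$weights <- 7.3 * sc$weights
  ft2 <- fit_contrast(sc)
  expect_equal(ft$logFC, ft2$logFC, tolerance = 1e-12)
  expect_equal(ft$logFC / (ft$sigma * ft$stdev_unscaled),
               ft2$logFC / (ft2$sigma * ft2$stdev_unscaled), tolerance = 1e-12)

  # random weights: brute-force normal-equations oracle
  rw <- eq; rw$weights <- matrix(runif(ng * n, 0.2, 3), ng, n)
  ftw <- fit_contrast(rw)
  for (g in c(1, 17, 40)) {
    o <- oracle_wls(E[g, ], design, rw$weights[g, ], c(0, 1))
    expect_equal(ftw$logFC[g], o$beta, tolerance = 1e-10)
    expect_equal(ftw$stdev_unscaled[g], o$stdev_unscaled, tolerance = 1e-10)
    expect_equal(ftw$sigma[g], o$sigma, tolerance = 1e-10)
  }
})

test_that("variance moderation matches the empirical-Bayes reference", {
  skip_if_not_installed("limma")
  set.seed(24)
  ng <- 600; n <- 8
  E <- matrix(rnorm(ng * n, sd = rep(sqrt(rchisq(ng, 4) / 4), n)), ng, n,
              dimnames = list(sprintf("g%03d", 1:ng), paste0("s", 1:n)))
  design <- two_group_design(4)
  we <- list(E = E, weights = matrix(1, ng, n), design = design)
  ms <- moderated_stats(fit_contrast(we))
  ref <- limma::eBayes(limma::lmFit(E, design))
  expect_equal(attr(ms, "d0"), ref$df.prior, tolerance = 1e-8)
  expect_equal(attr(ms, "s02"), ref$s2.prior, tolerance = 1e-8)
  expect_equal(ms$t_mod, unname(ref$t[, 2]), tolerance = 1e-8)
  expect_equal(ms$p, unname(ref$p.value[, 2]), tolerance = 1e-8)
  expect_true(all(ms$adj_p >= ms$p))
})

test_that("moderation degenerates correctly when all variances are equal", {
  set.seed(25)
  ng <- 100; n <- 8
  E <- matrix(rnorm(ng * n), ng, n,
              dimnames = list(sprintf("g%03d", 1:ng), paste0("s", 1:n)))
  ft <- fit_contrast(list(E = E, weights = matrix(1, ng, n),
                          design = two_group_design(4)))
  ft$sigma <- rep(1.3, ng)              # identical residual SDs
  ms <- moderated_stats(ft)
  expect_identical(attr(ms, "d0"), Inf)
  expect_equal(attr(ms, "s02"), 1.3^2, tolerance = 1e-12)
  expect_equal(unique(ms$s2_post), 1.3^2, tolerance = 1e-12)

  ft$sigma <- rep(0, ng)
  expect_error(moderated_stats(ft), "positive residual variance")
})

test_that("BH adjustment validates input and matches hand computations", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(26)
  for (i in 1:10) {
    p <- runif(sample(1:50, 1))
    a <- bh_adjust(p)
    expect_true(all(a >= p))
    expect_equal(a, oracle_bh(p), tolerance = 1e-14)
  }
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("DE calling uses strict thresholds on both axes", {
  s <- data.frame(gene = c("a", "b", "c", "d"),
                  logFC = c(0.60, 0.585, 2.0, -0.60),
                  adj_p = c(0.01, 0.001, 0.05, 0.04))
  out <- call_de(s)
  expect_identical(out$is_de, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("gene ranking is the signed -log10 p with deterministic ties", {
  s <- data.frame(gene = c("gB", "gA", "gC", "gD"),
                  p = c(0.01, 0.01, 0.5, 0.2),
                  logFC = c(1, 2, 0, -1.5))
  r <- rank_genes(s)
  expect_equal(r$score[r$gene == "gA"], 2)
  expect_equal(r$score[r$gene == "gD"], -log10(0.2) * -1)
  expect_equal(r$score[r$gene == "gC"], 0)          # sign(0) = 0
  expect_identical(r$gene[1:2], c("gA", "gB"))      # tie broken by name
  expect_true(all(diff(r$score) <= 0))

  # negating logFC negates every score and reverses the order
  s2 <- s; s2$logFC <- -s$logFC
  r2 <- rank_genes(s2)
  expect_equal(sort(r2$score), sort(-r$score))
  m <- merge(r, r2, by = "gene")
  expect_equal(m$score.x, -m$score.y)

  # underflow floor keeps scores finite
  s3 <- data.frame(gene = "g", p = 1e-320, logFC = 1)
  expect_equal(rank_genes(s3)$score, 300)
  expect_error(rank_genes(data.frame(gene = "g", p = NA, logFC = 1)), "missing p")
})

test_that("RNK round trip preserves the ranking", {
  d <- withr::local_tempdir()
  r <- make_ranked(c(2.5, -1, 0.3, 0))
  p <- file.path(d, "x.rnk")
  write_rnk(r, p)
  r2 <- read_rnk(p)
  expect_equal(r2$gene, r$gene)
  expect_equal(r2$score, r$score, tolerance = 1e-12)
})

test_that("null simulations keep false-positive control; planted effects are found", {
  frac <- sens <- fdr <- numeric(10)
  for (s in 1:10) {
    null_sim <- simulate_counts(sim_spec(n_genes = 800, de_fraction = 0,
                                         seed = 400 + s))
    f0 <- de_fit(filter_low_counts(null_sim$cm, min_samples = 10))
    frac[s] <- mean(f0$stats$adj_p < 0.05)

    sim <- simulate_counts(sim_spec(n_genes = 800, de_fraction = 0.06,
                                    de_log2fc = 1, dispersion_log_sd = 0,
                                    seed = 500 + s))
    f1 <- de_fit(filter_low_counts(sim$cm, min_samples = 10))
    called <- f1$stats$gene[f1$stats$is_de]
    planted <- names(sim$truth$de_genes)
    sens[s] <- mean(planted %in% called)
    fdr[s] <- if (length(called)) mean(!called %in% planted) else 0
  }
  expect_lte(mean(frac), 0.05)
  expect_gte(mean(sens), 0.5)
  expect_lte(mean(fdr), 0.10)
})

test_that("the DE stage is deterministic end to end", {
  sim <- simulate_counts(sim_spec(n_genes = 300, seed = 27))
  cm <- filter_low_counts(sim$cm, min_samples = 10)
  a <- de_fit(cm); b <- de_fit(cm)
  expect_identical(a$stats, b$stats)
  expect_identical(a$ranked, b$ranked)
})
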