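test_that("enrichment score reproduces the hand-enumerated running sums", {
  rk <- make_ranked(c(3, 2, 1, -1), genes = c("g1", "g2", "g3", "g4"))
  top <- enrichment_score(rk, "g1", weight_exponent = 1)
  expect_equal(top$running_sum, c(1, 2/3, 1/3, 0), tolerance = 1e-12)
  expect_equal(top$es, 1)
  expect_identical(top$leading_edge, "g1")

  bottom <- enrichment_score(rk, "g4", weight_exponent = 1)
  expect_equal(bottom$running_sum, c(-1/3, -2/3, -1, 0), tolerance = 1e-12)
  expect_equal(bottom$es, -1)
  expect_identical(bottom$leading_edge, "g4")

  expect_error(enrichment_score(rk, "absent"), "absent from universe")
  expect_error(enrichment_score(rk, rk$gene), "equals the ranked universe")
})

test_that("streaming ES equals full enumeration across random instances", {
  set.seed(41)
  worst <- 0
  for (i in 1:300) {
    N <- 50
    rk <- make_ranked(rnorm(N))
    k <- sample(1:25, 1)
    mem <- sample(rk$gene, k)
    q <- sample(c(0, 1), 1)
    es <- enrichment_score(rk, mem, q)
    brute <- oracle_es(rk$score, rk$gene %in% mem, q)
    worst <- max(worst, abs(es$es - brute))
    expect_lte(abs(es$es), 1)
  }
  expect_lt(worst, 1e-12)
})

test_that("weight 0 reduces |ES| to the two-sample KS statistic", {
  set.seed(42)
  for (i in 1:50) {
    N <- 60
    rk <- make_ranked(rnorm(N))
    mem <- sample(rk$gene, sample(5:30, 1))
    es <- enrichment_score(rk, mem, weight_exponent = 0)
    pos <- which(rk$gene %in% mem)
    ks <- suppressWarnings(
      stats::ks.test(pos, setdiff(seq_len(N), pos))$statistic)
    expect_equal(abs(es$es), unname(ks), tolerance = 1e-12)
  }
})

test_that("negating the ranking flips every ES sign", {
  set.seed(43)
  rk <- make_ranked(rnorm(100))
  neg <- make_ranked(-rk$score, genes = rk$gene)
  for (i in 1:20) {
    mem <- sample(rk$gene, 10)
    a <- enrichment_score(rk, mem, 1)$es
    b <- enrichment_score(neg, mem, 1)$es
    expect_equal(a, -b, tolerance = 1e-12)
  }
})

test_that("the permutation null is seeded and centred for symmetric scores", {
  rk <- make_ranked(c(seq(5, 0.5, by = -0.5), -seq(0.5, 5, by = 0.5)))
  cfg <- gsea_config(n_perm = 2000, seed = 9)
  nd <- null_distribution(rk, 5, cfg)
  expect_identical(nd, null_distribution(rk, 5, cfg))
  expect_lt(abs(mean(nd)), 3 * sd(nd) / sqrt(length(nd)) + 0.02)
  expect_error(gsea_config(n_perm = 50), "n_perm")
  expect_error(null_distribution(rk, nrow(rk), cfg), "smaller than the universe")
})

test_that("NES and nominal p follow their definitions", {
  null <- c(0.3, 0.3, 0.3, -0.2, -0.4)
  nz <- normalize_es(0.6, null)
  expect_equal(nz$nes, 2)
  expect_equal(nz$p_nominal, 1 / 4)               # 0 of 3 as extreme, +1/(n+1)

  # es equal to every same-sign null value -> p near 1
  nz2 <- normalize_es(0.3, c(0.3, 0.3, 0.3))
  expect_equal(nz2$p_nominal, 1)

  # no same-sign null -> flagged missing
  nz3 <- normalize_es(-0.5, c(0.2, 0.4))
  expect_true(is.na(nz3$nes) && is.na(nz3$p_nominal))
  expect_error(normalize_es(0.5, numeric(0)), "empty null")

  # negative es keeps its sign
  nz4 <- normalize_es(-0.6, c(-0.3, -0.3, 0.5))
  expect_equal(nz4$nes, -2)
})

test_that("FDR q is sign-stratified, clipped and monotone in |NES|", {
  set.seed(47)
  obs <- c(3, 2, 1.2, -2.5, -1)
  null <- c(rnorm(200, 1, 0.2), -rnorm(200, 1, 0.2))
  q <- fdr_q(obs, null)
  expect_true(all(q >= 0 & q <= 1))
  # more extreme never has larger q within a sign
  expect_true(q[1] <= q[2] && q[2] <= q[3])
  expect_lte(q[4], q[5])

  # observed far beyond every null -> q = 0
  expect_equal(fdr_q(10, c(0.5, 1, 1.5))[1], 0)
  # observed at the null median -> q near 1
  qq <- fdr_q(1, rnorm(500, 1, 0.001))
  expect_gt(qq, 0.4)
  expect_warning(fdr_q(-2, c(1, 2)), "no null NES")
})

test_that("run_gsea applies the selection rule and size bounds", {
  set.seed(44)
  sp <- sim_spec(n_genes = 600, de_log2fc = 1.5, dispersion_log_sd = 0, seed = 44)
  st <- simulate_enrichment_study(sp, n_planted_sets = 3, n_null_sets = 12,
                                  set_size = 25)
  f <- de_fit(filter_low_counts(st$cm, min_samples = 10))
  coll <- st$collection
  tiny <- c(unclass(coll), list(tiny_set = unclass(coll)[[1]][1:3]))
  coll2 <- gene_set_collection(tiny, source = "simulated")
  res <- run_gsea(f$ranked, coll2, gsea_config(n_perm = 500, seed = 44))
  expect_s3_class(res, "gsea_result")
  expect_true("tiny_set" %in% attr(res, "skipped")$set_name)
  expect_false("tiny_set" %in% res$set_name)
  ok <- !is.na(res$NES) & !is.na(res$fdr_q)
  expect_identical(res$selected[ok],
                   (res$fdr_q < 0.05 & abs(res$NES) > 1.4)[ok])
  expect_false(any(res$selected[!ok]))
  expect_true(all(diff(res$NES[!is.na(res$NES)]) <= 0))
  # leading edges are subsets of the set members present in the universe
  for (i in which(res$selected)) {
    le <- strsplit(res$leading_edge[i], ",")[[1]]
    expect_true(all(le %in% coll2[[res$set_name[i]]]))
    expect_true(all(le %in% f$ranked$gene))
  }
  # planted sets rise to the top
  expect_true(all(st$truth$enriched_sets %in% res$set_name[res$selected]))
})

test_that("negating the ranking flips NES under fixed seeds", {
  set.seed(45)
  rk <- make_ranked(c(rnorm(150, 0, 1) + c(rep(2, 30), rep(0, 120))))
  neg <- make_ranked(-rk$score, genes = rk$gene)
  coll <- gene_set_collection(list(S = rk$gene[1:20], T = rk$gene[41:70]))
  cfg <- gsea_config(n_perm = 500, seed = 46, min_size = 5)
  a <- run_gsea(rk, coll, cfg)
  b <- run_gsea(neg, coll, cfg)
  m <- merge(as.data.frame(a), as.data.frame(b), by = "set_name")
  expect_equal(m$ES.x, -m$ES.y, tolerance = 1e-12)
  expect_equal(m$NES.x, -m$NES.y, tolerance = 1e-9)
})
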