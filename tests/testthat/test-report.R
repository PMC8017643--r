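fake_stats <- function(universe, up = character(0), down = character(0)) {
  data.frame(gene = universe,
             logFC = ifelse(universe %in% up, 1,
                            ifelse(universe %in% down, -1, 0)),
             is_de = universe %in% c(up, down),
             stringsAsFactors = FALSE)
}

test_that("shared DE genes follow Venn-region logic", {
  uni <- sprintf("g%02d", 1:20)
  res <- list(A = fake_stats(uni, up = c("g01", "g02", "g03")),
              B = fake_stats(uni, up = c("g02", "g03", "g04")))
  tab <- shared_de_sets(res, "up")
  both <- tab[tab$strata == "A+B", ]
  expect_equal(both$n_at_least, 2)
  expect_identical(both$genes_at_least, "g02,g03")
  expect_equal(tab$n_exclusive[tab$strata == "A"], 1)
  expect_identical(tab$genes_exclusive[tab$strata == "A"], "g01")

  # identical up-sets: intersection is the set, exclusive regions empty
  same <- list(A = fake_stats(uni, up = c("g05", "g06")),
               B = fake_stats(uni, up = c("g05", "g06")))
  t2 <- shared_de_sets(same, "up")
  expect_equal(t2$n_exclusive[t2$strata %in% c("A", "B")], c(0, 0))
  expect_equal(t2$n_at_least[t2$strata == "A+B"], 2)

  # disjoint sets: every multi-stratum intersection empty
  disj <- list(A = fake_stats(uni, up = "g01"), B = fake_stats(uni, up = "g02"))
  t3 <- shared_de_sets(disj, "up")
  expect_equal(t3$n_at_least[t3$strata == "A+B"], 0)

  expect_error(shared_de_sets(res["A"]), "at least 2")
  bad <- list(A = fake_stats(uni), B = fake_stats(sprintf("h%02d", 1:20)))
  expect_error(shared_de_sets(bad, "up"), "universes differ")
})

test_that("four-stratum Venn regions match brute-force enumeration", {
  uni <- sprintf("g%02d", 1:30)
  set.seed(61)
  memb <- lapply(1:4, function(i) sample(uni, sample(3:10, 1)))
  names(memb) <- c("W", "X", "Y", "Z")
  res <- lapply(memb, function(m) fake_stats(uni, up = m))
  tab <- shared_de_sets(res, "up")
  expect_equal(nrow(tab), 15)
  # brute force: classify each gene by its exact membership pattern
  for (r in seq_len(nrow(tab))) {
    inc <- strsplit(tab$strata[r], "+", fixed = TRUE)[[1]]
    excl <- Filter(function(g) {
      setequal(names(memb)[vapply(memb, function(m) g %in% m, logical(1))], inc)
    }, uni)
    expect_equal(tab$n_exclusive[r], length(excl))
    at_least <- Filter(function(g) all(vapply(memb[inc], function(m) g %in% m,
                                              logical(1))), uni)
    expect_equal(tab$n_at_least[r], length(at_least))
  }
  # region counts sum to the union per direction
  expect_equal(sum(tab$n_exclusive), length(unique(unlist(memb))))

  # up and down never overlap in real fits
  sim <- simulate_counts(sim_spec(n_genes = 400, de_fraction = 0.1, seed = 62))
  f <- de_fit(filter_low_counts(sim$cm, min_samples = 10))
  up <- f$stats$gene[f$stats$is_de & f$stats$logFC > 0]
  down <- f$stats$gene[f$stats$is_de & f$stats$logFC < 0]
  expect_length(intersect(up, down), 0)
  expect_setequal(c(up, down), f$stats$gene[f$stats$is_de])
})

pipeline_config <- function(out_dir, seed = 3) {
  list(seed = seed, out_dir = out_dir,
       simulate = list(n_genes = 400, n_per_group = 4, de_fraction = 0.08,
                       de_log2fc = 2, dispersion_log_sd = 0,
                       regions = c("PFC", "HIP"), ages = "3m",
                       shared_fraction = 0.5),
       filter = list(min_samples = 8),
       collection = list(n_sets = 20, set_size_min = 10, set_size_max = 20),
       gsea = list(n_perm = 200, min_size = 5))
}

test_that("pipeline runs are reproducible byte for byte", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_pipeline(pipeline_config(d1), quiet = TRUE)
  run_pipeline(pipeline_config(d2), quiet = TRUE)
  files <- sort(list.files(d1))
  expect_true(length(files) >= 8)
  expect_identical(files, sort(list.files(d2)))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("pipeline outputs equal the stages run individually", {
  d <- withr::local_tempdir()
  out <- run_pipeline(pipeline_config(d), quiet = TRUE)
  # recompute one stratum by hand with the same derived seeds
  spec <- sim_spec(n_genes = 400, n_per_group = 4, de_fraction = 0.08,
                   de_log2fc = 2, dispersion_log_sd = 0, seed = 3)
  st <- simulate_study(spec, regions = c("PFC", "HIP"), ages = "3m",
                       shared_fraction = 0.5)
  combined <- count_matrix(
    cbind(st[["PFC_3m"]]$cm$counts, st[["HIP_3m"]]$cm$counts),
    rbind(st[["PFC_3m"]]$cm$meta, st[["HIP_3m"]]$cm$meta))
  filtered <- filter_low_counts(combined, min_samples = 8)
  pfc <- filtered$meta$region == "PFC"
  cm <- count_matrix(filtered$counts[, pfc, drop = FALSE],
                     filtered$meta[pfc, , drop = FALSE])
  f <- de_fit(cm)
  expect_identical(f$stats, out$fits[["PFC_3m"]]$stats)
  got <- read.delim(file.path(d, "genestats_PFC_3m.tsv"))
  expect_equal(got$logFC, f$stats$logFC, tolerance = 1e-9)
})

test_that("pipeline validates its configuration before running", {
  d <- withr::local_tempdir()
  expect_error(run_pipeline(list(seed = 1, out_dir = d), quiet = TRUE),
               "simulate block or counts")
  expect_error(run_pipeline(list(simulate = list(n_genes = 10)), quiet = TRUE),
               "out_dir")
  expect_length(list.files(d), 0)                 # nothing ran
})

test_that("YAML configs drive the pipeline and qPCR stage end to end", {
  d <- withr::local_tempdir()
  sim <- simulate_ct_table(c("t1", "t2", "e1", "e2"), planted_log2fc = c(t1 = 1),
                           endogenous = c("e1", "e2"), seed = 5)
  ctp <- file.path(d, "ct.tsv"); mtp <- file.path(d, "ctmeta.tsv")
  write_tsv(data.frame(gene = rownames(sim$ct$ct), sim$ct$ct,
                       check.names = FALSE), ctp)
  write_tsv(sim$ct$meta, mtp)
  cfg <- pipeline_config(file.path(d, "out"))
  cfg$qpcr <- list(ct = ctp, meta = mtp, candidates = c("e1", "e2"))
  yml <- file.path(d, "cfg.yaml")
  yaml::write_yaml(cfg, yml)
  out <- run_pipeline(yml, quiet = TRUE)
  expect_true(file.exists(file.path(d, "out", "qpcr_results.tsv")))
  expect_true(file.exists(file.path(d, "out", "manifest.yaml")))
  qr <- read.delim(file.path(d, "out", "qpcr_results.tsv"))
  expect_lt(qr$ddct[qr$gene == "t1"], -0.5)
})
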