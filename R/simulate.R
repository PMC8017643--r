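#' Simulation specification for synthetic RNA-seq counts
#'
#' Collects the parameters of the negative-binomial count generator in one
#' validated object. Defaults emulate a two-genotype bulk RNA-seq comparison
#' at n = 6 per group: log-normal baseline means, log-normal gene-wise
#' dispersion centred on 0.1 (typical bulk RNA-seq), mild library-size
#' variation, and a configurable fraction of genes carrying a planted
#' log2 fold change.
#'
#' @param n_genes number of genes (>= 1).
#' @param n_per_group samples per group (>= 2; default 6).
#' @param groups two condition labels; the second is the "affected" group
#'   in which planted effects are expressed.
#' @param baseline_mean_log,baseline_mean_sd meanlog/sdlog of the log-normal
#'   distribution of per-gene baseline expression means (counts scale).
#' @param dispersion_log_mean,dispersion_log_sd meanlog/sdlog of the
#'   log-normal gene-wise NB dispersion; `dispersion_log_sd = 0` gives every
#'   gene dispersion `exp(dispersion_log_mean)` exactly.
#' @param libsize_log_sd sdlog of the log-normal per-sample library factor.
#' @param de_fraction fraction of genes receiving a planted effect
#'   (rounded to an integer gene count).
#' @param de_log2fc absolute planted log2 fold change; signs are drawn
#'   at random per gene.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_genes = 2000L, n_per_group = 6L,
                     groups = c("control", "transgenic"),
                     baseline_mean_log = 5, baseline_mean_sd = 1.5,
                     dispersion_log_mean = log(0.1), dispersion_log_sd = 0.4,
                     libsize_log_sd = 0.2,
                     de_fraction = 0.06, de_log2fc = 1, seed = 1L) {
  n_genes <- .check_count(n_genes, "n_genes", min = 1L)
  n_per_group <- .check_count(n_per_group, "n_per_group", min = 2L)
  if (length(groups) != 2L || anyDuplicated(groups))
    .fail("groups must be two distinct condition labels")
  .check_scalar_num(baseline_mean_sd, "baseline_mean_sd", lower = 0)
  .check_scalar_num(dispersion_log_sd, "dispersion_log_sd", lower = 0)
  .check_scalar_num(libsize_log_sd, "libsize_log_sd", lower = 0)
  .check_scalar_num(de_fraction, "de_fraction", lower = 0, upper = 1)
  .check_scalar_num(de_log2fc, "de_log2fc", lower = 0)
  structure(list(n_genes = n_genes, n_per_group = n_per_group,
                 groups = as.character(groups),
                 baseline_mean_log = baseline_mean_log,
                 baseline_mean_sd = baseline_mean_sd,
                 dispersion_log_mean = dispersion_log_mean,
                 dispersion_log_sd = dispersion_log_sd,
                 libsize_log_sd = libsize_log_sd,
                 de_fraction = de_fraction, de_log2fc = de_log2fc,
                 seed = .check_count(seed, "seed", min = 0L)),
            class = "sim_spec")
}

# NB draw that degenerates to Poisson as dispersion -> 0
.rnb <- function(n, mu, phi) {
  out <- numeric(n)
  tiny <- phi <= 1e-8
  if (any(tiny)) out[tiny] <- stats::rpois(sum(tiny), mu[tiny])
  if (any(!tiny)) out[!tiny] <- stats::rnbinom(sum(!tiny), mu = mu[!tiny],
                                               size = 1 / phi[!tiny])
  out
}

#' Simulate a two-group negative-binomial count experiment
#'
#' Counts are drawn gene-wise from a negative binomial with mean
#' `mu_gj = s_j * m_g * 2^(x_j * beta_g)`, where `s_j` is a log-normal
#' per-sample library factor, `m_g` a log-normal baseline mean, `beta_g`
#' the planted log2 fold change (0 for non-DE genes) and `x_j` the
#' indicator of the second group. Gene-wise dispersion is log-normal.
#'
#' @param spec a [sim_spec()].
#' @param beta optional explicit per-gene signed log2 fold-change vector
#'   (length `n_genes`); overrides the random `de_fraction` assignment.
#'   Used by [simulate_enrichment_study()] to concentrate effects in
#'   designated gene sets.
#' @param meta_extra optional named list of constant annotation columns
#'   (e.g. `list(region = "PFC", age = "3m")`) added to the metadata.
#' @param sample_prefix prefix for sample IDs.
#' @return A list with elements `cm` (a [count_matrix]) and `truth`
#'   (list: `de_genes`, a named vector of planted signed log2FC over the
#'   affected genes; `beta`, the full per-gene vector).
#' @export
simulate_counts <- function(spec, beta = NULL, meta_extra = NULL,
                            sample_prefix = "s") {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genes
  n <- 2L * spec$n_per_group
  genes <- sprintf("g%0*d", max(4L, nchar(ng)), seq_len(ng))
  m <- stats::rlnorm(ng, spec$baseline_mean_log, spec$baseline_mean_sd)
  phi <- stats::rlnorm(ng, spec$dispersion_log_mean, spec$dispersion_log_sd)
  s <- stats::rlnorm(n, 0, spec$libsize_log_sd)
  if (is.null(beta)) {
    beta <- numeric(ng)
    n_de <- round(spec$de_fraction * ng)
    if (n_de > 0) {
      idx <- sample.int(ng, n_de)
      beta[idx] <- sample(c(-1, 1), n_de, replace = TRUE) * spec$de_log2fc
    }
  } else {
    if (length(beta) != ng) .fail("beta must have length n_genes")
  }
  x <- rep(c(0, 1), each = spec$n_per_group)
  mu <- outer(m, s) * 2^outer(beta, x)
  counts <- matrix(.rnb(length(mu), as.vector(mu), rep(phi, n)),
                   nrow = ng, ncol = n,
                   dimnames = list(genes, paste0(sample_prefix,
                                                 sprintf("%02d", seq_len(n)))))
  meta <- data.frame(sample_id = colnames(counts),
                     genotype = rep(spec$groups, each = spec$n_per_group),
                     stringsAsFactors = FALSE)
  for (nm in names(meta_extra)) meta[[nm]] <- meta_extra[[nm]]
  de <- beta[beta != 0]
  names(de) <- genes[beta != 0]
  list(cm = count_matrix(counts, meta),
       truth = list(de_genes = de, beta = stats::setNames(beta, genes)))
}

#' Simulate a gene-set collection with controlled redundancy
#'
#' Builds a collection whose pairwise Jaccard structure is known by
#' construction, for exercising the redundancy filter. The plan is a
#' character vector over `"distinct"` (one set, low overlap with others),
#' `"duplicate"` (a pair with identical members, Jaccard 1) and
#' `"near_duplicate"` (a pair where the copy lacks one member, so
#' Jaccard = (k-1)/k > 0.8 for size k >= 6).
#'
#' The expected survivors of the redundancy filter are computed by a direct
#' quadratic enumeration of the rule (sort by size then name; keep a set iff
#' its Jaccard with every already-kept set is <= threshold), independent of
#' [filter_redundant()], and returned alongside.
#'
#' @param universe character vector of gene identifiers to draw from.
#' @param n_sets number of plan entries when `redundancy_plan` is NULL
#'   (all `"distinct"`).
#' @param set_size_range integer length-2, inclusive range of base set
#'   sizes; near-duplicate bases are forced to size >= 6.
#' @param redundancy_plan character vector as described above.
#' @param threshold Jaccard threshold used for the expected-survivor
#'   enumeration (default 0.8).
#' @param seed integer seed.
#' @return A list: `collection` (a [gene_set_collection]),
#'   `expected_survivors` (character vector of surviving set names).
#' @export
simulate_collection <- function(universe, n_sets = NULL,
                                set_size_range = c(10L, 50L),
                                redundancy_plan = NULL, threshold = 0.8,
                                seed = 1L) {
  if (is.null(redundancy_plan)) {
    if (is.null(n_sets)) .fail("give n_sets or redundancy_plan")
    redundancy_plan <- rep("distinct", .check_count(n_sets, "n_sets"))
  }
  if (!all(redundancy_plan %in% c("distinct", "duplicate", "near_duplicate")))
    .fail("redundancy_plan entries must be distinct/duplicate/near_duplicate")
  lo <- .check_count(set_size_range[1], "set_size_range[1]")
  hi <- .check_count(set_size_range[2], "set_size_range[2]", min = lo)
  if (hi > length(universe))
    .fail("set_size_range exceeds universe size (", length(universe), ")")
  set.seed(.check_count(seed, "seed", min = 0L))
  sets <- list()
  for (i in seq_along(redundancy_plan)) {
    kind <- redundancy_plan[i]
    k <- sample(seq(lo, hi), 1L)
    if (kind == "near_duplicate") k <- max(k, 6L)
    base <- sample(universe, k)
    nm <- sprintf("set%03d", i)
    sets[[nm]] <- base
    if (kind == "duplicate") {
      sets[[paste0(nm, "_dup")]] <- base
    } else if (kind == "near_duplicate") {
      sets[[paste0(nm, "_near")]] <- base[-sample.int(k, 1L)]
    }
  }
  coll <- gene_set_collection(sets, source = "simulated")
  list(collection = coll,
       expected_survivors = .enumerate_survivors(sets, threshold))
}

# Direct enumeration of the redundancy rule, kept separate from
# filter_redundant() so generator truth and filter can disagree in tests.
.enumerate_survivors <- function(sets, threshold) {
  sizes <- vapply(sets, length, integer(1))
  ord <- names(sets)[order(-sizes, names(sets))]
  kept <- character(0)
  for (nm in ord) {
    ok <- TRUE
    for (kp in kept) {
      a <- unique(sets[[nm]]); b <- unique(sets[[kp]])
      j <- length(intersect(a, b)) / length(union(a, b))
      if (j > threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, nm)
  }
  kept
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Ct values are constructed as `baseline_g - x_j * planted_log2fc_g +
#' noise`, so a planted 2-fold expression increase lowers Ct by exactly one
#' cycle in the affected group. Endogenous candidates carry no planted
#' effect and reduced technical noise (a quarter of `ct_noise_sd`),
#' emulating stably expressed reference genes.
#'
#' @param genes character vector of gene names (targets plus endogenous
#'   candidates).
#' @param n_per_group samples per condition (default 6).
#' @param planted_log2fc named numeric vector of planted log2 fold changes;
#'   genes absent from it get 0. Endogenous genes must not appear with a
#'   non-zero value.
#' @param endogenous character vector of planted-stable genes, a subset of
#'   `genes`.
#' @param ct_noise_sd Gaussian noise SD in cycles (default 0.1).
#' @param groups two condition labels.
#' @param seed integer seed.
#' @return A list: `ct` (a [ct_table]) and `truth` (list with
#'   `endogenous_genes` and `planted_log2fc`).
#' @export
simulate_ct_table <- function(genes, n_per_group = 6L,
                              planted_log2fc = numeric(0),
                              endogenous = character(0),
                              ct_noise_sd = 0.1,
                              groups = c("control", "transgenic"),
                              seed = 1L) {
  n_per_group <- .check_count(n_per_group, "n_per_group", min = 2L)
  .check_scalar_num(ct_noise_sd, "ct_noise_sd", lower = 0)
  if (!all(endogenous %in% genes)) .fail("endogenous genes must be in genes")
  lfc <- stats::setNames(numeric(length(genes)), genes)
  lfc[names(planted_log2fc)] <- planted_log2fc
  if (any(lfc[endogenous] != 0))
    .fail("endogenous genes cannot carry a planted effect: ",
          paste(endogenous[lfc[endogenous] != 0], collapse = ", "))
  set.seed(.check_count(seed, "seed", min = 0L))
  n <- 2L * n_per_group
  x <- rep(c(0, 1), each = n_per_group)
  baseline <- stats::rnorm(length(genes), 25, 2)
  noise_sd <- ifelse(genes %in% endogenous, ct_noise_sd / 4, ct_noise_sd)
  ct <- outer(baseline, rep(1, n)) - outer(lfc, x) +
    matrix(stats::rnorm(length(genes) * n, 0, rep(noise_sd, n)),
           nrow = length(genes))
  dimnames(ct) <- list(genes, sprintf("q%02d", seq_len(n)))
  meta <- data.frame(sample_id = colnames(ct),
                     condition = rep(groups, each = n_per_group),
                     stringsAsFactors = FALSE)
  list(ct = ct_table(ct, meta, candidate_endogenous = endogenous),
       truth = list(endogenous_genes = endogenous, planted_log2fc = lfc))
}

#' Simulate a mouse-to-human style ortholog map
#'
#' Deterministic fixture for gene-set identifier translation: a requested
#' fraction of genes is left unmapped, a fraction maps to two targets, the
#' rest map one-to-one. Target symbols are the upper-cased source symbols
#' (the usual mouse-to-human symbol convention), suffixed for secondary
#' targets.
#'
#' @param genes character vector of source identifiers.
#' @param unmapped_fraction,one_to_many_fraction fractions in \[0, 1\].
#' @param seed integer seed.
#' @return A data frame of class `ortholog_map` with columns `source` and
#'   `target`; unmapped genes simply have no row.
#' @export
simulate_ortholog_map <- function(genes, unmapped_fraction = 0,
                                  one_to_many_fraction = 0, seed = 1L) {
  .check_scalar_num(unmapped_fraction, "unmapped_fraction", 0, 1)
  .check_scalar_num(one_to_many_fraction, "one_to_many_fraction", 0, 1)
  set.seed(.check_count(seed, "seed", min = 0L))
  n <- length(genes)
  unmapped <- sample(genes, round(unmapped_fraction * n))
  rest <- setdiff(genes, unmapped)
  multi <- sample(rest, round(one_to_many_fraction * length(rest)))
  src <- c(rest, multi)
  tgt <- c(toupper(rest),
           if (length(multi)) paste0(toupper(multi), "B") else character(0))
  ortholog_map(data.frame(source = src, target = tgt,
                          stringsAsFactors = FALSE))
}

#' Simulate counts with effects concentrated in designated gene sets
#'
#' Builds the planted-enrichment study: a gene universe, `n_planted_sets`
#' disjoint gene sets in which a fraction of members (default 80%) carries
#' the planted signed log2 fold change (signs alternate across planted
#' sets), `n_null_sets` gene sets drawn from the unaffected portion of the
#' universe, and NB counts simulated under the resulting per-gene effect
#' vector.
#'
#' @param spec a [sim_spec()]; its `de_fraction` is ignored (membership
#'   drives the effects), `de_log2fc` sets the planted magnitude.
#' @param n_planted_sets,n_null_sets numbers of enriched and null sets.
#' @param set_size members per set.
#' @param planted_frac fraction of a planted set's members that receive
#'   the effect (default 0.8).
#' @return A list: `cm`, `collection`, `truth` (with `de_genes`,
#'   `enriched_sets`).
#' @export
simulate_enrichment_study <- function(spec, n_planted_sets = 10L,
                                      n_null_sets = 90L, set_size = 40L,
                                      planted_frac = 0.8) {
  stopifnot(inherits(spec, "sim_spec"))
  n_planted_sets <- .check_count(n_planted_sets, "n_planted_sets", min = 1L)
  n_null_sets <- .check_count(n_null_sets, "n_null_sets", min = 0L)
  set_size <- .check_count(set_size, "set_size", min = 2L)
  .check_scalar_num(planted_frac, "planted_frac", 0, 1)
  ng <- spec$n_genes
  if (n_planted_sets * set_size > ng / 2)
    .fail("planted sets would cover more than half the universe")
  genes <- sprintf("g%0*d", max(4L, nchar(ng)), seq_len(ng))
  set.seed(.derive_seed(spec$seed, 7L))
  pool <- sample(genes, n_planted_sets * set_size)
  beta <- stats::setNames(numeric(ng), genes)
  sets <- list()
  for (i in seq_len(n_planted_sets)) {
    members <- pool[((i - 1L) * set_size + 1L):(i * set_size)]
    hit <- sample(members, round(planted_frac * set_size))
    beta[hit] <- (if (i %% 2L) 1 else -1) * spec$de_log2fc
    sets[[sprintf("planted%02d", i)]] <- members
  }
  null_pool <- setdiff(genes, names(beta)[beta != 0])
  for (i in seq_len(n_null_sets))
    sets[[sprintf("null%02d", i)]] <- sample(null_pool, set_size)
  sim <- simulate_counts(spec, beta = unname(beta))
  list(cm = sim$cm,
       collection = gene_set_collection(sets, source = "simulated"),
       truth = list(de_genes = sim$truth$de_genes,
                    enriched_sets = sprintf("planted%02d",
                                            seq_len(n_planted_sets))))
}

#' Simulate a multi-stratum brain-expression study
#'
#' Emulates the full study design: two genotypes per stratum across a grid
#' of brain regions and ages, with a configurable fraction of the planted
#' DE genes shared (same sign) across all strata and the rest
#' stratum-specific. Counts per stratum are independent NB draws; the gene
#' universe is common, which is what the shared-gene report intersects.
#'
#' @param spec a [sim_spec()]; `de_fraction`/`de_log2fc` set the per-stratum
#'   planted signal.
#' @param regions,ages character vectors defining the strata grid.
#' @param shared_fraction fraction of each stratum's DE genes drawn from a
#'   common core shared by all strata (default 0.5).
#' @return A named list (one element per `region_age` stratum), each with
#'   `cm` and `truth`; attribute `shared_de` holds the common core (named
#'   signed log2FC vector).
#' @export
simulate_study <- function(spec,
                           regions = c("PFC", "striatum", "hippocampus", "amygdala"),
                           ages = c("3m", "6m"), shared_fraction = 0.5) {
  stopifnot(inherits(spec, "sim_spec"))
  .check_scalar_num(shared_fraction, "shared_fraction", 0, 1)
  ng <- spec$n_genes
  genes <- sprintf("g%0*d", max(4L, nchar(ng)), seq_len(ng))
  n_de <- round(spec$de_fraction * ng)
  n_shared <- round(shared_fraction * n_de)
  set.seed(.derive_seed(spec$seed, 3L))
  core_idx <- sample.int(ng, n_shared)
  core_sign <- sample(c(-1, 1), n_shared, replace = TRUE)
  strata <- expand.grid(region = regions, age = ages,
                        stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(strata))) {
    key <- paste(strata$region[i], strata$age[i], sep = "_")
    set.seed(.derive_seed(spec$seed, 100L + i))
    beta <- numeric(ng)
    beta[core_idx] <- core_sign * spec$de_log2fc
    extra <- sample(setdiff(seq_len(ng), core_idx), n_de - n_shared)
    beta[extra] <- sample(c(-1, 1), length(extra), replace = TRUE) * spec$de_log2fc
    spec_i <- spec
    spec_i$seed <- .derive_seed(spec$seed, 200L + i)
    out[[key]] <- simulate_counts(
      spec_i, beta = beta,
      meta_extra = list(region = strata$region[i], age = strata$age[i]),
      sample_prefix = paste0(key, "_"))
  }
  attr(out, "shared_de") <- stats::setNames(core_sign * spec$de_log2fc,
                                            genes[core_idx])
  out
}
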