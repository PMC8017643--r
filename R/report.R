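#' Shared DE genes across strata (Venn-region logic)
#'
#' For a list of per-stratum DE results, computes for every non-empty
#' combination of strata both the genes DE in exactly that combination
#' (the Venn region) and the genes DE in at least that combination (the
#' plain intersection), in one direction of change at a time.
#'
#' @param results named list of per-stratum results: [de_fit] objects or
#'   `gene_stats` data frames carrying `gene`, `logFC`, `is_de`. All
#'   strata must share the same gene universe.
#' @param direction `"up"` (logFC > 0) or `"down"`.
#' @return A data frame: `strata` (combination key, `+`-joined),
#'   `n_exclusive`, `genes_exclusive`, `n_at_least`, `genes_at_least`
#'   (gene lists comma-joined). Gene lists are sorted, so output is
#'   deterministic.
#' @export
shared_de_sets <- function(results, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(results) < 2L) .fail("need at least 2 strata")
  if (is.null(names(results)) || any(names(results) == ""))
    .fail("results must be a named list")
  tabs <- lapply(results, function(r) {
    if (inherits(r, "de_fit")) r$stats
    else if (is.data.frame(r) && all(c("gene", "logFC", "is_de") %in% names(r))) r
    else .fail("each result must be a de_fit or a gene_stats table")
  })
  uni <- sort(tabs[[1]]$gene)
  for (i in seq_along(tabs)[-1]) {
    d <- c(setdiff(uni, tabs[[i]]$gene), setdiff(tabs[[i]]$gene, uni))
    if (length(d))
      .fail("gene universes differ between strata (", names(results)[1], " vs ",
            names(results)[i], "): ", paste(utils::head(d, 5), collapse = ", "))
  }
  de_sets <- lapply(tabs, function(s) {
    keep <- s$is_de & (if (direction == "up") s$logFC > 0 else s$logFC < 0)
    s$gene[keep]
  })
  k <- length(de_sets)
  nm <- names(de_sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    inc <- unlist(combos[i, ])
    at_least <- Reduce(intersect, de_sets[inc])
    excl <- at_least
    for (j in which(!inc)) excl <- setdiff(excl, de_sets[[j]])
    data.frame(strata = paste(nm[inc], collapse = "+"),
               n_exclusive = length(excl),
               genes_exclusive = paste(sort(excl), collapse = ","),
               n_at_least = length(at_least),
               genes_at_least = paste(sort(at_least), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Column-bind per-stratum count matrices sharing one gene universe
.bind_strata <- function(cms) {
  genes <- rownames(cms[[1]]$counts)
  for (cm in cms) stopifnot(identical(rownames(cm$counts), genes))
  counts <- do.call(cbind, lapply(cms, `[[`, "counts"))
  meta <- do.call(rbind, lapply(cms, `[[`, "meta"))
  count_matrix(counts, meta)
}

# Build per-stratum count matrices from a loaded experiment, splitting on
# whatever of region/age columns the metadata has. One stratum "all" when
# neither is present.
.split_strata <- function(cm) {
  cols <- intersect(c("region", "age"), names(cm$meta))
  if (!length(cols)) return(list(all = cm))
  key <- do.call(paste, c(cm$meta[cols], sep = "_"))
  out <- list()
  for (k in unique(key)) {
    idx <- key == k
    out[[k]] <- count_matrix(cm$counts[, idx, drop = FALSE],
                             cm$meta[idx, , drop = FALSE])
  }
  out
}

.stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    marker <- file.path(out_dir, paste0("FAILED_", name))
    try(writeLines(conditionMessage(e), marker), silent = TRUE)
    .fail("stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full pipeline from a YAML configuration
#'
#' Executes simulate (optional) -> low-count filter -> TMM/logCPM ->
#' per-stratum DE -> ranking -> gene-set redundancy filter -> optional
#' ortholog mapping -> per-stratum GSEA -> shared-gene report -> optional
#' qPCR stage, writing every result as TSV into the output directory
#' together with a deterministic run manifest. Re-running the same
#' configuration reproduces byte-identical outputs; all randomness
#' derives from the single top-level `seed`.
#'
#' Configuration keys (YAML): `seed`; `out_dir`; either `counts` +
#' `meta` (TSV paths) or a `simulate` block (fields of [sim_spec()] plus
#' optional `regions`, `ages`, `shared_fraction`); optional `filter`
#' (`min_count`, `min_samples`), `de` (`lfc_threshold`, `alpha`), `gmt`
#' (path) or `collection` (`n_sets`, `set_size_min`, `set_size_max`),
#' `ortholog_map` (TSV path), `gsea` (fields of [gsea_config()]), `qpcr`
#' (`ct`, `meta`, `candidates`, `k`).
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir optional override of the configured output directory.
#' @param quiet suppress progress messages (default FALSE).
#' @return Invisibly, a list with the per-stratum results and the paths
#'   written.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) .fail("config must be a YAML path or a list")
  if (is.null(cfg$simulate) && (is.null(cfg$counts) || is.null(cfg$meta)))
    .fail("config needs either a simulate block or counts + meta paths")
  out_dir <- out_dir %||% cfg$out_dir %||% .fail("config needs out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- .check_count(cfg$seed %||% 1L, "seed", min = 0L)
  say <- function(...) if (!quiet) message(...)

  combined <- .stage("input", out_dir, {
    if (!is.null(cfg$simulate)) {
      sb <- cfg$simulate
      spec_args <- sb[intersect(names(sb), names(formals(sim_spec)))]
      spec_args$seed <- seed
      spec <- do.call(sim_spec, spec_args)
      sim <- simulate_study(spec,
                            regions = sb$regions %||% c("PFC", "striatum",
                                                        "hippocampus", "amygdala"),
                            ages = sb$ages %||% c("3m", "6m"),
                            shared_fraction = sb$shared_fraction %||% 0.5)
      .bind_strata(lapply(sim, `[[`, "cm"))
    } else {
      load_experiment(cfg$counts, cfg$meta)
    }
  })

  # low-count rule applied once to the full sample set (the per-area
  # comparisons then share one tested gene universe), then split
  fl <- cfg$filter %||% list()
  de_cfg <- cfg$de %||% list()
  strata <- .stage("filter", out_dir, {
    .split_strata(filter_low_counts(combined,
                                    min_count = fl$min_count %||% 10L,
                                    min_samples = fl$min_samples %||% 10L))
  })
  say("strata: ", paste(names(strata), collapse = ", "))

  fits <- .stage("de", out_dir, {
    lapply(strata, function(cm)
      de_fit(cm, lfc_threshold = de_cfg$lfc_threshold %||% 0.585,
             alpha = de_cfg$alpha %||% 0.05))
  })
  for (k in names(fits)) {
    write_tsv(fits[[k]]$stats, file.path(out_dir, paste0("genestats_", k, ".tsv")))
    write_rnk(fits[[k]]$ranked, file.path(out_dir, paste0("ranked_", k, ".rnk")))
  }

  collection <- .stage("genesets", out_dir, {
    if (!is.null(cfg$gmt)) {
      read_gmt(cfg$gmt)
    } else if (!is.null(cfg$collection)) {
      cb <- cfg$collection
      universe <- fits[[1]]$stats$gene
      simulate_collection(universe, n_sets = cb$n_sets %||% 50L,
                          set_size_range = c(cb$set_size_min %||% 10L,
                                             cb$set_size_max %||% 50L),
                          seed = .derive_seed(seed, 301L))$collection
    } else NULL
  })

  gsea_res <- NULL
  if (!is.null(collection)) {
    gsea_res <- .stage("gsea", out_dir, {
      filtered <- filter_redundant(collection)
      write_tsv(filtered$removal_log, file.path(out_dir, "genesets_removed.tsv"))
      coll <- filtered$collection
      if (!is.null(cfg$ortholog_map)) {
        mapped <- map_orthologs(coll, read_ortholog_map(cfg$ortholog_map))
        write_tsv(mapped$unmapped_report, file.path(out_dir, "unmapped_genes.tsv"))
        coll <- mapped$collection
      }
      gc_args <- cfg$gsea %||% list()
      gc_args <- gc_args[intersect(names(gc_args), names(formals(gsea_config)))]
      gc_args$seed <- .derive_seed(seed, 401L)
      gcfg <- do.call(gsea_config, gc_args)
      lapply(fits, function(f) run_gsea(f$ranked, coll, gcfg))
    })
    for (k in names(gsea_res))
      write_tsv(as.data.frame(gsea_res[[k]]),
                file.path(out_dir, paste0("gsea_", k, ".tsv")))
  }

  if (length(fits) >= 2) {
    .stage("shared", out_dir, {
      write_tsv(shared_de_sets(fits, "up"), file.path(out_dir, "shared_up.tsv"))
      write_tsv(shared_de_sets(fits, "down"), file.path(out_dir, "shared_down.tsv"))
    })
  }

  qpcr_res <- NULL
  if (!is.null(cfg$qpcr)) {
    qpcr_res <- .stage("qpcr", out_dir, {
      qb <- cfg$qpcr
      ct <- read_ct_table(qb$ct, qb$meta, candidates = qb$candidates %||% character(0))
      fit <- qpcr_validate(ct, k = qb$k %||% 2L)
      write_tsv(fit$results, file.path(out_dir, "qpcr_results.tsv"))
      write_tsv(fit$endogenous$report, file.path(out_dir, "qpcr_endogenous.tsv"))
      fit
    })
  }

  manifest <- list(seed = seed,
                   strata = names(fits),
                   n_genes_tested = vapply(fits, function(f) nrow(f$stats),
                                           integer(1)),
                   de_called = vapply(fits, function(f) sum(f$stats$is_de),
                                      integer(1)),
                   parameters = list(filter = fl, de = de_cfg,
                                     gsea = cfg$gsea %||% list()),
                   package_version = as.character(utils::packageVersion("txenrich")))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  say("pipeline complete: ", out_dir)
  invisible(list(fits = fits, gsea = gsea_res, qpcr = qpcr_res,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
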