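#' Construct a gene-set collection
#'
#' A named list of character vectors (member genes), each with a source
#' label (pathway database of origin or a "simulated"/"published" tag).
#' Member genes are deduplicated; empty sets and duplicate names are
#' rejected.
#'
#' @param sets named list of character vectors.
#' @param source character vector of source labels, length 1 (recycled) or
#'   `length(sets)`.
#' @return A list of class `gene_set_collection` with a `source` attribute.
#' @export
gene_set_collection <- function(sets, source = "") {
  if (!is.list(sets)) .fail("sets must be a named list")
  if (is.null(names(sets)) || any(names(sets) == ""))
    .fail("every gene set needs a name")
  if (anyDuplicated(names(sets)))
    .fail("duplicate set names: ",
          paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) .fail("empty gene sets are not allowed")
  if (length(source) == 1L) source <- rep(source, length(sets))
  if (length(source) != length(sets))
    .fail("source must have length 1 or length(sets)")
  structure(sets, source = stats::setNames(as.character(source), names(sets)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x)
  cat("gene_set_collection:", length(x), "sets, sizes",
      if (length(x)) paste0(min(sz), "-", max(sz)) else "-", "\n")
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  src <- attr(x, "source")
  y <- unclass(x)[i]
  gene_set_collection(y, source = unname(src[names(y)]))
}

#' Read a gene-set collection from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#' The description column is kept as the set's source label; duplicate
#' member genes are collapsed.
#'
#' @param path GMT file path.
#' @return A [gene_set_collection] (empty file gives an empty collection).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) .fail("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(structure(list(), source = stats::setNames(character(0), character(0)),
                     class = "gene_set_collection"))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    .fail("GMT line ", short[1], " has fewer than 3 fields")
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms))
    .fail("duplicate set names in GMT: ",
          paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nms
  gene_set_collection(sets, source = vapply(fields, `[[`, "", 2L))
}

#' Write a gene-set collection to a GMT file
#'
#' Round-trips with [read_gmt()] up to member ordering.
#'
#' @param collection a [gene_set_collection].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  src <- attr(collection, "source")
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, src[[nm]], collection[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Jaccard coefficient of two gene sets
#'
#' `|a intersect b| / |a union b|`, on deduplicated members.
#'
#' @param a,b character vectors of gene identifiers; both non-empty.
#' @return A number in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) .fail("jaccard of an empty set is undefined")
  length(intersect(a, b)) / length(union(a, b))
}

#' Remove redundant gene sets by pairwise Jaccard coefficient
#'
#' Greedy pass over the sets sorted by descending size, ties broken by set
#' name: a set is kept iff its Jaccard coefficient with every previously
#' kept set is at most `threshold`. Exact duplicates (Jaccard 1) thereby
#' collapse to one representative, and within a near-duplicate cluster
#' (Jaccard > threshold) the largest set survives. Survivors are pairwise
#' at or below the threshold, and the filter is idempotent.
#'
#' @param collection a [gene_set_collection].
#' @param threshold sets with Jaccard strictly above this against a kept
#'   set are removed (default 0.8; a pair at exactly the threshold is kept).
#' @return A list: `collection` (the survivors, in their original order)
#'   and `removal_log` (data frame: `removed_set`, `kept_set`, `jaccard`).
#' @export
filter_redundant <- function(collection, threshold = 0.8) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    .fail("threshold must be in (0, 1]")
  nms <- names(collection)
  sizes <- lengths(collection)
  ord <- nms[order(-sizes, nms)]
  kept <- character(0)
  log_rm <- log_kp <- character(0); log_j <- numeric(0)
  for (nm in ord) {
    j_with <- vapply(kept, function(kp) jaccard(collection[[nm]],
                                                collection[[kp]]), numeric(1))
    if (length(j_with) && any(j_with > threshold)) {
      w <- which.max(j_with)
      log_rm <- c(log_rm, nm); log_kp <- c(log_kp, kept[w])
      log_j <- c(log_j, j_with[w])
    } else {
      kept <- c(kept, nm)
    }
  }
  list(collection = collection[nms[nms %in% kept]],
       removal_log = data.frame(removed_set = log_rm, kept_set = log_kp,
                                jaccard = log_j, stringsAsFactors = FALSE))
}

#' Construct an ortholog map
#'
#' @param df data frame with character columns `source` and `target`; a
#'   source symbol may repeat (one-to-many mapping). Unmapped symbols are
#'   simply absent.
#' @return The validated data frame with class `ortholog_map`.
#' @export
ortholog_map <- function(df) {
  if (!is.data.frame(df) || !all(c("source", "target") %in% names(df)))
    .fail("ortholog map needs source and target columns")
  df <- unique(df[, c("source", "target")])
  df$source <- as.character(df$source); df$target <- as.character(df$target)
  if (any(!nzchar(df$source)) || any(!nzchar(df$target)))
    .fail("empty symbols in ortholog map")
  class(df) <- c("ortholog_map", "data.frame")
  df
}

#' Read a two-column ortholog map from TSV
#'
#' @param path TSV with header columns `source` and `target`.
#' @return An [ortholog_map].
#' @export
read_ortholog_map <- function(path) ortholog_map(.read_tsv(path))

#' Translate a gene-set collection through an ortholog map
#'
#' Each member gene is replaced by all of its targets (one-to-many
#' mappings expand, then deduplicate). Genes without a target are dropped
#' and reported; sets emptied by the mapping are removed when
#' `drop_empty` is TRUE.
#'
#' @param collection a [gene_set_collection].
#' @param om an [ortholog_map].
#' @param drop_empty drop sets with no mapped member (default TRUE).
#' @return A list: `collection` (mapped) and `unmapped_report` (data
#'   frame: `set_name`, `gene` for every dropped member occurrence).
#' @export
map_orthologs <- function(collection, om, drop_empty = TRUE) {
  stopifnot(inherits(collection, "gene_set_collection"),
            inherits(om, "ortholog_map"))
  tgt <- split(om$target, om$source)
  un_set <- un_gene <- character(0)
  mapped <- lapply(names(collection), function(nm) {
    g <- collection[[nm]]
    hit <- g %in% names(tgt)
    if (any(!hit)) {
      un_set <<- c(un_set, rep(nm, sum(!hit)))
      un_gene <<- c(un_gene, g[!hit])
    }
    unique(unlist(tgt[g[hit]], use.names = FALSE))
  })
  names(mapped) <- names(collection)
  src <- attr(collection, "source")
  keep <- if (drop_empty) lengths(mapped) > 0 else rep(TRUE, length(mapped))
  mapped <- mapped[keep]
  # built directly: names/dedup already guaranteed, and drop_empty = FALSE
  # legitimately retains emptied sets the constructor would reject
  coll <- structure(mapped, source = src[names(mapped)],
                    class = "gene_set_collection")
  list(collection = coll,
       unmapped_report = data.frame(set_name = un_set, gene = un_gene,
                                    stringsAsFactors = FALSE))
}
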