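#' @keywords internal
"_PACKAGE"

# stop() with call suppressed; all validation errors route through here
.fail <- function(...) stop(..., call. = FALSE)

.check_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .fail(name, " must be a finite numeric scalar")
  if (x < lower || x > upper)
    .fail(name, " must be in [", lower, ", ", upper, "]")
  invisible(x)
}

.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    .fail(name, " must be an integer scalar")
  if (x < min) .fail(name, " must be >= ", min)
  as.integer(x)
}

# Deterministic per-stage seed expansion from one top-level seed.
# Offsets are small so derived seeds stay well below .Machine$integer.max.
.derive_seed <- function(seed, offset) {
  seed <- .check_count(seed, "seed", min = 0L)
  (seed * 131L + as.integer(offset)) %% 2147483647L
}

# Geometric mean of strictly positive values
.geomean <- function(x) exp(mean(log(x)))

#' Write a table as TSV
#'
#' Plain tab-separated export used by every pipeline stage: no quoting,
#' no row names, `NA` written as the empty string.
#'
#' @param df data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) .fail("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
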