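#' Derive a child seed from a parent seed and one or more integer indices
#'
#' Every stochastic step in the package draws its own seed deterministically
#' from a single top-level seed plus a structural index (permutation number,
#' replicate number, gene row, ...). This keeps results independent of
#' traversal order and reproducible from one integer.
#'
#' @param seed integer parent seed.
#' @param ... integer indices identifying the child stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  stopifnot(length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, keeps everything exactly representable as double
  h <- as.numeric(seed) %% m
  for (k in idx) {
    # affine mix with large odd multipliers; doubles stay below 2^53 so the
    # arithmetic is exact
    h <- (h * 69069 + (as.numeric(k) %% m) * 40503 + 12345) %% m
    h <- (h * 20021 + 1) %% m
  }
  as.integer(h)
}

#' Evaluate code with a temporary RNG seed
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`; the caller's RNG state is restored afterwards.
#' @keywords internal
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Write a data frame as TSV with a "#"-prefixed key=value metadata header
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param meta named list/vector of scalar metadata values.
#' @return `path`, invisibly.
#' @export
write_tsv_meta <- function(df, path, meta = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(meta)) {
    stopifnot(!is.null(names(meta)), all(nzchar(names(meta))))
    writeLines(sprintf("#%s=%s", names(meta), vapply(meta, format, "")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_meta()], returning data plus metadata
#'
#' @param path input path.
#' @return data.frame with attribute `"meta"` (named character vector).
#' @export
read_tsv_meta <- function(path) {
  lines <- readLines(path, n = 200L)
  n_meta <- 0L
  while (n_meta < length(lines) && startsWith(lines[n_meta + 1L], "#")) {
    n_meta <- n_meta + 1L
  }
  meta <- character(0)
  if (n_meta > 0L) {
    kv <- sub("^#", "", lines[seq_len(n_meta)])
    eq <- regexpr("=", kv, fixed = TRUE)
    meta <- structure(substring(kv, eq + 1L), names = substring(kv, 1L, eq - 1L))
  }
  df <- utils::read.delim(path, skip = n_meta, check.names = FALSE,
                          stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}
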