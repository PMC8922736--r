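#' Read a gene-by-sample count matrix
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`tsv`}{header row of sample ids, first column gene ids,
#'     tab-separated; leading `#`-prefixed metadata lines are skipped.}
#'   \item{`gct`}{GCT 1.2: line 1 is the literal version tag `#1.2`, line 2
#'     holds the row and column counts, data rows carry `Name` and
#'     `Description` columns before the sample columns. `Description` is
#'     discarded; ids are kept verbatim.}
#'   \item{`mtx-triplet`}{Matrix Market coordinate file with two sidecar id
#'     lists, `<path>.genes` and `<path>.samples`, one id per line.}
#' }
#'
#' @param path input file.
#' @param format one of `"tsv"`, `"gct"`, `"mtx-triplet"`.
#' @return a validated count matrix (see [count_matrix()]).
#' @export
read_count_matrix <- function(path, format = c("tsv", "gct", "mtx-triplet")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         "tsv" = read_counts_tsv(path),
         "gct" = read_counts_gct(path),
         "mtx-triplet" = read_counts_mtx(path))
}

read_counts_tsv <- function(path) {
  head_lines <- readLines(path, n = 500L)
  skip <- 0L
  while (skip < length(head_lines) && startsWith(head_lines[skip + 1L], "#")) {
    skip <- skip + 1L
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE, skip = skip,
                          data.table = FALSE, check.names = FALSE)
  if (ncol(dt) < 2L) stop("malformed TSV count table: fewer than 2 columns in ", path)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(dt[-1L], is.numeric, TRUE))[1L]
    stop("non-numeric counts in column '", colnames(dt)[bad + 1L], "' of ", path)
  }
  count_matrix(m, gene_ids = dt[[1L]], sample_ids = colnames(dt)[-1L])
}

read_counts_gct <- function(path) {
  lines12 <- readLines(path, n = 2L)
  if (length(lines12) < 2L || trimws(lines12[1L]) != "#1.2") {
    stop("malformed GCT header (line 1 must be '#1.2') in ", path)
  }
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines12[2L]), "\t")[[1L]]))
  if (length(dims) < 2L || anyNA(dims[1:2])) {
    stop("malformed GCT dimension line (line 2) in ", path)
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE, skip = 2L,
                          data.table = FALSE, check.names = FALSE)
  if (ncol(dt) < 3L) stop("GCT body needs Name, Description and sample columns: ", path)
  if (nrow(dt) != dims[1L] || ncol(dt) - 2L != dims[2L]) {
    stop(sprintf("GCT dimension mismatch in %s: line 2 declares %d x %d but body has %d x %d",
                 path, dims[1L], dims[2L], nrow(dt), ncol(dt) - 2L))
  }
  m <- as.matrix(dt[, -(1:2), drop = FALSE]) # Description column discarded
  count_matrix(m, gene_ids = dt[[1L]], sample_ids = colnames(dt)[-(1:2)])
}

read_counts_mtx <- function(path) {
  genes_path <- paste0(path, ".genes")
  samples_path <- paste0(path, ".samples")
  if (!file.exists(genes_path) || !file.exists(samples_path)) {
    stop("mtx-triplet sidecar id lists missing: expected ", genes_path,
         " and ", samples_path)
  }
  sp <- Matrix::readMM(path)
  gene_ids <- readLines(genes_path)
  sample_ids <- readLines(samples_path)
  if (nrow(sp) != length(gene_ids) || ncol(sp) != length(sample_ids)) {
    stop("mtx dimensions disagree with sidecar id lists for ", path)
  }
  count_matrix(as.matrix(sp), gene_ids = gene_ids, sample_ids = sample_ids)
}

#' Write a count matrix in any supported dialect
#'
#' Inverse of [read_count_matrix()]; `write` then `read` reproduces the same
#' gene ids, sample ids and counts.
#'
#' @param m validated count matrix.
#' @param path output file.
#' @param format one of `"tsv"`, `"gct"`, `"mtx-triplet"`.
#' @param meta optional named metadata written as `#key=value` lines (TSV only).
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path, format = c("tsv", "gct", "mtx-triplet"),
                               meta = list()) {
  format <- match.arg(format)
  validate_count_matrix(m)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    write_tsv_meta(df, path, meta = meta)
  } else if (format == "gct") {
    con <- file(path, open = "wt", encoding = "UTF-8")
    writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
    df <- data.frame(Name = rownames(m), Description = rownames(m), m,
                     check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  } else {
    sp <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), "TsparseMatrix")
    Matrix::writeMM(sp, path)
    writeLines(rownames(m), paste0(path, ".genes"))
    writeLines(colnames(m), paste0(path, ".samples"))
  }
  invisible(path)
}

#' Read a two-column sample/condition label table
#'
#' @param path TSV with columns `sample_id` and `condition` (header required;
#'   leading `#` metadata lines allowed).
#' @param levels optional explicit condition-level order.
#' @return named two-level factor (see [condition_labels()]).
#' @export
read_labels <- function(path, levels = NULL) {
  df <- read_tsv_meta(path)
  need <- c("sample_id", "condition")
  if (!all(need %in% colnames(df))) {
    stop("label table must have columns 'sample_id' and 'condition': ", path)
  }
  condition_labels(df$sample_id, df$condition, levels = levels)
}

#' Write a label table readable by [read_labels()]
#'
#' @param labels named two-level factor.
#' @param path output file.
#' @param meta optional metadata lines.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, meta = list()) {
  validate_labels(labels)
  write_tsv_meta(data.frame(sample_id = names(labels),
                            condition = as.character(labels)),
                 path, meta = meta)
}
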