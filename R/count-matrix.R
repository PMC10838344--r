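#' Experimental conditions recognised by the pipeline
#'
#' The design is fixed at three levels mirroring a
#' control / perturbed / perturbed-plus-drug experiment. Extra levels in a
#' condition file are rejected.
#'
#' @export
CONDITION_LEVELS <- c("control", "perturbed", "perturbed_drug")

#' Construct a validated count matrix
#'
#' The entry point type of the pipeline: a genes x samples matrix of
#' non-negative integer read counts (e.g. rounded expected counts from an
#' upstream quantifier) plus a condition label per sample.
#'
#' @param counts numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names. Entries must be non-negative integers.
#' @param condition named character vector mapping every sample id to one
#'   of `r toString(CONDITION_LEVELS)`.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (integer matrix), `gene_ids`, `sample_ids` and `condition`
#'   (named character).
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' cond <- setNames(rep(c("control", "perturbed"), each = 2), colnames(m))
#' cm <- count_matrix(m, cond)
#' @export
count_matrix <- function(counts, condition) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  gene_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("`counts` must have gene row names and sample column names")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid count (negative or not finite) at gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  frac <- which(counts != floor(counts), arr.ind = TRUE)
  if (nrow(frac)) {
    stop(sprintf(
      "fractional count at gene '%s', sample '%s'; use round_counts = TRUE to round at read time",
      gene_ids[frac[1L, 1L]], sample_ids[frac[1L, 2L]]))
  }
  missing_cond <- setdiff(sample_ids, names(condition))
  if (length(missing_cond))
    stop("no condition for sample(s): ", toString(missing_cond))
  condition <- condition[sample_ids]
  bad_lvl <- setdiff(unique(condition), CONDITION_LEVELS)
  if (length(bad_lvl))
    stop("unknown condition level(s): ", toString(bad_lvl),
         " (allowed: ", toString(CONDITION_LEVELS), ")")
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts, gene_ids = gene_ids, sample_ids = sample_ids,
         condition = condition),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", length(x$gene_ids), "genes x",
      length(x$sample_ids), "samples\n")
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(table(x$condition)),
                    as.integer(table(x$condition))), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix and its condition table
#'
#' Accepts either a plain TSV (gene rows x sample columns, header row of
#' sample ids, first column of gene ids) or a MatrixMarket triplet file
#' (`*.mtx`) with sidecar files `*.genes.txt` and `*.samples.txt` holding
#' one id per line. Both layouts produce identical in-memory objects.
#'
#' @param path counts file (`.tsv`/`.txt` or `.mtx`).
#' @param condition_path two-column TSV (sample_id, condition), no header
#'   required; a header line `sample_id<TAB>condition` is tolerated.
#' @param round_counts round fractional values (e.g. expected counts) to
#'   the nearest integer instead of rejecting them. Default `FALSE`:
#'   fractional entries are an error.
#' @return A validated [count_matrix()].
#' @export
read_counts <- function(path, condition_path, round_counts = FALSE) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    genes_f <- sub("\\.mtx$", ".genes.txt", path)
    samples_f <- sub("\\.mtx$", ".samples.txt", path)
    if (!file.exists(genes_f) || !file.exists(samples_f))
      stop("MatrixMarket sidecar file missing: expected ", genes_f,
           " and ", samples_f)
    rownames(m) <- readLines(genes_f)
    colnames(m) <- readLines(samples_f)
  } else {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (anyDuplicated(df[[1L]]))
      stop("duplicate gene id: ", df[[1L]][duplicated(df[[1L]])][1L])
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    if (!is.numeric(m)) stop("non-numeric entries in counts file ", path)
  }
  if (round_counts) m <- round(m)
  count_matrix(m, read_conditions(condition_path))
}

read_conditions <- function(path) {
  if (!file.exists(path)) stop("condition file not found: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 2L)
    stop("condition file must have exactly 2 columns (sample_id, condition)")
  if (identical(tolower(df[1L, 1L]), "sample_id")) df <- df[-1L, , drop = FALSE]
  if (anyDuplicated(df[[1L]]))
    stop("duplicate sample id in condition file: ",
         df[[1L]][duplicated(df[[1L]])][1L])
  setNames(df[[2L]], df[[1L]])
}

#' Write a count matrix (TSV or MatrixMarket) plus condition table
#'
#' Inverse of [read_counts()]; used by the simulator and for round-trip
#' testing. Format is chosen by the `path` extension (`.mtx` for
#' MatrixMarket with id sidecars, anything else for TSV).
#'
#' @param cm a [count_matrix()].
#' @param path counts output file.
#' @param condition_path condition output TSV.
#' @return Invisibly, `cm`.
#' @export
write_counts <- function(cm, path, condition_path) {
  stopifnot(inherits(cm, "count_matrix"))
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE), path)
    writeLines(cm$gene_ids, sub("\\.mtx$", ".genes.txt", path))
    writeLines(cm$sample_ids, sub("\\.mtx$", ".samples.txt", path))
  } else {
    df <- data.frame(gene_id = cm$gene_ids, cm$counts, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(data.frame(names(cm$condition), unname(cm$condition)),
              condition_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(cm)
}

# samples belonging to one condition; errors if below a minimum replicate count
condition_samples <- function(cm, cond, min_n = 2L) {
  s <- cm$sample_ids[cm$condition == cond]
  if (length(s) < min_n)
    stop(sprintf("condition '%s' has %d sample(s); >= %d required",
                 cond, length(s), min_n))
  s
}
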