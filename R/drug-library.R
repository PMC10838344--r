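#' Source databases accepted in a drug-target table
#'
#' The default vocabulary mirrors the seven public interaction databases
#' commonly pooled for target annotation.
#'
#' @export
DRUG_TARGET_SOURCES <- c("ChEMBL", "DGIdb", "DrugBank", "IUPHAR", "KEGG",
                         "PharmGKB", "DrugCentral")

#' Construct a drug-profile library
#'
#' A library of per-profile differential-expression score vectors over a
#' common gene space (an L1000-style signature library). A drug may own
#' several profiles (doses, times, cell lines); every profile scores
#' every gene in the shared gene space exactly once.
#'
#' @param scores numeric matrix, genes x profiles, with unique row and
#'   column names; no missing values.
#' @param meta data frame with columns `profile_id`, `drug_id`,
#'   `quality`, `fda_approved` (logical flags), one row per profile.
#' @return Object of class `drug_profile_library` with elements `scores`,
#'   `meta`, `gene_space`.
#' @export
drug_profile_library <- function(scores, meta) {
  if (!is.matrix(scores) || is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("`scores` must be a genes x profiles matrix with dimnames")
  if (anyDuplicated(rownames(scores)))
    stop("duplicate gene in gene_space")
  if (anyDuplicated(colnames(scores)))
    stop("duplicate profile_id")
  if (anyNA(scores)) {
    bad <- which(is.na(scores), arr.ind = TRUE)[1L, ]
    stop(sprintf("profile '%s' is missing a score for gene '%s'",
                 colnames(scores)[bad[2L]], rownames(scores)[bad[1L]]))
  }
  need <- c("profile_id", "drug_id", "quality", "fda_approved")
  if (!all(need %in% names(meta)))
    stop("meta must have columns: ", toString(need))
  missing_meta <- setdiff(colnames(scores), meta$profile_id)
  if (length(missing_meta))
    stop("profiles without metadata: ", toString(head(missing_meta, 5L)))
  meta <- meta[match(colnames(scores), meta$profile_id), need]
  rownames(meta) <- NULL
  meta$quality <- as.logical(meta$quality)
  meta$fda_approved <- as.logical(meta$fda_approved)
  structure(list(scores = scores, meta = meta,
                 gene_space = rownames(scores)),
            class = "drug_profile_library")
}

#' @export
print.drug_profile_library <- function(x, ...) {
  cat("drug_profile_library:", ncol(x$scores), "profiles /",
      length(unique(x$meta$drug_id)), "drugs over",
      length(x$gene_space), "genes\n")
  cat("retained by quality+FDA filter:",
      sum(x$meta$quality & x$meta$fda_approved), "profiles\n")
  invisible(x)
}

#' Read a drug-profile library from long-format TSV
#'
#' @param path long TSV with header `profile_id, drug_id, gene, score`.
#'   Every profile must score exactly the genes of the common gene space
#'   (the union over profiles); a gene scored twice or missing in a
#'   profile is an error naming that profile.
#' @param meta_path TSV with header `profile_id, quality, fda_approved`
#'   (logical / 0-1 flags).
#' @return A [drug_profile_library()].
#' @export
read_drug_profiles <- function(path, meta_path) {
  long <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("profile_id", "drug_id", "gene", "score")
  if (!all(need %in% names(long)))
    stop("profile file must have columns: ", toString(need))
  gene_space <- sort(unique(long$gene))
  profiles <- sort(unique(long$profile_id))
  dup <- duplicated(long[c("profile_id", "gene")])
  if (any(dup))
    stop("gene scored twice in profile '", long$profile_id[dup][1L], "'")
  n_per <- table(long$profile_id)
  short <- names(n_per)[n_per < length(gene_space)]
  if (length(short))
    stop("profile '", short[1L], "' does not score the full gene space (",
         n_per[short[1L]], " of ", length(gene_space), " genes)")
  scores <- matrix(NA_real_, length(gene_space), length(profiles),
                   dimnames = list(gene_space, profiles))
  scores[cbind(match(long$gene, gene_space),
               match(long$profile_id, profiles))] <- long$score
  drug_map <- long$drug_id[!duplicated(long$profile_id)]
  names(drug_map) <- long$profile_id[!duplicated(long$profile_id)]
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  if (!all(c("profile_id", "quality", "fda_approved") %in% names(meta)))
    stop("meta file must have columns profile_id, quality, fda_approved")
  meta$drug_id <- unname(drug_map[meta$profile_id])
  drug_profile_library(scores, meta)
}

#' Write a drug-profile library (long TSV + metadata TSV)
#'
#' @param lib a [drug_profile_library()].
#' @param path,meta_path output files, see [read_drug_profiles()].
#' @return Invisibly, `lib`.
#' @export
write_drug_profiles <- function(lib, path, meta_path) {
  stopifnot(inherits(lib, "drug_profile_library"))
  long <- data.frame(
    profile_id = rep(colnames(lib$scores), each = nrow(lib$scores)),
    drug_id = rep(lib$meta$drug_id, each = nrow(lib$scores)),
    gene = rep(rownames(lib$scores), ncol(lib$scores)),
    score = as.vector(lib$scores))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(lib$meta[c("profile_id", "quality", "fda_approved")],
              meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(lib)
}

#' Read a drug-target interaction table
#'
#' @param path TSV with header `drug_id, target_id, source_db`. Rows are
#'   deduplicated on (drug_id, target_id); the source annotation of the
#'   first occurrence is kept.
#' @param sources allowed vocabulary for `source_db`.
#' @return data frame of class `drug_target_table`.
#' @export
read_drug_targets <- function(path, sources = DRUG_TARGET_SOURCES) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "target_id", "source_db")
  if (!all(need %in% names(df)))
    stop("drug-target file must have columns: ", toString(need))
  bad <- setdiff(unique(df$source_db), sources)
  if (length(bad))
    stop("unknown source_db value(s): ", toString(bad))
  df <- df[!duplicated(df[c("drug_id", "target_id")]), need]
  rownames(df) <- NULL
  class(df) <- c("drug_target_table", "data.frame")
  df
}

#' Write a drug-target interaction table
#'
#' @param targets a `drug_target_table` (or equivalent data frame).
#' @param path output TSV.
#' @return Invisibly, `targets`.
#' @export
write_drug_targets <- function(targets, path) {
  write.table(as.data.frame(targets), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(targets)
}
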