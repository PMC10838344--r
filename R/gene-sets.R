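#' Construct a gene-set collection
#'
#' Carrier for pathway catalogues and transcription-factor regulons.
#'
#' @param sets named list of character vectors (members); names are set
#'   ids and must be unique. Members are deduplicated; empty sets are an
#'   error here (the GMT reader drops them with a warning instead).
#' @param descriptions optional character vector parallel to `sets`.
#' @param universe optional explicit gene universe.
#' @return Object of class `gene_set_collection` with elements `sets`,
#'   `descriptions`, `universe`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("set ids must be unique and non-empty")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L))
    stop("empty member list in set: ",
         names(sets)[lengths(sets) == 0L][1L])
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- setNames(as.character(descriptions), names(sets))
  structure(list(sets = sets, descriptions = descriptions,
                 universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets, member sizes",
      min(lengths(x$sets)), "-", max(lengths(x$sets)), "\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line,
#' `set_id<TAB>description<TAB>gene<TAB>gene...`. Members are
#' deduplicated within each set; sets left empty after parsing are
#' dropped with a warning.
#'
#' @param path GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  # sentinel keeps trailing empty fields (strsplit would drop them)
  fields <- strsplit(paste0(lines, "\t\x01"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) f[-length(f)])
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1L]))
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate set id in GMT: ", ids[duplicated(ids)][1L])
  desc <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty set(s): ",
            toString(ids[empty]))
    ids <- ids[!empty]; desc <- desc[!empty]; members <- members[!empty]
  }
  gene_set_collection(setNames(members, ids), desc)
}

#' Write a gene-set collection as GMT
#'
#' @param gsc a [gene_set_collection()].
#' @param path output file.
#' @return Invisibly, `gsc`.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(names(gsc$sets), function(id) {
    paste(c(id, gsc$descriptions[[id]], gsc$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(gsc)
}
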