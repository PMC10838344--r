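#' Read an ortholog map (e.g. human to mouse symbols)
#'
#' The raw table may contain many-to-many pairs; only rows forming a
#' strict one-to-one correspondence after filtering are kept, and a
#' summary of the dropped rows is reported via `message()`. No biological
#' collapse rule is applied beyond 1:1 filtering.
#'
#' @param path two-column TSV `source_gene<TAB>destination_gene`
#'   (a `source_gene`/`destination_gene` header line is tolerated).
#' @param to_upper normalize both columns to upper case before filtering
#'   (useful when human and mouse symbol casing differs).
#' @return Named character vector of class `ortholog_map`
#'   (`source -> destination`).
#' @export
read_ortholog_map <- function(path, to_upper = FALSE) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("ortholog map must have 2 columns")
  if (identical(tolower(df[1L, 1L]), "source_gene")) df <- df[-1L, , drop = FALSE]
  src <- as.character(df[[1L]]); dst <- as.character(df[[2L]])
  if (to_upper) { src <- toupper(src); dst <- toupper(dst) }
  keep <- !(src %in% src[duplicated(src)]) & !(dst %in% dst[duplicated(dst)])
  n_drop <- sum(!keep)
  if (n_drop)
    message("ortholog map: dropped ", n_drop,
            " row(s) not forming a 1:1 pair (kept ", sum(keep), ")")
  structure(setNames(dst[keep], src[keep]), class = "ortholog_map")
}

#' Translate gene ids through an ortholog map
#'
#' Genes with a mapping are translated; unmapped genes are dropped (lossy
#' by contract) and their count reported via `message()`.
#'
#' @param genes character vector of source gene ids.
#' @param map an [read_ortholog_map()] result (or any named character
#'   vector source -> destination).
#' @return Character vector of translated ids, in input order.
#' @export
apply_ortholog_map <- function(genes, map) {
  hit <- genes %in% names(map)
  if (any(!hit))
    message("ortholog mapping dropped ", sum(!hit), " of ",
            length(genes), " gene(s)")
  unname(map[genes[hit]])
}
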