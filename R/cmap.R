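#' Jaccard index of two gene sets
#'
#' `|a intersect b| / |a union b|`, with the convention that two empty
#' sets score 0.
#'
#' @param a,b character vectors (treated as sets).
#' @return Value in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Extreme up/down signature of a drug profile
#'
#' The `n_sig` most up-regulated and `n_sig` most down-regulated genes
#' of a per-gene score vector. Ties are broken deterministically by gene
#' id: the up flank prefers lexicographically earlier genes, the down
#' flank later ones (the two flanks are the head and tail of one total
#' ordering, so they can never overlap).
#'
#' @param profile named numeric score vector (>= `2 * n_sig` genes).
#' @param n_sig flank size (default 100).
#' @return Object of class `drug_signature`: list with `up`, `down`,
#'   `n_sig`.
#' @export
make_signature <- function(profile, n_sig = 100L) {
  if (is.null(names(profile))) stop("profile must be named by gene")
  if (length(profile) < 2L * n_sig)
    stop("profile scores ", length(profile), " genes; ",
         2L * n_sig, " required for n_sig = ", n_sig)
  ord <- order(-profile, names(profile))
  # down flank is the tail of the same total order, most extreme first
  structure(list(up = names(profile)[ord[seq_len(n_sig)]],
                 down = names(profile)[rev(ord)[seq_len(n_sig)]],
                 n_sig = as.integer(n_sig)),
            class = "drug_signature")
}

#' Screen a drug-profile library for flip-signature mimics
#'
#' Retains only high-quality profiles of FDA-approved drugs, scores each
#' retained profile's similarity to the flip signature by a Jaccard
#' index over its extreme up/down gene flanks, and flags the top decile.
#'
#' In `directional` mode (default) only direction-concordant signature
#' genes count as hits - a mimic must *down*-regulate the genes the drug
#' of interest reverses downwards (`up_down` flips) and *up*-regulate
#' the `down_up` flips - and the score is
#' `|concordant hits| / |flip genes union signature genes|`. In `pooled`
#' mode the plain Jaccard between all flip genes and the pooled
#' signature is used.
#'
#' Profiles with a score at or above the 90th-percentile cutoff are
#' flagged (`ceiling(decile * retained)` profiles, extended to ties at
#' the threshold).
#'
#' @param fs a [classify_flip()] result (after any ortholog mapping into
#'   the library's gene space).
#' @param lib a [drug_profile_library()].
#' @param mode `"directional"` or `"pooled"`.
#' @param n_sig signature flank size.
#' @param decile fraction of retained profiles flagged (default 0.10).
#' @return Object of class `mimicry_result` (a data frame): per retained
#'   profile `profile_id`, `drug_id`, `jaccard`, `hits_up_down`,
#'   `hits_down_up`, `rank`, `in_top_decile`.
#' @export
mimicry_scores <- function(fs, lib, mode = c("directional", "pooled"),
                           n_sig = 100L, decile = 0.1) {
  stopifnot(inherits(fs, "flip_set"), inherits(lib, "drug_profile_library"))
  mode <- match.arg(mode)
  keep <- lib$meta$quality & lib$meta$fda_approved
  if (!any(keep))
    stop("no profile passes the quality + FDA-approval filter")
  flip_all <- union(fs$up_down, fs$down_up)
  if (!length(intersect(flip_all, lib$gene_space)))
    stop("library gene space does not intersect the flip genes")
  meta <- lib$meta[keep, ]
  scores <- lib$scores[, meta$profile_id, drop = FALSE]
  stats_one <- function(v) {
    sig <- make_signature(setNames(v, rownames(scores)), n_sig)
    h_ud <- length(intersect(sig$down, fs$up_down))
    h_du <- length(intersect(sig$up, fs$down_up))
    j <- if (mode == "directional") {
      (h_ud + h_du) / length(union(flip_all, c(sig$up, sig$down)))
    } else {
      jaccard(flip_all, c(sig$up, sig$down))
    }
    c(j, h_ud, h_du)
  }
  st <- apply(scores, 2L, stats_one)
  res <- data.frame(profile_id = meta$profile_id, drug_id = meta$drug_id,
                    jaccard = st[1L, ], hits_up_down = as.integer(st[2L, ]),
                    hits_down_up = as.integer(st[3L, ]),
                    stringsAsFactors = FALSE)
  res$rank <- rank(-res$jaccard, ties.method = "min")
  n_top <- ceiling(decile * nrow(res))
  thr <- sort(res$jaccard, decreasing = TRUE)[n_top]
  res$in_top_decile <- res$jaccard >= thr
  res <- res[order(res$rank, res$profile_id), ]
  rownames(res) <- NULL
  attr(res, "mode") <- mode
  attr(res, "decile") <- decile
  attr(res, "n_sig") <- as.integer(n_sig)
  class(res) <- c("mimicry_result", "data.frame")
  res
}

#' @export
print.mimicry_result <- function(x, ...) {
  cat(sprintf("mimicry_result (%s mode): %d retained profiles, %d in top decile (%d drugs)\n",
              attr(x, "mode"), nrow(x), sum(x$in_top_decile),
              length(unique(x$drug_id[x$in_top_decile]))))
  print(head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Per-drug mimicry summary
#'
#' Collapses profiles to drugs: a drug is a mimic if any of its retained
#' profiles reaches the top decile. The two hit-count columns summarize
#' how strongly the drug moves each flip axis (the two axes of a
#' mimic-landscape plot).
#'
#' @param mim a [mimicry_scores()] result.
#' @return Data frame: `drug_id`, `best_jaccard`, `is_mimic`,
#'   `max_hits_up_down`, `max_hits_down_up`, `n_profiles`.
#' @export
mimic_drug_summary <- function(mim) {
  stopifnot(inherits(mim, "mimicry_result"))
  sp <- split(seq_len(nrow(mim)), mim$drug_id)
  out <- do.call(rbind, lapply(names(sp), function(d) {
    i <- sp[[d]]
    data.frame(drug_id = d, best_jaccard = max(mim$jaccard[i]),
               is_mimic = any(mim$in_top_decile[i]),
               max_hits_up_down = max(mim$hits_up_down[i]),
               max_hits_down_up = max(mim$hits_down_up[i]),
               n_profiles = length(i), stringsAsFactors = FALSE)
  }))
  out[order(-out$best_jaccard, out$drug_id), ]
}

#' Drug-target enrichment among mimicking drugs
#'
#' The target score of the screen: for each annotated target, the
#' enrichment factor of drug-target interactions among the mimic drugs
#' (those owning at least one top-decile profile) relative to all
#' screened drugs, with hypergeometric significance and a BH FDR across
#' targets. Targets with no annotation among the screened drugs are
#' skipped.
#'
#' @param mim a [mimicry_scores()] result.
#' @param targets a [read_drug_targets()] table (columns `drug_id`,
#'   `target_id`).
#' @return Object of class `target_score` (a data frame): `target_id`,
#'   `n_mimic_hits`, `n_total_hits`, `ef`, `p`, `fdr`.
#' @export
target_enrichment <- function(mim, targets) {
  stopifnot(inherits(mim, "mimicry_result"))
  screened <- unique(mim$drug_id)
  mimics <- unique(mim$drug_id[mim$in_top_decile])
  n <- length(mimics); N <- length(screened)
  if (n == 0L) stop("no mimic drug (empty top decile)")
  targets <- targets[targets$drug_id %in% screened, ]
  sp <- split(unique(targets[c("drug_id", "target_id")])$drug_id,
              unique(targets[c("drug_id", "target_id")])$target_id)
  rows <- lapply(names(sp), function(t) {
    K <- length(sp[[t]])
    k <- length(intersect(sp[[t]], mimics))
    data.frame(target_id = t, n_mimic_hits = k, n_total_hits = K,
               ef = (k / n) / (K / N), p = hypergeom_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) stop("no target annotated to any screened drug")
  res <- do.call(rbind, rows)
  res$fdr <- bh_adjust(res$p)
  res <- res[order(res$p, -res$ef, res$target_id), ]
  rownames(res) <- NULL
  attr(res, "n_mimic") <- n
  attr(res, "n_screened") <- N
  class(res) <- c("target_score", "data.frame")
  res
}

#' @export
print.target_score <- function(x, ...) {
  cat(sprintf("target_score: %d targets over %d screened drugs (%d mimics)\n",
              nrow(x), attr(x, "n_screened"), attr(x, "n_mimic")))
  print(head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
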