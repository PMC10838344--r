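#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing
#' at least `k` marked items when `n` items are drawn without
#' replacement from a universe of `N` items of which `K` are marked.
#' Evaluated through the stable log-space tail of [stats::phyper()].
#'
#' @param k observed overlap (>= 0).
#' @param K size of the first set within the universe.
#' @param n size of the second set (number of draws).
#' @param N universe size.
#' @return Tail probability in `[0, 1]`. Vectorized over all arguments.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | N < 0 | K > N | n > N | k > pmin(K, n)
  if (any(bad))
    stop("inconsistent hypergeometric counts: need 0 <= k <= min(K, n) <= N")
  exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Enrichment-factor pathway scoring of a flip gene list
#'
#' For each pathway the observed overlap with the flip list is compared
#' with the overlap expected under random draws from the universe:
#' `ef = observed / expected` with
#' `expected = |pathway| * |flip| / |universe|`. Significance is the
#' hypergeometric upper tail, corrected across pathways by
#' Benjamini-Hochberg. Pathways are restricted to the universe before
#' scoring; the universe should normally be the genes actually tested in
#' the differential-expression step.
#'
#' @param flip_genes character vector, a subset of `universe`.
#' @param sets a [gene_set_collection()].
#' @param universe character vector of background genes.
#' @return Object of class `pathway_enrichment` (a data frame): columns
#'   `pathway`, `size`, `overlap`, `expected`, `ef`, `p`, `fdr`.
#' @export
enrich_pathways <- function(flip_genes, sets, universe) {
  stopifnot(inherits(sets, "gene_set_collection"))
  flip_genes <- unique(flip_genes)
  universe <- unique(universe)
  outside <- setdiff(flip_genes, universe)
  if (length(outside))
    stop("flip gene(s) absent from the universe: ",
         toString(head(outside, 5L)))
  N <- length(universe)
  n <- length(flip_genes)
  rows <- lapply(names(sets$sets), function(id) {
    members <- intersect(sets$sets[[id]], universe)
    K <- length(members)
    k <- length(intersect(members, flip_genes))
    expected <- K * n / N
    data.frame(pathway = id, size = K, overlap = k, expected = expected,
               ef = if (expected > 0) k / expected else 0,
               p = if (K > 0) hypergeom_tail(k, K, n, N) else 1,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- bh_adjust(res$p)
  class(res) <- c("pathway_enrichment", "data.frame")
  res
}

#' @export
print.pathway_enrichment <- function(x, ...) {
  cat("pathway_enrichment:", nrow(x), "pathways,",
      sum(x$fdr < 0.05, na.rm = TRUE), "at FDR < 0.05\n")
  ord <- order(x$p, -x$ef)
  print(head(as.data.frame(x)[ord, ]), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Build the pathway overlap network
#'
#' Nodes are the pathways significantly enriched for flip genes
#' (`fdr < alpha`). Two pathways are connected when their flip-gene
#' memberships overlap more than expected by chance inside the flip set
#' (hypergeometric `p < edge_alpha`) and their flip-restricted Jaccard
#' similarity reaches `min_jaccard` (floor against hairball networks).
#'
#' @param enr an [enrich_pathways()] result.
#' @param sets the scored [gene_set_collection()].
#' @param flip_genes the flip gene list used for `enr`.
#' @param alpha node-inclusion FDR threshold.
#' @param min_jaccard Jaccard floor for edges.
#' @param edge_alpha significance threshold for the edge overlap test.
#' @param flip_class optional label stored on every node (e.g. which
#'   flip class was scored).
#' @return A [pathway_network()].
#' @export
build_network <- function(enr, sets, flip_genes, alpha = 0.05,
                          min_jaccard = 0.1, edge_alpha = 0.05,
                          flip_class = "") {
  stopifnot(inherits(enr, "pathway_enrichment"))
  missing_sets <- setdiff(enr$pathway, names(sets$sets))
  if (length(missing_sets))
    stop("enrichment rows not present in the collection: ",
         toString(head(missing_sets, 5L)))
  keep <- !is.na(enr$fdr) & enr$fdr < alpha
  nodes <- as.data.frame(enr)[keep, c("pathway", "overlap", "ef", "p", "fdr")]
  nodes$cluster <- NA_real_
  nodes$flip_class <- flip_class
  rownames(nodes) <- NULL
  flip_genes <- unique(flip_genes)
  memb <- lapply(setNames(nodes$pathway, nodes$pathway),
                 function(id) intersect(sets$sets[[id]], flip_genes))
  edges <- data.frame(from = character(), to = character(),
                      shared_genes = integer(), jaccard = numeric(),
                      p = numeric(), stringsAsFactors = FALSE)
  n_nodes <- nrow(nodes)
  if (n_nodes >= 2L) {
    pairs <- utils::combn(nodes$pathway, 2L)
    rows <- lapply(seq_len(ncol(pairs)), function(i) {
      a <- memb[[pairs[1L, i]]]; b <- memb[[pairs[2L, i]]]
      k <- length(intersect(a, b))
      jac <- jaccard(a, b)
      p <- hypergeom_tail(k, length(a), length(b), length(flip_genes))
      if (p < edge_alpha && jac >= min_jaccard)
        data.frame(from = pairs[1L, i], to = pairs[2L, i],
                   shared_genes = k, jaccard = jac, p = p,
                   stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows)) edges <- do.call(rbind, rows)
  }
  pathway_network(nodes, edges)
}

#' Group network pathways by K-means on flip-gene incidence
#'
#' Each node pathway becomes a row of the binary pathway x flip-gene
#' incidence matrix, L2-normalized; rows are clustered by K-means. When
#' `k = "auto"` the cluster count maximizing the mean silhouette width
#' over `k in 2..min(10, nodes - 1)` is used; if the silhouette
#' degenerates (e.g. identical rows), a single cluster is returned.
#' Labels are deterministic for a fixed `seed`.
#'
#' @param net a [pathway_network()].
#' @param sets the underlying [gene_set_collection()].
#' @param flip_genes flip gene list defining the incidence columns.
#' @param k integer cluster count, or `"auto"`.
#' @param seed integer seed for the K-means starts.
#' @return The network with `nodes$cluster` filled in (integer labels).
#' @export
cluster_pathways <- function(net, sets, flip_genes, k = "auto", seed = 1L) {
  stopifnot(inherits(net, "pathway_network"))
  n_nodes <- nrow(net$nodes)
  if (n_nodes == 0L) return(net)
  flip_genes <- sort(unique(flip_genes))
  inc <- t(vapply(net$nodes$pathway, function(id) {
    as.numeric(flip_genes %in% sets$sets[[id]])
  }, numeric(length(flip_genes))))
  nrm <- sqrt(rowSums(inc^2))
  inc <- inc / ifelse(nrm > 0, nrm, 1)
  if (!identical(k, "auto") && k > n_nodes)
    stop("k exceeds the number of network nodes")
  labels <- rep(1L, n_nodes)
  distinct <- nrow(unique(inc))
  if (identical(k, "auto")) {
    ks <- if (n_nodes >= 3L) seq(2L, min(10L, n_nodes - 1L)) else integer(0)
    ks <- ks[ks <= distinct]
    best_k <- 1L; best_sil <- -Inf
    d <- dist(inc)
    for (kk in ks) {
      set.seed(seed)
      cl <- kmeans(inc, centers = kk, nstart = 10L)$cluster
      if (length(unique(cl)) < 2L) next
      sil <- mean(cluster::silhouette(cl, d)[, "sil_width"])
      if (is.finite(sil) && sil > best_sil) { best_sil <- sil; best_k <- kk }
    }
    if (best_k > 1L) {
      set.seed(seed)
      labels <- kmeans(inc, centers = best_k, nstart = 10L)$cluster
    }
  } else if (k > 1L) {
    if (k > distinct)
      stop("k exceeds the number of distinct incidence rows")
    set.seed(seed)
    labels <- kmeans(inc, centers = k, nstart = 10L)$cluster
  }
  net$nodes$cluster <- as.numeric(labels)
  net
}
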