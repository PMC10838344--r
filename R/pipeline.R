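#' Run the full flip mode-of-action pipeline
#'
#' Convenience driver chaining every stage: both contrasts against the
#' control, flip classification, per-class pathway enrichment with
#' overlap networks and K-means grouping, regulon enrichment on the flip
#' ranking, and - when a drug library is supplied - the mimicry screen
#' with target enrichment.
#'
#' @param cm a [count_matrix()] with all three conditions.
#' @param pathways,regulons optional [gene_set_collection()]s.
#' @param library,targets optional [drug_profile_library()] and
#'   drug-target table.
#' @param rule_perturbed,rule_drug the two [deg_rule()]s; the defaults
#'   pair a strict FDR rule for the perturbation with a raw-p
#'   fold-change-1.5 rule for the drug contrast.
#' @param n_perm,seed permutation settings for the regulon stage (the
#'   seed also fixes the K-means starts).
#' @param n_sig,mimicry_mode drug-screen settings, see
#'   [mimicry_scores()].
#' @param alpha node-inclusion FDR for the pathway networks.
#' @return Object of class `flip_moa`: a list with elements
#'   `de_perturbed`, `de_drug`, `flip`, `pathway_enrichment` (per flip
#'   class), `networks` (per flip class), `tf`, `mimicry`,
#'   `target_scores` (the optional stages are `NULL` when their inputs
#'   are absent).
#' @export
flip_moa <- function(cm, pathways = NULL, regulons = NULL, library = NULL,
                     targets = NULL,
                     rule_perturbed = deg_rule(1.5, 0.05, "fdr"),
                     rule_drug = deg_rule(log2(1.5), 0.05, "raw_p"),
                     n_perm = 1000L, seed = 1L, n_sig = 100L,
                     mimicry_mode = "directional", alpha = 0.05) {
  de_p <- nb_wald_contrast(cm, "control", "perturbed")
  de_d <- nb_wald_contrast(cm, "control", "perturbed_drug")
  fs <- classify_flip(de_p, de_d, rule_perturbed, rule_drug)
  universe <- de_p$gene[!is.na(de_p$p)]
  out <- list(de_perturbed = de_p, de_drug = de_d, flip = fs,
              pathway_enrichment = NULL, networks = NULL, tf = NULL,
              mimicry = NULL, target_scores = NULL)
  if (!is.null(pathways)) {
    out$pathway_enrichment <- list()
    out$networks <- list()
    for (cls in c("up_down", "down_up")) {
      flip_genes <- intersect(fs[[cls]], universe)
      enr <- enrich_pathways(flip_genes, pathways, universe)
      net <- build_network(enr, pathways, flip_genes, alpha = alpha)
      net <- cluster_pathways(net, pathways, flip_genes, seed = seed)
      out$pathway_enrichment[[cls]] <- enr
      out$networks[[cls]] <- net
    }
  }
  if (!is.null(regulons)) {
    out$tf <- tf_enrichment(flip_score(de_p, de_d), regulons,
                            n_perm = n_perm, seed = seed)
  }
  if (!is.null(library)) {
    out$mimicry <- mimicry_scores(fs, library, mode = mimicry_mode,
                                  n_sig = n_sig)
    if (!is.null(targets))
      out$target_scores <- target_enrichment(out$mimicry, targets)
  }
  class(out) <- "flip_moa"
  out
}

#' @export
print.flip_moa <- function(x, ...) {
  cat("flip_moa pipeline result\n========================\n")
  print(x$flip)
  if (!is.null(x$pathway_enrichment)) {
    for (cls in names(x$pathway_enrichment)) {
      enr <- x$pathway_enrichment[[cls]]
      cat(sprintf("pathways (%s): %d scored, %d at FDR < 0.05; network %d nodes / %d edges\n",
                  cls, nrow(enr), sum(enr$fdr < 0.05, na.rm = TRUE),
                  nrow(x$networks[[cls]]$nodes),
                  nrow(x$networks[[cls]]$edges)))
    }
  }
  if (!is.null(x$tf))
    cat(sprintf("TF regulons: %d scored, top NES %s (%.2f)\n",
                nrow(x$tf), x$tf$tf[1L], x$tf$nes[1L]))
  if (!is.null(x$mimicry))
    cat(sprintf("drug screen: %d profiles retained, %d mimic drugs\n",
                nrow(x$mimicry),
                length(unique(x$mimicry$drug_id[x$mimicry$in_top_decile]))))
  if (!is.null(x$target_scores))
    cat(sprintf("top target: %s (EF %.2f, p %.2e)\n",
                x$target_scores$target_id[1L], x$target_scores$ef[1L],
                x$target_scores$p[1L]))
  invisible(x)
}
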