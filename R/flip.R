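#' Classify flip genes across the perturbation and drug contrasts
#'
#' The central signature of the pipeline. Both contrasts must be tested
#' against the same reference (control) over the same gene universe. A
#' gene is a `up_down` flip if it is called up by the perturbation rule
#' in the perturbation contrast and down by the drug rule in the drug
#' contrast; `down_up` is the mirror class. Perturbation DEGs that do
#' not flip are kept as `perturbed_only_up` / `perturbed_only_down`, so
#' that each perturbation DEG class is exactly partitioned.
#'
#' Flip membership requires the gene to pass the drug-contrast rule, not
#' merely to change sign; no reversion-magnitude requirement is imposed
#' beyond that rule.
#'
#' @param de_perturbed,de_drug [nb_wald_contrast()] results for the
#'   perturbed-vs-control and perturbed+drug-vs-control contrasts.
#' @param rule_perturbed,rule_drug the [deg_rule()]s for the two
#'   contrasts.
#' @return Object of class `flip_set`: lists `up_down`, `down_up`,
#'   `perturbed_only_up`, `perturbed_only_down` (sorted gene ids), the
#'   per-gene `log2fc` of both contrasts, and the two rules as
#'   `provenance`.
#' @export
classify_flip <- function(de_perturbed, de_drug, rule_perturbed, rule_drug) {
  stopifnot(inherits(de_perturbed, "de_result"),
            inherits(de_drug, "de_result"))
  u1 <- sort(de_perturbed$gene); u2 <- sort(de_drug$gene)
  if (!identical(u1, u2)) {
    sym <- length(union(setdiff(u1, u2), setdiff(u2, u1)))
    stop("gene universes differ between the two contrasts (symmetric difference: ",
         sym, " genes)")
  }
  calls_p <- call_degs(de_perturbed, rule_perturbed)
  calls_d <- call_degs(de_drug, rule_drug)
  up_p <- names(calls_p)[calls_p == "up"]
  down_p <- names(calls_p)[calls_p == "down"]
  up_d <- names(calls_d)[calls_d == "up"]
  down_d <- names(calls_d)[calls_d == "down"]
  up_down <- sort(intersect(up_p, down_d))
  down_up <- sort(intersect(down_p, up_d))
  structure(list(
    up_down = up_down,
    down_up = down_up,
    perturbed_only_up = sort(setdiff(up_p, up_down)),
    perturbed_only_down = sort(setdiff(down_p, down_up)),
    log2fc_perturbed = setNames(de_perturbed$log2fc, de_perturbed$gene),
    log2fc_drug = setNames(de_drug$log2fc, de_drug$gene),
    provenance = list(rule_perturbed = rule_perturbed,
                      rule_drug = rule_drug)),
    class = "flip_set")
}

#' @export
print.flip_set <- function(x, ...) {
  n_up <- length(x$up_down) + length(x$perturbed_only_up)
  n_down <- length(x$down_up) + length(x$perturbed_only_down)
  cat("flip_set:\n")
  cat(sprintf("  up_down : %d of %d perturbation-up DEGs flipped%s\n",
              length(x$up_down), n_up,
              if (n_up) sprintf(" (%d%%)", round(100 * length(x$up_down) / n_up)) else ""))
  cat(sprintf("  down_up : %d of %d perturbation-down DEGs flipped%s\n",
              length(x$down_up), n_down,
              if (n_down) sprintf(" (%d%%)", round(100 * length(x$down_up) / n_down)) else ""))
  invisible(x)
}

#' @export
summary.flip_set <- function(object, ...) {
  print(object)
  invisible(data.frame(
    class = c("up_down", "down_up", "perturbed_only_up", "perturbed_only_down"),
    n = c(length(object$up_down), length(object$down_up),
          length(object$perturbed_only_up), length(object$perturbed_only_down))))
}

#' Fraction of perturbation DEGs flipped by the drug
#'
#' `100 * |flip class| / |all perturbation DEGs of that sign|`, reported
#' both at full precision and rounded to the nearest integer percent.
#' The generic also accepts raw counts (`flip_fraction(82, 682)`).
#'
#' @param x a `flip_set`, or the flipped-gene count.
#' @param ... passed to methods.
#' @return List with elements `percent` (full precision) and
#'   `percent_int` (nearest integer).
#' @export
flip_fraction <- function(x, ...) UseMethod("flip_fraction")

#' @rdname flip_fraction
#' @param direction `"up_down"` or `"down_up"`.
#' @export
flip_fraction.flip_set <- function(x, direction = c("up_down", "down_up"),
                                   ...) {
  direction <- match.arg(direction)
  n_flip <- length(x[[direction]])
  n_total <- n_flip + length(
    x[[if (direction == "up_down") "perturbed_only_up" else "perturbed_only_down"]])
  flip_fraction(n_flip, n_total)
}

#' @rdname flip_fraction
#' @param n_total total DEG count of the corresponding sign (the
#'   denominator); must be positive.
#' @export
flip_fraction.numeric <- function(x, n_total, ...) {
  stopifnot(length(x) == 1L, length(n_total) == 1L, x >= 0)
  if (n_total <= 0) stop("empty denominator: no DEGs of this sign")
  pct <- 100 * x / n_total
  list(percent = pct, percent_int = round(pct))
}

#' Per-gene flip score
#'
#' A signed ranking metric for downstream regulon enrichment:
#' `-sign(log2fc_perturbed) * log2fc_drug` when the two contrasts
#' disagree in sign (a true reversal scores positive), `0` when the
#' signs are concordant or either fold change is zero.
#'
#' @param de_perturbed,de_drug the two contrasts (shared gene universe).
#' @return Named numeric vector over the common gene universe.
#' @export
flip_score <- function(de_perturbed, de_drug) {
  stopifnot(identical(sort(de_perturbed$gene), sort(de_drug$gene)))
  l1 <- setNames(de_perturbed$log2fc, de_perturbed$gene)
  l2 <- setNames(de_drug$log2fc, de_drug$gene)[names(l1)]
  score <- ifelse(l1 * l2 < 0, -sign(l1) * l2, 0)
  setNames(score, names(l1))
}

#' Write a flip table as TSV
#'
#' One row per classified gene: class, both log2 fold changes, and the
#' flip score.
#'
#' @param fs a `flip_set`.
#' @param path output file.
#' @return Invisibly, the written data frame.
#' @export
write_flip_table <- function(fs, path) {
  stopifnot(inherits(fs, "flip_set"))
  cls <- c(setNames(rep("up_down", length(fs$up_down)), fs$up_down),
           setNames(rep("down_up", length(fs$down_up)), fs$down_up),
           setNames(rep("perturbed_only_up", length(fs$perturbed_only_up)),
                    fs$perturbed_only_up),
           setNames(rep("perturbed_only_down", length(fs$perturbed_only_down)),
                    fs$perturbed_only_down))
  genes <- names(cls)
  l1 <- fs$log2fc_perturbed[genes]
  l2 <- fs$log2fc_drug[genes]
  df <- data.frame(gene = genes, class = unname(cls),
                   log2fc_perturbed = unname(l1), log2fc_drug = unname(l2),
                   flip_score = unname(ifelse(l1 * l2 < 0, -sign(l1) * l2, 0)))
  df <- df[order(df$gene), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
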