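#' Median-of-ratios size factors
#'
#' Per-sample scaling constants making counts comparable across
#' sequencing depths: each gene's geometric mean over samples forms a
#' pseudo-reference, and a sample's factor is the median over genes of
#' the ratio of its count to that reference. Genes with any zero count
#' are excluded from the reference by default.
#'
#' @param cm a [count_matrix()] (or a bare counts matrix).
#' @param pseudo_reference if no gene is expressed in every sample, fall
#'   back to geometric means computed over positive counts only.
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(cm, pseudo_reference = FALSE) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  lc <- log(counts)
  if (pseudo_reference) {
    lc[!is.finite(lc)] <- NA
    log_geo <- rowMeans(lc, na.rm = TRUE)
    use <- is.finite(log_geo)
  } else {
    log_geo <- rowMeans(lc)
    use <- is.finite(log_geo)
    if (!any(use))
      stop("no gene has a nonzero count in every sample; ",
           "re-run with pseudo_reference = TRUE")
  }
  sf <- apply(counts, 2, function(col) {
    median(col[use] / exp(log_geo[use]))
  })
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate size factor for sample ",
         names(sf)[!is.finite(sf) | sf <= 0][1L])
  sf
}

#' Benjamini-Hochberg adjustment with missing markers
#'
#' Standard step-up BH, monotone in ranks and capped at 1. Missing
#' values (genes excluded from testing) are removed from the family
#' before adjustment and reinserted as missing afterwards, so they never
#' influence the correction.
#'
#' @param p numeric vector of p-values in `[0, 1]`, `NA` allowed.
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  names(out) <- names(p)
  out
}

#' Define a DEG-calling rule
#'
#' A rule is a log2 fold-change threshold plus a significance cutoff
#' applied either to the BH-adjusted FDR or to the raw p-value. Both
#' inequalities are strict. Typical rules for a strong perturbation and
#' a milder drug response are
#' `deg_rule(1.5, 0.05, "fdr")` and `deg_rule(log2(1.5), 0.05, "raw_p")`
#' (the latter's threshold is a fold change of 1.5 on the natural scale).
#'
#' @param lfc_threshold non-negative threshold on the log2 scale.
#' @param alpha significance level in (0, 1).
#' @param alpha_on `"fdr"` or `"raw_p"`.
#' @return Object of class `deg_rule`.
#' @export
deg_rule <- function(lfc_threshold, alpha = 0.05,
                     alpha_on = c("fdr", "raw_p")) {
  alpha_on <- match.arg(alpha_on)
  stopifnot(lfc_threshold >= 0, alpha > 0, alpha < 1)
  structure(list(lfc_threshold = lfc_threshold, alpha = alpha,
                 alpha_on = alpha_on),
            class = "deg_rule")
}

#' @export
print.deg_rule <- function(x, ...) {
  cat(sprintf("deg_rule: |log2FC| > %g and %s < %g\n", x$lfc_threshold,
              if (x$alpha_on == "fdr") "FDR" else "p", x$alpha))
  invisible(x)
}

# Pooled method-of-moments dispersion per gene, optionally shrunk toward
# a fitted 1/mu trend. MoM at 2-3 replicates per group is extremely
# noisy (chi-square with ~4 df in the Wald denominator), which makes a
# normal-reference Wald test anti-conservative; empirical shrinkage with
# a moderate prior df restores calibration while leaving strong
# mean-dispersion structure intact.
estimate_dispersions <- function(m1, v1, m2, v2, n1, n2, tested,
                                 floor = 1e-8, shrink = TRUE,
                                 prior_df = 20) {
  denom <- m1^2 + m2^2
  a_raw <- ifelse(denom > 0, ((v1 - m1) + (v2 - m2)) / denom, floor)
  a_raw <- pmax(a_raw, floor)
  if (!shrink || sum(tested) < 10L) return(a_raw)
  df_gene <- n1 + n2 - 2L
  bm <- (m1 + m2) / 2
  fit <- tryCatch(lm(a_raw[tested] ~ I(1 / bm[tested])), error = function(e) NULL)
  if (is.null(fit)) return(a_raw)
  a_trend <- pmax(coef(fit)[1L] + coef(fit)[2L] / bm, floor)
  pmax((df_gene * a_raw + prior_df * a_trend) / (df_gene + prior_df), floor)
}

#' Negative-binomial Wald contrast between two conditions
#'
#' A transparent NB differential-expression test: counts are normalized
#' by median-of-ratios size factors (computed on all samples of `cm`);
#' per-gene dispersion is estimated by pooled method-of-moments across
#' the two groups and shrunk toward a fitted mean-dispersion trend; the
#' log2 fold change uses group means with a pseudocount; its standard
#' error comes from the delta method under the NB variance
#' `mu + alpha * mu^2`; and a two-sided normal Wald p-value is corrected
#' across genes by Benjamini-Hochberg. Genes below the
#' independent-expression filter (`base_mean < min_base_mean`) are
#' excluded from testing and from the BH family and carry `NA` p/FDR.
#'
#' This is a deliberately simple, fully documented pipeline, not a clone
#' of shrinkage-heavy DE packages; lists computed on real data will
#' differ in detail from those tools.
#'
#' @param cm a [count_matrix()] containing both conditions (>= 2 samples
#'   each).
#' @param ref,alt condition labels; `log2fc` is `alt` versus `ref`.
#' @param lfc_pseudocount added to both group means before the log ratio
#'   (bounds the fold change when one group is all zero).
#' @param min_base_mean independent-filter threshold on the mean
#'   normalized count.
#' @param dispersion_floor lower bound for the dispersion estimate.
#' @param shrink_dispersion shrink per-gene dispersion toward the fitted
#'   1/mu trend (recommended; raw method-of-moments at 3 replicates makes
#'   the Wald test anti-conservative).
#' @param prior_df weight of the trend in the shrunk estimate.
#' @param pseudo_reference passed to [size_factors()].
#' @return Object of class `de_result` (a data frame): columns `gene`,
#'   `base_mean`, `log2fc`, `se`, `p`, `fdr`; attributes `ref`, `alt`.
#' @export
nb_wald_contrast <- function(cm, ref, alt, lfc_pseudocount = 0.5,
                             min_base_mean = 1, dispersion_floor = 1e-8,
                             shrink_dispersion = TRUE, prior_df = 20,
                             pseudo_reference = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  for (cond in c(ref, alt))
    if (!cond %in% cm$condition)
      stop("condition '", cond, "' absent from the count matrix")
  s_ref <- condition_samples(cm, ref)
  s_alt <- condition_samples(cm, alt)
  sf <- size_factors(cm, pseudo_reference = pseudo_reference)
  norm <- sweep(cm$counts, 2, sf, "/")
  x1 <- norm[, s_ref, drop = FALSE]
  x2 <- norm[, s_alt, drop = FALSE]
  n1 <- length(s_ref); n2 <- length(s_alt)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, var); v2 <- apply(x2, 1, var)
  base_mean <- (m1 + m2) / 2
  tested <- base_mean >= min_base_mean
  alpha <- estimate_dispersions(m1, v1, m2, v2, n1, n2, tested,
                                floor = dispersion_floor,
                                shrink = shrink_dispersion,
                                prior_df = prior_df)
  pc <- lfc_pseudocount
  log2fc <- log2((m2 + pc) / (m1 + pc))
  var1 <- (m1 + alpha * m1^2) / n1
  var2 <- (m2 + alpha * m2^2) / n2
  se <- sqrt(var1 / (m1 + pc)^2 + var2 / (m2 + pc)^2) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * pnorm(-abs(z))
  p[!tested] <- NA_real_
  fdr <- bh_adjust(p)
  res <- data.frame(gene = cm$gene_ids, base_mean = base_mean,
                    log2fc = log2fc, se = se, p = p, fdr = fdr,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "ref") <- ref
  attr(res, "alt") <- alt
  class(res) <- c("de_result", "data.frame")
  res
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result: %s vs %s (reference), %d genes (%d tested)\n",
              attr(x, "alt"), attr(x, "ref"), nrow(x), sum(!is.na(x$p))))
  print(head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' @export
summary.de_result <- function(object, rule = deg_rule(1, 0.05, "fdr"), ...) {
  calls <- call_degs(object, rule)
  cat(sprintf("contrast %s vs %s: %d up, %d down under ",
              attr(object, "alt"), attr(object, "ref"),
              sum(calls == "up"), sum(calls == "down")))
  print(rule)
  invisible(calls)
}

#' Call differentially expressed genes under a rule
#'
#' A gene is called up if `log2fc > lfc_threshold` and its significance
#' value (FDR or raw p per the rule) is below `alpha`; down is the
#' mirror. Inequalities are strict; untested genes (missing p) are never
#' called.
#'
#' @param de a [nb_wald_contrast()] result.
#' @param rule a [deg_rule()].
#' @return Named character vector over the called genes only, values
#'   `"up"` or `"down"`.
#' @export
call_degs <- function(de, rule) {
  stopifnot(inherits(de, "de_result"), inherits(rule, "deg_rule"))
  sig_val <- if (rule$alpha_on == "fdr") de$fdr else de$p
  sig <- !is.na(sig_val) & sig_val < rule$alpha
  up <- sig & de$log2fc > rule$lfc_threshold
  down <- sig & de$log2fc < -rule$lfc_threshold
  out <- c(setNames(rep("up", sum(up)), de$gene[up]),
           setNames(rep("down", sum(down)), de$gene[down]))
  out[order(names(out))]
}

#' Write a differential-expression table as TSV
#'
#' @param de a `de_result`.
#' @param path output file.
#' @return Invisibly, `de`.
#' @export
write_de_result <- function(de, path) {
  write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(de)
}
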