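# Shared fixture builders: everything is generated in code at test time.

# 3-gene x 6-sample toy experiment, 2 samples per condition
tiny_counts <- function() {
  m <- matrix(c(10L, 12L, 30L, 28L, 5L, 6L,
                100L, 90L, 80L, 85L, 70L, 75L,
                0L, 1L, 2L, 0L, 3L, 1L),
              nrow = 3L, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"),
                              c("c1", "c2", "p1", "p2", "d1", "d2")))
  cond <- setNames(rep(c("control", "perturbed", "perturbed_drug"), each = 2L),
                   colnames(m))
  list(counts = m, condition = cond)
}

write_tiny_tsv <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  tc <- tiny_counts()
  counts_path <- file.path(dir, "counts.tsv")
  cond_path <- file.path(dir, "conditions.tsv")
  df <- data.frame(gene_id = rownames(tc$counts), tc$counts,
                   check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(names(tc$condition), unname(tc$condition)),
              cond_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  list(counts = counts_path, conditions = cond_path, dir = dir)
}

# fabricate a de_result with prescribed statistics
make_de <- function(genes, log2fc, p, fdr = bh_adjust(p),
                    base_mean = rep(100, length(genes)),
                    ref = "control", alt = "perturbed") {
  res <- data.frame(gene = genes, base_mean = base_mean, log2fc = log2fc,
                    se = rep(1, length(genes)), p = p, fdr = fdr,
                    stringsAsFactors = FALSE)
  attr(res, "ref") <- ref
  attr(res, "alt") <- alt
  class(res) <- c("de_result", "data.frame")
  res
}

# fabricate a flip_set directly from gene lists (e.g. simulator ground truth)
make_flip_set <- function(up_down, down_up, only_up = character(),
                          only_down = character()) {
  genes <- c(up_down, down_up, only_up, only_down)
  l1 <- setNames(c(rep(3, length(up_down)), rep(-3, length(down_up)),
                   rep(3, length(only_up)), rep(-3, length(only_down))), genes)
  l2 <- setNames(c(rep(-1.5, length(up_down)), rep(1.5, length(down_up)),
                   rep(3, length(only_up)), rep(-3, length(only_down))), genes)
  structure(list(up_down = sort(up_down), down_up = sort(down_up),
                 perturbed_only_up = sort(only_up),
                 perturbed_only_down = sort(only_down),
                 log2fc_perturbed = l1, log2fc_drug = l2,
                 provenance = list(rule_perturbed = deg_rule(1.5),
                                   rule_drug = deg_rule(log2(1.5), alpha_on = "raw_p"))),
            class = "flip_set")
}

# small simulation config for fast unit tests
small_cfg <- function(seed = 11L, ...) {
  sim_config(n_genes = 400L, n_up_down = 20L, n_down_up = 30L,
             n_perturbed_only_up = 25L, n_perturbed_only_down = 25L,
             n_pathways = 40L, n_regulons = 15L, n_drugs = 40L,
             n_planted_mimics = 4L, n_sig = 20L, n_targets = 10L,
             planted_pathway_size = 20L,
             pathway_size_range = c(8L, 20L), seed = seed, ...)
}

# brute-force BH step-up: adj_i = min over j >= i (by sorted order) of m*p_(j)/j
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(ord == i)  # rank of p[i]
    js <- seq(r, m)
    adj[i] <- min(1, min(m * p[ord[js]] / js))
  }
  adj
}

# exhaustive hypergeometric upper tail by direct combinatorial sums
hyper_tail_brute <- function(k, K, n, N) {
  xs <- seq(k, min(K, n))
  if (!length(xs)) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}
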