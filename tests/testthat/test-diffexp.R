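test_that("size factors reproduce pure depth scaling and the identity case", {
  v <- c(10L, 50L, 200L, 5L)
  m <- cbind(v, 2L * v, 4L * v)
  dimnames(m) <- list(paste0("g", 1:4), paste0("s", 1:3))
  sf <- size_factors(m)
  expect_equal(unname(sf / sf[1L]), c(1, 2, 4), tolerance = 1e-12)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)

  m2 <- cbind(v, v, v); dimnames(m2) <- dimnames(m)
  expect_equal(unname(size_factors(m2)), c(1, 1, 1), tolerance = 1e-12)
})

test_that("size factors match an independently coded median-of-ratios", {
  set.seed(9)
  m <- matrix(rnbinom(300, mu = 60, size = 5), 50, 6,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  # brute force: per-gene geometric mean over samples, then column medians
  geo <- apply(m, 1, function(x) prod(x)^(1 / length(x)))
  keep <- geo > 0
  expected <- apply(m, 2, function(col) median(col[keep] / geo[keep]))
  expect_equal(size_factors(m), expected, tolerance = 1e-12)
})

test_that("all-zero reference genes trigger the pseudo-reference fallback path", {
  m <- matrix(c(0L, 5L,
                4L, 0L,
                8L, 0L,
                0L, 3L), 4, 2, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  expect_error(size_factors(m), "pseudo_reference")
  sf <- size_factors(m, pseudo_reference = TRUE)
  expect_true(all(sf > 0))
})

test_that("BH adjustment matches the hand-computed step-up and handles markers", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_equal(bh_adjust(0.3), 0.3)
  p <- c(0.01, NA, 0.04, 0.5)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2L]))
  expect_equal(adj[-2L], bh_brute(p[-2L]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH equals the brute-force definition on random vectors", {
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1L))
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
})

nb_cm <- function(n_genes = 200L, n = 4L, seed = 3L, mu = NULL) {
  set.seed(seed)
  if (is.null(mu)) mu <- exp(rnorm(n_genes, 4, 1))
  counts <- matrix(rnbinom(n_genes * 3L * n, mu = mu, size = 10),
                   n_genes, 3L * n)
  dimnames(counts) <- list(sprintf("g%03d", seq_len(n_genes)),
                           sprintf("s%02d", seq_len(3L * n)))
  cond <- setNames(rep(CONDITION_LEVELS, each = n), colnames(counts))
  count_matrix(counts, cond)
}

test_that("a gene with identical counts in both groups gets log2fc 0 and p 1", {
  tc <- tiny_counts()
  m <- tc$counts
  m["gA", ] <- c(7L, 9L, 7L, 9L, 1L, 2L)  # control == perturbed columns
  cm <- count_matrix(m, tc$condition)
  cm$counts[, 1:4] <- cm$counts[, c(1, 2, 1, 2)]  # force identical normalized groups
  # use unit size factors by making columns identical in totals
  de <- nb_wald_contrast(count_matrix(matrix(c(5L, 5L, 5L, 5L, 5L, 5L,
                                               9L, 9L, 9L, 9L, 9L, 9L,
                                               2L, 4L, 2L, 4L, 1L, 1L),
                                             3, 6, byrow = TRUE,
                                             dimnames = dimnames(m)),
                                      tc$condition),
                         "control", "perturbed")
  expect_equal(de$log2fc, rep(0, 3L))
  expect_equal(de$p, rep(1, 3L))
})

test_that("near-Poisson two-group means 10 vs 40 approach log2fc = 2", {
  set.seed(21)
  n <- 120L
  # one shifted gene against a large unchanged background, so the
  # size-factor normalization stays neutral
  counts <- rbind(c(rpois(n, 10), rpois(n, 40)),
                  matrix(rpois(60L * 2L * n, 300), 60L))
  dimnames(counts) <- list(sprintf("g%02d", 1:61),
                           sprintf("s%03d", seq_len(2L * n)))
  cond <- setNames(rep(c("control", "perturbed"), each = n), colnames(counts))
  de <- nb_wald_contrast(count_matrix(counts, cond), "control", "perturbed")
  expect_equal(de$log2fc[1L], 2, tolerance = 0.1)
  expect_lt(de$p[1L], 1e-6)
})

test_that("swapping ref and alt negates log2fc exactly and preserves p", {
  cm <- nb_cm()
  a <- nb_wald_contrast(cm, "control", "perturbed")
  b <- nb_wald_contrast(cm, "perturbed", "control")
  expect_equal(b$log2fc, -a$log2fc, tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-12)
})

test_that("permuting sample order changes nothing", {
  cm <- nb_cm()
  set.seed(1)
  perm <- sample(ncol(cm$counts))
  cm2 <- count_matrix(cm$counts[, perm], cm$condition[perm])
  a <- nb_wald_contrast(cm, "control", "perturbed_drug")
  b <- nb_wald_contrast(cm2, "control", "perturbed_drug")
  expect_equal(b, a, tolerance = 1e-12)
})

test_that("missing contrast conditions and filtered genes are handled", {
  cm <- nb_cm()
  expect_error(nb_wald_contrast(cm, "control", "treated"), "absent")
  cm$counts[1L, ] <- 0L
  de <- nb_wald_contrast(count_matrix(cm$counts, cm$condition),
                         "control", "perturbed")
  expect_true(is.na(de$p[1L]) && is.na(de$fdr[1L]))
  expect_true(all(de$fdr >= de$p, na.rm = TRUE))
})

test_that("DEG calling applies strict thresholds on the right scale", {
  de <- make_de(c("a", "b", "c"), log2fc = c(1.5, 0.9, -2),
                p = c(0.001, 0.01, 0.001), fdr = c(0.01, 0.3, 0.01))
  strict <- deg_rule(1.5, 0.05, "fdr")
  mild <- deg_rule(log2(1.5), 0.05, "raw_p")
  expect_false("a" %in% names(call_degs(de, strict)))  # 1.5 is not > 1.5
  expect_identical(unname(call_degs(de, strict)["c"]), "down")
  expect_identical(unname(call_degs(de, mild)["b"]), "up")
})

test_that("Wald p approaches the classical rate-ratio test on large Poisson counts", {
  set.seed(77)
  n <- 40L
  x1 <- rpois(n, 500); x2 <- rpois(n, 600)
  counts <- rbind(c(x1, x2),
                  matrix(rpois(40L * 2L * n, 300), 40L))
  dimnames(counts) <- list(sprintf("g%02d", 1:41),
                           sprintf("s%03d", seq_len(2L * n)))
  cond <- setNames(rep(c("control", "perturbed"), each = n), colnames(counts))
  de <- nb_wald_contrast(count_matrix(counts, cond), "control", "perturbed")
  pois_p <- poisson.test(c(sum(x2), sum(x1)))$p.value
  # both highly significant and of comparable magnitude on the log scale
  expect_lt(de$p[1L], 1e-4)
  expect_lt(abs(log10(de$p[1L]) - log10(pois_p)) / abs(log10(pois_p)), 1)
})

test_that("planted DEGs are recovered with controlled error at n = 5", {
  cfg <- small_cfg(seed = 4L)
  sim <- simulate_counts(cfg)
  de <- nb_wald_contrast(sim$cm, "control", "perturbed")
  calls <- call_degs(de, deg_rule(1.5, 0.05, "fdr"))
  planted_up <- c(sim$truth$up_down, sim$truth$perturbed_only_up)
  planted_down <- c(sim$truth$down_up, sim$truth$perturbed_only_down)
  sens <- mean(c(planted_up %in% names(calls)[calls == "up"],
                 planted_down %in% names(calls)[calls == "down"]))
  fdr_obs <- mean(!names(calls) %in% c(planted_up, planted_down))
  expect_gte(sens, 0.9)
  expect_lte(fdr_obs, 0.1)
})
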