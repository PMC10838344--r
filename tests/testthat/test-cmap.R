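test_that("signatures take the extreme flanks with deterministic ties", {
  prof <- setNames(c(5, 4, 3, -4, -5), c("a", "b", "c", "d", "e"))
  sig <- make_signature(prof, n_sig = 2L)
  expect_setequal(sig$up, c("a", "b"))
  expect_setequal(sig$down, c("d", "e"))
  flat <- setNames(rep(1, 6), c("a", "b", "c", "d", "e", "f"))
  sig <- make_signature(flat, n_sig = 2L)
  expect_identical(sig$up, c("a", "b"))     # lexicographically first block
  expect_identical(sig$down, c("f", "e"))   # lexicographically last block
  expect_length(intersect(sig$up, sig$down), 0L)
  expect_error(make_signature(prof, n_sig = 3L), "required")
})

test_that("signature flanks equal a naive full-sort oracle on random data", {
  set.seed(3)
  prof <- setNames(rnorm(1000), sprintf("g%04d", sample(1000)))
  sig <- make_signature(prof, n_sig = 100L)
  ord <- names(prof)[order(-prof, names(prof))]
  expect_setequal(sig$up, ord[1:100])
  expect_setequal(sig$down, ord[901:1000])
})

test_that("jaccard follows the set-arithmetic definition", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccard(character(), character()), 0)
  expect_equal(jaccard(c("x", "y"), c("y", "x")), jaccard(c("y", "x"), c("x", "y")))
})

mimic_fixture <- function(seed = 2L) {
  cfg <- small_cfg(seed = seed)
  sim <- simulate_counts(cfg)
  lib <- simulate_drug_library(cfg, sim$truth)
  fs <- make_flip_set(sim$truth$up_down, sim$truth$down_up)
  list(cfg = cfg, truth = sim$truth, lib = lib, fs = fs)
}

test_that("a perfect mimic attains the library-wide maximum score", {
  fx <- mimic_fixture()
  lib <- fx$lib$library
  perfect <- rnorm(length(lib$gene_space))
  names(perfect) <- lib$gene_space
  perfect[fx$truth$up_down] <- -seq(20, 21, length.out = length(fx$truth$up_down))
  perfect[fx$truth$down_up] <- seq(20, 21, length.out = length(fx$truth$down_up))
  scores <- cbind(lib$scores, perfect_p1 = perfect)
  meta <- rbind(lib$meta, data.frame(profile_id = "perfect_p1",
                                     drug_id = "perfect", quality = TRUE,
                                     fda_approved = TRUE))
  lib2 <- drug_profile_library(scores, meta)
  mim <- mimicry_scores(fx$fs, lib2, n_sig = 20L)
  expect_identical(mim$profile_id[1L], "perfect_p1")
  expect_equal(mim$jaccard[1L],
               max(mim$jaccard))
})

test_that("filtered profiles never enter the screen", {
  fx <- mimic_fixture()
  mim <- mimicry_scores(fx$fs, fx$lib$library, n_sig = 20L)
  bad <- fx$lib$library$meta$profile_id[
    !(fx$lib$library$meta$quality & fx$lib$library$meta$fda_approved)]
  expect_gt(length(bad), 0L)
  expect_length(intersect(mim$profile_id, bad), 0L)
})

test_that("decile flagging keeps ceiling(decile * retained) up to ties", {
  fx <- mimic_fixture()
  mim <- mimicry_scores(fx$fs, fx$lib$library, n_sig = 20L)
  n_top <- ceiling(0.1 * nrow(mim))
  thr <- sort(mim$jaccard, decreasing = TRUE)[n_top]
  expect_identical(mim$in_top_decile, mim$jaccard >= thr)
  expect_gte(sum(mim$in_top_decile), n_top)
})

test_that("an orthogonal profile scores zero and misses the top decile", {
  fx <- mimic_fixture()
  lib <- fx$lib$library
  flat <- setNames(rep(0, length(lib$gene_space)), lib$gene_space)
  flip <- c(fx$truth$up_down, fx$truth$down_up)
  flat[flip] <- 1e-6  # keep flip genes away from both flanks
  ord_mid <- setdiff(lib$gene_space, flip)
  flat[ord_mid] <- rnorm(length(ord_mid), 0, 5)
  scores <- cbind(lib$scores, ortho_p1 = flat)
  meta <- rbind(lib$meta, data.frame(profile_id = "ortho_p1",
                                     drug_id = "ortho", quality = TRUE,
                                     fda_approved = TRUE))
  mim <- mimicry_scores(fx$fs, drug_profile_library(scores, meta), n_sig = 20L)
  row <- mim[mim$profile_id == "ortho_p1", ]
  expect_equal(row$jaccard, 0)
  expect_false(row$in_top_decile)
})

test_that("pooled mode reduces to the plain Jaccard over pooled flanks", {
  fx <- mimic_fixture()
  lib <- fx$lib$library
  mim <- mimicry_scores(fx$fs, lib, mode = "pooled", n_sig = 20L)
  j <- mim$jaccard[match("drug_001_p1", mim$profile_id)]
  sig <- make_signature(lib$scores[, "drug_001_p1"], n_sig = 20L)
  expect_equal(j, jaccard(c(fx$fs$up_down, fx$fs$down_up),
                          c(sig$up, sig$down)))
})

test_that("target enrichment reproduces the extremal and null cases", {
  mim <- structure(
    data.frame(profile_id = paste0("p", 1:10),
               drug_id = paste0("d", 1:10),
               jaccard = seq(1, 0.1, length.out = 10),
               hits_up_down = 0L, hits_down_up = 0L, rank = 1:10,
               in_top_decile = c(TRUE, TRUE, rep(FALSE, 8L))),
    class = c("mimicry_result", "data.frame"))
  targets <- data.frame(
    drug_id = c("d1", "d2", "d5", "d1", "d3"),
    target_id = c("tPerfect", "tPerfect", "tOther", "tShared", "tShared"),
    source_db = "KEGG")
  ts <- target_enrichment(mim, targets)
  perfect <- ts[ts$target_id == "tPerfect", ]
  expect_equal(perfect$ef, (2 / 2) / (2 / 10))  # N/K: maximal
  expect_equal(perfect$p, hypergeom_tail(2, 2, 2, 10), tolerance = 1e-12)
  expect_identical(ts$target_id[1L], "tPerfect")
  expect_true(all(ts$n_mimic_hits <= ts$n_total_hits))
})

test_that("random target annotation has mean EF near one", {
  set.seed(6)
  efs <- replicate(200, {
    mimics <- paste0("d", 1:5)
    screened <- paste0("d", 1:50)
    hit <- sample(screened, 12L)
    k <- length(intersect(hit, mimics))
    (k / 5) / (12 / 50)
  })
  expect_lt(abs(mean(efs) - 1), 0.1)
})

test_that("shuffling drug-target links destroys planted enrichment", {
  fx <- mimic_fixture(seed = 9L)
  mim <- mimicry_scores(fx$fs, fx$lib$library, n_sig = 20L)
  ts <- target_enrichment(mim, fx$lib$targets)
  planted_p <- ts$p[ts$target_id == fx$lib$planted_target]
  expect_lt(planted_p, 0.01)
  set.seed(1)
  shuffled <- fx$lib$targets
  shuffled$drug_id <- sample(unique(mim$drug_id), nrow(shuffled),
                             replace = TRUE)
  shuffled <- shuffled[!duplicated(shuffled[c("drug_id", "target_id")]), ]
  ts2 <- target_enrichment(mim, shuffled)
  expect_gt(ts2$p[ts2$target_id == fx$lib$planted_target], planted_p)
})
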