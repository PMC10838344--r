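test_that("hypergeometric tail handles boundary and inconsistent inputs", {
  expect_equal(hypergeom_tail(0, 5, 5, 20), 1)
  expect_equal(hypergeom_tail(4, 4, 4, 4), 1)
  expect_error(hypergeom_tail(5, 4, 4, 10), "inconsistent")
  expect_error(hypergeom_tail(2, 5, 4, 3), "inconsistent")
})

test_that("hypergeometric tail equals combinatorial enumeration on small universes", {
  for (N in c(5L, 9L, 14L)) {
    for (K in 0:N) for (n in 0:N) for (k in 0:min(K, n)) {
      expect_equal(hypergeom_tail(k, K, n, N),
                   hyper_tail_brute(k, K, n, N), tolerance = 1e-12)
    }
  }
})

test_that("the tail is monotone non-increasing in the overlap", {
  ks <- 0:10
  p <- hypergeom_tail(ks, 15, 10, 60)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("enrichment factors follow the observed/expected arithmetic", {
  universe <- paste0("g", 1:100)
  flip <- paste0("g", 1:10)
  sets <- gene_set_collection(list(
    hit = c(paste0("g", 1:5), paste0("g", 51:55)),   # overlap 5, size 10
    cold = paste0("g", 60:69)))                      # disjoint from flip
  enr <- enrich_pathways(flip, sets, universe)
  expect_equal(enr$ef[enr$pathway == "hit"], 5)
  expect_equal(enr$ef[enr$pathway == "cold"], 0)
  expect_equal(enr$p[enr$pathway == "cold"], 1)
  expect_error(enrich_pathways(c(flip, "absent"), sets, universe),
               "absent")
})

test_that("ef > 1 exactly when observed exceeds expected", {
  set.seed(13)
  universe <- sprintf("g%03d", 1:200)
  flip <- sample(universe, 30)
  sets <- gene_set_collection(setNames(
    lapply(1:25, function(i) sample(universe, sample(5:40, 1L))),
    paste0("S", 1:25)))
  enr <- enrich_pathways(flip, sets, universe)
  expect_identical(enr$ef > 1, enr$overlap > enr$expected)
})

test_that("a pathway planted from flip genes outranks decoys", {
  cfg <- small_cfg(seed = 19L)
  sim <- simulate_counts(cfg)
  paths <- simulate_pathways(cfg, sim$truth)
  enr <- enrich_pathways(sim$truth$up_down, paths$sets,
                         names(sim$truth$gene_class))
  expect_identical(enr$pathway[which.min(enr$p)], "planted_up_down")
})

test_that("network edges follow the overlap-significance rule", {
  flip <- paste0("f", 1:20)
  sets <- gene_set_collection(list(
    A = flip[1:10], B = flip[1:10],          # identical flip membership
    C = flip[11:20]))                        # disjoint from A and B
  enr <- enrich_pathways(flip, sets, c(flip, paste0("n", 1:180)))
  net <- build_network(enr, sets, flip, alpha = 0.05)
  key <- paste(pmin(net$edges$from, net$edges$to),
               pmax(net$edges$from, net$edges$to))
  expect_true("A B" %in% key)
  expect_equal(net$edges$jaccard[key == "A B"], 1)
  expect_false(any(grepl("C", key)))
})

test_that("the edge set equals a brute-force double loop on random input", {
  set.seed(23)
  universe <- sprintf("g%03d", 1:150)
  flip <- sample(universe, 40)
  sets <- gene_set_collection(setNames(
    lapply(1:30, function(i) sample(c(sample(flip, sample(3:12, 1L)),
                                      sample(universe, 10)))),
    paste0("P", 1:30)))
  enr <- enrich_pathways(flip, sets, universe)
  net <- build_network(enr, sets, flip, alpha = 0.9)  # keep most nodes
  # independent double loop over node pairs
  nodes <- net$nodes$pathway
  expected <- character()
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i < j) {
      a <- intersect(sets$sets[[nodes[i]]], flip)
      b <- intersect(sets$sets[[nodes[j]]], flip)
      k <- length(intersect(a, b))
      p <- hyper_tail_brute(k, length(a), length(b), length(flip))
      jac <- if (length(union(a, b))) k / length(union(a, b)) else 0
      if (p < 0.05 && jac >= 0.1)
        expected <- c(expected, paste(pmin(nodes[i], nodes[j]),
                                      pmax(nodes[i], nodes[j])))
    }
  }
  got <- paste(pmin(net$edges$from, net$edges$to),
               pmax(net$edges$from, net$edges$to))
  expect_setequal(got, expected)
})

test_that("the network is invariant under pathway relabeling", {
  set.seed(29)
  universe <- sprintf("g%03d", 1:100)
  flip <- sample(universe, 30)
  members <- setNames(lapply(1:12, function(i)
    c(sample(flip, sample(4:10, 1L)), sample(universe, 5))), paste0("P", 1:12))
  ren <- setNames(paste0("Q", 12:1), paste0("P", 1:12))
  sets1 <- gene_set_collection(members)
  sets2 <- gene_set_collection(setNames(members, ren[names(members)]))
  enr1 <- enrich_pathways(flip, sets1, universe)
  enr2 <- enrich_pathways(flip, sets2, universe)
  net1 <- build_network(enr1, sets1, flip, alpha = 0.9)
  net2 <- build_network(enr2, sets2, flip, alpha = 0.9)
  key1 <- sort(paste(pmin(ren[net1$edges$from], ren[net1$edges$to]),
                     pmax(ren[net1$edges$from], ren[net1$edges$to])))
  key2 <- sort(paste(pmin(net2$edges$from, net2$edges$to),
                     pmax(net2$edges$from, net2$edges$to)))
  expect_identical(key1, key2)
})

test_that("K-means separates pathway blocks built on disjoint flip halves", {
  flip <- paste0("f", 1:40)
  half1 <- flip[1:20]; half2 <- flip[21:40]
  members <- c(lapply(1:5, function(i) half1[c(1:10 + (i %% 2))]),
               lapply(1:5, function(i) half2[c(1:10 + (i %% 2))]))
  names(members) <- paste0("P", 1:10)
  sets <- gene_set_collection(members)
  nodes <- data.frame(pathway = names(members), overlap = 10L, ef = 3,
                      p = 1e-4, fdr = 1e-3, cluster = NA_real_,
                      flip_class = "up_down")
  net <- pathway_network(nodes, data.frame(from = character(),
                                           to = character()))
  cl <- cluster_pathways(net, sets, flip, k = 2L, seed = 5L)$nodes$cluster
  expect_length(unique(cl[1:5]), 1L)
  expect_length(unique(cl[6:10]), 1L)
  expect_false(cl[1L] == cl[6L])
})

test_that("degenerate incidence collapses to one cluster under auto-k", {
  flip <- paste0("f", 1:10)
  members <- setNames(rep(list(flip[1:5]), 6L), paste0("P", 1:6))
  sets <- gene_set_collection(members)
  nodes <- data.frame(pathway = names(members), overlap = 5L, ef = 2,
                      p = 1e-3, fdr = 1e-2, cluster = NA_real_,
                      flip_class = "up_down")
  net <- pathway_network(nodes, data.frame(from = character(),
                                           to = character()))
  cl <- cluster_pathways(net, sets, flip, k = "auto", seed = 1L)$nodes$cluster
  expect_identical(unique(cl), 1)
  expect_error(cluster_pathways(net, sets, flip, k = 99L, seed = 1L),
               "exceeds")
})

test_that("clustering is deterministic for a fixed seed", {
  cfg <- small_cfg(seed = 19L)
  sim <- simulate_counts(cfg)
  paths <- simulate_pathways(cfg, sim$truth)
  flip <- c(sim$truth$up_down, sim$truth$down_up)
  enr <- enrich_pathways(flip, paths$sets, names(sim$truth$gene_class))
  net <- build_network(enr, paths$sets, flip, alpha = 0.9)
  labs <- replicate(10, cluster_pathways(net, paths$sets, flip,
                                         seed = 7L)$nodes$cluster,
                    simplify = FALSE)
  for (l in labs[-1L]) expect_identical(l, labs[[1L]])
})
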