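test_that("linkage_dendrogram reproduces hand UPGMA merges", {
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"),
                                                        c("a", "b")))
  h <- linkage_dendrogram(D2, "UPGMA")
  expect_equal(h$height, 0.4)

  D3 <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  D3["A", "B"] <- D3["B", "A"] <- 1
  D3["A", "C"] <- D3["C", "A"] <- 4
  D3["B", "C"] <- D3["C", "B"] <- 4
  h3 <- linkage_dendrogram(D3, "UPGMA")
  expect_equal(h3$height, c(1, 4))
  expect_equal(sort(cutree(h3, 2)[c("A", "B")]), c(A = 1, B = 1))

  expect_error(linkage_dendrogram(D3, "nope"), class = "invalid_argument")
})

test_that("cophenetic correlation is exact on ultrametric input", {
  # an ultrametric dissimilarity is a fixed point of UPGMA
  D <- matrix(c(0, 1, 3, 3,
                1, 0, 3, 3,
                3, 3, 0, 2,
                3, 3, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  h <- linkage_dendrogram(D, "UPGMA")
  expect_equal(as.matrix(cophenetic(h))[letters[1:4], letters[1:4]], D)
  expect_equal(cophenetic_correlation(h, D), 1)

  # generic n=3 case equals direct Pearson on the three pairs
  h3 <- linkage_dendrogram(D3 <- matrix(c(0, .2, .7, .2, 0, .9, .7, .9, 0), 3,
                                        dimnames = list(1:3, 1:3)), "UPGMA")
  expect_equal(cophenetic_correlation(h3, D3),
               cor(as.vector(as.dist(D3)), as.vector(cophenetic(h3))))

  Dc <- matrix(0.5, 3, 3, dimnames = list(1:3, 1:3)); diag(Dc) <- 0
  hc <- linkage_dendrogram(Dc, "UPGMA")
  expect_error(cophenetic_correlation(hc, Dc), class = "undefined_correlation")
})

test_that("select_linkage picks the cophenetic argmax", {
  set.seed(12)
  x <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(x))
  sel <- select_linkage(D)
  brute <- vapply(names(phylorealms:::linkage_methods()), function(m) {
    cophenetic_correlation(suppressMessages(linkage_dendrogram(D, m)), D)
  }, numeric(1))
  expect_equal(sel$best, names(brute)[which.max(brute)])
  expect_equal(sel$coefficients, brute[names(sel$coefficients)])
  expect_equal(select_linkage(D, "UPGMA")$best, "UPGMA")
})

test_that("explained variance satisfies its closed forms and monotonicity", {
  cm <- random_community(12, 9, seed = 5)
  D <- simpson_beta(cm)
  n <- nrow(D)
  expect_equal(explained_variance(D, rep(1, n)), 0)
  expect_equal(explained_variance(D, seq_len(n)), 1)

  # planted two-block arithmetic: ev = 1 - (6*0.1)/(6*0.1 + 9*0.9)
  Db <- matrix(0.9, 6, 6); Db[1:3, 1:3] <- 0.1; Db[4:6, 4:6] <- 0.1
  diag(Db) <- 0
  expect_equal(explained_variance(Db, c(1, 1, 1, 2, 2, 2)),
               1 - (6 * 0.1) / (6 * 0.1 + 9 * 0.9), tolerance = 1e-12)

  # ev non-decreasing along dendrogram cuts
  dend <- linkage_dendrogram(D, "UPGMA")
  ev <- vapply(seq_len(n), function(k) explained_variance(D, cutree(dend, k)),
               numeric(1))
  expect_true(all(diff(ev) >= -1e-12))
})

test_that("optimal_k finds planted blocks and honours the tie rule", {
  # strong 4-block structure
  set.seed(8)
  lab <- rep(1:4, each = 6)
  Db <- matrix(0.8, 24, 24) + matrix(runif(24 * 24, 0, 0.02), 24)
  Db <- (Db + t(Db)) / 2
  Db[outer(lab, lab, "==")] <- 0.05
  diag(Db) <- 0
  dimnames(Db) <- list(paste0("c", 1:24), paste0("c", 1:24))
  dend <- linkage_dendrogram(Db, "UPGMA")
  el <- optimal_k(dend, Db, 12)
  expect_equal(el$k_opt, 4)
  expect_equal(unname(el$ev[1]), 0)

  # k_max = 2 forces k = 2
  expect_equal(optimal_k(dend, Db, 2)$k_opt, 2)

  # tie rule: on an all-equal dissimilarity the chord distances repeat, and
  # ties resolve to the smallest k (which.max takes the first maximum)
  Deq <- matrix(1, 5, 5); diag(Deq) <- 0
  dimnames(Deq) <- list(paste0("x", 1:5), paste0("x", 1:5))
  deq <- suppressMessages(linkage_dendrogram(Deq, "single"))
  ev <- optimal_k(deq, Deq, 5)
  dists <- abs(ev$ev - (seq_len(5) - 1) / 4 * ev$ev[[5]])
  cand <- 2:4
  expect_equal(ev$k_opt, unname(cand[which.max(dists[cand])]))
})

test_that("region and realm cuts nest and recover planted realms", {
  w <- simulate_world(synth_config(seed = 6))
  D <- phylo_simpson_beta(w$community, w$tree)
  dend <- suppressMessages(linkage_dendrogram(D, "UPGMA"))
  regions <- cut_regions(dend, 6)
  realms <- cut_realms(dend, D, 0.60)
  expect_equal(length(unique(realms$region)), 3) # planted 3 realms
  nested <- nest_realms(regions, realms)
  expect_length(nested$realm_of_region, 6)
  # every realm is a union of whole regions (same-dendrogram cuts nest)
  for (k in 2:10) {
    fine <- cutree(dend, k)
    coarse <- cutree(dend, k - 1)
    expect_true(all(vapply(split(coarse, fine),
                           function(v) length(unique(v)) == 1, logical(1))))
  }
  expect_error(cut_realms(dend, D, 1.2), class = "invalid_argument")

  lab1 <- cut_regions(dend, 1)
  expect_equal(unname(unique(lab1$region)), 1L)
})

test_that("evolutionary distinctiveness equals the naive double loop", {
  # two regions: both get the single cross-mean
  Db <- matrix(0.7, 6, 6); Db[1:3, 1:3] <- 0.2; Db[4:6, 4:6] <- 0.2
  diag(Db) <- 0
  ed2 <- evolutionary_distinctiveness(Db, c(1, 1, 1, 2, 2, 2))
  expect_equal(unname(ed2), c(0.7, 0.7))

  set.seed(3)
  D <- matrix(runif(100), 10, 10); D <- (D + t(D)) / 2; diag(D) <- 0
  lab <- c(1, 1, 1, 2, 2, 3, 3, 3, 3, 2)
  ed <- evolutionary_distinctiveness(D, lab)
  for (r in 1:3) {
    others <- setdiff(1:3, r)
    want <- mean(vapply(others, function(q)
      mean(D[lab == r, lab == q]), numeric(1)))
    expect_equal(unname(ed[as.character(r)]), want)
  }
  expect_error(evolutionary_distinctiveness(D, rep(1, 10)),
               class = "invalid_argument")
})

test_that("region diversity satisfies the WE/PE conservation identities", {
  w <- simulate_world(synth_config(n_species = 40, grid_nx = 8, grid_ny = 8,
                                   k_regions = 3, k_realms = 2, seed = 2))
  cm <- w$community; tree <- w$tree
  ce <- cell_endemism(cm, tree)
  expect_equal(sum(ce$WE), ncol(cm), tolerance = 1e-9)
  bi <- branch_incidence(cm, tree)
  expect_equal(sum(ce$PE), sum(bi$lengths), tolerance = 1e-9)

  # single-region labeling: SR = S and PD = total subtended length
  one <- setNames(rep(1, nrow(cm)), rownames(cm))
  dt <- region_diversity(cm, tree, one)
  expect_equal(dt$SR, ncol(cm))
  expect_equal(dt$PD, sum(bi$lengths), tolerance = 1e-9)

  lab <- w$truth$region_of_cell
  dt3 <- region_diversity(cm, tree, lab, D = phylo_simpson_beta(cm, tree))
  expect_equal(nrow(dt3), 3)
  expect_true(all(dt3$SR >= 1))
  expect_true(all(dt3$PD <= sum(tree$edge.length) + 1e-9))
  expect_true(all(dt3$ED >= 0 & dt3$ED <= 1))
  # mean per-cell endemism aggregates match direct averages
  expect_equal(dt3$mean_WE,
               vapply(1:3, function(r) mean(ce$WE[lab == r]), numeric(1)))
})

test_that("NMDS embeds exactly embeddable configurations", {
  # regions at known 2-D coordinates: stress ~ 0 and distances recovered
  set.seed(4)
  pts <- matrix(rnorm(12), 6, 2)
  Dr <- as.matrix(dist(pts))
  # expand each region to 2 cells with identical profiles
  lab <- rep(1:6, each = 2)
  Dc <- Dr[lab, lab]
  diag(Dc) <- 0
  dimnames(Dc) <- list(paste0("c", 1:12), paste0("c", 1:12))
  fit <- ordinate_regions(Dc, lab, seed = 1)
  expect_lt(fit$stress, 1e-4)
  emb <- as.matrix(dist(fit$coords))
  # monotone recovery: rank order of distances preserved
  expect_gt(cor(as.vector(as.dist(emb)), as.vector(as.dist(Dr)),
                method = "spearman"), 0.95)

  # three equidistant regions embed with ~0 stress
  D3 <- matrix(0.5, 6, 6); diag(D3) <- 0
  f3 <- ordinate_regions(D3, rep(1:3, each = 2), seed = 1)
  expect_lt(f3$stress, 1e-4)

  f1 <- ordinate_regions(Dc, lab, seed = 1)
  expect_identical(fit$coords, f1$coords)
  expect_error(ordinate_regions(D3, rep(1:2, 3)), class = "invalid_argument")
})
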