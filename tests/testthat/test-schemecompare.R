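test_that("v_measure reproduces hand-computed entropies", {
  cells <- sprintf("c%02d", 1:8)
  A <- setNames(rep(1:2, each = 4), cells)     # two equal halves
  B <- setNames(rep(1:4, each = 2), cells)     # four quarters nested in A
  out <- v_measure(A, B)
  expect_equal(out$h, 1)        # every B class is pure in A
  expect_equal(out$c, 0.5)      # H(B) = 2 ln 2, H(B|A) = ln 2
  expect_equal(out$V, 2 / 3)

  expect_equal(v_measure(A, A)$V, 1)

  one <- setNames(rep(1, 8), cells)
  o <- v_measure(one, B)
  expect_equal(o$h, 1)          # single-class A is trivially homogeneous
  expect_equal(o$c, 0)
  expect_equal(o$V, 0)

  # symmetry: h and c swap, V invariant
  sw <- v_measure(B, A)
  expect_equal(sw$h, out$c)
  expect_equal(sw$c, out$h)
  expect_equal(sw$V, out$V)

  # invariance under relabeling
  B2 <- setNames(c(9, 5, 7, 3)[B], cells)
  expect_equal(v_measure(A, B2)$V, out$V)

  expect_error(v_measure(A, setNames(B, rev(sprintf("x%02d", 1:8)))),
               class = "invalid_argument")
})

test_that("v_measure matches an independent entropy computation on random partitions", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 30
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    got <- v_measure(a, b)
    # independent route: direct entropy sums from the contingency table
    tab <- table(a, b) / n
    H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
    HA <- H(rowSums(tab)); HB <- H(colSums(tab)); HAB <- H(as.vector(tab))
    HAgB <- HAB - HB; HBgA <- HAB - HA
    h <- if (HA == 0) 1 else 1 - HAgB / HA
    cc <- if (HB == 0) 1 else 1 - HBgA / HB
    V <- if (h + cc > 0) 2 * h * cc / (h + cc) else 0
    expect_equal(got$h, h, tolerance = 1e-12)
    expect_equal(got$c, cc, tolerance = 1e-12)
    expect_equal(got$V, V, tolerance = 1e-12)
  }
})

test_that("random Voronoi labelings are nearest-seed tessellations", {
  g <- build_grid(10, 10)
  v1 <- random_voronoi_labeling(g, 1, seed = 1)
  expect_equal(unname(unique(v1$region)), 1L)
  vn <- random_voronoi_labeling(g, 100, seed = 1)
  expect_equal(length(unique(vn$region)), 100)
  expect_error(random_voronoi_labeling(g, 101), class = "invalid_argument")

  v3 <- random_voronoi_labeling(g, 3, seed = 11)
  # brute-force nearest-seed scan
  set.seed(11)
  li <- land_indices_test(g)
  seeds <- sample(li, 3)
  for (p in seq_along(li)) {
    d2 <- (g$cells$x[li[p]] - g$cells$x[seeds])^2 +
      (g$cells$y[li[p]] - g$cells$y[seeds])^2
    expect_equal(unname(v3$region[p]), which.min(d2))
  }
  # regions connected on a convex all-land mask
  expect_true(label_contiguous(g, unname(v3$region)))
})

test_that("v_measure_test gives small p for identical schemes", {
  g <- build_grid(8, 8)
  A <- random_voronoi_labeling(g, 4, seed = 5)
  out <- v_measure_test(A, A, g, n_null = 99, seed = 1)
  expect_equal(out$V, 1)
  expect_lte(out$p, 0.02) # = 0.01 unless a null reaches V = 1
  expect_length(out$null_V, 99)

  no_p <- v_measure_test(A, A, g, n_null = 0)
  expect_null(no_p$p)
})

test_that("boundary distances match hand counts and the naive oracle", {
  strip <- build_grid(10, 1)
  lab <- setNames(rep(1:2, each = 5), strip$cells$cell)
  d <- boundary_distance(lab, strip, "region")
  expect_equal(unname(d), c(400, 300, 200, 100, 0, 0, 100, 200, 300, 400))

  g <- build_grid(6, 6)
  every <- setNames(seq_len(36), g$cells$cell)
  expect_true(all(boundary_distance(every, g) == 0))

  one <- setNames(rep(1, 36), g$cells$cell)
  expect_error(boundary_distance(one, g), class = "no_boundary")

  for (seed in 1:5) {
    vl <- random_voronoi_labeling(g, 3, seed = seed)
    d <- boundary_distance(vl, g)
    # naive oracle: minimum distance to any boundary cell
    li <- land_indices_test(g)
    lab <- vl$region
    isb <- vapply(seq_along(li), function(p) {
      any(lab[match(g$cells$cell[g$adj[[li[p]]]], names(lab))] != lab[p])
    }, logical(1))
    for (p in seq_along(li)) {
      want <- min(sqrt((g$cells$x[li[p]] - g$cells$x[li[isb]])^2 +
                       (g$cells$y[li[p]] - g$cells$y[li[isb]])^2))
      expect_equal(unname(d[p]), want)
    }
  }
})

test_that("modified_t_test handles exact and degenerate cases", {
  g <- build_grid(8, 8)
  set.seed(1)
  x <- rnorm(64)
  out <- modified_t_test(x, x, g)
  expect_equal(out$r, 1)
  expect_lt(out$p, 1e-10)
  expect_lte(out$M, 64)

  expect_error(modified_t_test(x, rep(1, 64), g),
               class = "undefined_correlation")
  expect_error(modified_t_test(x[1:9], x[1:9], build_grid(3, 3)),
               class = "invalid_argument")

  # the log-distance helper keeps boundary cells finite
  expect_equal(log_boundary_distance(0, 100), log(50))
  expect_equal(log_boundary_distance(300, 100), log(350))
})

test_that("effective sample size shrinks under spatial autocorrelation", {
  g <- build_grid(15, 15)
  set.seed(2)
  n <- 225
  sm <- function() {
    m <- matrix(rnorm(n), 15, 15)
    phylorealms:::mean_filter_3x3(m)[cbind(g$cells$ix, g$cells$iy)]
  }
  M_white <- mean(replicate(20, {
    modified_t_test(rnorm(n), rnorm(n), g)$M
  }))
  M_smooth <- mean(replicate(20, modified_t_test(sm(), sm(), g)$M))
  expect_gt(M_white, 0.8 * n)  # white noise keeps nearly all information
  expect_lt(M_smooth, 0.75 * M_white) # smoothing costs effective samples
})
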