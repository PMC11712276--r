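test_that("focal_cv matches hand arithmetic and degenerate contracts", {
  g <- build_grid(3, 3)
  expect_true(all(focal_cv(rep(5, 9), g) == 0))

  vals <- setNames(1:9, g$cells$cell) # centre window = {1..9}
  cv <- focal_cv(vals, g)
  centre <- g$cells$cell[g$cells$ix == 2 & g$cells$iy == 2]
  expect_equal(unname(cv[centre]), sd(1:9) / 5, tolerance = 1e-4)

  # mean-zero window -> missing
  v0 <- setNames(c(-4:4), g$cells$cell)
  expect_true(is.na(focal_cv(v0, g)[centre]))
})

test_that("terrain ruggedness equals window enumeration", {
  g <- build_grid(5, 5)
  expect_true(all(terrain_ruggedness(rep(100, 25), g) == 0))

  # linear ramp 10 m per cell along x: interior TRI = 60/8
  ramp <- setNames(g$cells$ix * 10, g$cells$cell)
  tri <- terrain_ruggedness(ramp, g)
  interior <- g$cells$cell[g$cells$ix %in% 2:4 & g$cells$iy %in% 2:4]
  expect_equal(unname(tri[interior]), rep(7.5, length(interior)))

  # checkerboard vs brute-force window scan
  cb <- setNames(100 * ((g$cells$ix + g$cells$iy) %% 2), g$cells$cell)
  tri_cb <- terrain_ruggedness(cb, g)
  li <- land_indices_test(g)
  for (p in seq_along(li)) {
    nb <- g$adj[[li[p]]]
    expect_equal(unname(tri_cb[p]), mean(abs(cb[nb] - cb[li[p]])))
  }

  # translation invariance and linear scaling
  expect_equal(terrain_ruggedness(ramp + 500, g), tri)
  expect_equal(terrain_ruggedness(ramp * 3, g), tri * 3)
  cvr <- focal_cv(ramp, g)
  expect_equal(focal_cv(ramp * 3, g), cvr) # CV is scale-free
})

test_that("climate velocity follows the gradient quotient", {
  g <- build_grid(6, 6)
  base <- setNames(g$cells$x * 0.01, g$cells$cell) # uniform 0.01 units/km
  expect_true(all(suppressMessages(
    climate_velocity(base, base, g)) == 0))

  past <- base - 2 # uniform +2 units of warming since the LGM
  v <- suppressMessages(climate_velocity(base, past, g, delta_years = 21000))
  expect_equal(unname(v), rep((2 / 21000) / 0.01, 36), tolerance = 1e-9)

  flat <- setNames(rep(3, 36), g$cells$cell)
  expect_message(vf <- climate_velocity(flat, flat - 1, g), "flat")
  expect_true(all(vf > 1e4)) # capped by the eps floor
  expect_error(climate_velocity(base, past, g, delta_years = 0),
               class = "invalid_argument")
})

test_that("boundary_contact splits into realm and within-realm layers", {
  strip <- build_grid(10, 1)
  lab <- structure(list(region = setNames(rep(1:2, each = 5),
                                          strip$cells$cell),
                        realm_of_region = c(1, 1), scheme = "s"),
                   class = "pr_labeling")
  bc <- boundary_contact(lab, strip, "all")
  expect_equal(unname(bc), c(0, 0, 0, 0, 1, 1, 0, 0, 0, 0))

  one <- structure(list(region = setNames(rep(1, 10), strip$cells$cell),
                        realm_of_region = 1, scheme = "s"),
                   class = "pr_labeling")
  expect_true(all(boundary_contact(one, strip, "all") == 0))

  # all = OR(realm, within-realm) on random nested labelings
  g <- build_grid(8, 8)
  for (seed in 1:5) {
    vl <- random_voronoi_labeling(g, 6, seed = seed)
    vl$realm_of_region <- c(1, 1, 2, 2, 3, 3)
    a <- boundary_contact(vl, g, "all")
    r <- boundary_contact(vl, g, "realm")
    wr <- boundary_contact(vl, g, "within-realm")
    expect_equal(a, pmax(r, wr))
  }
  vl$realm_of_region <- NULL
  expect_error(boundary_contact(vl, g, "realm"), class = "invalid_argument")
})

test_that("vif matches closed forms", {
  set.seed(9)
  X <- matrix(rnorm(300), 100, 3)
  X <- qr.Q(qr(X)) # orthogonal columns
  colnames(X) <- paste0("p", 1:3)
  expect_equal(unname(vif(X)), rep(1, 3), tolerance = 1e-3)

  Xd <- cbind(X, p4 = X[, 1])
  expect_true(is.infinite(vif(Xd)["p4"]))

  # correlated Gaussians with known covariance: VIF = 1/(1 - R^2) where
  # R^2 for x1 ~ x2 is rho^2
  rho <- 0.6
  set.seed(10)
  z <- matrix(rnorm(20000), 10000, 2)
  x1 <- z[, 1]; x2 <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  v <- vif(cbind(a = x1, b = x2))
  expect_equal(unname(v), rep(1 / (1 - rho^2), 2), tolerance = 0.05)
})

test_that("the spatial boundary model is invariant to predictor units", {
  set.seed(21)
  g <- build_grid(12, 12)
  n <- 144
  X <- replicate(3, rnorm(n))
  y <- rbinom(n, 1, plogis(X[, 1]))
  preds <- list(a = setNames(X[, 1], g$cells$cell),
                b = setNames(X[, 2], g$cells$cell),
                cc = setNames(X[, 3], g$cells$cell))
  f1 <- fit_boundary_model(setNames(y, g$cells$cell), preds, g,
                           neighbor_km = 150)
  preds2 <- preds; preds2$b <- preds2$b * 10
  f2 <- fit_boundary_model(setNames(y, g$cells$cell), preds2, g,
                           neighbor_km = 150)
  expect_equal(f1$coefficients$fisher_z, f2$coefficients$fisher_z,
               tolerance = 1e-6)
  expect_true(f1$converged)

  expect_error(fit_boundary_model(setNames(rep(0, n), g$cells$cell), preds, g,
                                  neighbor_km = 150),
               class = "degenerate_response")
})

test_that("band restriction and auto neighbourhood are applied", {
  w <- simulate_world(synth_config(n_species = 40, grid_nx = 10, grid_ny = 10,
                                   k_regions = 3, k_realms = 2, seed = 4))
  lab <- planted_labeling(w$truth)
  bd <- boundary_distance(lab, w$grid, "region")
  resp <- boundary_contact(lab, w$grid, "all")
  preds <- build_boundary_predictors(w$env, w$grid)
  f <- fit_boundary_model(resp, preds, w$grid, neighbor_km = "auto",
                          band_km = 200, boundary_km = bd)
  expect_equal(f$n, sum(bd <= 200))
  expect_gt(f$neighbor_km, 0)
  expect_error(fit_boundary_model(resp, preds, w$grid, band_km = -5,
                                  boundary_km = bd),
               class = "invalid_argument")
})
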