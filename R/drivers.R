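align_layer <- function(x, grid) {
  li <- land_indices(grid)
  ids <- grid$cells$cell[li]
  if (!is.null(names(x))) x <- x[ids]
  if (length(x) != length(li))
    pr_stop("layer does not align with the grid's land cells", "invalid_argument")
  setNames(as.numeric(x), ids)
}

#' Focal coefficient of variation (spatial heterogeneity)
#'
#' Climate-heterogeneity predictor: for each land cell, the coefficient of
#' variation (sample SD / |mean|) of the layer over the focal cell and its
#' available queen neighbours. Edge and coastal cells use the neighbours they
#' have (no padding). A zero window mean yields `NA` (CV undefined), as does
#' an isolated cell.
#'
#' @param layer Numeric vector over land cells (named by cell id or in land
#'   order).
#' @param grid The grid.
#' @return Named numeric vector; `NA` where undefined.
#' @export
focal_cv <- function(layer, grid) {
  v <- align_layer(layer, grid)
  li <- land_indices(grid)
  pos <- setNames(seq_along(li), as.character(li))
  out <- vapply(seq_along(li), function(p) {
    nb <- pos[as.character(grid$adj[[li[p]]])]
    if (!length(nb)) return(NA_real_)
    w <- c(v[p], v[nb])
    m <- mean(w)
    if (m == 0) return(NA_real_)
    sd(w) / abs(m)
  }, numeric(1))
  setNames(out, names(v))
}

#' Terrain ruggedness index
#'
#' TRI: the mean absolute elevation difference between each cell and its
#' available queen neighbours. Translation-invariant, scales linearly with
#' elevation.
#'
#' @inheritParams focal_cv
#' @param elev Elevation layer over land cells.
#' @export
terrain_ruggedness <- function(elev, grid) {
  v <- align_layer(elev, grid)
  li <- land_indices(grid)
  pos <- setNames(seq_along(li), as.character(li))
  out <- vapply(seq_along(li), function(p) {
    nb <- pos[as.character(grid$adj[[li[p]]])]
    if (!length(nb)) return(NA_real_)
    mean(abs(v[nb] - v[p]))
  }, numeric(1))
  setNames(out, names(v))
}

#' Climate change velocity
#'
#' Velocity = temporal change rate divided by the local spatial gradient of
#' the present-day layer: `v = (|present - past| / delta_years) / max(g, eps)`
#' in km/yr, with `g` the gradient magnitude from central differences over
#' `cell_km` (one-sided at edges and coasts) and `eps = 1e-9` units/km a
#' floor that caps velocity where the field is locally flat (flat cells are
#' reported via a message).
#'
#' @param present,past Layers over land cells (same units).
#' @param grid The grid.
#' @param delta_years Elapsed time (default 21000, the LGM).
#' @return Named numeric vector, km/yr.
#' @export
climate_velocity <- function(present, past, grid, delta_years = 21000) {
  if (delta_years <= 0) pr_stop("delta_years must be > 0", "invalid_argument")
  pv <- align_layer(present, grid)
  qv <- align_layer(past, grid)
  li <- land_indices(grid)
  val <- matrix(NA_real_, grid$nx, grid$ny)
  val[cbind(grid$cells$ix[li], grid$cells$iy[li])] <- pv
  grad1 <- function(i, j, along) {
    get <- function(ii, jj) {
      if (ii < 1 || ii > grid$nx || jj < 1 || jj > grid$ny) NA_real_
      else val[ii, jj]
    }
    if (along == "x") { lo <- get(i - 1, j); hi <- get(i + 1, j) }
    else { lo <- get(i, j - 1); hi <- get(i, j + 1) }
    mid <- val[i, j]
    if (!is.na(lo) && !is.na(hi)) (hi - lo) / (2 * grid$cell_km)
    else if (!is.na(hi)) (hi - mid) / grid$cell_km
    else if (!is.na(lo)) (mid - lo) / grid$cell_km
    else 0
  }
  eps <- 1e-9
  flat <- 0L
  out <- vapply(seq_along(li), function(p) {
    i <- grid$cells$ix[li[p]]; j <- grid$cells$iy[li[p]]
    g <- sqrt(grad1(i, j, "x")^2 + grad1(i, j, "y")^2)
    if (g < eps) flat <<- flat + 1L
    (abs(pv[p] - qv[p]) / delta_years) / max(g, eps)
  }, numeric(1))
  if (flat > 0)
    message(sprintf("climate_velocity: %d cell(s) with flat present layer; velocity capped by eps floor", flat))
  setNames(out, names(pv))
}

#' Boundary-contact response layer
#'
#' Binary layer: 1 iff the cell has at least one queen neighbour with a
#' different label at the requested level. `"all"` uses region labels,
#' `"realm"` realm labels (deep boundaries), and `"within-realm"` marks cells
#' whose neighbour is in a different region of the same realm (shallow
#' boundaries); the all-boundaries layer is the elementwise OR of the other
#' two.
#'
#' @param labels A `pr_labeling` (realm levels require `realm_of_region`).
#' @param grid The grid.
#' @param level `"all"`, `"realm"` or `"within-realm"`.
#' @return Named 0/1 vector over land cells.
#' @export
boundary_contact <- function(labels, grid, level = c("all", "realm", "within-realm")) {
  level <- match.arg(level)
  reg <- label_vector(labels, "region")
  if (level != "all" && is.null(labels$realm_of_region))
    pr_stop("realm-level contact requires realm ids", "invalid_argument")
  rlm <- if (level != "all") label_vector(labels, "realm") else NULL
  li <- land_indices(grid)
  ids <- grid$cells$cell[li]
  reg <- reg[ids]; if (!is.null(rlm)) rlm <- rlm[ids]
  pos <- setNames(seq_along(li), as.character(li))
  out <- vapply(seq_along(li), function(p) {
    nb <- pos[as.character(grid$adj[[li[p]]])]
    if (!length(nb)) return(0)
    switch(level,
      all = as.numeric(any(reg[nb] != reg[p])),
      realm = as.numeric(any(rlm[nb] != rlm[p])),
      `within-realm` = as.numeric(any(reg[nb] != reg[p] & rlm[nb] == rlm[p])))
  }, numeric(1))
  setNames(out, ids)
}

#' Variance inflation factors
#'
#' VIF_j = 1/(1 - R^2_j) from regressing predictor j on the others with an
#' intercept; `Inf` under perfect collinearity. Predictors with VIF below 2
#' are conventionally taken as minimally collinear.
#'
#' @param X Data frame or matrix of predictors (>= 2 columns, n > p).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2) pr_stop("need at least 2 predictors", "invalid_argument")
  if (nrow(X) <= p) pr_stop("need n > p observations", "invalid_argument")
  vapply(seq_len(p), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(colnames(X))
}

# adjacency within a km threshold among given coordinates (binary, no self)
distance_adjacency <- function(x, y, threshold_km) {
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  W <- (d2 <= threshold_km^2 + 1e-9) * 1
  diag(W) <- 0
  W
}

#' Spatial binomial boundary model (PQL)
#'
#' Models boundary contact as a binomial-logit hierarchical GLM with a
#' spatially structured random effect: one random intercept per analysis
#' cell with a proper-CAR prior on the binary adjacency of cells within
#' `neighbor_km` (precision `Q = D - 0.95 W`, relative to the
#' row-standardized neighbourhood), fitted by Breslow–Clayton penalized
#' quasi-likelihood; at each outer iteration the random-effect variance is
#' re-estimated by profiling the REML criterion of the working linear mixed
#' model (tolerance 1e-6 on the fixed effects, at most 200 outer
#' iterations). Predictors are centred
#' and scaled internally, so effect sizes are unit-free. The analysis set is
#' restricted to cells within `band_km` of a boundary when per-cell boundary
#' distances are supplied, avoiding excessive zero inflation far from any
#' boundary.
#'
#' Effect sizes are reported as Fisher's z via the Wald-statistic chain:
#' partial correlation `r_p = w / sqrt(w^2 + df_res)` with `w` the Wald
#' statistic and `df_res = n - p`, then `z = atanh(r_p)` — a sample-size-free
#' scale comparable across models.
#'
#' @param response Binary layer over land cells (e.g. [boundary_contact()]).
#' @param predictors Named list/data.frame of numeric layers over land cells.
#' @param grid The grid.
#' @param neighbor_km Neighbourhood radius in km, or `"auto"` for the
#'   smallest radius connecting every analysis cell to at least one other
#'   (the rule behind the 282.84 km default on a 100-km grid: 2 * 100 * sqrt(2)).
#' @param band_km Band half-width in km (default 200).
#' @param boundary_km Optional per-cell distances to the nearest boundary,
#'   used to apply the band restriction.
#' @return A `pr_boundary_fit`: data.frame `coefficients` (term, estimate,
#'   se, wald, fisher_z, p), plus `sigma2`, `converged`, `iterations`,
#'   `n`, `neighbor_km`, `band_km`.
#' @export
fit_boundary_model <- function(response, predictors, grid,
                               neighbor_km = 282.84, band_km = 200,
                               boundary_km = NULL) {
  y <- align_layer(response, grid)
  if (!all(y %in% c(0, 1)))
    pr_stop("response must be binary", "invalid_argument")
  P <- lapply(predictors, align_layer, grid = grid)
  keep <- rep(TRUE, length(y))
  if (!is.null(boundary_km)) {
    bd <- align_layer(boundary_km, grid)
    keep <- keep & bd <= band_km
  }
  for (v in P) keep <- keep & is.finite(v)
  if (!any(keep)) pr_stop("empty analysis band", "invalid_argument")
  y <- y[keep]
  n <- length(y)
  if (all(y == 0) || all(y == 1))
    pr_stop("degenerate response: all cells identical", "degenerate_response")
  X <- cbind(`(Intercept)` = 1,
             vapply(P, function(v) {
               v <- v[keep]
               s <- sd(v)
               if (s == 0) pr_stop("constant predictor", "invalid_argument")
               (v - mean(v)) / s
             }, numeric(n)))
  li <- land_indices(grid)
  cx <- grid$cells$x[li][keep]; cy <- grid$cells$y[li][keep]
  if (identical(neighbor_km, "auto")) {
    d2 <- outer(cx, cx, "-")^2 + outer(cy, cy, "-")^2
    diag(d2) <- Inf
    neighbor_km <- sqrt(max(apply(d2, 1, min)))
  }
  W <- Matrix::Matrix(distance_adjacency(cx, cy, neighbor_km), sparse = TRUE)
  Q <- Matrix::Diagonal(x = Matrix::rowSums(W) + 1e-6) - 0.95 * W
  ldQ <- as.numeric(Matrix::determinant(Q, logarithm = TRUE)$modulus)
  p <- ncol(X)
  beta <- rep(0, p); beta[1] <- qlogis(max(min(mean(y), 1 - 1e-3), 1e-3))
  b <- rep(0, n)
  sigma2 <- 0.5
  converged <- FALSE
  it <- 0
  solve_mme <- function(w, z, sigma2) {
    XtW <- t(X * w)
    A <- rbind(cbind(Matrix::Matrix(XtW %*% X), Matrix::Matrix(XtW)),
               cbind(Matrix::Matrix(t(XtW)),
                     Matrix::Diagonal(x = w) + Q / sigma2))
    sol <- Matrix::solve(A, c(XtW %*% z, w * z))
    list(beta = as.numeric(sol[seq_len(p)]), b = as.numeric(sol[-seq_len(p)]),
         A = A)
  }
  # profiled REML criterion of the working linear mixed model
  neg2reml <- function(log_s2, w, z) {
    s2 <- exp(log_s2)
    fit <- solve_mme(w, z, s2)
    r <- z - as.numeric(X %*% fit$beta) - fit$b
    ldA <- as.numeric(Matrix::determinant(fit$A, logarithm = TRUE)$modulus)
    -sum(log(w)) - (ldQ - n * log(s2)) + ldA +
      sum(w * r^2) + sum(fit$b * as.numeric(Q %*% fit$b)) / s2
  }
  for (it in seq_len(200)) {
    eta <- as.numeric(X %*% beta + b)
    mu <- pmin(pmax(plogis(eta), 1e-6), 1 - 1e-6)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    opt <- optimize(neg2reml, c(log(1e-4), log(50)), w = w, z = z,
                    tol = 1e-3)
    sigma2_new <- exp(opt$minimum)
    fit <- solve_mme(w, z, sigma2_new)
    delta <- max(abs(fit$beta - beta)) +
      abs(sigma2_new - sigma2) / (sigma2 + 1e-8)
    beta <- fit$beta; b <- fit$b; sigma2 <- sigma2_new
    if (delta < 1e-6) { converged <- TRUE; break }
  }
  eta <- as.numeric(X %*% beta + b)
  mu <- pmin(pmax(plogis(eta), 1e-6), 1 - 1e-6)
  w <- mu * (1 - mu)
  XtW <- t(X * w)
  A <- rbind(cbind(Matrix::Matrix(XtW %*% X), Matrix::Matrix(XtW)),
             cbind(Matrix::Matrix(t(XtW)),
                   Matrix::Diagonal(x = w) + Q / sigma2))
  Ainv_cols <- Matrix::solve(A, rbind(diag(p), matrix(0, n, p)))
  Vb <- as.matrix(Ainv_cols[seq_len(p), , drop = FALSE])
  se <- sqrt(diag(Vb))
  wald <- beta / se
  df_res <- n - p
  r_p <- wald / sqrt(wald^2 + df_res)
  fisher_z <- atanh(r_p)
  pvals <- 2 * pnorm(-abs(wald))
  coefs <- data.frame(term = colnames(X), estimate = beta, se = se,
                      wald = wald, fisher_z = fisher_z, p = pvals,
                      row.names = NULL)
  structure(list(coefficients = coefs, sigma2 = sigma2,
                 converged = converged, iterations = it, n = n,
                 neighbor_km = neighbor_km, band_km = band_km),
            class = "pr_boundary_fit")
}

#' @export
print.pr_boundary_fit <- function(x, ...) {
  cat(sprintf("Spatial binomial boundary model (PQL): n = %d, sigma2 = %.3f, %s\n",
              x$n, x$sigma2,
              if (x$converged) sprintf("converged in %d iterations", x$iterations)
              else "DID NOT CONVERGE"))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Build the standard predictor table from environmental layers
#'
#' Applies [focal_cv()] to the four climate layers, [terrain_ruggedness()]
#' to elevation, and [climate_velocity()] to the present/LGM temperature
#' pair, yielding the six boundary-model predictors.
#'
#' @param env Named list of layers including `temp_seasonality`,
#'   `precip_seasonality`, `mat`, `map`, `elevation`, `temp_present`,
#'   `temp_lgm`.
#' @param grid The grid.
#' @return Named list of predictor layers.
#' @export
build_boundary_predictors <- function(env, grid) {
  list(
    cv_temp_seasonality = focal_cv(env$temp_seasonality, grid),
    cv_precip_seasonality = focal_cv(env$precip_seasonality, grid),
    cv_mat = focal_cv(env$mat, grid),
    cv_map = focal_cv(env$map, grid),
    tri = terrain_ruggedness(env$elevation, grid),
    velocity = suppressMessages(
      climate_velocity(env$temp_present, env$temp_lgm, grid))
  )
}
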