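label_vector <- function(x, level = c("region", "realm")) {
  level <- match.arg(level)
  if (inherits(x, "pr_labeling")) {
    if (level == "realm") {
      if (is.null(x$realm_of_region))
        pr_stop("labeling has no realm level", "invalid_argument")
      rl <- x$realm_of_region
      idx <- if (is.null(names(rl))) as.integer(x$region)
             else as.character(x$region)
      setNames(unname(rl[idx]), names(x$region))
    } else x$region
  } else x # plain named vector
}

#' V-measure association between two regionalization schemes
#'
#' Entropy-based comparison of two partitions of the same cells. From the
#' cell-count contingency table (equal cell weights on an equal-area grid):
#' homogeneity `h = 1 - H(A|B)/H(A)`, completeness `c = 1 - H(B|A)/H(B)`
#' (1 when the conditioning entropy is 0), and `V = 2hc/(h+c)` — 0 for no
#' association, 1 for identical partitions. Natural-log entropies; invariant
#' to region relabeling and symmetric up to swapping h and c.
#'
#' @param A,B `pr_labeling`s or named label vectors on the same cells.
#' @return List with `h`, `c`, `V`.
#' @export
v_measure <- function(A, B) {
  a <- label_vector(A); b <- label_vector(B)
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      pr_stop("schemes are defined on different cell sets", "invalid_argument")
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    pr_stop("schemes are defined on different cell sets", "invalid_argument")
  }
  n <- length(a)
  tab <- table(a, b)
  p <- tab / n
  ent <- function(pv) { pv <- pv[pv > 0]; -sum(pv * log(pv)) }
  HA <- ent(rowSums(p)); HB <- ent(colSums(p))
  # H(A|B) = -sum p(a,b) log p(a,b)/p(b)
  cond <- function(p, margin) {
    pm <- if (margin == 2) colSums(p) else rowSums(p)
    tot <- 0
    for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) {
        pj <- if (margin == 2) pm[j] else pm[i]
        tot <- tot - p[i, j] * log(p[i, j] / pj)
      }
    }
    tot
  }
  HAgB <- cond(p, 2); HBgA <- cond(p, 1)
  h <- unname(if (HA == 0) 1 else 1 - HAgB / HA)
  cc <- unname(if (HB == 0) 1 else 1 - HBgA / HB)
  V <- if (h + cc > 0) 2 * h * cc / (h + cc) else 0
  list(h = h, c = cc, V = V)
}

#' Random Voronoi regionalization of a grid
#'
#' Null-model scheme generator: samples `k` land cells uniformly without
#' replacement as Voronoi seeds and assigns every land cell to the nearest
#' seed by planar centroid distance (discrete Voronoi tessellation clipped to
#' the land mask); distance ties go to the lowest seed index.
#'
#' @param grid A grid.
#' @param k Number of regions.
#' @param seed RNG seed.
#' @return A `pr_labeling` with regions `1..k`.
#' @export
random_voronoi_labeling <- function(grid, k, seed = 1) {
  k <- pr_check_count(k, "k")
  li <- land_indices(grid)
  if (k > length(li))
    pr_stop("k exceeds the number of land cells", "invalid_argument")
  set.seed(seed)
  seeds <- sample(li, k)
  x <- grid$cells$x[li]; y <- grid$cells$y[li]
  sx <- grid$cells$x[seeds]; sy <- grid$cells$y[seeds]
  d2 <- outer(x, sx, "-")^2 + outer(y, sy, "-")^2
  lab <- apply(d2, 1, which.min) # first minimum = lowest seed index
  structure(list(region = setNames(lab, grid$cells$cell[li]),
                 realm_of_region = NULL, scheme = "voronoi-null"),
            class = "pr_labeling")
}

#' V-measure with a Voronoi-null Monte Carlo test
#'
#' Compares the observed V-measure of schemes A and B with the distribution
#' of V(A, null) over `n_null` random Voronoi schemes with the same number of
#' regions as B. The p-value uses the add-one permutation estimator
#' `p = (1 + #\{V_null >= V_obs\}) / (n_null + 1)`.
#'
#' @param A,B Labelings on the grid's land cells.
#' @param grid The common grid.
#' @param n_null Number of null schemes (default 999).
#' @param seed RNG seed; null i uses `seed + i - 1`.
#' @return List `h`, `c`, `V`, `p` (and `null_V`); `p` absent if
#'   `n_null = 0`.
#' @export
v_measure_test <- function(A, B, grid, n_null = 999, seed = 1) {
  obs <- v_measure(A, B)
  if (n_null == 0) return(obs)
  kB <- length(unique(label_vector(B)))
  nullV <- vapply(seq_len(n_null), function(i) {
    v_measure(A, random_voronoi_labeling(grid, kB, seed + i - 1))$V
  }, numeric(1))
  obs$p <- (1 + sum(nullV >= obs$V)) / (n_null + 1)
  obs$null_V <- nullV
  obs
}

#' Distance of each cell to the nearest region boundary
#'
#' Boundary cells are cells with at least one queen neighbour carrying a
#' different label at the requested level; every cell's boundary distance is
#' the planar centroid distance to the nearest boundary cell (0 on the
#' boundary itself).
#'
#' @param labels A `pr_labeling` (or named label vector) on the grid.
#' @param grid The grid.
#' @param level `"region"` or `"realm"`.
#' @return Named numeric vector of distances in km over land cells.
#' @export
boundary_distance <- function(labels, grid, level = "region") {
  lab <- label_vector(labels, level)
  li <- land_indices(grid)
  lab <- lab[grid$cells$cell[li]]
  pos <- setNames(seq_along(li), as.character(li))
  is_bnd <- vapply(seq_along(li), function(p) {
    any(lab[pos[as.character(grid$adj[[li[p]]])]] != lab[p])
  }, logical(1))
  if (!any(is_bnd))
    pr_stop("single-label scheme has no boundary", "no_boundary")
  x <- grid$cells$x[li]; y <- grid$cells$y[li]
  bx <- x[is_bnd]; by <- y[is_bnd]
  d <- sqrt(outer(x, bx, "-")^2 + outer(y, by, "-")^2)
  setNames(apply(d, 1, min), names(lab))
}

#' Log-transform boundary distances
#'
#' Convenience helper `log(d + cell_km/2)`: the half-cell offset keeps
#' boundary cells (distance 0) finite on the log scale.
#'
#' @param d Distances in km.
#' @param cell_km Cell size.
#' @export
log_boundary_distance <- function(d, cell_km = 100) log(d + cell_km / 2)

#' Modified t-test for correlation between spatial processes
#'
#' Tests the Pearson correlation of two variables observed on the same grid
#' cells while correcting for spatial autocorrelation, in the spirit of the
#' Clifford–Richardson distance-class estimator: pairwise distances are
#' binned into `n_classes` equal-width classes up to half the maximum
#' pairwise distance, per-class autocorrelations of each variable estimated
#' by moment, and the effective sample size
#' `M = 1 + 1/var_hat(r)` with
#' `var_hat(r) = 1/n + (2/n^2) * sum_k N_k rho_x(k) rho_y(k)` (clamped to
#' \[3, n\]). The test statistic is `t = r sqrt((M-2)/(1-r^2))` on `M - 2`
#' degrees of freedom. Callers comparing boundary distances should pass
#' [log_boundary_distance()]-transformed values.
#'
#' @param x,y Numeric vectors over the grid's land cells (named or in land
#'   order).
#' @param grid The grid.
#' @param n_classes Number of distance classes (default 10).
#' @return List `r`, `M`, `t`, `p` (two-sided).
#' @export
modified_t_test <- function(x, y, grid, n_classes = 10) {
  li <- land_indices(grid)
  cells <- grid$cells[li, ]
  if (!is.null(names(x))) x <- x[cells$cell]
  if (!is.null(names(y))) y <- y[cells$cell]
  n <- length(li)
  if (length(x) != n || length(y) != n || anyNA(x) || anyNA(y))
    pr_stop("x and y must be finite over all land cells", "invalid_argument")
  if (n < 10) pr_stop("need at least 10 cells", "invalid_argument")
  if (sd(x) == 0 || sd(y) == 0)
    pr_stop("zero variance", "undefined_correlation")
  r <- cor(x, y)
  dx <- outer(cells$x, cells$x, "-"); dy <- outer(cells$y, cells$y, "-")
  dmat <- sqrt(dx^2 + dy^2)
  ut <- upper.tri(dmat)
  dv <- dmat[ut]
  dmax <- max(dv) / 2
  cls <- findInterval(dv, seq(0, dmax, length.out = n_classes + 1),
                      rightmost.closed = TRUE)
  keep <- cls >= 1 & cls <= n_classes
  xc <- x - mean(x); yc <- y - mean(y)
  sx2 <- mean(xc^2); sy2 <- mean(yc^2)
  px <- outer(xc, xc)[ut]; py <- outer(yc, yc)[ut]
  varr <- 1 / n
  for (k in seq_len(n_classes)) {
    sel <- keep & cls == k
    Nk <- sum(sel)
    if (Nk > 0) {
      rx <- mean(px[sel]) / sx2
      ry <- mean(py[sel]) / sy2
      varr <- varr + (2 / n^2) * Nk * rx * ry
    }
  }
  varr <- max(varr, 1e-12)
  M <- 1 + 1 / varr
  M <- min(max(M, 3), n)
  if (M <= 2) pr_stop("degenerate degrees of freedom", "degenerate_df")
  tt <- r * sqrt((M - 2) / max(1 - r^2, 1e-12))
  p <- 2 * pt(-abs(tt), df = M - 2)
  list(r = r, M = M, t = tt, p = p)
}
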