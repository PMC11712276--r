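#' Presence/absence community matrices
#'
#' A community matrix is a sparse binary cells x species incidence matrix
#' aligned to a [build_grid()] grid: rows are land-cell ids in grid order,
#' columns are species ids. Constructed from a sparse/dense matrix, from
#' range geometries via [rasterize_ranges()], or from disk via
#' [load_community()].
#'
#' @param m A binary matrix or `Matrix::sparseMatrix` with dimnames
#'   (cells, species).
#' @param drop_empty_species Drop species with no presences (with a warning)
#'   instead of erroring.
#' @return An object of class `pr_community`: a `dgCMatrix` with attribute
#'   checks applied (entries in \{0,1\}, no all-zero species).
#' @export
community_matrix <- function(m, drop_empty_species = TRUE) {
  m <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "dMatrix"),
                   "CsparseMatrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    pr_stop("community matrix needs cell rownames and species colnames",
            "invalid_argument")
  if (length(m@x) && !all(m@x %in% c(0, 1)))
    pr_stop("community matrix entries must be 0/1", "nonbinary_community")
  m <- Matrix::drop0(m)
  cs <- Matrix::colSums(m)
  if (any(cs == 0)) {
    if (!drop_empty_species)
      pr_stop("species with zero presences", "empty_species")
    warning(sprintf("dropping %d species with zero presences", sum(cs == 0)))
    m <- m[, cs > 0, drop = FALSE]
  }
  if (ncol(m) == 0)
    pr_stop("no species retained in community", "empty_community")
  class(m) <- class(m) # keep dgCMatrix; tag via attr
  attr(m, "pr_community") <- TRUE
  m
}

is_community <- function(x) isTRUE(attr(x, "pr_community"))

# ray-casting point-in-polygon; polygon is a 2-column matrix, open or closed
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) { poly <- poly[-n, , drop = FALSE]; n <- n - 1L }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

segments_intersect <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2); d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c)
    d(a, b, c) == 0 && min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
    min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  on_seg(q1, q2, p1) || on_seg(q1, q2, p2) || on_seg(p1, p2, q1) || on_seg(p1, p2, q2)
}

# does a polygon overlap the axis-aligned square [x0,x1] x [y0,y1]?
polygon_overlaps_cell <- function(poly, x0, x1, y0, y1) {
  # vertex inside cell
  if (any(poly[, 1] >= x0 & poly[, 1] <= x1 & poly[, 2] >= y0 & poly[, 2] <= y1))
    return(TRUE)
  # cell corner inside polygon
  cx <- c(x0, x1, x1, x0); cy <- c(y0, y0, y1, y1)
  if (any(point_in_polygon(cx, cy, poly))) return(TRUE)
  # edge crossings
  n <- nrow(poly)
  if (!all(poly[1, ] == poly[n, ])) poly <- rbind(poly, poly[1, ])
  corners <- cbind(c(cx, cx[1]), c(cy, cy[1]))
  for (i in seq_len(nrow(poly) - 1)) {
    for (j in 1:4) {
      if (segments_intersect(poly[i, ], poly[i + 1, ],
                             corners[j, ], corners[j + 1, ])) return(TRUE)
    }
  }
  FALSE
}

#' Rasterize species ranges onto a grid
#'
#' Stacks per-species range geometries into a presence/absence community
#' matrix. A species is present in a cell if its polygon overlaps the cell
#' square at all (any overlap, not centroid-in-polygon) or if at least one of
#' its points falls inside the cell. Species with no presences on the grid are
#' dropped with a warning, mirroring real workflows where ranges fall outside
#' the study grid.
#'
#' @param ranges A named list, one element per species: either a 2-column
#'   matrix of polygon vertices (x, y in km; closed or open ring) wrapped as
#'   `list(polygon = m)`, or `list(points = m)` with a 2-column matrix of
#'   occurrence points.
#' @param grid A [build_grid()] grid.
#' @return A `pr_community` matrix over the grid's land cells.
#' @export
rasterize_ranges <- function(ranges, grid) {
  if (!length(ranges) || is.null(names(ranges)))
    pr_stop("`ranges` must be a non-empty named list", "invalid_argument")
  li <- land_indices(grid)
  cells <- grid$cells[li, ]
  h <- grid$cell_km / 2
  trip_i <- integer(0); trip_j <- integer(0)
  for (s in seq_along(ranges)) {
    r <- ranges[[s]]
    pres <- logical(nrow(cells))
    if (!is.null(r$polygon)) {
      poly <- as.matrix(r$polygon)
      xr <- range(poly[, 1]); yr <- range(poly[, 2])
      cand <- which(cells$x + h >= xr[1] & cells$x - h <= xr[2] &
                    cells$y + h >= yr[1] & cells$y - h <= yr[2])
      for (k in cand) {
        pres[k] <- polygon_overlaps_cell(poly, cells$x[k] - h, cells$x[k] + h,
                                         cells$y[k] - h, cells$y[k] + h)
      }
    } else if (!is.null(r$points)) {
      pts <- as.matrix(r$points)
      ix <- ceiling(pts[, 1] / grid$cell_km)
      iy <- ceiling(pts[, 2] / grid$cell_km)
      ok <- ix >= 1 & ix <= grid$nx & iy >= 1 & iy <= grid$ny
      if (any(ok)) {
        flat <- (iy[ok] - 1) * grid$nx + ix[ok]
        pres[match(flat, li, nomatch = 0)] <- TRUE
        pres <- pres[seq_len(nrow(cells))]
      }
    } else {
      pr_stop("each range needs a $polygon or $points entry", "invalid_argument")
    }
    w <- which(pres)
    trip_i <- c(trip_i, w); trip_j <- c(trip_j, rep(s, length(w)))
  }
  if (!length(trip_i))
    pr_stop("no species retained: all ranges fall outside the grid",
            "empty_community")
  m <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = 1,
                            dims = c(nrow(cells), length(ranges)),
                            dimnames = list(cells$cell, names(ranges)))
  community_matrix(m)
}

#' Read and write community matrices
#'
#' Two lossless on-disk formats: a triplet CSV with columns
#' `cell,species,value` (value must be 1) plus a header row, and MatrixMarket
#' (`.mtx`) with sidecar `<path>.rows` / `<path>.cols` name files. Duplicate
#' (cell, species) entries and non-binary values are rejected.
#'
#' @param cm A `pr_community`.
#' @param path Output path.
#' @param format `"triplet-csv"` or `"mtx"`.
#' @return `load_community` returns a `pr_community`.
#' @export
write_community <- function(cm, path, format = c("triplet-csv", "mtx")) {
  format <- match.arg(format)
  if (format == "triplet-csv") {
    tm <- methods::as(cm, "TsparseMatrix")
    df <- data.frame(cell = rownames(cm)[tm@i + 1L],
                     species = colnames(cm)[tm@j + 1L],
                     value = 1L)
    df <- df[order(match(df$cell, rownames(cm)), match(df$species, colnames(cm))), ]
    write.csv(df, path, row.names = FALSE)
  } else {
    Matrix::writeMM(methods::as(cm, "generalMatrix"), path)
    writeLines(rownames(cm), paste0(path, ".rows"))
    writeLines(colnames(cm), paste0(path, ".cols"))
  }
  invisible(path)
}

#' @rdname write_community
#' @param cells,species Optional canonical orderings; for `"triplet-csv"`
#'   defaults to first-appearance order in the file.
#' @export
load_community <- function(path, format = c("triplet-csv", "mtx"),
                           cells = NULL, species = NULL) {
  format <- match.arg(format)
  if (format == "triplet-csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("cell", "species", "value") %in% names(df)))
      pr_stop("triplet CSV needs cell,species,value columns", "parse_error")
    if (!all(df$value == 1))
      pr_stop("triplet CSV values must all be 1", "parse_error")
    if (anyDuplicated(df[c("cell", "species")]))
      pr_stop("duplicate (cell, species) entries", "parse_error")
    if (is.null(cells)) cells <- unique(df$cell)
    if (is.null(species)) species <- unique(df$species)
    i <- match(df$cell, cells); j <- match(df$species, species)
    if (anyNA(i) || anyNA(j))
      pr_stop("cell or species id outside the declared ordering", "parse_error")
    m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(length(cells), length(species)),
                              dimnames = list(cells, species))
  } else {
    m <- Matrix::readMM(path)
    if (methods::is(m, "nMatrix")) { # pattern MTX: all entries are 1
      m <- methods::as(m, "dMatrix")
    }
    m <- methods::as(m, "CsparseMatrix")
    if (length(m@x) && !all(m@x %in% c(0, 1)))
      pr_stop("MTX community must be binary", "parse_error")
    rn <- readLines(paste0(path, ".rows")); cn <- readLines(paste0(path, ".cols"))
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      pr_stop("MTX sidecar name files do not match matrix extent", "parse_error")
    dimnames(m) <- list(rn, cn)
  }
  community_matrix(m)
}
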