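#' Build an equal-area grid of square cells
#'
#' Constructs the spatial backbone of the pipeline: a regular lattice of
#' square cells in an abstract equal-area plane, with centroid coordinates in
#' km, an optional land mask, and queen (8-neighbour) adjacency among land
#' cells. Real-data users are expected to pre-project ranges to an equal-area
#' plane (e.g. Mollweide) so that planar km distances are meaningful.
#'
#' @param nx,ny Number of columns and rows of the lattice.
#' @param cell_km Cell edge length in km (default 100, i.e. a
#'   100 km x 100 km grid).
#' @param land_mask Optional logical matrix of dimension `nx` x `ny`
#'   (`land_mask[i, j]` is column i, row j); `TRUE` marks land. All cells are
#'   land if omitted.
#' @return An object of class `pr_grid`: a list with `cells` (data.frame with
#'   `cell`, `ix`, `iy`, `x`, `y`, `is_land`), `cell_km`, `nx`, `ny`, and
#'   `adj`, a list mapping each land cell to the integer indices (into
#'   `cells`) of its land queen neighbours.
#' @examples
#' g <- build_grid(3, 3)
#' length(g$adj[[5]]) # centre cell has 8 neighbours
#' @export
build_grid <- function(nx, ny, cell_km = 100, land_mask = NULL) {
  nx <- pr_check_count(nx, "nx"); ny <- pr_check_count(ny, "ny")
  if (!is.numeric(cell_km) || cell_km <= 0)
    pr_stop("`cell_km` must be a positive length in km", "invalid_argument")
  if (is.null(land_mask)) {
    land_mask <- matrix(TRUE, nx, ny)
  } else {
    land_mask <- as.matrix(land_mask)
    if (!identical(dim(land_mask), c(nx, ny)))
      pr_stop(sprintf("land_mask must be %d x %d", nx, ny), "invalid_argument")
    mode(land_mask) <- "logical"
  }
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  w <- max(4L, nchar(as.character(nx * ny)))
  cells <- data.frame(
    cell = sprintf(paste0("c%0", w, "d"), seq_len(nx * ny)),
    ix = ix, iy = iy,
    x = (ix - 0.5) * cell_km,
    y = (iy - 0.5) * cell_km,
    is_land = land_mask[cbind(ix, iy)],
    stringsAsFactors = FALSE
  )
  idx <- matrix(seq_len(nx * ny), nx, ny)
  land <- cells$is_land
  off <- expand.grid(dx = -1:1, dy = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0), ]
  adj <- vector("list", nx * ny)
  for (c0 in which(land)) {
    i <- ix[c0]; j <- iy[c0]
    nb <- integer(0)
    for (r in seq_len(nrow(off))) {
      ii <- i + off$dx[r]; jj <- j + off$dy[r]
      if (ii >= 1 && ii <= nx && jj >= 1 && jj <= ny) {
        k <- idx[ii, jj]
        if (land[k]) nb <- c(nb, k)
      }
    }
    adj[[c0]] <- sort(nb)
  }
  structure(list(cells = cells, cell_km = cell_km, nx = nx, ny = ny,
                 adj = adj),
            class = "pr_grid")
}

#' @export
print.pr_grid <- function(x, ...) {
  cat(sprintf("pr_grid: %d x %d cells (%g km), %d land\n",
              x$nx, x$ny, x$cell_km, sum(x$cells$is_land)))
  invisible(x)
}

# integer indices of land cells, in cells-table order
land_indices <- function(grid) which(grid$cells$is_land)

#' Land cell ids of a grid, in canonical order
#'
#' The row ordering used by every community matrix and layer on the grid.
#'
#' @param grid A `pr_grid`.
#' @return Character vector of cell ids.
#' @export
land_cells <- function(grid) grid$cells$cell[grid$cells$is_land]

#' Write / read a grid as CSV
#'
#' @param grid A `pr_grid`.
#' @param path File path.
#' @return `read_grid` returns a `pr_grid` rebuilt from the table.
#' @export
write_grid <- function(grid, path) {
  df <- grid$cells[, c("cell", "x", "y", "is_land")]
  df$cell_km <- grid$cell_km
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  cell_km <- df$cell_km[1]
  nx <- round(max(df$x) / cell_km + 0.5)
  ny <- round(max(df$y) / cell_km + 0.5)
  mask <- matrix(FALSE, nx, ny)
  ix <- round(df$x / cell_km + 0.5); iy <- round(df$y / cell_km + 0.5)
  mask[cbind(ix, iy)] <- df$is_land
  build_grid(nx, ny, cell_km, mask)
}
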