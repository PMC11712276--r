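#' Hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering under one of the eight conventional linkage
#' criteria. Names map onto `stats::hclust` methods: UPGMA = "average",
#' WPGMA = "mcquitty", UPGMC = "centroid", WPGMC = "median",
#' ward = "ward.D", ward2 = "ward.D2", plus "single" and "complete".
#' The centroid/median criteria are not monotone and may produce height
#' inversions; cuts are defined by cluster count, not height, so inversions
#' are tolerated (and reported via a message).
#'
#' @param D Symmetric dissimilarity matrix (or `dist`).
#' @param method One of `"UPGMA"`, `"WPGMA"`, `"UPGMC"`, `"WPGMC"`,
#'   `"single"`, `"complete"`, `"ward"`, `"ward2"`.
#' @return An `hclust` dendrogram.
#' @export
linkage_dendrogram <- function(D, method = "UPGMA") {
  hm <- linkage_methods()[method][[1]]
  if (is.null(hm) || is.na(hm))
    pr_stop(sprintf("unknown linkage method '%s'", method), "invalid_argument")
  d <- as.dist(D)
  if (attr(d, "Size") < 2) pr_stop("need at least 2 cells", "invalid_argument")
  h <- hclust(d, method = hm)
  if (is.unsorted(h$height))
    message(sprintf("linkage '%s' produced height inversions (non-monotone method)",
                    method))
  h
}

linkage_methods <- function() {
  c(UPGMA = "average", WPGMA = "mcquitty", UPGMC = "centroid",
    WPGMC = "median", single = "single", complete = "complete",
    ward = "ward.D", ward2 = "ward.D2")
}

#' Cophenetic correlation of a dendrogram
#'
#' Pearson correlation between the original pairwise dissimilarities and the
#' cophenetic distances implied by the dendrogram — how faithfully the tree
#' preserves the Simpson distances.
#'
#' @param dend An `hclust` object over `D`'s cells.
#' @param D The dissimilarity matrix the dendrogram was built from.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
cophenetic_correlation <- function(dend, D) {
  x <- as.vector(as.dist(D))
  y <- as.vector(cophenetic(dend))
  if (sd(x) == 0 || sd(y) == 0)
    pr_stop("zero variance: cophenetic correlation undefined",
            "undefined_correlation")
  cor(x, y)
}

#' Select the best linkage method by cophenetic correlation
#'
#' Builds a dendrogram under each candidate linkage and returns the method
#' whose cophenetic distances correlate best with the input dissimilarities;
#' ties go to the first method in the canonical order (UPGMA, WPGMA, UPGMC,
#' WPGMC, single, complete, ward, ward2).
#'
#' @param D Dissimilarity matrix.
#' @param methods Character vector of linkage names (default: all eight).
#' @return List with `best` (method name), `coefficients` (named vector) and
#'   `dendrogram` (the winning `hclust`).
#' @export
select_linkage <- function(D, methods = names(linkage_methods())) {
  if (!length(methods)) pr_stop("no methods supplied", "invalid_argument")
  methods <- methods[order(match(methods, names(linkage_methods())))]
  cc <- vapply(methods, function(m) {
    tryCatch(
      cophenetic_correlation(suppressMessages(linkage_dendrogram(D, m)), D),
      undefined_correlation = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(cc)))
    pr_stop("cophenetic correlation undefined for every method",
            "undefined_correlation")
  best <- methods[which.max(cc)] # first maximum; NAs never win
  list(best = best, coefficients = cc,
       dendrogram = suppressMessages(linkage_dendrogram(D, best)))
}

#' Explained variance of a partition of a dissimilarity matrix
#'
#' The fraction of total pairwise dissimilarity falling between clusters:
#' `ev = 1 - sum(within-cluster d) / sum(all d)`. Raw (not squared)
#' dissimilarities are the pinned default; set `squared = TRUE` for the
#' sum-of-squares variant. By construction ev = 0 for one cluster and 1 for
#' singletons, and ev is non-decreasing along refinements.
#'
#' @param D Dissimilarity matrix.
#' @param labels Cluster label per cell (any atomic type), cells in `D` order.
#' @param squared Use squared dissimilarities.
#' @return Fraction in \[0, 1\].
#' @export
explained_variance <- function(D, labels, squared = FALSE) {
  D <- as.matrix(D)
  if (length(labels) != nrow(D))
    pr_stop("labels must cover all cells of D", "invalid_argument")
  if (squared) D <- D^2
  tot <- sum(D[upper.tri(D)])
  if (tot == 0) pr_stop("all dissimilarities zero: ev undefined", "invalid_argument")
  same <- outer(labels, labels, "==")
  within <- sum(D[same & upper.tri(D)])
  1 - within / tot
}

#' Elbow selection of the number of regions
#'
#' Computes explained variance along dendrogram cuts k = 1..k_max and picks
#' the elbow: the k maximizing the perpendicular distance from (k, ev(k)) to
#' the chord joining (1, ev(1)) and (k_max, ev(k_max)); ties go to the
#' smallest k (parsimony).
#'
#' @param dend `hclust` dendrogram.
#' @param D Dissimilarity matrix it was built from.
#' @param k_max Largest cluster count to examine (2..n).
#' @return List with `ev` (named vector over k), `k_opt`.
#' @export
optimal_k <- function(dend, D, k_max = 30) {
  n <- nrow(as.matrix(D))
  k_max <- pr_check_count(k_max, "k_max", 2L)
  if (k_max > n) pr_stop("k_max exceeds the number of cells", "invalid_argument")
  ks <- seq_len(k_max)
  ev <- vapply(ks, function(k) explained_variance(D, cutree(dend, k = k)),
               numeric(1))
  x1 <- 1; y1 <- ev[1]; x2 <- k_max; y2 <- ev[k_max]
  # perpendicular distance from each (k, ev) to the chord
  num <- abs((y2 - y1) * ks - (x2 - x1) * ev + x2 * y1 - y2 * x1)
  dd <- num / sqrt((y2 - y1)^2 + (x2 - x1)^2)
  # endpoints always sit on the chord; the elbow is an interior point
  # (k_max = 2 leaves no interior and forces k = 2)
  cand <- if (k_max == 2) 2L else 2:(k_max - 1L)
  k_opt <- cand[which.max(dd[cand])] # first max = smallest k on ties
  list(ev = setNames(ev, ks), k_opt = k_opt)
}

#' Cut a dendrogram into regions or realms
#'
#' `cut_regions` returns the k-cluster cut. `cut_realms` cuts at the smallest
#' k' whose explained variance reaches `threshold` (default 0.60 — the
#' variance-preservation rule used to delimit realms), so realms from the
#' same dendrogram always nest the finer region cut.
#'
#' @param dend `hclust` dendrogram.
#' @param k Number of regions.
#' @param scheme Name recorded on the labeling.
#' @return A `pr_labeling`: list with `region` (named integer per cell),
#'   optional `realm_of_region`, and `scheme`.
#' @export
cut_regions <- function(dend, k, scheme = "regions") {
  k <- pr_check_count(k, "k")
  lab <- cutree(dend, k = k)
  structure(list(region = lab, realm_of_region = NULL, scheme = scheme),
            class = "pr_labeling")
}

#' @rdname cut_regions
#' @param D Dissimilarity matrix (needed for the variance threshold).
#' @param threshold Fraction of variance the realm cut must preserve.
#' @export
cut_realms <- function(dend, D, threshold = 0.60, scheme = "realms") {
  if (threshold <= 0 || threshold >= 1)
    pr_stop("threshold must be in (0, 1)", "invalid_argument")
  n <- length(dend$order)
  for (k in seq_len(n)) {
    if (explained_variance(D, cutree(dend, k = k)) >= threshold) {
      return(cut_regions(dend, k, scheme))
    }
  }
  warning("variance threshold unreachable below n; returning singletons")
  cut_regions(dend, n, scheme)
}

#' Attach a realm cut to a finer region labeling
#'
#' Maps each region of the finer cut to the realm that contains its cells;
#' cuts of the same dendrogram guarantee every region lies wholly inside one
#' realm.
#'
#' @param regions,realms `pr_labeling`s from the same dendrogram.
#' @return `regions` with `realm_of_region` filled in (named by region id).
#' @export
nest_realms <- function(regions, realms) {
  rl <- vapply(split(realms$region[names(regions$region)], regions$region),
               function(v) {
                 u <- unique(v)
                 if (length(u) > 1)
                   pr_stop("realm cut does not nest the region cut",
                           "invalid_argument")
                 u
               }, numeric(1))
  regions$realm_of_region <- rl
  regions
}

#' Evolutionary distinctiveness of regions
#'
#' ED of a region is the mean over all other regions of the mean pairwise
#' dissimilarity between the two regions' cells (mean of between-region
#' means, unweighted by region size; set `weighted = TRUE` to weight by cell
#' counts).
#'
#' @param D Dissimilarity matrix.
#' @param labels Region label per cell (in `D` order).
#' @param weighted Weight the outer mean by the other regions' cell counts.
#' @return Named numeric vector of per-region ED in \[0, 1\].
#' @export
evolutionary_distinctiveness <- function(D, labels, weighted = FALSE) {
  D <- as.matrix(D)
  regs <- sort(unique(labels))
  if (length(regs) < 2)
    pr_stop("ED needs at least 2 regions", "invalid_argument")
  idx <- split(seq_along(labels), labels)
  cross <- function(r, q) mean(D[idx[[as.character(r)]], idx[[as.character(q)]]])
  vapply(regs, function(r) {
    others <- setdiff(regs, r)
    m <- vapply(others, cross, numeric(1), r = r)
    if (weighted) {
      w <- lengths(idx[as.character(others)])
      sum(m * w) / sum(w)
    } else mean(m)
  }, numeric(1)) -> ed
  setNames(ed, regs)
}

#' Per-region diversity and endemism summaries
#'
#' For each region: species richness SR (size of the union of species over
#' the region's cells); Faith's PD (summed length of the branches subtending
#' that union, computed region-level); mean weighted endemism (per-cell
#' WE = sum over the cell's species of 1/range size, averaged over the
#' region's cells); mean phylogenetic endemism (per-cell PE = sum over the
#' cell's branches of length/branch range size, averaged likewise); and ED
#' from `D` if supplied. WE and PE telescope: summing the per-cell values
#' over all cells returns the total species count and total tree length.
#'
#' @param cm Community matrix.
#' @param tree Phylogeny covering the community's species.
#' @param labels Region label per cell, named by cell id or in `cm` row
#'   order.
#' @param D Optional dissimilarity matrix for the ED column.
#' @return A data.frame with one row per region: `region`, `n_cells`, `SR`,
#'   `PD`, `mean_WE`, `mean_PE` (and `ED`).
#' @export
region_diversity <- function(cm, tree, labels, D = NULL) {
  if (!is.null(names(labels))) labels <- labels[rownames(cm)]
  if (length(labels) != nrow(cm))
    pr_stop("labels must align with community cells", "invalid_argument")
  bi <- branch_incidence(cm, tree)
  inc <- bi$incidence; len <- bi$lengths
  sp_range <- Matrix::colSums(cm)
  br_range <- Matrix::colSums(inc)
  we_cell <- as.numeric(cm %*% (1 / sp_range))
  pe_cell <- as.numeric(inc %*% (len / br_range))
  regs <- sort(unique(labels))
  out <- lapply(regs, function(r) {
    rows <- which(labels == r)
    sp <- Matrix::colSums(cm[rows, , drop = FALSE]) > 0
    br <- Matrix::colSums(inc[rows, , drop = FALSE]) > 0
    data.frame(region = r, n_cells = length(rows),
               SR = sum(sp), PD = sum(len[br]),
               mean_WE = mean(we_cell[rows]), mean_PE = mean(pe_cell[rows]))
  })
  out <- do.call(rbind, out)
  if (!is.null(D)) out$ED <- unname(evolutionary_distinctiveness(D, labels)[as.character(regs)])
  rownames(out) <- NULL
  out
}

#' Per-cell weighted and phylogenetic endemism
#'
#' @inheritParams region_diversity
#' @return Data frame `cell`, `WE`, `PE`.
#' @export
cell_endemism <- function(cm, tree) {
  bi <- branch_incidence(cm, tree)
  data.frame(cell = rownames(cm),
             WE = as.numeric(cm %*% (1 / Matrix::colSums(cm))),
             PE = as.numeric(bi$incidence %*%
                               (bi$lengths / Matrix::colSums(bi$incidence))),
             stringsAsFactors = FALSE)
}

#' NMDS ordination of regions
#'
#' Non-metric multidimensional scaling (Kruskal stress-1, monotone
#' regression, metric-MDS start) of the region x region matrix of mean
#' between-region dissimilarities, for visualizing relationships among
#' regions.
#'
#' @param D Cell-level dissimilarity matrix.
#' @param labels Region labels per cell.
#' @param seed RNG seed (the fit itself is deterministic from the metric
#'   start; the seed is set for reproducibility of any tie handling).
#' @param maxit Maximum iterations.
#' @return List with `coords` (regions x 2) and `stress` (Kruskal stress-1,
#'   fraction).
#' @export
ordinate_regions <- function(D, labels, seed = 1, maxit = 500) {
  D <- as.matrix(D)
  regs <- sort(unique(labels))
  if (length(regs) < 3)
    pr_stop("NMDS needs at least 3 regions", "invalid_argument")
  idx <- split(seq_along(labels), labels)
  k <- length(regs)
  M <- matrix(0, k, k, dimnames = list(regs, regs))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    M[i, j] <- M[j, i] <- mean(D[idx[[as.character(regs[i])]],
                                 idx[[as.character(regs[j])]]])
  }
  set.seed(seed)
  fit <- vegan::monoMDS(as.dist(M), k = 2, model = "global",
                        maxit = maxit, smin = 1e-7, sratmax = 1 - 1e-7)
  coords <- fit$points
  rownames(coords) <- as.character(regs)
  list(coords = coords, stress = fit$stress)
}

#' Write / read a region labeling as CSV
#'
#' Columns `cell,region[,realm]`.
#'
#' @param labeling A `pr_labeling`.
#' @param path File path.
#' @export
write_labeling <- function(labeling, path) {
  df <- data.frame(cell = names(labeling$region),
                   region = unname(labeling$region))
  if (!is.null(labeling$realm_of_region))
    df$realm <- unname(labeling$realm_of_region[as.character(df$region)])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labeling
#' @export
read_labeling <- function(path, scheme = basename(path)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lab <- setNames(df$region, df$cell)
  rl <- NULL
  if ("realm" %in% names(df)) {
    rl <- vapply(split(df$realm, df$region), function(v) unique(v)[1], df$realm[1])
  }
  structure(list(region = lab, realm_of_region = rl, scheme = scheme),
            class = "pr_labeling")
}
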