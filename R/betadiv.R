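#' Simpson (turnover-only) beta diversity between grid cells
#'
#' For a pair of cells with `a` shared species and `b`, `c` species unique to
#' each, the Simpson dissimilarity is
#' \deqn{\beta_{sim} = \min(b, c) / (a + \min(b, c)),}
#' the turnover component of beta diversity: insensitive to richness
#' differences, 0 for identical or nested assemblages, 1 for disjoint ones.
#' Computed for all cell pairs via sparse cross-products, never a per-pair
#' loop.
#'
#' @param cm A [community_matrix()] (cells x species, binary). Every cell
#'   must contain at least one species.
#' @return A dense symmetric cells x cells matrix in \[0, 1\] with zero
#'   diagonal and cell dimnames.
#' @export
simpson_beta <- function(cm) {
  rs <- Matrix::rowSums(cm)
  if (any(rs == 0))
    pr_stop(paste("empty cell(s):",
                  paste(rownames(cm)[rs == 0], collapse = ", ")),
            "invalid_community")
  a <- as.matrix(Matrix::tcrossprod(cm))          # shared species counts
  bi <- outer(rs, rs, function(x, y) x) - a        # unique to row cell
  ci <- t(bi)
  m <- pmin(bi, ci)
  d <- m / (a + m)
  d[a + m == 0] <- 0
  diag(d) <- 0
  dimnames(d) <- list(rownames(cm), rownames(cm))
  d
}

#' Branch-level incidence of a community on a phylogeny
#'
#' Maps species incidence to branch incidence: a branch (edge of the tree) is
#' present in a cell iff at least one tip descending from it is present
#' there. The substrate of phylogenetic beta diversity, PD and PE. Species in
#' the community absent from the tree are dropped with a warning; the root
#' has no subtending edge in the representation so no root-edge handling is
#' needed.
#'
#' @param cm A community matrix.
#' @param tree A rooted `phylo` with branch lengths.
#' @return List with `incidence` (sparse cells x branches, branch ids
#'   `"e<k>"` indexing `tree$edge` rows) and `lengths` (named branch
#'   lengths).
#' @export
branch_incidence <- function(cm, tree) {
  common <- intersect(colnames(cm), tree$tip.label)
  if (!length(common))
    pr_stop("no species shared between community and tree", "invalid_argument")
  if (length(common) < ncol(cm))
    warning(sprintf("dropping %d species absent from the tree",
                    ncol(cm) - length(common)))
  cm <- cm[, common, drop = FALSE]
  n_tip <- length(tree$tip.label)
  n_edge <- nrow(tree$edge)
  # tip x edge descendant indicator, built tips-up in postorder
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", n_tip + tree$Nnode) # tips under each node
  for (i in seq_len(n_tip)) desc[[i]] <- i
  for (r in seq_len(nrow(po$edge))) {
    p <- po$edge[r, 1]; ch <- po$edge[r, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  ti <- unlist(lapply(seq_len(n_edge), function(e) desc[[tree$edge[e, 2]]]))
  ei <- rep(seq_len(n_edge),
            vapply(tree$edge[, 2], function(nd) length(desc[[nd]]), integer(1)))
  tipedge <- Matrix::sparseMatrix(i = ti, j = ei, x = 1,
                                  dims = c(n_tip, n_edge))
  sp_idx <- match(common, tree$tip.label)
  inc <- cm %*% tipedge[sp_idx, , drop = FALSE]
  inc@x[inc@x > 0] <- 1
  inc <- Matrix::drop0(inc)
  colnames(inc) <- sprintf("e%d", seq_len(n_edge))
  list(incidence = inc,
       lengths = setNames(tree$edge.length, colnames(inc)))
}

#' Phylogenetic Simpson beta diversity
#'
#' The Simpson dissimilarity computed on shared versus unique branch
#' \emph{lengths} instead of species counts: with `A` the summed length of
#' branches present in both cells and `B`, `C` the lengths unique to each,
#' \deqn{p\beta_{sim} = \min(B, C) / (A + \min(B, C)).}
#' On a star tree with unit pendant branches this reduces exactly to
#' [simpson_beta()].
#'
#' @inheritParams branch_incidence
#' @return Dense symmetric cells x cells matrix in \[0, 1\].
#' @export
phylo_simpson_beta <- function(cm, tree) {
  bi <- branch_incidence(cm, tree)
  inc <- bi$incidence
  len <- bi$lengths
  # A = inc diag(len) inc'
  A <- as.matrix(inc %*% (Matrix::Diagonal(x = len) %*% Matrix::t(inc)))
  tot <- as.numeric(inc %*% len)
  B <- outer(tot, tot, function(x, y) x) - A
  C <- t(B)
  m <- pmin(B, C)
  d <- m / (A + m)
  d[A + m <= 0] <- 0
  d[d < 0] <- 0 # numerical guard
  diag(d) <- 0
  dimnames(d) <- list(rownames(cm), rownames(cm))
  d
}

#' Average phylogenetic dissimilarity over a set of trees
#'
#' Elementwise arithmetic mean of per-tree phylogenetic Simpson matrices,
#' accumulated in streaming fashion so only one matrix is in memory at a
#' time. Used to integrate over the uncertainty of randomly grafted trees.
#'
#' @param trees A `multiPhylo`/list of trees sharing a tip set compatible
#'   with `cm`.
#' @param cm A community matrix.
#' @return Dense symmetric matrix, the mean dissimilarity.
#' @export
mean_dissimilarity <- function(trees, cm) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) pr_stop("empty tree set", "invalid_argument")
  acc <- NULL
  for (tr in trees) {
    d <- phylo_simpson_beta(cm, tr)
    acc <- if (is.null(acc)) d else acc + d
  }
  acc / length(trees)
}
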