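# tip sets of the two daughters of an internal node, in canonical child order
node_daughters <- function(tree, node) {
  n <- length(tree$tip.label)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  if (length(kids) < 2)
    pr_stop("node must have at least two daughters", "invalid_argument")
  desc_tips <- function(nd) {
    out <- integer(0); stack <- nd
    kmap <- split(tree$edge[, 2], tree$edge[, 1])
    while (length(stack)) {
      x <- stack[[1]]; stack <- stack[-1]
      if (x <= n) out <- c(out, x)
      else stack <- c(stack, kmap[[as.character(x)]])
    }
    out
  }
  # canonical order: first two children as stored; a polytomy's extra
  # daughters are pooled into B so every node yields a two-way split
  A <- desc_tips(kids[1])
  B <- unlist(lapply(kids[-1], desc_tips))
  list(A = tree$tip.label[A], B = tree$tip.label[B])
}

# per-cell richness of two species sets, plus permutation machinery.
# The null is always drawn for the canonical first daughter (the set holding
# the lexicographically smallest species id) and each permutation's B-side
# richness is the complement, so SOS is exactly antisymmetric and GND
# exactly invariant under swapping the daughter order.
daughter_richness <- function(cm, A, B) {
  A <- intersect(A, colnames(cm)); B <- intersect(B, colnames(cm))
  if (!length(A) || !length(B))
    pr_stop("a daughter lineage has no species in the community",
            "empty_daughter")
  flipped <- min(B) < min(A)
  if (flipped) { tmp <- A; A <- B; B <- tmp }
  sub <- cm[, c(A, B), drop = FALSE]
  occ <- Matrix::rowSums(sub) > 0
  list(sub = sub[occ, , drop = FALSE], nA = length(A), nB = length(B),
       occupied = rownames(cm)[occ], flipped = flipped)
}

#' Specific overrepresentation scores (SOS) for a node
#'
#' For an internal node with daughter lineages A and B, scores each occupied
#' cell by how over- or under-represented daughter A is relative to a
#' permutation null that reshuffles the A/B labels over the node's species
#' (preserving every species' range and the two clade sizes):
#' `SOS(cell) = (r_A_obs - mean_null) / sd_null`. Positive scores mark cells
#' dominated by daughter A, negative by daughter B; cells where the null is
#' degenerate (sd 0) score 0. Swapping the daughter order negates every
#' score.
#'
#' @param tree Phylogeny.
#' @param cm Community matrix.
#' @param node Internal node id (ape numbering), or `daughters = list(A, B)`
#'   given directly.
#' @param n_perm Number of label permutations (default 100).
#' @param seed RNG seed.
#' @param daughters Optional explicit list with character vectors `A`, `B`.
#' @return List: `node`, `A`, `B`, `sos` (named over occupied cells),
#'   `n_perm`, `seed`.
#' @export
node_sos <- function(tree, cm, node, n_perm = 100, seed = 1, daughters = NULL) {
  if (is.null(daughters)) daughters <- node_daughters(tree, node)
  dr <- daughter_richness(cm, daughters$A, daughters$B)
  sub <- dr$sub
  nA <- dr$nA; nsp <- nA + dr$nB
  rA_obs <- as.numeric(Matrix::rowSums(sub[, seq_len(nA), drop = FALSE]))
  set.seed(seed)
  perm <- matrix(0, nrow(sub), n_perm)
  dense <- as.matrix(sub)
  for (i in seq_len(n_perm)) {
    idx <- sample.int(nsp, nA)
    perm[, i] <- rowSums(dense[, idx, drop = FALSE])
  }
  mu <- rowMeans(perm)
  sdv <- apply(perm, 1, sd)
  sos <- ifelse(sdv == 0, 0, (rA_obs - mu) / sdv)
  if (dr$flipped) sos <- -sos # user's A was the non-canonical daughter
  list(node = node, A = daughters$A, B = daughters$B,
       sos = setNames(sos, rownames(sub)), n_perm = n_perm, seed = seed)
}

#' Geographic node divergence (GND)
#'
#' A 0-1 score of how geographically divergent a node's two daughter
#' lineages are. With `p_A(cell)` the local share of daughter-A richness and
#' `P_A` its global share, the observed divergence is the mean absolute
#' deviation `D_obs = mean |p_A - P_A|` over occupied cells. GND rescales
#' `D_obs` between the expectation under the A/B label permutation null and
#' the maximum attainable deviation `D_max = mean max(P_A, 1 - P_A)`:
#' `GND = clip((D_obs - D_null) / (D_max - D_null), 0, 1)` (0 when
#' `D_max = D_null`). Disjoint daughter ranges approach 1, identically
#' distributed daughters 0.
#'
#' @inheritParams node_sos
#' @return List: `gnd`, `D_obs`, `D_null`, `D_max`.
#' @export
gnd <- function(tree, cm, node, n_perm = 100, seed = 1, daughters = NULL) {
  if (is.null(daughters)) daughters <- node_daughters(tree, node)
  dr <- daughter_richness(cm, daughters$A, daughters$B)
  sub <- dr$sub
  nA <- dr$nA; nsp <- nA + dr$nB
  dense <- as.matrix(sub)
  rtot <- rowSums(dense)
  rA <- rowSums(dense[, seq_len(nA), drop = FALSE])
  PA <- sum(rA) / sum(rtot)
  D_obs <- mean(abs(rA / rtot - PA))
  set.seed(seed)
  Dn <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(nsp, nA)
    rAp <- rowSums(dense[, idx, drop = FALSE])
    PAp <- sum(rAp) / sum(rtot)
    mean(abs(rAp / rtot - PAp))
  }, numeric(1))
  D_null <- mean(Dn)
  D_max <- mean(pmax(PA, 1 - PA))
  g <- if (abs(D_max - D_null) < 1e-12) 0
       else min(max((D_obs - D_null) / (D_max - D_null), 0), 1)
  list(gnd = g, D_obs = D_obs, D_null = D_null, D_max = D_max)
}

#' Indicator clades for realm divisions
#'
#' Screens every internal node of the tree for geographically divergent
#' daughter lineages (GND above `gnd_threshold`, conventionally 0.65); for
#' each retained node and each unordered realm pair, fits ordinary least
#' squares of the node's SOS values on realm membership over the occupied
#' cells of the two realms and records the R-squared together with the two
#' realm mean SOS values. A node is flagged as an indicator for a pair
#' (`included`) when the mean SOS signs differ between the realms — the
#' daughters sort onto opposite sides of that realm boundary.
#'
#' @param tree Phylogeny.
#' @param cm Community matrix.
#' @param labels A `pr_labeling` with realms over the community's cells.
#' @param gnd_threshold GND screening threshold (default 0.65).
#' @param n_perm Permutations for GND/SOS (default 100).
#' @param seed RNG seed.
#' @param min_cells Minimum occupied cells per realm side (rows below it get
#'   `NA` R-squared).
#' @return Data frame: `node`, `gnd`, `realm_a`, `realm_b`, `r2`,
#'   `mean_sos_a`, `mean_sos_b`, `included`.
#' @export
indicator_clades <- function(tree, cm, labels, gnd_threshold = 0.65,
                             n_perm = 100, seed = 1, min_cells = 3) {
  realm <- label_vector(labels, "realm")
  realms <- sort(unique(realm))
  if (length(realms) < 2)
    pr_stop("need at least 2 realms", "invalid_argument")
  pairs <- utils::combn(realms, 2)
  n_tip <- length(tree$tip.label)
  nodes <- n_tip + seq_len(tree$Nnode)
  rows <- list()
  for (nd in nodes) {
    daughters <- node_daughters(tree, nd)
    scores <- tryCatch({
      g <- gnd(tree, cm, nd, n_perm, pr_child_seed(seed, nd),
               daughters = daughters)
      if (g$gnd <= gnd_threshold) NULL
      else list(g = g, s = node_sos(tree, cm, nd, n_perm,
                                    pr_child_seed(seed, nd),
                                    daughters = daughters))
    }, phylorealms_error = function(e) {
      message(sprintf("node %d skipped: %s", nd, conditionMessage(e)))
      NULL
    })
    if (is.null(scores)) next
    sos <- scores$s$sos
    rlm <- realm[names(sos)]
    for (pp in seq_len(ncol(pairs))) {
      ra <- pairs[1, pp]; rb <- pairs[2, pp]
      sa <- sos[!is.na(rlm) & rlm == ra]; sb <- sos[!is.na(rlm) & rlm == rb]
      if (length(sa) < min_cells || length(sb) < min_cells) {
        rows[[length(rows) + 1]] <- data.frame(
          node = nd, gnd = scores$g$gnd, realm_a = ra, realm_b = rb,
          r2 = NA_real_, mean_sos_a = if (length(sa)) mean(sa) else NA_real_,
          mean_sos_b = if (length(sb)) mean(sb) else NA_real_,
          included = FALSE)
        next
      }
      yv <- c(sa, sb)
      xv <- rep(c(0, 1), c(length(sa), length(sb)))
      sst <- sum((yv - mean(yv))^2)
      fit <- lm.fit(cbind(1, xv), yv)
      r2 <- if (sst == 0) 0 else 1 - sum(fit$residuals^2) / sst
      rows[[length(rows) + 1]] <- data.frame(
        node = nd, gnd = scores$g$gnd, realm_a = ra, realm_b = rb,
        r2 = r2, mean_sos_a = mean(sa), mean_sos_b = mean(sb),
        included = mean(sa) * mean(sb) < 0)
    }
  }
  if (!length(rows))
    return(data.frame(node = integer(0), gnd = numeric(0),
                      realm_a = character(0), realm_b = character(0),
                      r2 = numeric(0), mean_sos_a = numeric(0),
                      mean_sos_b = numeric(0), included = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
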