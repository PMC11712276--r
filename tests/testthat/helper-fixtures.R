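# fixtures built in code: small random communities, labelings and trees

random_community <- function(n_cells, n_species, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n_cells * n_species, 1, p), n_cells, n_species,
                dimnames = list(sprintf("c%03d", seq_len(n_cells)),
                                sprintf("s%03d", seq_len(n_species))))
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
  }
  community_matrix(m)
}

star_tree <- function(labels, pendant = 1) {
  n <- length(labels)
  structure(list(edge = cbind(rep(n + 1L, n), seq_len(n)),
                 edge.length = rep(pendant, n),
                 tip.label = labels, Nnode = 1L),
            class = "phylo")
}

# 4-tip balanced ultrametric tree ((t1:1,t2:1):1,(t3:1,t4:1):1);
balanced4 <- function() ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")

# naive Simpson beta for the oracle route
naive_simpson <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- sum(m[i, ] & m[j, ])
    b <- sum(m[i, ] & !m[j, ])
    cc <- sum(!m[i, ] & m[j, ])
    mn <- min(b, cc)
    d[i, j] <- if (a + mn == 0) 0 else mn / (a + mn)
  }
  d
}

# naive phylogenetic Simpson via explicit per-branch presence
naive_phylo_simpson <- function(m, tree) {
  m <- as.matrix(m)
  n_tip <- length(tree$tip.label)
  desc <- lapply(seq_len(nrow(tree$edge)), function(e) {
    node <- tree$edge[e, 2]
    if (node <= n_tip) return(tree$tip.label[node])
    tree$tip.label[unlist(phangorn::Descendants(tree, node, "tips"))]
  })
  pres <- sapply(seq_len(nrow(tree$edge)), function(e) {
    sp <- intersect(desc[[e]], colnames(m))
    if (!length(sp)) return(rep(FALSE, nrow(m)))
    rowSums(m[, sp, drop = FALSE]) > 0
  })
  len <- tree$edge.length
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    A <- sum(len[pres[i, ] & pres[j, ]])
    B <- sum(len[pres[i, ] & !pres[j, ]])
    C <- sum(len[!pres[i, ] & pres[j, ]])
    mn <- min(B, C)
    d[i, j] <- if (A + mn <= 0) 0 else mn / (A + mn)
  }
  d
}

planted_labeling <- function(truth) {
  structure(list(region = truth$region_of_cell,
                 realm_of_region = truth$realm_of_region,
                 scheme = "planted"),
            class = "pr_labeling")
}

# flood fill on land cells restricted to one label: TRUE if contiguous
label_contiguous <- function(grid, labels) {
  li <- land_indices_test(grid)
  pos <- setNames(seq_along(li), as.character(li))
  ok <- TRUE
  for (r in unique(labels)) {
    cells <- which(labels == r)
    seen <- rep(FALSE, length(labels))
    queue <- cells[1]; seen[cells[1]] <- TRUE
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      for (nb in grid$adj[[li[p]]]) {
        q <- pos[as.character(nb)]
        if (!seen[q] && labels[q] == r) { seen[q] <- TRUE; queue <- c(queue, q) }
      }
    }
    ok <- ok && all(seen[cells])
  }
  ok
}

land_indices_test <- function(grid) which(grid$cells$is_land)
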