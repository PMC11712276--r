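# --- low-level phylo surgery -------------------------------------------------
# ape numbering: tips 1..n, root n+1, internal n+1..n+Nnode. Adding a tip
# shifts every node index >= n+1 up by one.

shift_nodes <- function(edge, n) {
  edge[edge > n] <- edge[edge > n] + 1L
  edge
}

# attach a new tip as an extra child of an existing internal node (polytomy);
# pendant = height of that node above the tips, so ultrametricity is exact
add_tip_at_node <- function(tree, node, label, pendant) {
  n <- length(tree$tip.label)
  edge <- shift_nodes(tree$edge, n)
  node <- node + 1L
  tree$edge <- rbind(edge, c(node, n + 1L))
  tree$edge.length <- c(tree$edge.length, pendant)
  tree$tip.label <- c(tree$tip.label, label)
  tree
}

# split the pendant edge of tip `sib` at its midpoint and hang the new tip
# from the inserted node (used when a genus/family clade is a single tip)
add_tip_split_edge <- function(tree, sib, label) {
  n <- length(tree$tip.label)
  edge <- shift_nodes(tree$edge, n)
  e <- which(edge[, 2] == sib)
  L <- tree$edge.length[e]
  newnode <- n + 1L + tree$Nnode + 1L
  parent <- edge[e, 1]
  edge[e, ] <- c(parent, newnode)
  tree$edge <- rbind(edge, c(newnode, sib), c(newnode, n + 1L))
  tree$edge.length <- c(replace(tree$edge.length, e, L / 2), L / 2, L / 2)
  tree$tip.label <- c(tree$tip.label, label)
  tree$Nnode <- tree$Nnode + 1L
  tree
}

# height of each node above the tips (0 at tips for an ultrametric tree)
node_heights <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths[seq_along(tree$tip.label)]) - depths
}

# internal nodes within the clade rooted at `node` (inclusive)
internal_descendants <- function(tree, node) {
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    if (nd > n) {
      out <- c(out, nd)
      stack <- c(stack, kids[[as.character(nd)]])
    }
  }
  sort(out)
}

# --- grafting ---------------------------------------------------------------

#' Graft missing species onto a backbone phylogeny
#'
#' Adds each target species absent from the backbone at a random position
#' within its genus clade, or its family clade when no congener is present
#' ("scenario-2" style grafting). For a genus (or family) with two or more
#' members in the current tree, the attachment node is drawn uniformly from
#' the clade's basal node (the members' MRCA) together with all internal
#' nodes below it; the new tip hangs from the chosen node with pendant length
#' equal to the node's height above the tips, creating a polytomy but
#' preserving ultrametricity exactly. When the clade is a single tip, its
#' pendant edge is split at the midpoint and the new tip attached there.
#' Species are grafted in sorted-id order, so one seed fixes the whole tree;
#' earlier grafts count as congeners for later ones.
#'
#' @param backbone Rooted ultrametric `phylo`.
#' @param taxonomy Data frame `species`, `genus`, `family` covering backbone
#'   tips and targets.
#' @param targets Character vector of species the output must contain.
#' @param seed RNG seed.
#' @return A `phylo` with tips = backbone tips plus all targets.
#' @export
graft_species <- function(backbone, taxonomy, targets, seed = 1) {
  tax <- taxonomy
  need <- union(backbone$tip.label, targets)
  missing_tax <- setdiff(need, tax$species)
  if (length(missing_tax))
    pr_stop(paste("species without taxonomy:",
                  paste(missing_tax, collapse = ", ")), "invalid_argument")
  gen <- setNames(tax$genus, tax$species)
  fam <- setNames(tax$family, tax$species)
  todo <- sort(setdiff(targets, backbone$tip.label))
  bb_fams <- unique(fam[backbone$tip.label])
  bad <- todo[!(fam[todo] %in% bb_fams)]
  if (length(bad))
    pr_stop(paste("unplaceable species (family absent from backbone):",
                  paste(bad, collapse = ", ")), "unplaceable_species")
  set.seed(seed)
  tree <- backbone
  for (sp in todo) {
    members <- tree$tip.label[gen[tree$tip.label] == gen[sp]]
    if (!length(members))
      members <- tree$tip.label[fam[tree$tip.label] == fam[sp]]
    if (length(members) == 1L) {
      tree <- add_tip_split_edge(tree, match(members, tree$tip.label), sp)
    } else {
      mrca <- ape::getMRCA(tree, members)
      cand <- internal_descendants(tree, mrca)
      node <- cand[sample.int(length(cand), 1)]
      h <- node_heights(tree)[node]
      tree <- add_tip_at_node(tree, node, sp, h)
    }
  }
  attr(tree, "order") <- NULL
  ape::reorder.phylo(tree, "cladewise")
}

#' Sample a set of independently grafted trees
#'
#' Runs [graft_species()] `n_trees` times with seeds `seed + 0 ... seed +
#' n_trees - 1`, producing a `multiPhylo` of random grafted trees sharing an
#' identical tip set, for downstream averaging of phylogenetic
#' dissimilarities.
#'
#' @inheritParams graft_species
#' @param n_trees Number of trees (the consensus-regionalization workflow
#'   uses 100).
#' @return A `multiPhylo`; `attr(, "seeds")` records the seeds used.
#' @export
sample_tree_set <- function(backbone, taxonomy, targets, n_trees = 100,
                            seed = 1) {
  n_trees <- pr_check_count(n_trees, "n_trees")
  seeds <- seed + seq_len(n_trees) - 1L
  trees <- lapply(seeds, function(s) graft_species(backbone, taxonomy, targets, s))
  class(trees) <- "multiPhylo"
  attr(trees, "seeds") <- seeds
  trees
}

#' Read / write taxonomy tables
#'
#' CSV with columns `species,genus,family`; every genus must map to exactly
#' one family.
#'
#' @param path File path.
#' @export
read_taxonomy <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "genus", "family") %in% names(df)))
    pr_stop("taxonomy CSV needs species,genus,family columns", "parse_error")
  gf <- unique(df[c("genus", "family")])
  if (anyDuplicated(gf$genus))
    pr_stop("a genus maps to more than one family", "parse_error")
  df
}

#' @rdname read_taxonomy
#' @param taxonomy Data frame `species`, `genus`, `family`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  write.csv(taxonomy[c("species", "genus", "family")], path, row.names = FALSE)
  invisible(path)
}
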