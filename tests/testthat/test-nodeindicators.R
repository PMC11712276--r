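# community with daughter A on the left half, daughter B on the right
split_world <- function(n_cells = 20, nA = 5, nB = 5, seed = 1) {
  set.seed(seed)
  cells <- sprintf("c%02d", seq_len(n_cells))
  spA <- sprintf("a%02d", seq_len(nA)); spB <- sprintf("b%02d", seq_len(nB))
  m <- matrix(0, n_cells, nA + nB, dimnames = list(cells, c(spA, spB)))
  m[1:(n_cells / 2), spA] <- rbinom(n_cells / 2 * nA, 1, 0.8)
  m[(n_cells / 2 + 1):n_cells, spB] <- rbinom(n_cells / 2 * nB, 1, 0.8)
  # keep every species somewhere, on its own side of the split
  for (s in which(colSums(m) == 0)) {
    side <- if (s <= nA) 1:(n_cells / 2) else (n_cells / 2 + 1):n_cells
    m[sample(side, 1), s] <- 1
  }
  tree <- ape::read.tree(text = sprintf("((%s),(%s));",
                                        paste(spA, collapse = ","),
                                        paste(spB, collapse = ",")))
  tree <- ape::compute.brlen(tree)
  cm <- community_matrix(Matrix::Matrix(m, sparse = TRUE))
  list(cm = cm, tree = tree, root = length(tree$tip.label) + 1L)
}

test_that("SOS signs track daughter overrepresentation", {
  w <- split_world()
  s <- node_sos(w$tree, w$cm, w$root, n_perm = 200, seed = 1)
  left <- sprintf("c%02d", 1:10); right <- sprintf("c%02d", 11:20)
  expect_true(all(s$sos[intersect(names(s$sos), left)] > 0))
  expect_true(all(s$sos[intersect(names(s$sos), right)] < 0))

  # antisymmetry: swapping the daughter order negates every score
  s2 <- node_sos(w$tree, w$cm, w$root, n_perm = 200, seed = 1,
                 daughters = list(A = s$B, B = s$A))
  expect_equal(s2$sos, -s$sos, tolerance = 1e-12)
})

test_that("SOS is null-centred for identically distributed daughters", {
  # averaged across independently drawn null worlds, mean SOS over cells
  # stays near 0 (each single world retains O(1/sqrt(n_cells)) noise)
  tree <- ape::compute.brlen(ape::read.tree(
    text = "((a1,a2,a3,a4,a5),(b1,b2,b3,b4,b5));"))
  means <- vapply(1:10, function(i) {
    set.seed(i + 100)
    m <- matrix(rbinom(15 * 10, 1, 0.6), 15, 10,
                dimnames = list(sprintf("c%02d", 1:15),
                                c(sprintf("a%d", 1:5), sprintf("b%d", 1:5))))
    m[1, ] <- 1
    cm <- community_matrix(Matrix::Matrix(m, sparse = TRUE))
    mean(node_sos(tree, cm, 11L, n_perm = 200, seed = i)$sos)
  }, numeric(1))
  expect_lt(abs(mean(means)), 2 / sqrt(200))
  m <- matrix(1, 15, 10, dimnames = list(sprintf("c%02d", 1:15),
                                         c(sprintf("a%d", 1:5),
                                           sprintf("b%d", 1:5))))

  # single occupied cell with all species: degenerate null -> SOS = 0
  m1 <- matrix(1, 1, 10, dimnames = list("c1", colnames(m)))
  s1 <- node_sos(tree, community_matrix(Matrix::Matrix(m1, sparse = TRUE)),
                 11L, n_perm = 50, seed = 1)
  expect_equal(unname(s1$sos), 0)
})

test_that("GND separates divergent from co-distributed daughters", {
  w <- split_world(n_cells = 30, nA = 8, nB = 8, seed = 5)
  g_div <- gnd(w$tree, w$cm, w$root, n_perm = 200, seed = 1)
  expect_gte(g_div$gnd, 0.9)

  set.seed(6)
  cells <- sprintf("c%02d", 1:20)
  m <- matrix(rbinom(20 * 16, 1, 0.6), 20, 16,
              dimnames = list(cells, c(sprintf("a%d", 1:8),
                                       sprintf("b%d", 1:8))))
  m[1, ] <- 1
  tree <- ape::compute.brlen(ape::read.tree(text = sprintf(
    "((%s),(%s));", paste(sprintf("a%d", 1:8), collapse = ","),
    paste(sprintf("b%d", 1:8), collapse = ","))))
  cm <- community_matrix(Matrix::Matrix(m, sparse = TRUE))
  g_same <- gnd(tree, cm, 17L, n_perm = 200, seed = 1)
  expect_lte(g_same$gnd, 0.1)

  # invariant to swapping the daughters
  d <- phylorealms:::node_daughters(w$tree, w$root)
  g_swap <- gnd(w$tree, w$cm, w$root, n_perm = 200, seed = 1,
                daughters = list(A = d$B, B = d$A))
  expect_equal(g_swap$gnd, g_div$gnd, tolerance = 1e-12)
})

test_that("indicator_clades enumerates realm pairs and scores separation", {
  # 6 realms -> choose(6,2) = 15 pairs
  w <- split_world(n_cells = 24, nA = 6, nB = 6, seed = 8)
  g <- build_grid(24, 1)
  rownames(w$cm) <- g$cells$cell
  lab <- structure(list(region = setNames(rep(1:6, each = 4), g$cells$cell),
                        realm_of_region = 1:6, scheme = "s"),
                   class = "pr_labeling")
  tab <- suppressMessages(
    indicator_clades(w$tree, w$cm, lab, gnd_threshold = 0.65,
                     n_perm = 100, seed = 1, min_cells = 2))
  expect_equal(length(unique(paste(tab$realm_a, tab$realm_b))), 15)
  root_rows <- tab[tab$node == w$root, ]
  expect_equal(nrow(root_rows), 15)

  # realms 1-3 are all-A (positive SOS), realms 4-6 all-B (negative):
  # cross-side pairs separate perfectly and are flagged as indicators
  cross <- root_rows[root_rows$realm_a %in% 1:3 & root_rows$realm_b %in% 4:6, ]
  expect_true(all(cross$included))
  expect_true(all(cross$r2 > 0.8, na.rm = TRUE))
  same_side <- root_rows[root_rows$realm_a %in% 1:3 &
                           root_rows$realm_b %in% 1:3, ]
  expect_true(all(!same_side$included))
})

test_that("indicator R2 equals the squared point-biserial correlation", {
  w <- split_world(n_cells = 24, nA = 6, nB = 6, seed = 12)
  g <- build_grid(24, 1)
  rownames(w$cm) <- g$cells$cell
  lab <- structure(list(region = setNames(rep(1:4, each = 6), g$cells$cell),
                        realm_of_region = 1:4, scheme = "s"),
                   class = "pr_labeling")
  tab <- suppressMessages(
    indicator_clades(w$tree, w$cm, lab, gnd_threshold = 0.65,
                     n_perm = 100, seed = 3, min_cells = 2))
  sos <- node_sos(w$tree, w$cm, w$root, n_perm = 100,
                  seed = phylorealms:::pr_child_seed(3, w$root))$sos
  realm <- setNames(lab$realm_of_region[lab$region], names(lab$region))
  for (i in which(tab$node == w$root & !is.na(tab$r2))) {
    sel <- names(sos)[realm[names(sos)] %in%
                        c(tab$realm_a[i], tab$realm_b[i])]
    pb <- cor(sos[sel], as.numeric(realm[sel] == tab$realm_b[i]))^2
    expect_equal(tab$r2[i], pb, tolerance = 1e-10)
  }
})
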