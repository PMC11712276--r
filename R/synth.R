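#' Synthetic-data configuration
#'
#' Bundles the parameters of the synthetic world: grid extent, planted
#' nested regionalization (regions within realms), species occupancy
#' probabilities, and environmental layer structure. Defaults describe a
#' desk-scale world with strong but not deterministic regional signal:
#' 120 species on a 20 x 20 grid of 100-km cells, 6 regions nested in 3
#' realms, in-region occupancy 0.6 versus 0.02 elsewhere, 10% widespread
#' species, an environmental step of 10 layer units at realm boundaries and
#' smooth noise of sd 1.
#'
#' @param n_species,grid_nx,grid_ny,cell_km,k_regions,k_realms World shape.
#' @param p_in,p_out Occupancy probability inside/outside a species' home
#'   region; requires `0 <= p_out < p_in <= 1` unless `p_in == p_out`
#'   (the explicit no-signal configuration).
#' @param p_realm Occupancy probability in the bleed zone: cells of the
#'   home realm within `bleed_rings` queen steps of the home region.
#'   Defaults to 0.08, between `p_out` and `p_in`: ranges extend a little
#'   way into neighbouring regions of the same realm (realm boundaries act
#'   as dispersal barriers, region cores stay distinct), producing the
#'   nested turnover — shallow within realms, deep between — that real
#'   biotas show and realm cuts rely on. When `p_in == p_out` it is forced
#'   equal to them so the no-signal world stays signal-free.
#' @param bleed_rings Width of the bleed zone in queen-adjacency steps
#'   (default 1 cell).
#' @param realm_widespread_frac Fraction of species whose range is their
#'   whole home realm rather than one region (default 0.10). Real range-size
#'   distributions are hierarchical — most species are regional, some span a
#'   realm, a few are cosmopolitan — and the realm-wide tier gives realms
#'   their faunal cohesion.
#' @param widespread_frac Fraction of species with no home region (present
#'   everywhere with probability `p_in`).
#' @param boundary_step Environmental step at realm boundaries (layer units).
#' @param noise_sd Standard deviation of the smooth noise field.
#' @param seed RNG seed.
#' @return A `pr_synth_config` list.
#' @export
synth_config <- function(n_species = 120, grid_nx = 20, grid_ny = 20,
                         cell_km = 100, k_regions = 6, k_realms = 3,
                         p_in = 0.6, p_out = 0.02, p_realm = 0.08,
                         bleed_rings = 1, realm_widespread_frac = 0.10,
                         widespread_frac = 0.1,
                         boundary_step = 10, noise_sd = 1, seed = 1) {
  cfg <- list(n_species = pr_check_count(n_species, "n_species", 2L),
              grid_nx = pr_check_count(grid_nx, "grid_nx"),
              grid_ny = pr_check_count(grid_ny, "grid_ny"),
              cell_km = cell_km,
              k_regions = pr_check_count(k_regions, "k_regions"),
              k_realms = pr_check_count(k_realms, "k_realms"),
              p_in = p_in, p_out = p_out,
              p_realm = if (p_in == p_out) p_in else p_realm,
              bleed_rings = pr_check_count(bleed_rings, "bleed_rings", 0L),
              realm_widespread_frac = realm_widespread_frac,
              widespread_frac = widespread_frac,
              boundary_step = boundary_step, noise_sd = noise_sd,
              seed = as.integer(seed))
  if (cfg$k_realms > cfg$k_regions)
    pr_stop("k_realms must be <= k_regions", "invalid_argument")
  if (p_out < 0 || p_in > 1 || p_out > p_in)
    pr_stop("need 0 <= p_out <= p_in <= 1", "invalid_argument")
  if (cfg$p_realm < p_out || cfg$p_realm > p_in)
    pr_stop("p_realm must lie within [p_out, p_in]", "invalid_argument")
  if (widespread_frac < 0 || widespread_frac > 1)
    pr_stop("widespread_frac must be in [0,1]", "invalid_argument")
  if (is.null(cfg$realm_widespread_frac) || cfg$realm_widespread_frac < 0 ||
      cfg$realm_widespread_frac + widespread_frac > 1)
    pr_stop("realm_widespread_frac must be in [0, 1 - widespread_frac]",
            "invalid_argument")
  structure(cfg, class = "pr_synth_config")
}

#' Simulate a pure-birth ultrametric phylogeny
#'
#' Yule (pure-birth) tree with the root age rescaled to 100 arbitrary
#' Myr-like units; tips are labelled `s0001`, `s0002`, ... The birth rate is
#' irrelevant after rescaling.
#'
#' @param n_species Number of tips (>= 2).
#' @param seed RNG seed.
#' @return A rooted binary ultrametric `ape::phylo`.
#' @export
simulate_phylogeny <- function(n_species, seed = 1) {
  n_species <- pr_check_count(n_species, "n_species", 2L)
  set.seed(seed)
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  depths <- ape::node.depth.edgelength(tr)
  age <- max(depths[seq_len(n_species)])
  tr$edge.length <- tr$edge.length * (100 / age)
  tr$tip.label <- sprintf("s%04d", seq_len(n_species))
  tr
}

#' Plant a nested regionalization on a grid
#'
#' Seeds `k_regions` cells and grows contiguous regions by competitive
#' breadth-first claiming of unclaimed queen neighbours; regions are then
#' merged into `k_realms` contiguous realm groups by the same competitive
#' growth on the region adjacency graph. Every region is contiguous under
#' queen adjacency by construction, and the realm map is a surjective
#' coarsening of the region map.
#'
#' @param grid A [build_grid()] grid.
#' @param k_regions,k_realms Planted counts.
#' @param seed RNG seed.
#' @return A `pr_planted_truth` list: `region_of_cell` (named integer over
#'   land cells), `realm_of_region` (integer vector over regions),
#'   `home_region_of_species` is added by [simulate_communities()].
#' @export
plant_regions <- function(grid, k_regions, k_realms = 1, seed = 1) {
  k_regions <- pr_check_count(k_regions, "k_regions")
  k_realms <- pr_check_count(k_realms, "k_realms")
  li <- land_indices(grid)
  if (k_regions > length(li))
    pr_stop("k_regions exceeds the number of land cells", "invalid_argument")
  if (k_realms > k_regions)
    pr_stop("k_realms must be <= k_regions", "invalid_argument")
  set.seed(seed)
  lab <- setNames(rep(NA_integer_, length(li)), grid$cells$cell[li])
  pos <- setNames(seq_along(li), as.character(li)) # cells-index -> land index
  # farthest-point seeding: first seed random, each next seed maximizes its
  # distance to the chosen ones — regions of comparable spatial extent
  xs <- grid$cells$x[li]; ys <- grid$cells$y[li]
  seeds <- li[sample.int(length(li), 1)]
  while (length(seeds) < k_regions) {
    dmin <- rep(Inf, length(li))
    for (s in seeds) {
      p <- pos[as.character(s)]
      dmin <- pmin(dmin, (xs - xs[p])^2 + (ys - ys[p])^2)
    }
    seeds <- c(seeds, li[which.max(dmin)])
  }
  lab[pos[as.character(seeds)]] <- seq_len(k_regions)
  # balanced competitive growth: each round the smallest region claims one
  # unclaimed frontier cell, keeping planted regions contiguous and of
  # comparable size
  terr <- lapply(seq_len(k_regions), function(r) seeds[r])
  repeat {
    grew <- FALSE
    for (r in order(lengths(terr))) {
      cand <- unique(unlist(lapply(terr[[r]], function(c0) grid$adj[[c0]])))
      cand <- cand[is.na(lab[pos[as.character(cand)]])]
      if (length(cand)) {
        # compactness: expand towards the cell nearest the region's seed
        sx <- grid$cells$x[seeds[r]]; sy <- grid$cells$y[seeds[r]]
        d2 <- (grid$cells$x[cand] - sx)^2 + (grid$cells$y[cand] - sy)^2
        pick <- cand[which.min(d2)]
        lab[pos[as.character(pick)]] <- r
        terr[[r]] <- c(terr[[r]], pick)
        grew <- TRUE
        break
      }
    }
    if (!grew) break
  }
  # any stranded cells (disconnected land) -> nearest labelled centroid
  if (anyNA(lab)) {
    xy <- grid$cells[li, c("x", "y")]
    for (p in which(is.na(lab))) {
      d <- (xy$x - xy$x[p])^2 + (xy$y - xy$y[p])^2
      d[is.na(lab)] <- Inf
      lab[p] <- lab[which.min(d)]
    }
  }
  # realm growth over the region adjacency graph
  radj <- matrix(FALSE, k_regions, k_regions)
  for (p in seq_along(li)) {
    for (nb in grid$adj[[li[p]]]) {
      q <- pos[as.character(nb)]
      if (lab[p] != lab[q]) radj[lab[p], lab[q]] <- TRUE
    }
  }
  # realm seeds: farthest-point over region centroids, then balanced
  # competitive growth (fewest-regions realm claims next)
  cx <- vapply(seq_len(k_regions), function(r) mean(xs[lab == r]), numeric(1))
  cy <- vapply(seq_len(k_regions), function(r) mean(ys[lab == r]), numeric(1))
  realm <- rep(NA_integer_, k_regions)
  rs <- sample.int(k_regions, 1)
  while (length(rs) < k_realms) {
    dmin <- rep(Inf, k_regions)
    for (s in rs) dmin <- pmin(dmin, (cx - cx[s])^2 + (cy - cy[s])^2)
    dmin[rs] <- -Inf
    rs <- c(rs, which.max(dmin))
  }
  realm[rs] <- seq_len(k_realms)
  while (anyNA(realm)) {
    grew <- FALSE
    for (g in order(tabulate(realm, k_realms))) {
      cand <- which(is.na(realm) & apply(radj[, realm %in% g, drop = FALSE], 1, any))
      if (length(cand)) {
        realm[cand[sample.int(length(cand), 1)]] <- g
        grew <- TRUE
        break # re-rank realms by size after every claim
      }
    }
    if (!grew) { realm[which(is.na(realm))[1]] <- 1L } # disconnected fallback
  }
  structure(list(region_of_cell = lab, realm_of_region = realm,
                 home_region_of_species = NULL),
            class = "pr_planted_truth")
}

# hand clades to regions so that deep splits align with realms and
# shallower splits with regions. The tree is decomposed into "tribes":
# maximal clades of at most ceil(n / (2 k_regions)) tips (singletons where
# the topology is pectinate). Tribes are then greedily packed, in cladewise
# order, into k_regions bins of near-equal species number, and bins are
# assigned to regions with same-realm regions taking adjacent bins. Because
# every tribe is a whole clade, no clade is split between regions: two
# regions share no branches below their tribes' roots, giving uniform
# between-region turnover regardless of where the topology places its deep
# splits, while balanced bin sums keep endemic counts even. Realm cohesion
# comes from the realm-wide and bleed tiers of the occupancy model, not
# from tree depth alone.
assign_clades <- function(tree, truth) {
  cw <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  kids <- split(cw$edge[, 2], cw$edge[, 1])
  nt <- integer(n_tip + tree$Nnode) # tips under each node
  po <- ape::reorder.phylo(tree, "postorder")
  nt[seq_len(n_tip)] <- 1L
  for (r in seq_len(nrow(po$edge))) {
    nt[po$edge[r, 1]] <- nt[po$edge[r, 1]] + nt[po$edge[r, 2]]
  }
  k <- length(truth$realm_of_region)
  cap <- ceiling(n_tip / (2 * k))
  tips_under <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack)) {
      x <- stack[[1]]; stack <- stack[-1]
      if (x <= n_tip) out <- c(out, x)
      else stack <- c(kids[[as.character(x)]], stack)
    }
    out
  }
  tribes <- list()
  walk <- function(node) {
    if (nt[node] <= cap) {
      tribes[[length(tribes) + 1L]] <<- tips_under(node)
    } else {
      for (ch in kids[[as.character(node)]]) walk(ch)
    }
  }
  walk(n_tip + 1L)
  # optimal contiguous packing of tribes into k bins: dynamic programme
  # minimizing the largest absolute deviation of a bin sum from the even
  # share, so every region receives a near-equal number of endemics
  sizes <- lengths(tribes)
  n_tr <- length(tribes)
  target <- n_tip / k
  csum <- c(0, cumsum(sizes))
  cost <- function(i, j) abs(csum[j + 1] - csum[i] - target) # tribes i..j
  DP <- matrix(Inf, k, n_tr)
  choice <- matrix(0L, k, n_tr)
  for (j in seq_len(n_tr)) DP[1, j] <- cost(1, j)
  for (b in 2:k) {
    for (j in seq_len(n_tr)) {
      if (j < b) next
      best <- Inf; arg <- 0L
      for (i in (b - 1):(j - 1)) {
        v <- max(DP[b - 1, i], cost(i + 1, j))
        if (v < best) { best <- v; arg <- i }
      }
      DP[b, j] <- best; choice[b, j] <- arg
    }
  }
  bin <- integer(n_tr)
  j <- n_tr
  for (b in k:1) {
    i <- if (b == 1) 0L else choice[b, j]
    bin[(i + 1):j] <- b
    j <- i
  }
  # same-realm regions take adjacent bins
  regs_by_realm <- order(truth$realm_of_region)
  home <- setNames(rep(NA_integer_, n_tip), tree$tip.label)
  for (i in seq_along(tribes)) home[tribes[[i]]] <- regs_by_realm[bin[i]]
  home
}

#' Simulate a clade-structured community
#'
#' Species are assigned home regions by slicing the tree's tips, taken in
#' cladewise traversal order, into near-equal phylogenetically contiguous
#' blocks, with same-realm regions receiving adjacent blocks — so deep
#' phylogenetic splits align with realm boundaries and shallower splits with
#' region boundaries, the turnover structure phylogenetic beta diversity is
#' designed to detect, while species counts stay balanced across regions
#' even on unbalanced pure-birth topologies. Each species then occupies cells of its
#' home region independently with probability `p_in` and all other cells with
#' `p_out`; a fraction `widespread_frac` of species is widespread (all cells
#' at `p_in`). Empty land cells are repaired deterministically by copying one
#' species from the nearest (Euclidean centroid) occupied cell.
#'
#' @param tree Phylogeny whose tips cover the configured species.
#' @param truth A [plant_regions()] truth (home assignments are filled in and
#'   returned via attribute `"truth"`).
#' @param cfg A [synth_config()].
#' @param grid The grid the truth was planted on.
#' @param seed RNG seed.
#' @return A `pr_community` matrix; `attr(, "truth")` carries the completed
#'   planted truth including `home_region_of_species`.
#' @export
simulate_communities <- function(tree, truth, cfg, grid, seed = 1) {
  if (!inherits(truth, "pr_planted_truth"))
    pr_stop("`truth` must come from plant_regions()", "invalid_argument")
  n <- cfg$n_species
  if (length(tree$tip.label) < n)
    pr_stop("tree has fewer tips than cfg$n_species", "invalid_argument")
  set.seed(seed)
  home <- assign_clades(tree, truth)
  species <- tree$tip.label
  n_wide <- round(cfg$widespread_frac * n)
  wide <- if (n_wide > 0) sample(species, n_wide) else character(0)
  home_chr <- as.character(home)
  names(home_chr) <- species
  # realm-wide tier: per realm, promote a fraction of its clade's species
  rw <- if (is.null(cfg$realm_widespread_frac)) 0 else cfg$realm_widespread_frac
  if (rw > 0 && cfg$p_in > cfg$p_out) {
    for (g in unique(truth$realm_of_region)) {
      pool <- setdiff(species[home[species] %in%
                                which(truth$realm_of_region == g)], wide)
      n_rw <- round(rw * length(pool))
      if (n_rw > 0)
        home_chr[sample(pool, n_rw)] <- paste0("realm", g)
    }
  }
  home_chr[wide] <- "widespread"
  lab <- truth$region_of_cell
  realm_of_cell <- truth$realm_of_region[lab]
  n_cells <- length(lab)
  li0 <- land_indices(grid)
  pos0 <- setNames(seq_along(li0), as.character(li0))
  # bleed zone per region: same-realm cells within bleed_rings queen steps
  k_reg <- length(truth$realm_of_region)
  bleed <- lapply(seq_len(k_reg), function(r) {
    zone <- which(lab == r)
    for (ring in seq_len(cfg$bleed_rings)) {
      nb <- unique(unlist(lapply(li0[zone], function(c0)
        pos0[as.character(grid$adj[[c0]])])))
      zone <- union(zone, nb)
    }
    setdiff(zone[realm_of_cell[zone] == truth$realm_of_region[r]],
            which(lab == r))
  })
  inc <- matrix(FALSE, n_cells, n)
  for (s in seq_len(n)) {
    sp <- species[s]
    if (home_chr[sp] == "widespread") {
      inc[, s] <- runif(n_cells) < cfg$p_in
    } else if (startsWith(home_chr[sp], "realm")) {
      # realm-characteristic common species: near-ubiquitous in their realm
      g <- as.integer(sub("realm", "", home_chr[sp]))
      p_cell <- ifelse(realm_of_cell == g, cfg$p_in, cfg$p_out)
      inc[, s] <- runif(n_cells) < p_cell
    } else {
      hr <- as.integer(home_chr[sp])
      p_cell <- rep(cfg$p_out, n_cells)
      p_cell[bleed[[hr]]] <- cfg$p_realm
      p_cell[lab == hr] <- cfg$p_in
      inc[, s] <- runif(n_cells) < p_cell
    }
  }
  # guarantee every species somewhere: force one home (or random) cell
  for (s in which(colSums(inc) == 0)) {
    sp <- species[s]
    cand <- if (home_chr[sp] == "widespread") seq_len(n_cells)
            else if (startsWith(home_chr[sp], "realm"))
              which(realm_of_cell == as.integer(sub("realm", "", home_chr[sp])))
            else which(lab == as.integer(home_chr[sp]))
    inc[cand[sample.int(length(cand), 1)], s] <- TRUE
  }
  # empty-cell repair: copy one species from the nearest occupied cell
  li <- land_indices(grid)
  xy <- grid$cells[li, c("x", "y")]
  empty <- which(rowSums(inc) == 0)
  if (length(empty)) {
    occ <- which(rowSums(inc) > 0)
    for (e in empty) {
      d <- (xy$x[occ] - xy$x[e])^2 + (xy$y[occ] - xy$y[e])^2
      src <- occ[which.min(d)]
      inc[e, which(inc[src, ])[1]] <- TRUE
    }
  }
  m <- Matrix::Matrix(inc * 1, sparse = TRUE,
                      dimnames = list(names(lab), species))
  cm <- community_matrix(m)
  truth$home_region_of_species <- home_chr
  attr(cm, "truth") <- truth
  cm
}

# 3x3 mean filter with edge truncation, on a nx x ny value matrix
mean_filter_3x3 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(0, nx, ny); cnt <- matrix(0, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    xt <- max(1, 1 - dx):min(nx, nx - dx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    yt <- max(1, 1 - dy):min(ny, ny - dy)
    out[xt, yt] <- out[xt, yt] + m[xs, ys]
    cnt[xt, yt] <- cnt[xt, yt] + 1
  }
  out / cnt
}

#' Simulate environmental layers with realm-boundary steps
#'
#' Builds the seven layers the boundary-driver stage consumes:
#' `temp_seasonality`, `precip_seasonality`, `mat`, `map`, `elevation`,
#' `temp_present` and `temp_lgm`, each with a plausible nonzero baseline.
#' The realm step (`boundary_step * (realm - 1)`) is added to the designated
#' layers `temp_present` and `elevation` — the synthetic realms are
#' climatically and topographically delimited, so temperature regime and
#' terrain jump across realm boundaries while the remaining climate layers
#' carry only independent smooth noise (3x3 mean-filtered white noise).
#' Elevation receives five-fold noise (terrain is rougher than climate), the
#' seasonality and annual layers three-fold, so their focal heterogeneity
#' varies but stays mutually independent. `temp_lgm` equals `temp_present`
#' plus a smooth spatially varying cooling offset.
#'
#' @param truth A planted truth on `grid`.
#' @param grid The grid.
#' @param cfg A [synth_config()].
#' @param seed RNG seed.
#' @return A named list of numeric vectors over land cells (a `RasterSet`),
#'   with cell names.
#' @export
simulate_environment <- function(truth, grid, cfg, seed = 1) {
  set.seed(seed)
  li <- land_indices(grid)
  cells <- grid$cells[li, ]
  realm_of_cell <- truth$realm_of_region[truth$region_of_cell]
  step <- cfg$boundary_step * (realm_of_cell - 1)
  smooth_noise <- function(mult = 1) {
    full <- matrix(rnorm(grid$nx * grid$ny, sd = mult * cfg$noise_sd),
                   grid$nx, grid$ny)
    mean_filter_3x3(full)[cbind(cells$ix, cells$iy)]
  }
  bases <- c(temp_seasonality = 30, precip_seasonality = 40, mat = 15,
             map = 1000, elevation = 500, temp_present = 15)
  layer <- function(nm, stepped, mult) {
    setNames(bases[[nm]] + (if (stepped) step else 0) + smooth_noise(mult),
             cells$cell)
  }
  out <- list(temp_seasonality = layer("temp_seasonality", FALSE, 3),
              precip_seasonality = layer("precip_seasonality", FALSE, 3),
              mat = layer("mat", FALSE, 3),
              map = layer("map", FALSE, 3),
              elevation = layer("elevation", TRUE, 5),
              temp_present = layer("temp_present", TRUE, 1))
  # LGM offset: smooth cooling that varies across the map
  offset <- -5 + cells$y / max(cells$y) * 2 + smooth_noise()
  if (cfg$boundary_step == 0 && cfg$noise_sd == 0) offset <- offset * 0
  out$temp_lgm <- setNames(out$temp_present + offset, cells$cell)
  out
}

#' Prune a tree to a backbone subset
#'
#' Retains `ceiling(keep_frac * n)` tips, sampled so that every family keeps
#' at least one representative where the budget allows (one random tip per
#' family first, then uniform fill). Used to exercise the grafting stage:
#' the dropped tips become the graft targets.
#'
#' @param tree Ultrametric phylogeny.
#' @param taxonomy Data frame with columns `species`, `genus`, `family`.
#' @param keep_frac Fraction of tips to keep, in (0, 1].
#' @param seed RNG seed.
#' @return List with `backbone` (pruned `phylo`) and `targets` (character:
#'   the full species list to graft back).
#' @export
make_backbone <- function(tree, taxonomy, keep_frac, seed = 1) {
  if (!is.numeric(keep_frac) || keep_frac <= 0 || keep_frac > 1)
    pr_stop("keep_frac must be in (0, 1]", "invalid_argument")
  n <- length(tree$tip.label)
  k <- ceiling(keep_frac * n)
  if (k == n) return(list(backbone = tree, targets = tree$tip.label))
  set.seed(seed)
  fam <- taxonomy$family[match(tree$tip.label, taxonomy$species)]
  keep <- character(0)
  fams <- unique(fam)
  if (length(fams) <= k) {
    keep <- vapply(fams, function(f) {
      tips <- tree$tip.label[fam == f]
      tips[sample.int(length(tips), 1)]
    }, character(1))
  }
  rest <- setdiff(tree$tip.label, keep)
  extra <- k - length(keep)
  if (extra > 0) keep <- c(keep, sample(rest, extra))
  keep <- keep[seq_len(k)]
  list(backbone = ape::keep.tip(tree, keep), targets = tree$tip.label)
}

#' Generate a random taxonomy for a simulated tree
#'
#' Carves the tree's tips into genera and families by cutting the tree at
#' two depths, so taxonomy is phylogenetically coherent (each genus
#' monophyletic, nested in a monophyletic family).
#'
#' @param tree Ultrametric phylogeny.
#' @param genus_age,family_age Depths (time before present) at which lineage
#'   membership defines genera and families.
#' @return Data frame `species`, `genus`, `family`.
#' @export
simulate_taxonomy <- function(tree, genus_age = 25, family_age = 60) {
  n <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  age <- max(depths[seq_len(n)])
  cut_at <- function(t_before_present) {
    # lineage id = ancestor edge crossing the time slice
    target <- age - t_before_present
    memb <- integer(n)
    children <- split(tree$edge[, 2], tree$edge[, 1])
    assign <- function(node, cur) {
      if (depths[node] >= target || node <= n) {
        if (node <= n) memb[node] <<- cur
        else for (k in children[[as.character(node)]]) assign(k, cur)
      } else {
        for (k in children[[as.character(node)]]) assign(k, k)
      }
    }
    assign(n + 1L, n + 1L)
    match(memb, unique(memb))
  }
  g <- cut_at(genus_age); f <- cut_at(family_age)
  data.frame(species = tree$tip.label,
             genus = sprintf("g%03d", g),
             family = sprintf("f%03d", f),
             stringsAsFactors = FALSE)
}

#' Generate the full synthetic world
#'
#' Convenience wrapper running [simulate_phylogeny()], [plant_regions()],
#' [simulate_communities()], [simulate_environment()] and
#' [simulate_taxonomy()] with per-stage seeds derived from `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return List with `grid`, `tree`, `truth`, `community`, `env`, `taxonomy`,
#'   `config`.
#' @export
simulate_world <- function(cfg = synth_config()) {
  grid <- build_grid(cfg$grid_nx, cfg$grid_ny, cfg$cell_km)
  tree <- simulate_phylogeny(cfg$n_species, pr_child_seed(cfg$seed, 1))
  truth <- plant_regions(grid, cfg$k_regions, cfg$k_realms,
                         pr_child_seed(cfg$seed, 2))
  cm <- simulate_communities(tree, truth, cfg, grid, pr_child_seed(cfg$seed, 3))
  env <- simulate_environment(truth, grid, cfg, pr_child_seed(cfg$seed, 4))
  list(grid = grid, tree = tree, truth = attr(cm, "truth"), community = cm,
       env = env, taxonomy = simulate_taxonomy(tree), config = cfg)
}
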