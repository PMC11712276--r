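#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis with the conventional
#' defaults: automatic linkage selection and elbow k, a 0.60
#' variance-preservation realm cut, 100 random grafted trees, 999 Voronoi
#' nulls, GND screening at 0.65, a 200 km boundary band and a 282.84 km
#' neighbourhood (or `"auto"`). Exactly one of `synth` or `data` must be
#' supplied: a [synth_config()] for a simulated world, or a list with
#' `grid`, `community`, `tree` (or `trees`), optional `taxonomy`, `env`.
#'
#' @param synth A [synth_config()], or `NULL` when `data` is given.
#' @param data Pre-built inputs, or `NULL` when `synth` is given.
#' @param linkage Linkage name or `"auto"` (cophenetic-correlation choice).
#' @param k Region count or `"auto"` (elbow).
#' @param k_max Elbow search limit.
#' @param realm_threshold Variance fraction the realm cut preserves.
#' @param keep_frac Backbone fraction for the grafting stage (1 = use the
#'   full tree, no grafting).
#' @param n_trees Grafted trees to average over.
#' @param n_null Voronoi nulls for V-measure tests.
#' @param gnd_threshold GND screening threshold.
#' @param band_km,neighbor_km Boundary-model geometry.
#' @param n_perm Permutations for GND/SOS.
#' @param run_drivers,run_indicators Stage switches.
#' @param seed Master seed; stages derive their own seeds by fixed offsets.
#' @return A `pr_pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(), data = NULL,
                            linkage = "auto", k = "auto", k_max = 30,
                            realm_threshold = 0.60, keep_frac = 1,
                            n_trees = 100, n_null = 999,
                            gnd_threshold = 0.65, band_km = 200,
                            neighbor_km = "auto", n_perm = 100,
                            run_drivers = TRUE, run_indicators = TRUE,
                            seed = 1) {
  if (is.null(synth) == is.null(data))
    pr_stop("supply exactly one of `synth` or `data`", "invalid_argument")
  if (realm_threshold <= 0 || realm_threshold >= 1)
    pr_stop("realm_threshold must be in (0,1)", "invalid_argument")
  structure(list(synth = synth, data = data, linkage = linkage, k = k,
                 k_max = k_max, realm_threshold = realm_threshold,
                 keep_frac = keep_frac, n_trees = n_trees, n_null = n_null,
                 gnd_threshold = gnd_threshold, band_km = band_km,
                 neighbor_km = neighbor_km, n_perm = n_perm,
                 run_drivers = run_drivers, run_indicators = run_indicators,
                 seed = as.integer(seed)),
            class = "pr_pipeline_config")
}

#' Run the full regionalization pipeline
#'
#' Sequences every stage: synthetic world (or supplied data) -> grafted tree
#' set -> mean phylogenetic Simpson dissimilarity -> linkage selection ->
#' elbow k -> nested regions and realms -> diversity table and NMDS ->
#' V-measure against the planted truth (synthetic runs) -> boundary-driver
#' fits (all / realm / within-realm boundaries) -> indicator clades. All
#' stage seeds derive from the master seed by fixed offsets so stages can be
#' rerun in isolation.
#'
#' @param cfg A [pipeline_config()].
#' @param outdir Optional directory; when given, every intermediate is
#'   written in its standard format plus a `report.json`.
#' @return A list of stage results (see elements of the return value).
#' @export
run_pipeline <- function(cfg = pipeline_config(), outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  world <- stage("ingest", {
    if (!is.null(cfg$synth)) simulate_world(cfg$synth)
    else {
      d <- cfg$data
      if (is.null(d$grid) || is.null(d$community) ||
          (is.null(d$tree) && is.null(d$trees)))
        pr_stop("data needs grid, community and tree(s)", "invalid_argument")
      d
    }
  })
  cm <- world$community
  tree <- if (!is.null(world$tree)) world$tree else world$trees[[1]]

  trees <- stage("treegraft", {
    if (cfg$keep_frac < 1) {
      bb <- make_backbone(tree, world$taxonomy, cfg$keep_frac,
                          pr_child_seed(cfg$seed, 10))
      note("backbone retained %d of %d tips", length(bb$backbone$tip.label),
           length(tree$tip.label))
      sample_tree_set(bb$backbone, world$taxonomy, bb$targets,
                      cfg$n_trees, pr_child_seed(cfg$seed, 11))
    } else if (!is.null(world$trees)) world$trees else list(tree)
  })

  D <- stage("betadiv", mean_dissimilarity(trees, cm))

  sel <- stage("linkage", {
    if (identical(cfg$linkage, "auto")) select_linkage(D)
    else list(best = cfg$linkage,
              coefficients = setNames(
                cophenetic_correlation(linkage_dendrogram(D, cfg$linkage), D),
                cfg$linkage),
              dendrogram = linkage_dendrogram(D, cfg$linkage))
  })
  dend <- sel$dendrogram

  elbow <- stage("elbow", optimal_k(dend, D, min(cfg$k_max, nrow(as.matrix(D)))))
  k <- if (identical(cfg$k, "auto")) elbow$k_opt else cfg$k
  regions <- stage("regions", cut_regions(dend, k, "phyloregions"))
  realms <- stage("realms", cut_realms(dend, D, cfg$realm_threshold, "realms"))
  regions <- stage("nesting", nest_realms(regions, realms))

  diversity <- stage("diversity",
                     region_diversity(cm, tree, regions$region, D))
  nmds <- if (k >= 3)
    stage("nmds", ordinate_regions(D, regions$region,
                                   pr_child_seed(cfg$seed, 20)))
  else NULL

  truth_cmp <- NULL
  if (!is.null(world$truth)) {
    truth_cmp <- stage("schemecompare", {
      tl <- structure(list(region = world$truth$region_of_cell,
                           realm_of_region = world$truth$realm_of_region,
                           scheme = "planted"), class = "pr_labeling")
      vt <- v_measure_test(tl, regions, world$grid, cfg$n_null,
                           pr_child_seed(cfg$seed, 30))
      vt$null_V <- NULL
      vt$k_recovered <- k
      vt$n_realms_recovered <- length(unique(regions$realm_of_region))
      vt
    })
  }

  drivers <- NULL
  if (isTRUE(cfg$run_drivers) && !is.null(world$env)) {
    drivers <- stage("boundarydrivers", {
      preds <- build_boundary_predictors(world$env, world$grid)
      bd <- boundary_distance(regions, world$grid, "region")
      lapply(setNames(nm = c("all", "realm", "within-realm")), function(lv) {
        resp <- boundary_contact(regions, world$grid, lv)
        if (all(resp == 0) || all(resp == 1)) {
          note("boundary level '%s' degenerate; fit skipped", lv)
          return(NULL)
        }
        fit_boundary_model(resp, preds, world$grid,
                           neighbor_km = cfg$neighbor_km,
                           band_km = cfg$band_km, boundary_km = bd)
      })
    })
  } else if (isTRUE(cfg$run_drivers)) {
    stage("boundarydrivers",
          pr_stop("drivers requested but no environmental layers supplied",
                  "invalid_argument"))
  }

  indicators <- NULL
  if (isTRUE(cfg$run_indicators)) {
    indicators <- stage("nodeindicators",
                        suppressMessages(indicator_clades(
                          tree, cm, regions, cfg$gnd_threshold, cfg$n_perm,
                          pr_child_seed(cfg$seed, 40))))
  }

  res <- list(config = cfg, grid = world$grid, community = cm, tree = tree,
              trees = trees, dissimilarity = D, linkage = sel,
              elbow = elbow, regions = regions, realms = realms,
              diversity = diversity, nmds = nmds, truth = world$truth,
              truth_comparison = truth_cmp, drivers = drivers,
              indicators = indicators, log = log)
  if (!is.null(outdir)) write_pipeline(res, outdir)
  res
}

#' Persist pipeline outputs
#'
#' Writes every intermediate in its module's standard format plus a
#' machine-readable `report.json` with the statistics, seeds and config
#' echo.
#'
#' @param res A [run_pipeline()] result.
#' @param outdir Output directory (created if needed).
#' @export
write_pipeline <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(outdir, f)
  write_grid(res$grid, fp("grid.csv"))
  write_community(res$community, fp("community.csv"))
  ape::write.tree(res$tree, fp("tree.nwk"))
  if (length(res$trees) > 1)
    ape::write.tree(do.call(c, res$trees), fp("tree_set.nwk"))
  dm <- as.data.frame(res$dissimilarity)
  write.csv(cbind(cell = rownames(dm), dm), fp("dissimilarity.csv"),
            row.names = FALSE)
  write_labeling(res$regions, fp("regions.csv"))
  write.csv(res$diversity, fp("diversity.csv"), row.names = FALSE)
  if (!is.null(res$nmds))
    write.csv(data.frame(region = rownames(res$nmds$coords),
                         res$nmds$coords), fp("nmds.csv"), row.names = FALSE)
  if (!is.null(res$indicators))
    write.csv(res$indicators, fp("indicators.csv"), row.names = FALSE)
  report <- list(
    seed = res$config$seed,
    linkage = res$linkage$best,
    cophenetic = as.list(res$linkage$coefficients),
    k_opt = res$elbow$k_opt,
    explained_variance = as.list(res$elbow$ev),
    n_realms = length(unique(res$regions$realm_of_region)),
    nmds_stress = if (!is.null(res$nmds)) res$nmds$stress else NULL,
    truth_comparison = res$truth_comparison,
    drivers = lapply(res$drivers, function(f) {
      if (is.null(f)) NULL
      else list(n = f$n, sigma2 = f$sigma2, converged = f$converged,
                coefficients = f$coefficients)
    }),
    n_indicator_rows = if (!is.null(res$indicators)) nrow(res$indicators) else 0,
    log = res$log,
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(report, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(outdir)
}
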