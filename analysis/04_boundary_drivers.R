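#!/usr/bin/env Rscript
# Stage 4: environmental drivers of region boundaries. Build the six
# turnover predictors (focal CV of four climate layers, terrain ruggedness,
# LGM climate velocity), screen collinearity by VIF, and fit the spatial
# binomial boundary model three times: all boundaries, deep between-realm
# boundaries, shallow within-realm boundaries — each restricted to the
# 200 km band around boundaries with an automatically connected
# neighbourhood.

suppressPackageStartupMessages(library(phylorealms))

wdir <- "results/world"; rdir <- "results/regionalization"
outdir <- "results/drivers"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

grid <- read_grid(file.path(wdir, "grid.csv"))
regions <- read_labeling(file.path(rdir, "regions.csv"), "phyloregions")
env <- lapply(setNames(nm = c("temp_seasonality", "precip_seasonality", "mat",
                              "map", "elevation", "temp_present", "temp_lgm")),
              function(nm) {
                df <- read.csv(file.path(wdir, paste0("env_", nm, ".csv")))
                setNames(df$value, df$cell)
              })

preds <- build_boundary_predictors(env, grid)
v <- vif(do.call(cbind, preds))
message("variance inflation factors:")
print(round(v, 2))

bd <- boundary_distance(regions, grid, "region")
fits <- list()
for (lv in c("all", "realm", "within-realm")) {
  resp <- boundary_contact(regions, grid, lv)
  if (all(resp == 0) || all(resp == 1)) {
    message(sprintf("level '%s': degenerate response, skipped", lv))
    next
  }
  f <- fit_boundary_model(resp, preds, grid, neighbor_km = "auto",
                          band_km = 200, boundary_km = bd)
  message(sprintf("level '%s': n = %d, neighbourhood %.0f km, %s",
                  lv, f$n, f$neighbor_km,
                  if (f$converged) "converged" else "NOT converged"))
  tab <- f$coefficients
  tab$level <- lv
  fits[[lv]] <- tab
  top <- tab[tab$term != "(Intercept)", ]
  top <- top[order(-abs(top$fisher_z)), ][1, ]
  message(sprintf("  strongest effect: %s (Fisher z = %.3f, p = %.3g)",
                  top$term, top$fisher_z, top$p))
}
write.csv(do.call(rbind, fits), file.path(outdir, "boundary_models.csv"),
          row.names = FALSE)
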