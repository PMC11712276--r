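#!/usr/bin/env Rscript
# Stage 2: the regionalization chain. Prune the tree to a backbone, regraft
# the missing species into a set of random trees, average the phylogenetic
# Simpson dissimilarities over the set, choose the linkage by cophenetic
# correlation, pick the number of regions by the elbow on explained
# variance, cut realms at the 60% variance threshold, and summarize
# diversity and endemism per region with an NMDS ordination.

suppressPackageStartupMessages(library(phylorealms))

indir <- "results/world"; outdir <- "results/regionalization"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

grid <- read_grid(file.path(indir, "grid.csv"))
cm <- load_community(file.path(indir, "community.csv"), "triplet-csv",
                     cells = land_cells(grid))
tree <- ape::read.tree(file.path(indir, "tree.nwk"))
tax <- read_taxonomy(file.path(indir, "taxonomy.csv"))

# backbone + scenario-2 grafting (20 random trees keep this desk-sized; the
# full-scale workflow uses 100)
bb <- make_backbone(tree, tax, keep_frac = 0.8, seed = 11)
trees <- sample_tree_set(bb$backbone, tax, bb$targets, n_trees = 20, seed = 12)
message(sprintf("grafted %d species onto a %d-tip backbone, %d random trees",
                length(bb$targets) - length(bb$backbone$tip.label),
                length(bb$backbone$tip.label), length(trees)))

D <- mean_dissimilarity(trees, cm)
write.csv(cbind(cell = rownames(D), as.data.frame(D)),
          file.path(outdir, "mean_phylo_simpson.csv"), row.names = FALSE)

sel <- select_linkage(D)
message(sprintf("linkage by cophenetic correlation: %s (%.3f); runner-up %s (%.3f)",
                sel$best, max(sel$coefficients),
                names(sort(sel$coefficients, decreasing = TRUE))[2],
                sort(sel$coefficients, decreasing = TRUE)[2]))

el <- optimal_k(sel$dendrogram, D, k_max = 30)
message(sprintf("elbow: k = %d regions (ev at k: %.3f)", el$k_opt,
                el$ev[el$k_opt]))
regions <- cut_regions(sel$dendrogram, el$k_opt, "phyloregions")
realms <- cut_realms(sel$dendrogram, D, threshold = 0.60, "realms")
message(sprintf("realm cut at 0.60 variance: %d realms (ev %.3f)",
                length(unique(realms$region)),
                explained_variance(D, realms$region)))
regions <- nest_realms(regions, realms)
write_labeling(regions, file.path(outdir, "regions.csv"))

div <- region_diversity(cm, tree, regions$region, D)
write.csv(div, file.path(outdir, "diversity.csv"), row.names = FALSE)
message("per-region diversity (SR, PD, mean WE/PE, ED):")
print(div, digits = 3)

nm <- ordinate_regions(D, regions$region, seed = 13)
write.csv(data.frame(region = rownames(nm$coords), nm$coords),
          file.path(outdir, "nmds.csv"), row.names = FALSE)
message(sprintf("NMDS stress: %.3f", nm$stress))
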