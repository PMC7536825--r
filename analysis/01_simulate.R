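#!/usr/bin/env Rscript
# Stage 1: build the synthetic embryo used by the whole analysis.
#
# 500 spatial bins on a half-ellipsoid shell, 60 reference genes (45
# spatially structured, 15 random decoys), 300 dissociated cells with
# mild profile noise (flip_prob = 0.05) and realistic sequencing depth.
# Everything downstream reads the files written here.

suppressPackageStartupMessages(library(crowdmap))

seed <- 20240925L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

geometry <- generate_geometry(500, k_neighbors = 10, seed = seed)
atlas <- generate_atlas(geometry, default_pattern_panel(60, 15),
                        seed = seed + 1L)
sim <- generate_cells(atlas, geometry, 300,
                      synthetic_truth(flip_prob = 0.05,
                                      depth_mean = 5000,
                                      dropout_midpoint = 10,
                                      seed = seed + 2L))

write_spatial_reference(atlas, geometry,
                        file.path(out, "atlas.tsv"),
                        file.path(out, "geometry.tsv"))
write_expression(sim$expr, file.path(out, "expression_raw.tsv"),
                 layer = "raw")
# latent ON/OFF truth and true bins, for later benchmarking only
latent <- sim$expr$latent
write.table(data.frame(gene = rownames(latent), latent,
                       check.names = FALSE),
            file.path(out, "latent_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.csv(data.frame(cell_id = names(sim$truth$true_bin_per_cell),
                     bin = sim$truth$true_bin_per_cell),
          file.path(out, "true_bins.csv"), row.names = FALSE,
          quote = FALSE)

cat(sprintf("bins: %d (half-shell), genes: %d (%d decoys), cells: %d\n",
            nrow(geometry$coords), length(atlas$genes), 15,
            length(sim$expr$cells)))
cat(sprintf("mean UMI per cell: %.0f; zero fraction: %.2f\n",
            mean(colSums(sim$expr$raw)), mean(sim$expr$raw == 0)))
cat("wrote", out, "\n")
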