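#!/usr/bin/env Rscript
# Stage 4 (Approach 2): shape PCA per jaw, through-origin PIC correlations
# of the leading axes against a Brownian-motion null band, and phylogenetic
# two-block PLS of the full aligned coordinates.

suppressPackageStartupMessages(library(evodecouple))

out_dir <- "results/evocorr"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

tree <- read_newick(file = "results/data/tree.nwk")
load_means <- function(jaw) {
  species_mean_shapes(
    read_landmarks_csv(sprintf("results/aligned/%s_species_means.csv", jaw)))
}
oral_means <- load_means("oral")
lpj_means <- load_means("lpj")

pca_oral <- shape_pca(oral_means)
pca_lpj <- shape_pca(lpj_means)
message(sprintf("oral PC1-3 explain %.1f / %.1f / %.1f %% of variance",
                pca_oral$percent_variance[1], pca_oral$percent_variance[2],
                pca_oral$percent_variance[3]))
message(sprintf("LPJ  PC1-3 explain %.1f / %.1f / %.1f %% of variance",
                pca_lpj$percent_variance[1], pca_lpj$percent_variance[2],
                pca_lpj$percent_variance[3]))

for (jaw in c("oral", "lpj")) {
  p <- if (jaw == "oral") pca_oral else pca_lpj
  write.csv(data.frame(species = rownames(p$scores), p$scores[, 1:3]),
            file.path(out_dir, paste0(jaw, "_pc_scores.csv")),
            row.names = FALSE)
}

null <- null_correlations(tree, n_pairs = 1000, seed = 433)
print(null)
grid <- pic_correlation_grid(tree, pca_oral$scores[, 1:3],
                             pca_lpj$scores[, 1:3], null)
write.csv(grid, file.path(out_dir, "pic_correlation_grid.csv"),
          row.names = FALSE)
n_integrated <- sum(grid$outside_null)
message(sprintf("%d of 9 PC-axis pairs exceed the null band [%.3f, %.3f]",
                n_integrated, null$min, null$max))

flat <- function(m) t(apply(m, 3, as.numeric))
pls <- phylo_pls(flat(oral_means), flat(lpj_means), tree,
                 n_permutations = 999, seed = 434)
print(pls)
jsonlite::write_json(
  list(null = list(min = null$min, max = null$max, ci95 = null$ci95),
       pls = list(r = pls$r_pls, p = pls$p),
       percent_variance = list(oral = pca_oral$percent_variance[1:3],
                               lpj = pca_lpj$percent_variance[1:3])),
  file.path(out_dir, "evocorr.json"), auto_unbox = TRUE, digits = NA)
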