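#!/usr/bin/env Rscript
# Stage 2: landmark alignment. Mirrors the LPJ half-configurations into
# full bilateral configurations, runs generalized Procrustes analysis on
# both jaws, and stores species mean shapes.

suppressPackageStartupMessages(library(evodecouple))

data_dir <- "results/data"
out_dir <- "results/aligned"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

scn <- yaml::read_yaml(file.path(data_dir, "scenario.yaml"))
oral <- read_tps(file.path(data_dir, "oral_premaxilla.tps"),
                 structure = "oral_premaxilla")
lpj_half <- read_tps(file.path(data_dir, "lpj_half.tps"), structure = "lpj_half")

full <- lapply(seq_len(dim(lpj_half$coords)[3]), function(i) {
  mirror_landmarks(lpj_half$coords[, , i],
                   unlist(scn$lpj_midline_ids), unlist(scn$lpj_paired_ids))
})
lpj_full <- landmark_set(full, lpj_half$specimens$specimen_id,
                         lpj_half$specimens$species_id, structure = "lpj_full")

oral_gpa <- gpa(oral, scale = TRUE)
lpj_gpa <- gpa(lpj_full, scale = TRUE)
message(sprintf("GPA converged in %d (oral) / %d (LPJ) iterations",
                oral_gpa$iterations, lpj_gpa$iterations))

for (jaw in c("oral", "lpj")) {
  fit <- if (jaw == "oral") oral_gpa else lpj_gpa
  means <- species_mean_shapes(fit)
  sp <- dimnames(means)[[3]]
  lms <- landmark_set(lapply(sp, function(s) means[, , s]), sp, sp,
                      structure = paste0(jaw, "_species_mean"))
  write_landmarks_csv(lms, file.path(out_dir, paste0(jaw, "_species_means.csv")))
  write.csv(data.frame(specimen_id = names(fit$centroid_sizes),
                       centroid_size = fit$centroid_sizes),
            file.path(out_dir, paste0(jaw, "_centroid_sizes.csv")),
            row.names = FALSE)
}
message("species mean shapes written under ", out_dir)
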