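#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study inputs.
#
# No patient radiographs ship with this workflow; everything downstream
# runs on phantoms with known ground truth. This script writes:
#   results/inputs/images/        phantom ROI images (PNG, 8-bit grey)
#   results/inputs/rois.csv       ROI origin table
#   results/inputs/landmarks.csv  landmark table with known MCW/PMI
#   results/inputs/metadata.csv   patient id, group, age, sex
#   results/inputs/cohort_sim.csv large simulated per-patient table for
#                                 the statistical layer (92 patients,
#                                 groups 35/33/24)

suppressPackageStartupMessages(library(mandifrac))

seed <- 20250930L
out <- "results/inputs"
dir.create(file.path(out, "images"), recursive = TRUE, showWarnings = FALSE)

# -- a small imaging cohort: 12 patients, 4 per group, mixed textures ----
n_img <- 12L
groups <- rep(c("normal", "borderline", "high"), each = 4)
models <- rep(c("ifs_fractal", "spectral_surface", "strut_lattice"), 4)
meta <- data.frame(patient_id = sprintf("P%02d", 1:n_img),
                   image = sprintf("img%02d.png", 1:n_img),
                   group = groups,
                   age = round(seq(45, 78, length.out = n_img)),
                   sex = rep(c("male", "female"), 6))
rois <- NULL
lms <- NULL
known <- NULL
for (i in 1:n_img) {
  img <- make_grey_patch(synth_params(
    seed = seed + i, texture_model = models[i], size = 80,
    illumination_amplitude = 40, noise_sd = 6))
  write_image(img, file.path(out, "images", meta$image[i]))
  rois <- rbind(rois, data.frame(
    image = meta$image[i], region = c("anterior", "premolar", "molar"),
    side = "right", row = c(0, 8, 16), col = c(0, 8, 16), size = 64))
  a <- 10 + (i %% 5); b <- 38 + i
  fx <- make_landmark_fixture(seed = seed + 100 + i, a = a, b = b)
  lm <- fx$landmarks
  for (side in c("right", "left")) {
    lms <- rbind(
      lms,
      data.frame(image = meta$image[i], side = side,
                 role = "inferior_border",
                 point_index = seq_len(nrow(lm$inferior_border)),
                 row = lm$inferior_border[, 1],
                 col = lm$inferior_border[, 2]),
      data.frame(image = meta$image[i], side = side,
                 role = "foramen_lower_edge", point_index = 1,
                 row = lm$foramen_lower_edge[1],
                 col = lm$foramen_lower_edge[2]),
      data.frame(image = meta$image[i], side = side,
                 role = "cortical_inner_margin",
                 point_index = seq_len(nrow(lm$cortical_inner_margin)),
                 row = lm$cortical_inner_margin[, 1],
                 col = lm$cortical_inner_margin[, 2]))
  }
  known <- rbind(known, data.frame(image = meta$image[i], mcw = a, b = b,
                                   pmi = a / b))
}
write.csv(meta, file.path(out, "metadata.csv"), row.names = FALSE)
write.csv(rois, file.path(out, "rois.csv"), row.names = FALSE)
write.csv(lms, file.path(out, "landmarks.csv"), row.names = FALSE)
write.csv(known, file.path(out, "landmark_truth.csv"), row.names = FALSE)

# -- full-size statistical cohort: 92 patients, published group medians --
co <- make_cohort(cohort_params(seed = seed))
write_cohort(co, file.path(out, "cohort_sim.csv"))

cat("wrote", n_img, "phantom images +", nrow(co), "cohort rows under",
    out, "\n")
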