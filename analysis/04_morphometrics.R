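#!/usr/bin/env Rscript
# Stage 4: cranial shape. Procrustes superimposition with the bilateral
# symmetry decomposition, ontogenetic allometry of shape (and pes length)
# on log centroid size, per-sex interpopulation permutation linear models
# on the age-trimmed sample, and predicted young/old shape endpoints.

suppressPackageStartupMessages(library(fenceroo))

seed <- 2026L
n_perm <- 1000L
dir.create("results", showWarnings = FALSE)

records <- read_specimens("results/data/specimens.csv", quiet = TRUE)
trimmed <- read_specimens("results/data/specimens_trimmed.csv", quiet = TRUE)
pairing <- read_pairing("results/data/landmark_pairing.csv")
configs <- read_landmarks("results/data/landmarks.tps", format = "tps",
                          pairing = pairing)

shapes <- bilateral_symmetry(configs, pairing)
message(sprintf("GPA converged in %d iterations (change %.1e)",
                shapes$convergence$iterations,
                shapes$convergence$final_change))

allo <- allometry_model(shapes, records, n_perm = n_perm, seed = seed + 10L)
print(allo$perm)
pes_dat <- data.frame(
  log_cs = log(shapes$centroid_sizes),
  sex = factor(records$sex[match(shapes$specimen_ids, records$specimen_id)]),
  pes = records$pes_length_cm[match(shapes$specimen_ids,
                                    records$specimen_id)])
pes_allo <- rrpp_lm(pes_dat$pes, ~ log_cs * sex, pes_dat, n_perm = n_perm,
                    seed = seed + 11L)
print(pes_allo)

# shape predicted at the young and old ends of the size range
young <- predicted_shape(allo, data.frame(
  log_cs = min(allo$data$log_cs), sex = levels(allo$data$sex)[1]))
old <- predicted_shape(allo, data.frame(
  log_cs = max(allo$data$log_cs), sex = levels(allo$data$sex)[1]))
write_tps(list(landmark_config("predicted_young", young),
               landmark_config("predicted_old", old)),
          "results/predicted_shapes.tps")

interpop <- interpopulation_tests(trimmed, shapes, n_perm = n_perm,
                                  seed = seed + 12L)
print(interpop)

write.table(rbind(
  cbind(model = "shape_allometry", allo$perm$aov_table),
  cbind(model = "pes_allometry", pes_allo$aov_table)),
  "results/allometry.tsv", sep = "\t", row.names = FALSE, quote = FALSE)
write.table(interpop$table, "results/interpopulation_tests.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("wrote results/allometry.tsv, results/interpopulation_tests.tsv, ",
        "results/predicted_shapes.tps")
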