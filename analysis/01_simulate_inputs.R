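#!/usr/bin/env Rscript
# Generate every synthetic input used by the downstream analyses: a planted
# plane-wave grid record, an evoked trial set with strong/weak late waves,
# a calcium raster with planted ensembles, a laminar dipole record, and a
# whisker pose table. All ground truth is written alongside the data.

suppressPackageStartupMessages(library(cortexwaves))
seed <- 1
out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

wave <- wave_field_spec(f0 = 10, speed = 0.3, amplitude = 50, noise_sd = 5,
                        duration = 2, seed = seed)
write_grid_lfp(generate_wave_lfp(wave), file.path(out, "plane_wave"))

trials <- trial_set_spec(n_trials = 30, early_amp = 80,
                         late_amp = rep(c(50, 0), 15),
                         responsive_fraction = 1, seed = seed)
trial_lfp <- generate_trial_lfp(trials, wave)
write_grid_lfp(trial_lfp, file.path(out, "trials"))

members <- split(1:24, rep(1:3, each = 8))
cal <- ensemble_raster_spec(
  n_cells = 200, n_frames = 1200, frame_rate = 20,
  ensembles = lapply(members, function(m)
    list(members = m, p_active = 0.3, amplitude = 0.5)),
  background_rate = 0.005, seed = seed)
write_calcium_raster(generate_calcium_raster(cal), file.path(out, "calcium"))

lam <- generate_laminar_lfp(laminar_dipole_spec(sink_depth = 5,
                                                source_depth = 11,
                                                seed = seed))
write_matrix_tsv <- function(m, p) write.table(m, p, sep = "\t",
                                               row.names = FALSE,
                                               col.names = FALSE)
write_matrix_tsv(lam$data, file.path(out, "laminar_lfp.tsv"))

pose <- generate_whisker_traces(behavior_spec(seed = seed))
write_pose_table(pose, file.path(out, "pose.tsv"))
jsonlite::write_json(attr(pose, "ground_truth")["touch_frames"],
                     file.path(out, "pose_ground_truth.json"),
                     auto_unbox = TRUE, digits = NA)

cat("wrote synthetic inputs (wave, trials, calcium, laminar, pose) to",
    out, "\n")
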