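#!/usr/bin/env Rscript
# Generate one synthetic instance of every input modality with known
# ground truth, and write them in the interchange formats the rest of
# the workflow reads.  All downstream scripts start from these files.

suppressMessages(library(abmorph))

seed <- 20260925L
out_dir <- "results/simulated"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cat("== simulating inputs (seed", seed, ") ==\n")

# --- AFM time series of one elongating oligomer (Fig.-4-like) --------
pars <- growth_sim_params(rate_end_a = 7.9, rate_end_b = 8.0,
                          frame_interval = 8, n_frames = 6,
                          pixel_size = 12, roughness_sd = 0.05)
afm <- gen_afm_series(pars, initial_length = 20, seed = seed)
write_afm_series(afm$series, file.path(out_dir, "afm_growth.tif"))
jsonlite::write_json(
  lapply(afm$truth, function(t) t[c("length_nm", "excursion_a", "excursion_b")]),
  file.path(out_dir, "afm_growth_truth.json"), auto_unbox = TRUE, digits = NA)
cat("AFM series:", length(afm$series$frames), "frames,",
    "final true length", afm$truth[[6]]$length_nm, "nm\n")

# --- 2D class-average-like field with 2.8 nm tubes -------------------
cl <- cbind(seq(6, 54, by = 0.5), rep(30, 97))
tube <- assembly_truth("curvilinear", centerline = cl, tube_diameter = 2.8)
dens2d <- gen_density_field(list(tube), dims = c(300, 300), voxel_size = 0.2,
                            blur_sd = 0.1, noise_sd = 0.2, seed = seed,
                            mode = "projection")
write_mrc(dens2d$field, file.path(out_dir, "tube_2d.mrc"))

# --- 3D annular assembly volumes (tomogram-like) ---------------------
torus <- assembly_truth("annulus", center = c(10, 10, 6.4),
                        ring_outer_diameter = 7.5, ring_inner_diameter = 2.0)
vol1 <- gen_density_field(list(torus), dims = c(80, 80, 52),
                          voxel_size = 0.25, blur_sd = 0, noise_sd = 0,
                          seed = seed + 1L)
write_mrc(vol1$field, file.path(out_dir, "annulus_tomo.mrc"))

recon <- assembly_truth("annulus", center = c(9, 9, 5.8),
                        ring_outer_diameter = 6.0, ring_inner_diameter = 1.25,
                        channel_length = 5.4)
vol2 <- gen_density_field(list(recon), dims = c(72, 72, 47),
                          voxel_size = 0.25, blur_sd = 0, noise_sd = 0,
                          seed = seed + 2L)
write_mrc(vol2$field, file.path(out_dir, "annulus_recon.mrc"))
cat("density fields written (2D tube, 2 annulus volumes)\n")

# --- ThT aggregation curve (28 h lag, 50 h midpoint) -----------------
tht <- gen_tht_curve(lag_h = 28, midpoint_h = 50, plateau = 100,
                     noise_sd = 1, t_grid = seq(0, 150, by = 0.5),
                     seed = seed)
write_curve_csv(tht, file.path(out_dir, "tht_curve.csv"))

# --- length populations over the growth time course ------------------
pops <- gen_length_population(c(28, 30, 32, 34, 36),
                              c(5, 55, 110, 170, 225),
                              dispersion = 0.35, n_per_t = 100, seed = seed)
lengths_df <- do.call(rbind, lapply(pops, function(p)
  data.frame(t_label = p$t_label, length_nm = p$lengths)))
utils::write.csv(lengths_df, file.path(out_dir, "length_populations.csv"),
                 row.names = FALSE)
cat("kinetic curve and", nrow(lengths_df), "particle lengths written\n")

# --- patch-clamp current trace (320 pS two-state channel) ------------
eph <- gen_current_trace(channel_sim_params(), duration_ms = 100000,
                         seed = seed)
write_trace_csv(eph$trace, file.path(out_dir, "channel_trace.csv"))
utils::write.csv(data.frame(state = eph$states),
                 file.path(out_dir, "channel_trace_truth.csv"),
                 row.names = FALSE)
cat("100 s channel trace written\n")
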