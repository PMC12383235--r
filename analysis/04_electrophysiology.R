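#!/usr/bin/env Rscript
# Single-channel analysis: idealization, windowed modal conductance,
# and conductance-to-pore-diameter conversion.

suppressMessages(library(abmorph))

in_dir <- "results/simulated"
cfg <- run_config(seed = 20260925L)
cat("== electrophysiology ==\n")

trace <- read_trace_csv(file.path(in_dir, "channel_trace.csv"))
id <- idealize(trace)
cat(sprintf("detected level(s): %s pS; open probability %.3f\n",
            paste(round(id$levels_pS), collapse = ", "),
            id$open_probability))

truth <- utils::read.csv(file.path(in_dir, "channel_trace_truth.csv"))$state
acc <- mean(((id$states > 0) == (truth > 0))[id$valid])
cat(sprintf("idealization accuracy vs ground truth: %.1f%%\n", 100 * acc))

w <- windowed_modal_conductance(trace, window_ms = cfg$window_ms, ideal = id)
s <- ephys_summary(w, pore_model(cfg$channel_length_nm, cfg$rho_ohm_cm))
cat(sprintf("median modal conductance: %.0f pS over %d windows\n",
            s$median_modal_g_pS, sum(!w$flagged)))
cat(sprintf("pore diameter at the median: %.2f nm (range %.2f-%.2f)\n",
            s$d_nm_point, s$d_nm_range[1], s$d_nm_range[2]))

utils::write.csv(w, "results/conductance_windows.csv", row.names = FALSE)
write_report_json(
  list(levels_pS = id$levels_pS, open_probability = id$open_probability,
       idealization_accuracy = acc,
       median_modal_g_pS = s$median_modal_g_pS,
       g_range_pS = s$g_range_pS, g_typical_pS = s$g_typical_pS,
       d_nm_point = s$d_nm_point, d_nm_range = s$d_nm_range),
  "results/ephys_summary.json", cfg)
cat("wrote results/conductance_windows.csv, ephys_summary.json\n")
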