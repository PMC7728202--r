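#!/usr/bin/env Rscript
# Simulate the study cohort: event-free-ish control mice vs "obstructed"
# treated mice (higher apnea and flow-limitation burst rates, mimicking a
# bulked tongue base), written out as CSV traces with JSON sidecars.
#
# Recordings are 10 min at 1 kHz: long enough for ~1800 breaths, i.e. ~17
# full 100-breath baseline windows, while keeping the cohort cheap to
# regenerate. Seeds are fixed so every later stage is reproducible.

suppressPackageStartupMessages(library(wbpleth))

trace_dir <- "scratch/cohort"  # bulky raw traces; tables go under results/
out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
dir.create(trace_dir, recursive = TRUE, showWarnings = FALSE)

n_per_group <- 8
base_seed <- 20260401

control_cfg <- function(seed)
  sim_config(duration_s = 600, apnea_rate_per_h = 6,
             ifl_event_rate_per_h = 15, seed = seed)
treated_cfg <- function(seed)
  sim_config(duration_s = 600, apnea_rate_per_h = 60,
             ifl_event_rate_per_h = 60, seed = seed)

manifest <- data.frame()
for (g in c("control", "treated")) {
  for (i in seq_len(n_per_group)) {
    seed <- base_seed + 100 * (g == "treated") + i
    cfg <- if (g == "control") control_cfg(seed) else treated_cfg(seed)
    rec <- simulate_recording(cfg)
    id <- sprintf("%s_%02d", g, i)
    path <- file.path(trace_dir, paste0(id, ".csv"))
    write_flow_csv(rec$trace, path)
    write.csv(rec$truth$apneas,
              file.path(out_dir, paste0(id, "_truth_apneas.csv")),
              row.names = FALSE)
    manifest <- rbind(manifest, data.frame(
      animal_id = id, group = g, trace_path = path, seed = seed,
      truth_apneas = nrow(rec$truth$apneas),
      truth_ifl_breaths = length(rec$truth$ifl_breaths)))
    cat(sprintf("%s: %d breaths, %d apneas, %d IFL breaths injected\n",
                id, rec$truth$n_breaths, nrow(rec$truth$apneas),
                length(rec$truth$ifl_breaths)))
  }
}
write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
cat("cohort written to", out_dir, "\n")
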