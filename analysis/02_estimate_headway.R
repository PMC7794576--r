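#!/usr/bin/env Rscript
# Estimate the gaze time headway signal for every trial: read the plain-text
# logs written by 01_simulate_dataset.R, map gaze onto the track midline in
# screen coordinates, convert to seconds, apply the four exclusion filters.
# Writes the pooled tidy headway table to results/th_table.csv.

library(gazeway)

track <- track_config()
ml <- build_midline(track)
cam <- camera_model()

files <- list.files("results/data", "^vehicle_", full.names = TRUE)
stopifnot(length(files) > 0)
th <- do.call(rbind, lapply(files, function(vf) {
  gf <- sub("vehicle_", "gaze_", vf)
  veh <- read_vehicle_log(vf)
  gaz <- read_gaze_log(gf)
  win <- default_trial_window(track, participant = veh$participant[1],
                              trial = veh$trial[1], mode = veh$mode[1])
  estimate_th(veh, gaz, ml, cam, win)
}))
write_th_table(th, "results/th_table.csv")

cat(sprintf("estimated headway for %d samples; %.1f%% excluded\n",
            nrow(th), 100 * mean(th$excluded)))
print(table(th$reason))
inc <- th[!th$excluded, ]
cat("pooled median headway by mode (s):\n")
print(round(tapply(inc$th_s, inc$mode, median), 3))
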