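# gazeway

Tools for analysing *where drivers look along the road ahead* in
driving-simulator experiments, built around the gaze **time headway (TH)**
signal: the time it would take, at current speed, to reach the point on the
path where gaze falls.

During curve driving, gaze mostly tracks waypoints on the future path 1–3 s
ahead in a move–dwell–move ("sawtooth") rhythm, occasionally dwelling on
salient allocentric points such as the entry of an upcoming bend. This
package implements that analysis end to end for a stadium-shaped test track:

* **Headway estimation** — gaze in screen coordinates is mapped to the
  nearest point of the projected track midline (avoiding the ill-conditioned
  screen-to-world inverse projection near the horizon), converted to seconds
  along the midline, and filtered by four exclusion rules (low pupil
  confidence, off-surface gaze, >20° from the midline reference, gaze on an
  optical marker).
* **Mixture decomposition** — per participant and driving mode, the TH point
  cloud in (time into trial $x$, headway $y$) coordinates is decomposed by EM
  into components with structurally fixed slopes:

  $$p(y \mid x) \;=\; w_{GF}\,\mathcal N\!\left(y;\ \mu_{GF},\ \sigma_{GF}^2\right)
    \;+\; w_{EF}\,\mathcal N\!\left(y;\ c_{EF}-x,\ \sigma_{EF}^2\right)
    \;+\; w_{0}\,\mathcal U(y;\ 0, 8)$$

  The slope-0 **guiding fixation** (GF) component is a region that moves with
  the observer; the slope −1 **entry fixation** (EF) component is a fixed
  world point (the bend-entry attractor) whose intercept $c_{EF}$ is its
  time-along-midline; the fixed uniform component absorbs off-task noise.
  Every sample gets a responsibility vector rather than a hard class.
* **Gaze sequencing** — penalised segmented linear regression (exact dynamic
  programming) parses the gaze-angle trace into tracking episodes and
  saccades, yielding forward-saccade launch/land headways and inter-saccadic
  tracking durations on the bend.
* **Condition inference** — participant medians enter a hierarchical Bayesian
  normal model (JAGS); driving modes (Manual, Auto-Replay, Auto-Stock) are
  compared via posterior contrast means, 95% highest-density intervals and
  posterior mass above zero.
* **Synthetic data** — a generator with full ground truth (sawtooth waypoint
  tracking, bend-entry attractor, off-task artefacts, angular measurement
  noise, configurable between-mode shifts) that makes every stage testable
  for *recovery*, not just plausibility.

The methods vignette (`vignettes/gaze-time-headway-methods.Rmd`) documents
the models, assumptions, parameter defaults and known limitations.

## Worked example

Simulate six trials of one participant driving the approach straight and
bend, estimate the headway signal, and decompose it:

```r
library(gazeway)

track   <- track_config()            # 120 m straights, 25 m bends, 8 m/s
midline <- build_midline(track)
cam     <- camera_model()            # 89 x 58 degree display, eye at 1.2 m

cfg    <- synth_config(seed = 7)
window <- default_trial_window(track)
traj   <- simulate_trajectory(midline, window)
vehicle <- cbind(data.frame(participant = 1L, mode = "Manual", trial = 1L),
                 traj[, c("t", "x", "z", "yaw")])
th <- do.call(rbind, lapply(1:6, function(k) {
  set.seed(100 + k)
  sim <- simulate_gaze(traj, midline, cam, cfg, mode = "Manual")
  estimate_th(vehicle, sim$gaze, midline, cam, window)
}))

entry <- bend_entry(track, window)   # bend entry 5 s into the trial
inc   <- th[!th$excluded, ]
fit   <- grid_fit(inc$time_into_trial_s, inc$th_s,
                  default_init_grid(entry$time_s))
```

This prints (via the `sprintf` calls in `analysis/`-style drivers):

```
5340 samples, 4.4% excluded, median TH 2.02 s
GF mean 2.05 s (sd 0.61), attractor at 5.74 s along the midline
weights: GF 0.96, EF 0.03, noise 0.01
```

Read: gaze spent most of its time about 2 s ahead of the vehicle (the
guiding-fixation region); a small share of samples lay on the slope −1 line
through the point 5.74 s along the midline — about 0.74 s of travel past the
bend entry, which this generator placed 1 s past it; ~1% of samples were
off-task noise. The exclusion filters removed 4.4% of samples, almost all of
them injected artefacts.

The numbered drivers under `analysis/` run the full study — simulate 11
participants × 3 modes (`01`), estimate headway from the written logs
(`02`), fit all mixtures (`03`), sequence gaze on the bend (`04`), and
compare conditions (`05`) — writing tables under `results/`.

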