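# Shared fixtures: hand-built runs and the brute-force support oracle.

# Build a gait_run from a compact event spec without validity checks.
make_run <- function(paw, t_on, t_off, x = seq_along(paw), y = 0,
                     area = 0.7, intensity = 0.35,
                     runway_length = 60, frame_rate = 100) {
  gait_run(tibble::tibble(paw = paw, t_on = t_on, t_off = t_off,
                          x = x, y = rep_len(y, length(paw)),
                          max_area = rep_len(area, length(paw)),
                          max_intensity = rep_len(intensity, length(paw))),
           runway_length = runway_length, frame_rate = frame_rate,
           validate = FALSE)
}

# Independent support-profile oracle: per-sample counting at 1 ms resolution.
support_oracle <- function(run, dt = 1e-3) {
  ev <- run$events
  t0 <- min(ev$t_on); t1 <- max(ev$t_off)
  ts <- seq(t0 + dt / 2, t1 - dt / 2, by = dt)
  cats <- c("zero", "single", "diagonal", "girdle", "lateral", "three", "four")
  counts <- stats::setNames(numeric(7), cats)
  for (tt in ts) {
    act <- ev$paw[ev$t_on <= tt & ev$t_off > tt]
    k <- length(act)
    cat <- if (k == 0) "zero" else if (k == 1) "single" else if (k >= 4) {
      "four"
    } else if (k == 3) "three" else {
      s <- sort(act)
      if (identical(s, c("LF", "RH")) || identical(s, c("LH", "RF"))) {
        "diagonal"
      } else if (identical(s, c("LF", "RF")) || identical(s, c("LH", "RH"))) {
        "girdle"
      } else "lateral"
    }
    counts[cat] <- counts[cat] + 1
  }
  100 * counts / length(ts)
}

# Random valid parameter draw with event times aligned to the 1 ms grid, so
# that a 1 kHz sample counter partitions time exactly.
random_run <- function(seed) {
  run <- with_seed_local(seed, {
    p <- gait_params(
      step_cycle_mean = stats::runif(1, 0.15, 0.3),
      step_cycle_cv = stats::runif(1, 0, 0.1),
      duty_factor = stats::runif(1, 0.35, 0.7),
      phase_offsets = sort_offsets(stats::runif(1, 0.01, 0.2)),
      stride_length_mean = stats::runif(1, 3.5, 6.5),
      body_speed_cv = stats::runif(1, 0, 0.4),
      timing_jitter_sd = stats::runif(1, 0, 0.004),
      stance_jitter_sd = stats::runif(1, 0, 0.02),
      bos_fore = stats::runif(1, 1.5, 2.5),
      bos_hind = stats::runif(1, 3, 4.5))
    simulate_run(p, seed = seed + 1L)
  })
  run$events$t_on <- round(run$events$t_on, 3)
  run$events$t_off <- pmax(round(run$events$t_off, 3),
                           run$events$t_on + 1e-3)
  run
}

sort_offsets <- function(lag) c(LF = 0, RH = lag, RF = 0.5, LH = 0.5 + lag)

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Zero-noise parameter sets used by round-trip tests.
zero_noise <- function(preset, ...) {
  preset(step_cycle_cv = 0, body_speed_cv = 0, timing_jitter_sd = 0,
         stance_jitter_sd = 0, pattern_noise = 0, start_jitter = 0, ...)
}

# Canonical exactly-solvable configuration: single support throughout,
# phi_max + duty = 1, so every profile field has a simple closed form.
canonical_params <- function() {
  gait_params(step_cycle_mean = 0.2, duty_factor = 0.25,
              phase_offsets = c(LF = 0, RH = 0.25, RF = 0.5, LH = 0.75),
              stride_length_mean = 5, bos_fore = 2, bos_hind = 3.6,
              start_jitter = 0)
}

# Full acquisition chain: render -> detect -> label.
frames_chain <- function(run, ...) {
  fs <- render_frames(run, ...)
  label_paws(detect_contacts(fs), frame_rate = fs$frame_rate,
             runway_length = run$runway_length)
}
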