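#' @keywords internal
"_PACKAGE"

# Deterministic stream splitting: every animal/run/stage RNG stream is derived
# from one master seed by mixing small integer indices. Arithmetic stays below
# 2^53 so the modulo is exact in doubles; results stay below 2^31.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in seq_along(idx)) {
    h <- (h * 69621 + as.numeric(idx[k]) * 104729 + 7919) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

rnorm_trunc <- function(n, sd, lim = 3) {
  if (sd == 0) return(numeric(n))
  pmin(pmax(stats::rnorm(n, 0, sd), -lim * sd), lim * sd)
}

#' Simulate one runway crossing
#'
#' Walks the kinematic gait model down the runway and returns the resulting
#' contact-event table as a [gait_run()]. The body centre advances
#' monotonically; each paw alternates stance (stationary print at the
#' placement point) and swing; footfall order follows the phase offsets, with
#' optional stochastic order swaps at rate `pattern_noise`.
#'
#' @details
#' Cycle `k` draws a duration `T_k = T (1 + e_k)` (`e ~ N(0, step_cycle_cv)`,
#' truncated at 3 sd) and a body speed `v_k = v (1 + d_k)`
#' (`d ~ N(0, body_speed_cv)`), so the cycle's stride is `v_k T_k`. Cycles are
#' generated until the next one would overrun the far margin. Paw `j` touches
#' down at phase `phi_j` of the cycle for `duty_factor * T_k` seconds, at the
#' body-centre position plus its longitudinal reach and half its girdle's base
#' of support laterally; Gaussian `timing_jitter_sd` perturbs both contact
#' boundaries. With all noise terms zero every downstream gait parameter has a
#' closed form in the parameters (exact round trip).
#'
#' @param params A [gait_params()] object.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A [gait_run()].
#' @export
#' @examples
#' run <- simulate_run(control_params(), seed = 42)
#' run
simulate_run <- function(params, seed = NULL) {
  validate_gait_params(params)
  with_seed(seed, {
    p <- params
    T0 <- p$step_cycle_mean
    v0 <- p$body_speed_mean
    x_start <- p$start_margin +
      if (p$start_jitter > 0) stats::runif(1, 0, p$start_jitter) else 0
    x_end <- p$runway_length - p$end_margin

    # generate step cycles until the next stride would overrun the runway
    cap <- ceiling((x_end - x_start) / p$stride_length_mean) + 10L
    Tk <- T0 * (1 + rnorm_trunc(cap, p$step_cycle_cv, 2.5))
    # per-cycle speed multipliers follow an AR(1) so that speed drifts on the
    # run scale (accelerations/decelerations), the component of walking-speed
    # variation the cycle-window CV statistic is sensitive to
    ar <- 0.65
    if (p$body_speed_cv > 0) {
      dk <- numeric(cap)
      dk[1L] <- stats::rnorm(1, 0, p$body_speed_cv)
      innov <- stats::rnorm(cap - 1L, 0, p$body_speed_cv * sqrt(1 - ar^2))
      for (k in seq_len(cap - 1L)) dk[k + 1L] <- ar * dk[k] + innov[k]
      dk <- pmin(pmax(dk, -2.5 * p$body_speed_cv), 2.5 * p$body_speed_cv)
    } else dk <- numeric(cap)
    vk <- v0 * pmax(1 + dk, 0.15)
    strides <- vk * Tk
    Xk <- x_start + cumsum(c(0, strides))
    n <- findInterval(x_end, Xk) - 1L  # placements per paw fitting the runway
    # k placements give k - 1 complete cycles; floor keeps the run valid
    n <- max(n, p$n_cycles_min + 1L)
    # a slow-to-fit draw (long strides) may overrun the runway once the cycle
    # floor applies: compress the strides just enough to stay on the glass
    if (Xk[n + 1L] > x_end) {
      scl <- (x_end - x_start) / (Xk[n + 1L] - x_start)
      strides <- strides * scl
      vk <- vk * scl
      Xk <- x_start + cumsum(c(0, strides))
    }
    Tk <- Tk[seq_len(n)]
    vk <- vk[seq_len(n)]
    tk <- cumsum(c(0, Tk))[seq_len(n)] # cycle start times
    Xc <- Xk[seq_len(n)]               # body position at cycle start

    phi <- p$phase_offsets[PAWS]
    reach <- c(LF = p$reach_fore, RF = p$reach_fore,
               LH = p$reach_hind, RH = p$reach_hind)
    ypos <- c(LF = p$bos_fore / 2, RF = -p$bos_fore / 2,
              LH = p$bos_hind / 2, RH = -p$bos_hind / 2)

    paw <- rep(PAWS, times = n)
    cyc <- rep(seq_len(n), each = 4L)
    t_on <- unname(tk[cyc] + phi[paw] * Tk[cyc])
    stance <- p$duty_factor * Tk[cyc]
    x <- unname(Xc[cyc] + vk[cyc] * phi[paw] * Tk[cyc] + reach[paw])
    y <- unname(ypos[paw])

    # stochastic footfall-order swaps: exchange the onsets of one adjacent
    # pair within the cycle's footfall sequence
    if (p$pattern_noise > 0 && n > 0L) {
      do_swap <- stats::runif(n) < p$pattern_noise
      which_pair <- sample.int(3L, n, replace = TRUE)
      ord_phi <- order(phi)            # footfall order within a cycle
      for (k in which(do_swap)) {
        i <- (k - 1L) * 4L + ord_phi[which_pair[k]]
        j <- (k - 1L) * 4L + ord_phi[which_pair[k] + 1L]
        tmp <- t_on[i]; t_on[i] <- t_on[j]; t_on[j] <- tmp
      }
    }

    if (p$timing_jitter_sd > 0) {
      t_on <- t_on + rnorm_trunc(length(t_on), p$timing_jitter_sd)
    }
    if (p$stance_jitter_sd > 0) {
      stance <- pmax(stance + rnorm_trunc(length(t_on), p$stance_jitter_sd),
                     0.25 * stance)
    }
    t_off <- t_on + stance
    shift <- min(t_on)                 # time origin at first contact
    t_on <- t_on - shift
    t_off <- t_off - shift

    ev <- tibble::tibble(
      paw = paw, t_on = t_on, t_off = t_off, x = x, y = y,
      max_area = p$print_area_mean,
      max_intensity = p$print_intensity_mean
    )

    # guard: enforce per-paw non-overlap (can only trip under extreme jitter)
    ev <- ev[order(ev$t_on), ]
    for (pw in PAWS) {
      i <- which(ev$paw == pw)
      if (length(i) > 1L) {
        over <- which(ev$t_off[i[-length(i)]] > ev$t_on[i[-1L]])
        if (length(over)) {
          ev$t_off[i[over]] <- ev$t_on[i[over + 1L]] - 1e-6
        }
      }
    }

    gait_run(ev, runway_length = p$runway_length, frame_rate = p$frame_rate,
             direction = 1, min_cycles = min(p$n_cycles_min, 5L))
  })
}

#' Simulate an open-field trajectory
#'
#' Bounded correlated random walk in a square arena: the heading diffuses with
#' per-step Gaussian increments and the instantaneous speed fluctuates around
#' `speed_mean`; steps reflect off the arena walls (reflection preserves step
#' length, so the path length is unaffected by wall encounters).
#'
#' @param speed_mean Mean walking speed in cm/s (set lower for lesioned
#'   animals, whose spontaneous activity is reduced).
#' @param duration Session length in seconds (> 0).
#' @param dt Sampling interval in seconds.
#' @param arena Side of the square arena in cm.
#' @param turn_sd SD of per-step heading increments (radians).
#' @param speed_cv Coefficient of variation of instantaneous speed.
#' @param seed Integer seed or `NULL`.
#' @return A tibble with columns `t`, `x`, `y`.
#' @export
simulate_open_field <- function(speed_mean, duration = 600, dt = 0.1,
                                arena = 50, turn_sd = 0.6, speed_cv = 0.3,
                                seed = NULL) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("simulate_open_field: `duration` must be > 0", call. = FALSE)
  }
  stopifnot(speed_mean >= 0, dt > 0, arena > 0)
  with_seed(seed, {
    nstep <- floor(duration / dt)
    heading <- stats::runif(1, 0, 2 * pi) +
      cumsum(c(0, stats::rnorm(nstep - 1L, 0, turn_sd)))
    speed <- pmax(speed_mean * (1 + stats::rnorm(nstep, 0, speed_cv)), 0)
    step <- speed * dt
    x <- numeric(nstep + 1L); y <- numeric(nstep + 1L)
    x[1L] <- arena / 2; y[1L] <- arena / 2
    for (i in seq_len(nstep)) {
      xi <- x[i] + step[i] * cos(heading[i])
      yi <- y[i] + step[i] * sin(heading[i])
      # reflect position and heading off walls (repeat for long steps)
      while (xi < 0 || xi > arena || yi < 0 || yi > arena) {
        if (xi < 0 || xi > arena) {
          xi <- if (xi < 0) -xi else 2 * arena - xi
          heading[i:nstep] <- pi - heading[i:nstep]
        }
        if (yi < 0 || yi > arena) {
          yi <- if (yi < 0) -yi else 2 * arena - yi
          heading[i:nstep] <- -heading[i:nstep]
        }
      }
      x[i + 1L] <- xi; y[i + 1L] <- yi
    }
    tibble::tibble(t = seq(0, by = dt, length.out = nstep + 1L), x = x, y = y)
  })
}

# Block-noise SD for a target readout~TH population correlation rho.
# With severity s = m_g + u (balanced groups, Var(s) = 1/4 + sev_sd^2),
# TH linear in s plus noise, and block severity s_b = s + eta:
#   cor(TH, s_b) = c * sd(s) / sqrt(Var(s) + Var(eta)),
#   c = dTH * sd(s) / sqrt(dTH^2 Var(s) + th_sd^2),
# so Var(eta) = Var(s) * (c^2 / rho^2 - 1) (0 when |rho| >= c).
block_tau <- function(rho, sev_sd, d_th, th_sd) {
  var_s <- 0.25 + sev_sd^2
  cc <- d_th * sqrt(var_s) / sqrt(d_th^2 * var_s + th_sd^2)
  if (abs(rho) >= cc) return(0)
  sqrt(var_s * (cc^2 / rho^2 - 1))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Interpolate generator parameters between the two presets at block-specific
# severities. Fields are clamped to a physiological envelope for walking mice
# (e.g. step cycles of 0.12-0.42 s, strides of 2.2-7.4 cm): the block noise
# needed to reproduce weak TH correlations is substantial, and without the
# envelope the severity tails would produce gaits no real animal walks
# (and whose Jensen-type tails would distort the cohort group means).
animal_params <- function(control, mptp, s_block, group_preset) {
  lerp <- function(field, s) {
    control[[field]] + (mptp[[field]] - control[[field]]) * s
  }
  p <- group_preset
  # timing interpolates on the step-frequency (1/T) scale: cadence is then
  # linear in the block severity (symmetric across animals), and the
  # reciprocal skew lands on run duration, which tolerates it
  f <- 1 / control$step_cycle_mean +
    (1 / mptp$step_cycle_mean - 1 / control$step_cycle_mean) *
    s_block[["timing"]]
  p$step_cycle_mean <- 1 / clamp(f, 1 / 0.42, 1 / 0.12)
  p$stride_length_mean <- clamp(lerp("stride_length_mean", s_block[["stride"]]),
                                2.2, 9.0)
  p$duty_factor <- clamp(lerp("duty_factor", s_block[["posture"]]), 0.30, 0.80)
  lag <- clamp(lerp("phase_offsets", s_block[["posture"]])[["RH"]],
               0.008, 0.16)
  p$phase_offsets <- c(LF = 0, RH = lag, RF = 0.5, LH = 0.5 + lag)
  p$stance_jitter_sd <- clamp(lerp("stance_jitter_sd", s_block[["posture"]]),
                              0, 0.045)
  p$body_speed_cv <- clamp(lerp("body_speed_cv", s_block[["speed"]]), 0, 0.75)
  p$bos_fore <- clamp(lerp("bos_fore", s_block[["bos"]]), 1.2, 3.2)
  p$bos_hind <- clamp(lerp("bos_hind", s_block[["bos"]]), 2.2, 5.6)
  p$body_speed_mean <- p$stride_length_mean / p$step_cycle_mean
  validate_gait_params(p)
  p
}

#' Simulate a two-group cohort
#'
#' Generates `n_per_group` control and MPTP-lesioned animals. One latent
#' lesion severity per animal drives both the tyrosine-hydroxylase (TH)
#' depletion and the shift of every gait-parameter block from the control
#' towards the lesioned preset, which is what induces the population
#' correlations between gait readouts and TH (see [cohort_params()]).
#'
#' @param control,mptp `gait_params` presets for the two groups.
#' @param cohort A [cohort_params()] object.
#' @return A `gait_cohort` object: a list with `animals` (tibble of per-animal
#'   group, latent severity, TH levels and open-field speed), `runs` (per
#'   animal, a list of [gait_run()]), `trajectories` (per animal, an
#'   open-field tibble) and the generating parameter sets.
#' @export
#' @examples
#' co <- simulate_cohort(control_params(), mptp_params(),
#'                       cohort_params(n_per_group = 2, runs_per_animal = 2,
#'                                     seed = 1))
#' co$animals
simulate_cohort <- function(control = control_params(),
                            mptp = mptp_params(),
                            cohort = cohort_params()) {
  stopifnot(inherits(cohort, "cohort_params"))
  if (cohort$n_per_group < 2L) {
    stop("simulate_cohort: n_per_group must be >= 2 (no variance estimable)",
         call. = FALSE)
  }
  n <- cohort$n_per_group
  d_th <- cohort$th_sn_control_mean - cohort$th_sn_mptp_mean
  blocks <- names(.coupling_blocks)
  rho <- cohort$gait_th_coupling

  animals <- with_seed(derive_seed(cohort$seed, 1), {
    grp <- rep(c("control", "mptp"), each = n)
    m <- ifelse(grp == "mptp", 1, 0)
    u <- stats::rnorm(2 * n, 0, cohort$severity_sd)
    s <- m + u
    th_sn <- cohort$th_sn_control_mean - d_th * s +
      stats::rnorm(2 * n, 0, cohort$th_noise_sd)
    d_str <- cohort$th_str_control_mean - cohort$th_str_mptp_mean
    th_str <- cohort$th_str_control_mean - d_str * s +
      stats::rnorm(2 * n, 0, cohort$th_noise_sd)
    sb <- sapply(blocks, function(b) {
      r <- if (b %in% names(rho)) rho[[b]] else NA_real_
      if (!is.na(r) && r == 0) {
        m + stats::rnorm(2 * n, 0, cohort$severity_sd)  # decoupled
      } else {
        tau <- if (is.na(r)) 0 else {
          block_tau(r, cohort$severity_sd, d_th, cohort$th_noise_sd)
        }
        s + stats::rnorm(2 * n, 0, tau)
      }
    })
    r_of <- cohort$openfield_th_coupling
    s_of <- if (r_of == 0) {
      m + stats::rnorm(2 * n, 0, cohort$severity_sd)
    } else {
      s + stats::rnorm(2 * n, 0,
                       block_tau(r_of, cohort$severity_sd, d_th,
                                 cohort$th_noise_sd))
    }
    of_speed <- pmax(cohort$openfield_speed_control +
                       (cohort$openfield_speed_mptp -
                          cohort$openfield_speed_control) * s_of, 0.3)
    list(tab = tibble::tibble(
      animal = sprintf("%s_%02d", ifelse(grp == "mptp", "M", "C"),
                       rep(seq_len(n), 2L)),
      group = grp, severity = s, th_sn = th_sn, th_striatum = th_str,
      of_speed = of_speed), sb = sb)
  })
  tab <- animals$tab
  sb <- animals$sb

  runs <- vector("list", nrow(tab))
  trajs <- vector("list", nrow(tab))
  names(runs) <- names(trajs) <- tab$animal
  for (a in seq_len(nrow(tab))) {
    preset <- if (tab$group[a] == "mptp") mptp else control
    pa <- animal_params(control, mptp, sb[a, ], preset)
    runs[[a]] <- lapply(seq_len(cohort$runs_per_animal), function(r) {
      simulate_run(pa, seed = derive_seed(cohort$seed, 2, a, r))
    })
    trajs[[a]] <- simulate_open_field(
      tab$of_speed[a], duration = cohort$openfield_duration,
      seed = derive_seed(cohort$seed, 3, a))
  }
  structure(list(animals = tab, runs = runs, trajectories = trajs,
                 control = control, mptp = mptp, cohort = cohort),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d animals (%d per group), %d runs each\n",
              nrow(x$animals), x$cohort$n_per_group, x$cohort$runs_per_animal))
  print(x$animals, n = 6)
  invisible(x)
}
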