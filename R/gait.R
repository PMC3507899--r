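contralateral <- c(LF = "RF", RF = "LF", LH = "RH", RH = "LH")

paw_events <- function(run, paw) {
  ev <- run$events[run$events$paw == paw, ]
  ev[order(ev$t_on), ]
}

#' Run duration
#'
#' Time to finish an entire crossing: from the first initial contact to the
#' last lift-off.
#'
#' @param run A [gait_run()].
#' @return Duration in seconds.
#' @export
run_duration <- function(run) {
  max(run$events$t_off) - min(run$events$t_on)
}

#' Temporal phases of one paw
#'
#' Per step cycle of a paw: the step cycle (time between two consecutive
#' initial contacts), the stance (contact duration), the swing (lift-off to
#' next contact), and the duty cycle (stance as a percentage of the step
#' cycle). Cycle `i` is defined by consecutive events `i`, `i + 1`, so a paw
#' with `k` contacts yields `k - 1` cycles.
#'
#' @param run A [gait_run()].
#' @param paw One of `"LF"`, `"RF"`, `"LH"`, `"RH"`.
#' @return A tibble with columns `cycle`, `stance`, `swing`, `step_cycle`,
#'   `duty_cycle` (empty, with a warning, when the paw has fewer than two
#'   contacts).
#' @export
temporal_phases <- function(run, paw) {
  ev <- paw_events(run, paw)
  if (nrow(ev) < 2L) {
    warning(sprintf("paw %s has %d contact(s): no complete step cycle",
                    paw, nrow(ev)), call. = FALSE)
    return(tibble::tibble(cycle = integer(), stance = numeric(),
                          swing = numeric(), step_cycle = numeric(),
                          duty_cycle = numeric()))
  }
  n <- nrow(ev) - 1L
  stance <- (ev$t_off - ev$t_on)[seq_len(n)]
  step_cycle <- diff(ev$t_on)
  swing <- step_cycle - stance
  tibble::tibble(cycle = seq_len(n), stance = stance, swing = swing,
                 step_cycle = step_cycle,
                 duty_cycle = 100 * stance / step_cycle)
}

#' Stride length and swing speed of one paw
#'
#' Stride length is the Euclidean distance between consecutive placements of
#' the same paw; swing speed is stride length over swing duration (reported
#' missing when the paw never leaves the floor within the cycle).
#'
#' @inheritParams temporal_phases
#' @return A tibble with columns `cycle`, `stride_length`, `swing_speed`.
#' @export
stride_and_speed <- function(run, paw) {
  ev <- paw_events(run, paw)
  if (nrow(ev) < 2L) {
    warning(sprintf("paw %s has %d contact(s): no stride", paw, nrow(ev)),
            call. = FALSE)
    return(tibble::tibble(cycle = integer(), stride_length = numeric(),
                          swing_speed = numeric()))
  }
  stride <- sqrt(diff(ev$x)^2 + diff(ev$y)^2)
  swing <- diff(ev$t_on) - (ev$t_off - ev$t_on)[-nrow(ev)]
  tibble::tibble(cycle = seq_along(stride), stride_length = stride,
                 swing_speed = ifelse(swing > 0, stride / swing, NA_real_))
}

#' Cadence
#'
#' Steps per second over the trial: the total number of initial contacts of
#' all four paws divided by the run duration.
#'
#' @param run A [gait_run()].
#' @return Cadence in steps/s.
#' @export
cadence <- function(run) {
  nrow(run$events) / run_duration(run)
}

#' Body-centre track
#'
#' The body-centre proxy sampled at the frame rate: at each frame, the
#' unweighted mean of the centroids of the prints currently in contact.
#' Frames with no active print are dropped.
#'
#' @param run A [gait_run()].
#' @param frame_rate Sampling rate; defaults to the run's.
#' @return A tibble with columns `t`, `x`, `y`, `n_active`.
#' @export
body_center_track <- function(run, frame_rate = run$frame_rate) {
  ev <- run$events
  # sample at frame midpoints so contact boundaries cannot sit on the grid
  tfr <- seq(min(ev$t_on) + 0.5 / frame_rate, max(ev$t_off) - 1e-9,
             by = 1 / frame_rate)
  active <- outer(ev$t_on, tfr, `<=`) & outer(ev$t_off, tfr, `>`)
  n <- colSums(active)
  keep <- n > 0L
  tibble::tibble(t = tfr[keep],
                 x = (colSums(active * ev$x) / n)[keep],
                 y = (colSums(active * ev$y) / n)[keep],
                 n_active = n[keep])
}

#' Coefficient of variation (population convention)
#'
#' `100 * sd_pop(x) / mean(x)` with the population (1/n) standard deviation;
#' the convention used by [speed_variation()].
#'
#' @param x Numeric vector with positive mean.
#' @return CV in percent.
#' @export
#' @examples
#' coef_variation(c(4, 6, 4, 6)) # 20
coef_variation <- function(x) {
  m <- mean(x)
  if (m <= 0) stop("coef_variation: mean must be positive", call. = FALSE)
  100 * sqrt(mean((x - m)^2)) / m
}

#' Walking-speed variation
#'
#' Coefficient of variation (population SD over mean, in percent) of the
#' instantaneous body-centre speed. The body-centre proxy is a staircase
#' (prints are stationary while in contact), so its position is first smoothed
#' with a centred moving average of one median step cycle and the speed is
#' taken as a central difference over half that window; for a perfectly
#' periodic constant-speed gait this cancels the staircase exactly (CV = 0)
#' while leaving cycle-to-cycle speed fluctuation visible. The startup and
#' ending transients (where not all paws have landed yet) are trimmed.
#'
#' @param run A [gait_run()].
#' @param window Smoothing window in seconds, or `"cycle"` for one median
#'   step cycle, or `0`/`NULL` for raw per-frame differencing.
#' @return CV of walking speed in percent.
#' @export
speed_variation <- function(run, window = "cycle") {
  trk <- body_center_track(run)
  if (nrow(trk) < 3L) {
    stop("speed_variation: need at least 3 body-centre samples",
         call. = FALSE)
  }
  dt <- 1 / run$frame_rate
  if (identical(window, "cycle")) {
    sc <- unlist(lapply(PAWS, function(p) {
      ev <- paw_events(run, p)
      if (nrow(ev) > 1L) diff(ev$t_on) else numeric(0)
    }))
    window <- stats::median(sc)
  }
  w <- if (is.null(window) || window <= 0) 1L else
    max(1L, round(window / dt))
  if (w > 1L) {
    ker <- rep(1 / w, w)
    xs <- stats::filter(trk$x, ker, sides = 2)
    ys <- stats::filter(trk$y, ker, sides = 2)
    keep <- !is.na(xs)
    xs <- as.numeric(xs[keep]); ys <- as.numeric(ys[keep])
  } else {
    xs <- trk$x; ys <- trk$y
  }
  # central difference over half a window on the smoothed positions: the
  # adjacent-sample difference would amplify the residual staircase ripple
  h <- max(1L, w %/% 2L)
  if (length(xs) <= 2L * h + 2L) {
    stop("speed_variation: run too short for the smoothing window",
         call. = FALSE)
  }
  i <- (h + 1L):(length(xs) - h)
  v <- sqrt((xs[i + h] - xs[i - h])^2 + (ys[i + h] - ys[i - h])^2) /
    (2 * h * dt)
  # drop the startup/ending transient (the proxy is periodic only once all
  # four paws contribute complete cycles): one window from each end
  if (w > 1L && length(v) > 3L * w) v <- v[(w + 1L):(length(v) - w)]
  if (length(v) < 2L || mean(v) <= 0) {
    stop("speed_variation: zero mean speed", call. = FALSE)
  }
  coef_variation(v)
}

#' Base of support
#'
#' Mean lateral (perpendicular to travel) distance between the left and right
#' paw prints of a girdle, each print taken at its maximum-area frame. Each
#' left print is paired with the contralateral print closest in onset time.
#'
#' @param run A [gait_run()].
#' @param girdle `"fore"` or `"hind"`.
#' @return Base of support in cm.
#' @export
base_of_support <- function(run, girdle = c("fore", "hind")) {
  girdle <- match.arg(girdle)
  lp <- if (girdle == "fore") "LF" else "LH"
  rp <- contralateral[lp]
  evl <- paw_events(run, lp); evr <- paw_events(run, rp)
  if (nrow(evl) == 0L || nrow(evr) == 0L) {
    stop(sprintf("base_of_support: one-sided data for the %s girdle", girdle),
         call. = FALSE)
  }
  j <- vapply(evl$t_on, function(t) which.min(abs(evr$t_on - t)), integer(1))
  mean(abs(evl$y - evr$y[j]))
}

#' Support-phase profile
#'
#' Partitions the run span `[first contact, last lift-off)` at every contact
#' boundary and classifies each sub-interval by which paws touch the floor:
#' `zero`, `single`, `diagonal` pair (LF+RH or RF+LH), `girdle` pair (both
#' fore or both hind), `lateral` pair (ipsilateral), `three`, `four`. The
#' relative duration of each category is returned in percent; by construction
#' the fractions sum to exactly 100.
#'
#' @param run A [gait_run()].
#' @return A named numeric of class `support_profile` with entries `zero`,
#'   `single`, `diagonal`, `girdle`, `lateral`, `three`, `four` (percent).
#' @export
support_profile <- function(run) {
  ev <- run$events
  t0 <- min(ev$t_on); t1 <- max(ev$t_off)
  bounds <- sort(unique(c(t0, t1, ev$t_on, ev$t_off)))
  bounds <- bounds[bounds >= t0 & bounds <= t1]
  mids <- (bounds[-1L] + bounds[-length(bounds)]) / 2
  len <- diff(bounds)
  active <- outer(ev$t_on, mids, `<=`) & outer(ev$t_off, mids, `>`)
  ntot <- colSums(active)
  cF <- colSums(active[ev$paw %in% c("LF", "RF"), , drop = FALSE])
  cL <- colSums(active[ev$paw %in% c("LF", "LH"), , drop = FALSE])
  cat2 <- ifelse(cL == 1L & cF == 1L, "diagonal",
                 ifelse(cL == 1L, "girdle", "lateral"))
  cat <- ifelse(ntot == 0L, "zero",
                ifelse(ntot == 1L, "single",
                       ifelse(ntot == 2L, cat2,
                              ifelse(ntot == 3L, "three", "four"))))
  cats <- c("zero", "single", "diagonal", "girdle", "lateral", "three", "four")
  dur <- vapply(cats, function(cc) sum(len[cat == cc]), numeric(1))
  structure(100 * dur / (t1 - t0), class = "support_profile")
}

#' @export
print.support_profile <- function(x, ...) {
  cat("<support_profile> (% of run time)\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Initial and terminal dual stance
#'
#' For each stance of a paw, the overlap durations with its contralateral
#' partner's stances: the *initial* dual stance is the overlap already ongoing
#' at (or beginning with) the stance onset; the *terminal* dual stance is the
#' first overlap that begins strictly later within the stance. Absent overlaps
#' yield 0; an overlap spanning the whole stance counts as initial.
#'
#' @param run A [gait_run()].
#' @param paw The reference paw (classically a hind paw).
#' @return A tibble with columns `cycle`, `initial_dual_stance`,
#'   `terminal_dual_stance` (seconds), one row per stance of `paw`.
#' @export
dual_stances <- function(run, paw) {
  ev <- paw_events(run, paw)
  co <- paw_events(run, contralateral[paw])
  init <- term <- numeric(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    a <- ev$t_on[i]; b <- ev$t_off[i]
    ov_on <- pmax(co$t_on, a); ov_off <- pmin(co$t_off, b)
    ov <- ov_off - ov_on
    has <- ov > 0
    ini <- which(has & co$t_on <= a)
    lat <- which(has & co$t_on > a)
    if (length(ini)) init[i] <- ov[ini[1L]]
    if (length(lat)) term[i] <- ov[lat[1L]]
  }
  tibble::tibble(cycle = seq_len(nrow(ev)),
                 initial_dual_stance = init, terminal_dual_stance = term)
}

#' Footfall sequence
#'
#' Paw labels ordered by initial contact time; simultaneous contacts are
#' broken by the fixed order LF, RF, LH, RH.
#'
#' @param run A [gait_run()].
#' @return Character vector of paw labels.
#' @export
footfalls <- function(run) {
  ev <- run$events
  ev$paw[order(ev$t_on, match(ev$paw, PAWS))]
}

step_patterns <- list(
  Aa = c("RF", "RH", "LF", "LH"), Ab = c("LF", "RH", "RF", "LH"),
  Ca = c("RF", "LF", "RH", "LH"), Cb = c("LF", "RF", "LH", "RH"),
  Ra = c("RF", "LF", "LH", "RH"), Rb = c("LF", "RF", "RH", "LH")
)

#' Classify step patterns
#'
#' Tiles the footfall sequence greedily left-to-right into consecutive
#' non-overlapping 4-footfall windows and matches each against the six normal
#' step-sequence patterns (alternate `Aa`/`Ab`, cruciate `Ca`/`Cb`, rotary
#' `Ra`/`Rb`; a match requires the exact order, which implies all four paws
#' appear). Windows matching no pattern are counted as `other`; up to three
#' trailing footfalls remain unclassified.
#'
#' @param footfalls Character vector from [footfalls()] (>= 4 entries).
#' @return Named integer counts for `Aa`, `Ab`, `Ca`, `Cb`, `Ra`, `Rb`,
#'   `other`, with attribute `trailing` (number of unclassified trailing
#'   footfalls).
#' @export
classify_step_patterns <- function(footfalls) {
  if (length(footfalls) < 4L) {
    stop("classify_step_patterns: need at least 4 footfalls", call. = FALSE)
  }
  nwin <- length(footfalls) %/% 4L
  counts <- stats::setNames(integer(7L), c(names(step_patterns), "other"))
  for (w in seq_len(nwin)) {
    win <- footfalls[(4L * w - 3L):(4L * w)]
    hit <- "other"
    for (nm in names(step_patterns)) {
      if (identical(win, step_patterns[[nm]])) { hit <- nm; break }
    }
    counts[hit] <- counts[hit] + 1L
  }
  attr(counts, "trailing") <- length(footfalls) - 4L * nwin
  counts
}

#' Regularity index
#'
#' The number of normal step-sequence patterns relative to the total number of
#' paw placements: `RI = 100 * (4 * NSSP) / P`, where NSSP is the number of
#' windows matching any of the six patterns and P the total number of
#' footfalls. Perfect alternation scores 100%. The factor 4 (one window
#' consumes four placements) is the standard normalization; set
#' `normalization` to change it.
#'
#' @param footfalls Character vector from [footfalls()].
#' @param normalization Placements per matched window (default 4).
#' @return Regularity index in percent.
#' @export
regularity_index <- function(footfalls, normalization = 4) {
  counts <- classify_step_patterns(footfalls)
  nssp <- sum(counts[names(step_patterns)])
  100 * normalization * nssp / length(footfalls)
}

#' Full gait profile of a run
#'
#' Computes the complete battery of temporal, spatial and coordination
#' readouts for one validated run: run duration; per-paw stance, swing, step
#' cycle, duty cycle, stride length and swing speed; cadence; walking-speed
#' variation; fore and hind base of support; per-paw initial/terminal dual
#' stance; the support-phase profile; step-pattern counts; regularity index;
#' and per-paw maximum print area and intensity (means over the run's
#' contacts).
#'
#' @param run A [gait_run()].
#' @return An object of class `gait_profile`.
#' @export
#' @examples
#' prof <- gait_profile(simulate_run(control_params(), seed = 1))
#' prof$cadence
#' profile_table(prof)
gait_profile <- function(run) {
  paws <- lapply(stats::setNames(PAWS, PAWS), function(p) {
    dplyr::bind_cols(temporal_phases(run, p),
                     stride_and_speed(run, p)[c("stride_length",
                                                "swing_speed")])
  })
  dual <- lapply(stats::setNames(PAWS, PAWS), function(p) dual_stances(run, p))
  ff <- footfalls(run)
  ev <- run$events
  structure(list(
    run_duration = run_duration(run),
    paws = paws,
    cadence = cadence(run),
    speed_variation = speed_variation(run),
    bos_fore = base_of_support(run, "fore"),
    bos_hind = base_of_support(run, "hind"),
    dual = dual,
    support = support_profile(run),
    pattern_counts = classify_step_patterns(ff),
    regularity_index = regularity_index(ff),
    max_area = vapply(stats::setNames(PAWS, PAWS),
                      function(p) mean(ev$max_area[ev$paw == p]), numeric(1)),
    max_intensity = vapply(stats::setNames(PAWS, PAWS),
                           function(p) mean(ev$max_intensity[ev$paw == p]),
                           numeric(1))
  ), class = "gait_profile")
}

#' @export
print.gait_profile <- function(x, ...) {
  cat(sprintf(paste0("<gait_profile> duration %.3f s, cadence %.2f steps/s, ",
                     "speed CV %.1f%%, RI %.1f%%\n"),
              x$run_duration, x$cadence, x$speed_variation,
              x$regularity_index))
  cat(sprintf("  BOS fore %.2f cm, hind %.2f cm; support diagonal %.1f%%, ",
              x$bos_fore, x$bos_hind, x$support[["diagonal"]]))
  cat(sprintf("three %.1f%%, four %.1f%%\n",
              x$support[["three"]], x$support[["four"]]))
  invisible(x)
}

#' Tidy view of one or more gait profiles
#'
#' Flattens a `gait_profile` into a long tibble with one row per
#' (parameter, paw) pair; per-cycle quantities are averaged over the run.
#' Whole-run scalars carry `paw = NA`.
#'
#' @param profile A `gait_profile`, or a list of them.
#' @return A tibble with columns `parameter`, `paw`, `value` (plus `run` when
#'   a list is given).
#' @export
profile_table <- function(profile) {
  if (inherits(profile, "gait_profile")) {
    per_paw <- dplyr::bind_rows(lapply(PAWS, function(p) {
      pp <- profile$paws[[p]]
      dd <- profile$dual[[p]]
      tibble::tibble(
        parameter = c("stance", "swing", "step_cycle", "duty_cycle",
                      "stride_length", "swing_speed",
                      "initial_dual_stance", "terminal_dual_stance",
                      "max_area", "max_intensity"),
        paw = p,
        value = c(mean(pp$stance), mean(pp$swing), mean(pp$step_cycle),
                  mean(pp$duty_cycle), mean(pp$stride_length),
                  mean(pp$swing_speed, na.rm = TRUE),
                  mean(dd$initial_dual_stance), mean(dd$terminal_dual_stance),
                  profile$max_area[[p]], profile$max_intensity[[p]])
      )
    }))
    whole <- tibble::tibble(
      parameter = c("run_duration", "cadence", "speed_variation",
                    "bos_fore", "bos_hind", "regularity_index",
                    paste0("support_", names(profile$support))),
      paw = NA_character_,
      value = c(profile$run_duration, profile$cadence,
                profile$speed_variation, profile$bos_fore, profile$bos_hind,
                profile$regularity_index, unname(unclass(profile$support)))
    )
    return(dplyr::bind_rows(per_paw, whole))
  }
  dplyr::bind_rows(lapply(seq_along(profile), function(i) {
    dplyr::mutate(profile_table(profile[[i]]), run = i, .before = 1L)
  }))
}

#' Gait table for a whole cohort
#'
#' Profiles every run of a cohort and returns a tidy table, one row per
#' animal x run x parameter (x paw). The `chain` argument selects the analysis
#' path: `"events"` profiles the simulated event tables directly, `"frames"`
#' first renders each run to a luminance stack, detects and labels the prints,
#' and profiles the reconstructed run (the full acquisition chain).
#'
#' @param cohort A `gait_cohort` from [simulate_cohort()].
#' @param chain `"events"` or `"frames"`.
#' @param on_invalid What to do when the acquisition chain rejects a crossing
#'   as invalid (labeling failure or fewer than the minimum step cycles):
#'   `"drop"` excludes the crossing, mirroring the experimental protocol's
#'   exclusion of unusable runs (a message reports the count); `"error"`
#'   aborts.
#' @param ... Passed to [render_frames()] when `chain = "frames"`.
#' @return A tibble with columns `animal`, `group`, `run`, `parameter`,
#'   `paw`, `value`.
#' @export
cohort_gait_table <- function(cohort, chain = c("events", "frames"),
                              on_invalid = c("drop", "error"), ...) {
  chain <- match.arg(chain)
  on_invalid <- match.arg(on_invalid)
  dropped <- 0L
  out <- vector("list", nrow(cohort$animals))
  for (a in seq_len(nrow(cohort$animals))) {
    runs <- cohort$runs[[a]]
    profs <- lapply(runs, function(r) {
      res <- tryCatch({
        if (chain == "frames") {
          fs <- render_frames(r, ...)
          ev <- detect_contacts(fs)
          r <- label_paws(ev, frame_rate = fs$frame_rate,
                          runway_length = r$runway_length)
        }
        gait_profile(r)
      }, mousegait_invalid_run = function(e) e)
      if (rlang::cnd_inherits(res, "mousegait_invalid_run") &&
          on_invalid == "error") {
        stop(res)
      }
      res
    })
    ok <- vapply(profs, inherits, logical(1), "gait_profile")
    dropped <- dropped + sum(!ok)
    if (!any(ok)) next
    tab <- profile_table(profs[ok])
    tab$run <- which(ok)[tab$run]
    tab$animal <- cohort$animals$animal[a]
    tab$group <- cohort$animals$group[a]
    out[[a]] <- tab
  }
  if (dropped > 0L) {
    message(sprintf("cohort_gait_table: excluded %d invalid crossing(s)",
                    dropped))
  }
  dplyr::bind_rows(out)[, c("animal", "group", "run", "parameter", "paw",
                            "value")]
}
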