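#' Runway crossings as event tables
#'
#' A `gait_run` holds one validated runway crossing: a table of paw-contact
#' events (one row per stance of one paw) plus the runway geometry and the
#' acquisition frame rate. Events carry the paw identity (`LF`, `RF`, `LH`,
#' `RH`), the contact interval `[t_on, t_off)` in seconds, the print centroid
#' `(x, y)` in cm taken at the maximum-area frame, and the maximum print area
#' (cm^2) and luminance. Coordinates follow the runway convention: `x` along
#' the travel direction from the runway start, `y` lateral, time from the
#' first acquired frame; all contact intervals are half-open.
#'
#' @param events Data frame with columns `paw`, `t_on`, `t_off`, `x`, `y`,
#'   `max_area`, `max_intensity` (an optional `frames` list-column keeps the
#'   per-frame track of detected events).
#' @param runway_length Runway length in cm.
#' @param frame_rate Acquisition frame rate in Hz.
#' @param direction Sign of travel along `x` (+1 or -1).
#' @param validate Check run validity (default `TRUE`).
#' @param min_cycles Minimum complete step cycles per paw for a valid run.
#' @return An object of class `gait_run`.
#' @export
gait_run <- function(events, runway_length, frame_rate, direction = 1,
                     validate = TRUE, min_cycles = 5L) {
  events <- tibble::as_tibble(events)
  need <- c("paw", "t_on", "t_off", "x", "y", "max_area", "max_intensity")
  miss <- setdiff(need, names(events))
  if (length(miss)) {
    stop("gait_run: events are missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  events <- events[order(events$t_on, match(events$paw, PAWS)), ]
  run <- structure(list(events = events,
                        runway_length = runway_length,
                        frame_rate = frame_rate,
                        direction = sign(direction)),
                   class = "gait_run")
  if (validate) validate_run(run, min_cycles = min_cycles)
  run
}

#' @export
print.gait_run <- function(x, ...) {
  ev <- x$events
  cat(sprintf("<gait_run> %d contact events, %.3f s, %d Hz, runway %.3g cm\n",
              nrow(ev), max(ev$t_off) - min(ev$t_on), x$frame_rate,
              x$runway_length))
  print(table(ev$paw))
  invisible(x)
}

#' Validate a runway crossing
#'
#' Checks the run invariants: known paw codes, `t_on < t_off`, per-paw
#' non-overlapping contact intervals, placements advancing along the travel
#' direction, and at least `min_cycles` complete step cycles per paw.
#'
#' @param run A [gait_run()].
#' @param min_cycles Minimum complete step cycles per paw.
#' @return `run`, invisibly; signals a classed error
#'   (`mousegait_invalid_run`) with a diagnostic otherwise.
#' @export
validate_run <- function(run, min_cycles = 5L) {
  ev <- run$events
  fail <- function(...) {
    stop(rlang::error_cnd("mousegait_invalid_run",
                          message = sprintf(...),
                          call = NULL))
  }
  if (nrow(ev) == 0L) fail("invalid run: no contact events")
  bad <- setdiff(unique(ev$paw), PAWS)
  if (length(bad)) fail("invalid run: unknown paw code(s) %s",
                        paste(bad, collapse = ", "))
  if (any(ev$t_on >= ev$t_off)) {
    fail("invalid run: %d event(s) with t_on >= t_off",
         sum(ev$t_on >= ev$t_off))
  }
  for (p in PAWS) {
    pe <- ev[ev$paw == p, ]
    if (nrow(pe) < 2L) next
    pe <- pe[order(pe$t_on), ]
    if (any(pe$t_on[-1L] < pe$t_off[-nrow(pe)])) {
      fail("invalid run: overlapping contacts for paw %s", p)
    }
    if (any(run$direction * diff(pe$x) <= 0)) {
      fail("invalid run: placements of paw %s do not advance along the travel direction",
           p)
    }
  }
  # A paw with k contacts completes k - 1 step cycles.
  cyc <- vapply(PAWS, function(p) sum(ev$paw == p) - 1L, integer(1))
  if (any(cyc < min_cycles)) {
    short <- PAWS[cyc < min_cycles]
    fail("invalid run: fewer than %d complete step cycles for paw(s) %s (%s)",
         min_cycles, paste(short, collapse = ", "),
         paste(pmax(cyc[cyc < min_cycles], 0L), collapse = ", "))
  }
  invisible(run)
}

#' Read and write contact-event tables
#'
#' Event CSVs are the interchange format of the pipeline: one row per
#' paw-floor contact with columns `paw`, `t_on`, `t_off`, `x`, `y`,
#' `max_area`, `max_intensity` plus the run metadata stored in the columns
#' `runway_length`, `frame_rate`, `direction` (constant within a file).
#' The round trip `write_events()` then `read_events()` is lossless for these
#' fields, so the detection stage can be bypassed by feeding event CSVs
#' directly into the analysis.
#'
#' @param run A [gait_run()].
#' @param path CSV file path.
#' @param min_cycles Validity threshold passed to [gait_run()].
#' @return `read_events()` returns a `gait_run`; `write_events()` returns
#'   `path` invisibly.
#' @export
write_events <- function(run, path) {
  ev <- run$events[c("paw", "t_on", "t_off", "x", "y",
                     "max_area", "max_intensity")]
  ev$runway_length <- run$runway_length
  ev$frame_rate <- run$frame_rate
  ev$direction <- run$direction
  readr::write_csv(ev, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, min_cycles = 5L) {
  ev <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("paw", "t_on", "t_off", "x", "y", "max_area", "max_intensity",
            "runway_length", "frame_rate", "direction")
  miss <- setdiff(need, names(ev))
  if (length(miss)) {
    stop("read_events: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!ev$paw %in% PAWS)
  if (length(bad)) {
    stop(sprintf("read_events: unknown paw code '%s' at row %d",
                 ev$paw[bad[1L]], bad[1L]), call. = FALSE)
  }
  bad <- which(ev$t_on >= ev$t_off)
  if (length(bad)) {
    stop(sprintf("read_events: t_on >= t_off at row %d", bad[1L]),
         call. = FALSE)
  }
  gait_run(ev[c("paw", "t_on", "t_off", "x", "y", "max_area", "max_intensity")],
           runway_length = ev$runway_length[1L],
           frame_rate = ev$frame_rate[1L],
           direction = ev$direction[1L],
           min_cycles = min_cycles)
}

#' Read and write open-field trajectories
#'
#' Trajectory CSVs hold columns `t` (s), `x`, `y` (cm, arena coordinates).
#'
#' @param traj A data frame with columns `t`, `x`, `y`.
#' @param path CSV file path.
#' @return `read_trajectory()` returns a tibble; `write_trajectory()` returns
#'   `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  readr::write_csv(tibble::as_tibble(traj)[c("t", "x", "y")], path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("t", "x", "y"), names(tr))
  if (length(miss)) {
    stop("read_trajectory: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tr
}
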