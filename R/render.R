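#' Render a run as a luminance frame stack
#'
#' Emulates the glass-walkway acquisition: the background is dark and, while a
#' paw is in stance, an elliptical bright region appears at the placement
#' point. The region's pixel area and peak luminance ramp from a floor value
#' up to the event's maximum at mid-stance (where braking turns into
#' propulsion) and back down. Luminance is stored as a fraction of the camera
#' dynamic range in `[0, 1]`.
#'
#' @param run A [gait_run()].
#' @param px_per_cm Spatial resolution in pixels per cm; values below 4 are
#'   rejected as too coarse to separate fore and hind prints.
#' @param width Imaged runway width in cm (lateral extent, centred on the
#'   runway midline).
#' @param frame_cap Maximum number of frames the renderer will produce.
#' @param area_floor,intensity_floor Fraction of the maximum print area /
#'   luminance at contact onset and lift-off (the ramp floor). The luminance
#'   floor is deliberately high so that a print is above any reasonable
#'   detection threshold for its whole contact interval.
#' @param aspect Print ellipse aspect ratio (longitudinal / lateral semi-axis).
#' @return A `frame_stack` object: list with `pix` (numeric array
#'   `[x, y, frame]`), `px_per_cm`, `frame_rate`, `width`.
#' @export
#' @examples
#' fs <- render_frames(simulate_run(control_params(), seed = 1))
#' dim(fs$pix)
render_frames <- function(run, px_per_cm = 8, width = 8, frame_cap = 5000,
                          area_floor = 0.6, intensity_floor = 0.7,
                          aspect = 1.3) {
  stopifnot(inherits(run, "gait_run"))
  if (px_per_cm < 4) {
    stop("render_frames: px_per_cm below the documented minimum of 4; ",
         "fore and hind prints would not be separable", call. = FALSE)
  }
  ev <- run$events
  fr <- run$frame_rate
  nx <- round(run$runway_length * px_per_cm)
  ny <- round(width * px_per_cm)
  nt <- ceiling((max(ev$t_off) + 2 / fr) * fr)
  if (nt > frame_cap) {
    stop(sprintf("render_frames: run needs %d frames, above frame_cap = %d",
                 nt, frame_cap), call. = FALSE)
  }
  pix <- array(0, c(nx, ny, nt))
  npx_frame <- nx * ny

  for (e in seq_len(nrow(ev))) {
    t_on <- ev$t_on[e]; t_off <- ev$t_off[e]
    f0 <- ceiling(t_on * fr + 1 - 1e-9)
    f1 <- ceiling(t_off * fr + 1 - 1e-9) - 1L
    if (f1 < f0) next
    tf <- (seq(f0, f1) - 1) / fr
    u <- (tf - t_on) / (t_off - t_on)
    ramp <- 1 - abs(2 * u - 1)
    area_t <- ev$max_area[e] * (area_floor + (1 - area_floor) * ramp)
    int_t <- ev$max_intensity[e] *
      (intensity_floor + (1 - intensity_floor) * ramp)

    ry <- sqrt(ev$max_area[e] / (pi * aspect)) * px_per_cm
    rx <- aspect * ry
    ci <- ev$x[e] * px_per_cm + 0.5          # pixel-centre coordinates
    cj <- (ev$y[e] + width / 2) * px_per_cm + 0.5
    ii <- max(1L, floor(ci - rx - 1)):min(nx, ceiling(ci + rx + 1))
    jj <- max(1L, floor(cj - ry - 1)):min(ny, ceiling(cj + ry + 1))
    if (!length(ii) || !length(jj)) next
    nrm <- outer(((ii - ci) / rx)^2, ((jj - cj) / ry)^2, `+`)
    base_idx <- outer(ii, (jj - 1L) * nx, `+`)   # linear index within a frame
    scl <- area_t / ev$max_area[e]                # ellipse area scale per frame
    for (k in seq_along(tf)) {
      sel <- nrm <= scl[k]
      if (!any(sel)) next
      idx <- base_idx[sel] + (f0 + k - 2L) * npx_frame
      pix[idx] <- pmax(pix[idx], int_t[k])
    }
  }
  structure(list(pix = pix, px_per_cm = px_per_cm, frame_rate = fr,
                 width = width, runway_length = run$runway_length),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d x %d px, %d frames @ %g Hz, %g px/cm\n",
              dim(x$pix)[1], dim(x$pix)[2], dim(x$pix)[3],
              x$frame_rate, x$px_per_cm))
  invisible(x)
}

#' Write / read a frame stack as multi-page TIFF
#'
#' Frames are stored as 16-bit grayscale pages; the acquisition metadata
#' (`frame_rate`, `px_per_cm`, `width`) must be carried alongside (the reader
#' takes them as arguments).
#'
#' @param stack A `frame_stack` from [render_frames()].
#' @param path TIFF file path.
#' @param frame_rate,px_per_cm,width Acquisition metadata for the reader.
#' @param runway_length Runway length in cm (defaults to image extent / scale).
#' @return `read_frames_tiff()` returns a `frame_stack`; `write_frames_tiff()`
#'   returns `path` invisibly.
#' @export
write_frames_tiff <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack$pix)[3]),
                  function(k) t(stack$pix[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_frames_tiff
#' @export
read_frames_tiff <- function(path, frame_rate, px_per_cm, width = NULL,
                             runway_length = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nx <- ncol(pages[[1]]); ny <- nrow(pages[[1]])
  pix <- array(0, c(nx, ny, length(pages)))
  for (k in seq_along(pages)) pix[, , k] <- t(pages[[k]])
  structure(list(pix = pix, px_per_cm = px_per_cm, frame_rate = frame_rate,
                 width = width %||% ny / px_per_cm,
                 runway_length = runway_length %||% nx / px_per_cm),
            class = "frame_stack")
}
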