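#' Detect paw contacts in a luminance frame stack
#'
#' Recovers unlabeled contact events from a frame stack: per frame, pixels
#' above the luminance threshold are grouped into 8-connected components;
#' components are linked across consecutive frames when their centroids lie
#' within the linking gate; each linked track becomes one candidate contact
#' event with `[t_on, t_off)` spanning its first to last frame (half-open, in
#' frame units), per-frame area in cm^2 (pixel count over `px_per_cm`^2) and
#' intensity (component maximum pixel value).
#'
#' Labeling uses `EBImage::bwlabel()` (4-connected) followed by a union-find
#' merge of diagonally adjacent components, which yields exact 8-connectivity.
#'
#' @param stack A `frame_stack` from [render_frames()] or [read_frames_tiff()].
#' @param threshold Luminance threshold as a fraction of the dynamic range,
#'   in (0, 1).
#' @param gate Maximum centroid displacement (cm) between consecutive frames
#'   for two components to be linked into the same track.
#' @param min_frames Tracks shorter than this many frames are discarded as
#'   flicker.
#' @return A tibble of unlabeled events: `t_on`, `t_off`, `x`, `y`,
#'   `max_area`, `max_intensity` and a `frames` list-column with the per-frame
#'   track (`time`, `area`, `intensity`, `x`, `y`). An all-dark stack yields a
#'   zero-row tibble.
#' @seealso [label_paws()] to assign paw identities and build a [gait_run()].
#' @export
detect_contacts <- function(stack, threshold = 0.15, gate = 1.5,
                            min_frames = 2L) {
  stopifnot(inherits(stack, "frame_stack"))
  if (threshold <= 0 || threshold >= 1) {
    stop("detect_contacts: `threshold` must lie in (0, 1)", call. = FALSE)
  }
  pix <- stack$pix
  if (length(dim(pix)) != 3L || dim(pix)[3] < 2L) {
    stop("detect_contacts: need a stack of at least 2 frames", call. = FALSE)
  }
  nx <- dim(pix)[1]; ny <- dim(pix)[2]; nt <- dim(pix)[3]
  px <- stack$px_per_cm; fr <- stack$frame_rate

  mask <- pix > threshold
  idx <- which(mask)
  empty <- tibble::tibble(t_on = numeric(), t_off = numeric(), x = numeric(),
                          y = numeric(), max_area = numeric(),
                          max_intensity = numeric(), frames = list())
  if (!length(idx)) return(empty)

  lab <- EBImage::bwlabel(mask)
  # frame-unique component ids, working only on the (sparse) lit pixels
  fidx <- (idx - 1L) %/% (nx * ny) + 1L
  ii <- (idx - 1L) %% nx + 1L
  jj <- ((idx - 1L) %/% nx) %% ny + 1L
  labv <- as.integer(lab[idx])
  pfm <- integer(nt)
  agg <- tapply(labv, fidx, max)
  pfm[as.integer(names(agg))] <- as.integer(agg)
  offset <- cumsum(c(0L, pfm[-nt]))
  gl <- labv + offset[fidx]

  # upgrade 4- to 8-connectivity: merge labels touching diagonally
  # (neighbour lookup via binary search on the sorted lit-pixel index,
  # avoiding a full-size label array)
  nb_pairs <- function(di, dj) {
    ok <- ii + di >= 1L & ii + di <= nx & jj + dj >= 1L & jj + dj <= ny
    nb <- idx[ok] + di + dj * nx
    pos <- findInterval(nb, idx)
    hit <- pos > 0L & idx[pmax(pos, 1L)] == nb
    g2 <- gl[pos[hit]]
    g1 <- gl[ok][hit]
    sel <- g2 != g1
    cbind(g1[sel], g2[sel])
  }
  pairs <- rbind(nb_pairs(1L, 1L), nb_pairs(-1L, 1L))
  nlab <- sum(pfm)
  parent <- seq_len(nlab)
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1L]; while (parent[a] != a) a <- parent[a]
      b <- pairs[r, 2L]; while (parent[b] != b) b <- parent[b]
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    for (i in seq_len(nlab)) {         # path-compress to roots
      r <- i; while (parent[r] != r) r <- parent[r]
      parent[i] <- r
    }
  }

  # per-component features
  comp <- data.table::data.table(
    lab = parent[gl], frame = fidx, i = ii, j = jj, val = pix[idx]
  )
  feats <- comp[, list(n = .N, ci = mean(i), cj = mean(j), maxv = max(val),
                       pixset = list(i + (j - 1L) * nx)),
                by = list(frame, lab)]
  feats <- feats[order(feats$frame), ]
  feats$x <- (feats$ci - 0.5) / px
  feats$y <- (feats$cj - 0.5) / px - stack$width / 2
  feats$area <- feats$n / px^2

  # link components across consecutive frames: centroid within the gate and
  # overlapping pixel masks (prints are stationary, so a vanishing print
  # followed by a nearby appearing one is two events, not a continuation)
  track_of <- integer(nrow(feats))
  last_frame <- integer(0); last_x <- numeric(0); last_y <- numeric(0)
  last_pix <- list()
  ntr <- 0L
  rows_by_frame <- split(seq_len(nrow(feats)), feats$frame)
  for (fi in names(rows_by_frame)) {
    f <- as.integer(fi)
    rows <- rows_by_frame[[fi]]
    open <- which(last_frame == f - 1L)
    taken <- rep(FALSE, length(open))
    for (r in rows) {
      tr <- 0L
      if (length(open)) {
        d <- sqrt((last_x[open] - feats$x[r])^2 +
                    (last_y[open] - feats$y[r])^2)
        d[taken] <- Inf
        while (length(d) && min(d) <= gate) {
          kk <- which.min(d)
          if (any(feats$pixset[[r]] %in% last_pix[[open[kk]]])) {
            tr <- open[kk]; taken[kk] <- TRUE; break
          }
          d[kk] <- Inf
        }
      }
      if (tr == 0L) {
        ntr <- ntr + 1L
        tr <- ntr
        last_frame <- c(last_frame, 0L)
        last_x <- c(last_x, 0); last_y <- c(last_y, 0)
        last_pix <- c(last_pix, list(integer()))
      }
      track_of[r] <- tr
      last_frame[tr] <- f; last_x[tr] <- feats$x[r]; last_y[tr] <- feats$y[r]
      last_pix[[tr]] <- feats$pixset[[r]]
    }
  }

  rows_by_track <- unname(split(seq_len(nrow(feats)), track_of))
  rows_by_track <- rows_by_track[lengths(rows_by_track) >= min_frames]
  if (!length(rows_by_track)) return(empty)
  out <- tibble::tibble(
    t_on = vapply(rows_by_track,
                  function(rw) (min(feats$frame[rw]) - 1) / fr, numeric(1)),
    t_off = vapply(rows_by_track,
                   function(rw) max(feats$frame[rw]) / fr, numeric(1)),
    x = vapply(rows_by_track,
               function(rw) feats$x[rw[which.max(feats$area[rw])]],
               numeric(1)),
    y = vapply(rows_by_track,
               function(rw) feats$y[rw[which.max(feats$area[rw])]],
               numeric(1)),
    max_area = vapply(rows_by_track,
                      function(rw) max(feats$area[rw]), numeric(1)),
    max_intensity = vapply(rows_by_track,
                           function(rw) max(feats$maxv[rw]), numeric(1)),
    frames = lapply(rows_by_track, function(rw) {
      tibble::tibble(time = (feats$frame[rw] - 1) / fr,
                     area = feats$area[rw], intensity = feats$maxv[rw],
                     x = feats$x[rw], y = feats$y[rw])
    })
  )
  out[order(out$t_on), ]
}

#' Assign paw identities to detected contacts
#'
#' Left/right is assigned from the sign of the lateral offset to a
#' running-mean midline of the print centroids ordered along the runway.
#' Fore/hind is decided per side: the fore and hind paw of one side leave two
#' distinct lateral tracks (their bases of support differ), so the side's
#' events are split at the largest gap in lateral position and the cluster
#' whose prints lie, on average, ahead of the concurrent body centre (the
#' unweighted mean of active print centroids) along the travel direction is
#' the fore paw; when the two tracks are not separable each event's own
#' longitudinal offset decides. The labeled run is then validated (per-paw
#' non-overlap, placements advancing, at least `min_cycles` complete cycles
#' per paw) and rejected with a classed diagnostic error
#' (`mousegait_invalid_run`) if invalid, mirroring the experimental exclusion
#' of unusable crossings.
#'
#' @param events Tibble of unlabeled events from [detect_contacts()].
#' @param frame_rate Acquisition frame rate (Hz).
#' @param runway_length Runway length (cm).
#' @param direction Sign of travel along `x`; `NULL` to estimate from the data.
#' @param min_cycles Validity threshold.
#' @return A validated [gait_run()].
#' @export
label_paws <- function(events, frame_rate, runway_length, direction = NULL,
                       min_cycles = 5L) {
  if (is.null(events) || nrow(events) == 0L) {
    stop("label_paws: no events to label", call. = FALSE)
  }
  ev <- events[order(events$t_on), ]
  if (is.null(direction)) {
    direction <- sign(stats::coef(stats::lm(ev$x ~ ev$t_on))[[2]])
    if (direction == 0) direction <- 1
  }

  # left/right: running-mean midline along the runway (a local window holds a
  # balanced mix of left and right prints, so its mean tracks the body axis)
  ox <- order(ev$x)
  k <- min(9L, nrow(ev))
  mid <- numeric(nrow(ev))
  if (k >= 3) {
    sm <- stats::filter(ev$y[ox], rep(1 / k, k), sides = 2)
    ok <- which(!is.na(sm))
    if (length(ok)) {
      sm[seq_len(min(ok) - 1L)] <- sm[min(ok)]
      sm[seq(max(ok) + 1L, length.out = length(sm) - max(ok))] <- sm[max(ok)]
    } else sm[] <- mean(ev$y)
    mid[ox] <- as.numeric(sm)
  } else {
    mid[] <- mean(ev$y)
  }
  side <- ifelse((ev$y - mid) * direction > 0, "L", "R")

  # per-event longitudinal offset to the body centre over the stance
  t0 <- min(ev$t_on); t1 <- max(ev$t_off)
  tfr <- seq(t0, t1, by = 1 / frame_rate)
  active <- outer(ev$t_on, tfr, `<=`) & outer(ev$t_off, tfr, `>`)
  nact <- colSums(active)
  bodyx <- colSums(active * ev$x) / pmax(nact, 1L)
  offs <- vapply(seq_len(nrow(ev)), function(e) {
    fcols <- which(active[e, ] & nact > 0L)
    if (!length(fcols)) return(0)
    mean(ev$x[e] - bodyx[fcols])
  }, numeric(1))

  # fore/hind per side: the two paws of one side leave two lateral tracks
  # (fore and hind base of support differ); split the side's events at the
  # largest gap in |lateral offset| and let the cluster whose prints lie
  # ahead of the concurrent body centre on average be the fore paw. The
  # cluster-level decision is robust to single prints being overtaken by the
  # advancing body; when the two tracks are not separable, each event's own
  # offset decides.
  girdle <- character(nrow(ev))
  for (sd_ in c("L", "R")) {
    i <- which(side == sd_)
    if (!length(i)) next
    ay <- ev$y[i] * direction * (if (sd_ == "L") 1 else -1)
    o <- order(ay)
    gaps <- diff(ay[o])
    split_ok <- length(i) >= 4L && max(gaps) >= 0.35
    if (split_ok) {
      cut <- which.max(gaps)
      cl <- integer(length(i))
      cl[o[seq_len(cut)]] <- 1L          # nearer the midline
      cl[o[-seq_len(cut)]] <- 2L
      m1 <- mean(offs[i[cl == 1L]]) * direction
      m2 <- mean(offs[i[cl == 2L]]) * direction
      fore_cluster <- if (m1 >= m2) 1L else 2L
      girdle[i] <- ifelse(cl == fore_cluster, "F", "H")
    } else {
      girdle[i] <- ifelse(offs[i] * direction > 0, "F", "H")
    }
  }

  ev$paw <- paste0(side, girdle)
  gait_run(ev, runway_length = runway_length, frame_rate = frame_rate,
           direction = direction, min_cycles = min_cycles)
}

# required for data.table syntax inside an importing package
.datatable.aware <- TRUE
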