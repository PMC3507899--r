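blob_stack <- function(frames_on, nt = 30, nx = 80, ny = 40, cx = 40, cy = 20,
                       r = 3, value = 0.8, px_per_cm = 8, frame_rate = 100) {
  pix <- array(0, c(nx, ny, nt))
  for (f in frames_on) {
    for (i in (cx - r):(cx + r)) for (j in (cy - r):(cy + r)) {
      if ((i - cx)^2 + (j - cy)^2 <= r^2) pix[i, j, f] <- value
    }
  }
  structure(list(pix = pix, px_per_cm = px_per_cm, frame_rate = frame_rate,
                 width = ny / px_per_cm, runway_length = nx / px_per_cm),
            class = "frame_stack")
}

test_that("a single stationary blob becomes one event with frame-accurate timing", {
  fs <- blob_stack(frames_on = 11:20)
  ev <- detect_contacts(fs, threshold = 0.15)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$t_on, 0.10)
  expect_equal(ev$t_off, 0.20)
})

test_that("well-separated concurrent blobs are never merged", {
  fs <- blob_stack(frames_on = 5:15)
  fs2 <- blob_stack(frames_on = 10:20, cx = 10)   # 30 px ~ 3.75 cm away
  fs$pix <- pmax(fs$pix, fs2$pix)
  ev <- detect_contacts(fs)
  expect_identical(nrow(ev), 2L)
})

test_that("degenerate stacks are handled", {
  fs <- blob_stack(frames_on = integer(0))
  expect_identical(nrow(detect_contacts(fs)), 0L)  # all-dark: empty, no error
  fs1 <- fs; fs1$pix <- fs1$pix[, , 1, drop = FALSE]
  expect_error(detect_contacts(fs1), "2 frames")
  expect_error(detect_contacts(fs, threshold = 0), "threshold")
  expect_error(detect_contacts(fs, threshold = 1), "threshold")
})

test_that("diagonally touching pixels form one component (8-connectivity)", {
  fs <- blob_stack(frames_on = integer(0), nt = 4)
  fs$pix[40, 20, 2:3] <- 0.9
  fs$pix[41, 21, 2:3] <- 0.9   # touches only at the corner
  ev <- detect_contacts(fs, min_frames = 2)
  expect_identical(nrow(ev), 1L)
})

test_that("raising the threshold never increases durations or areas", {
  run <- simulate_run(control_params(), seed = 11)
  fs <- render_frames(run)
  lo <- detect_contacts(fs, threshold = 0.25)
  hi <- detect_contacts(fs, threshold = 0.32)
  expect_lte(nrow(hi), nrow(lo))
  for (i in seq_len(nrow(hi))) {
    j <- which.min((lo$x - hi$x[i])^2 + (lo$y - hi$y[i])^2)
    expect_lte(hi$t_off[i] - hi$t_on[i], lo$t_off[j] - lo$t_on[j] + 1e-9)
    expect_lte(hi$max_area[i], lo$max_area[j] + 1e-9)
  }
})

test_that("detection round-trips the generating run", {
  for (preset in list(control_params, mptp_params)) {
    run <- simulate_run(zero_noise(preset), seed = 4)
    fs <- render_frames(run)
    ev <- detect_contacts(fs)
    expect_identical(nrow(ev), nrow(run$events))
    run2 <- label_paws(ev, frame_rate = fs$frame_rate,
                       runway_length = run$runway_length)
    dt <- 1 / fs$frame_rate
    for (paw in c("LF", "RF", "LH", "RH")) {
      a <- run$events[run$events$paw == paw, ]
      b <- run2$events[run2$events$paw == paw, ]
      a <- a[order(a$t_on), ]; b <- b[order(b$t_on), ]
      expect_identical(nrow(a), nrow(b))
      expect_lt(max(abs(a$t_on - b$t_on)), dt + 1e-9)
      expect_lt(max(abs(a$t_off - b$t_off)), dt + 1e-9)
      expect_lt(max(abs(a$x - b$x)), 1 / fs$px_per_cm)     # within 1 px
      expect_lt(max(abs(a$y - b$y)), 1 / fs$px_per_cm)
      expect_lt(max(abs(a$max_area - b$max_area)), 0.15)
      expect_lt(max(abs(a$max_intensity - b$max_intensity)), 0.03)
    }
  }
})

test_that("peak pixel value scales linearly with print intensity", {
  run1 <- simulate_run(zero_noise(control_params,
                                  print_intensity_mean = 0.2), seed = 5)
  run2 <- simulate_run(zero_noise(control_params,
                                  print_intensity_mean = 0.4), seed = 5)
  p1 <- max(render_frames(run1)$pix)
  p2 <- max(render_frames(run2)$pix)
  expect_equal(p2, 2 * p1, tolerance = 1e-9)
})

test_that("mirroring the stack swaps left/right but not fore/hind", {
  run <- simulate_run(zero_noise(control_params), seed = 6)
  fs <- render_frames(run)
  fsm <- fs
  fsm$pix <- fs$pix[, rev(seq_len(dim(fs$pix)[2])), , drop = FALSE]
  r1 <- label_paws(detect_contacts(fs), fs$frame_rate, run$runway_length)
  r2 <- label_paws(detect_contacts(fsm), fs$frame_rate, run$runway_length)
  swap <- c(LF = "RF", RF = "LF", LH = "RH", RH = "LH")
  a <- r1$events[order(r1$events$t_on, r1$events$x), ]
  b <- r2$events[order(r2$events$t_on, r2$events$x), ]
  expect_identical(unname(swap[a$paw]), b$paw)
})

test_that("runs with too few cycles are rejected with a diagnostic", {
  p <- zero_noise(control_params)
  full <- simulate_run(p, seed = 12)
  short <- full
  # keep only the first 4 placements per paw (3 complete cycles)
  short$events <- do.call(rbind, lapply(split(full$events, full$events$paw),
                                        function(d) d[order(d$t_on), ][1:4, ]))
  fs <- render_frames(gait_run(short$events, 60, 100, validate = FALSE))
  err <- tryCatch(
    label_paws(detect_contacts(fs), fs$frame_rate, 60),
    condition = function(c) c)
  expect_s3_class(err, "mousegait_invalid_run")
  expect_match(conditionMessage(err), "fewer than 5 complete step cycles")
})

test_that("renderer rejects unusable settings", {
  run <- simulate_run(control_params(), seed = 1)
  expect_error(render_frames(run, px_per_cm = 2), "px_per_cm")
  expect_error(render_frames(run, frame_cap = 10), "frame_cap")
})

test_that("frame stacks survive the TIFF round trip", {
  run <- simulate_run(zero_noise(control_params), seed = 13)
  fs <- render_frames(run)
  path <- withr::local_tempfile(fileext = ".tiff")
  write_frames_tiff(fs, path)
  fs2 <- read_frames_tiff(path, frame_rate = fs$frame_rate,
                          px_per_cm = fs$px_per_cm, width = fs$width)
  expect_identical(dim(fs2$pix), dim(fs$pix))
  # 16-bit quantization
  expect_lt(max(abs(fs2$pix - fs$pix)), 1 / 65535 + 1e-9)
  ev1 <- detect_contacts(fs)
  ev2 <- detect_contacts(fs2)
  expect_identical(nrow(ev1), nrow(ev2))
  expect_equal(ev1$t_on, ev2$t_on)
})
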