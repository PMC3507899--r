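test_that("temporal phases follow the interval definitions", {
  run <- make_run(paw = c("LF", "LF"), t_on = c(0, 0.20),
                  t_off = c(0.15, 0.35))
  tp <- temporal_phases(run, "LF")
  expect_equal(tp$step_cycle, 0.20)
  expect_equal(tp$stance, 0.15)
  expect_equal(tp$swing, 0.05)
  expect_equal(tp$duty_cycle, 75)

  run <- make_run(paw = c("RH", "RH"), t_on = c(0, 0.2), t_off = c(0.1, 0.3))
  expect_equal(temporal_phases(run, "RH")$duty_cycle, 50)

  expect_warning(tp1 <- temporal_phases(run, "LF"), "no complete step cycle")
  expect_identical(nrow(tp1), 0L)
})

test_that("duty cycle round-trips the configured duty factor exactly", {
  run <- simulate_run(zero_noise(control_params, duty_factor = 0.6), seed = 1)
  for (paw in c("LF", "RF", "LH", "RH")) {
    expect_equal(temporal_phases(run, paw)$duty_cycle,
                 rep(60, nrow(temporal_phases(run, paw))), tolerance = 1e-9)
  }
})

test_that("stride length and swing speed follow their definitions", {
  run <- make_run(paw = rep("LF", 3), t_on = c(0, 0.2, 0.4),
                  t_off = c(0.15, 0.35, 0.55), x = c(0, 5, 10))
  ss <- stride_and_speed(run, "LF")
  expect_equal(ss$stride_length, c(5, 5))
  expect_equal(ss$swing_speed, c(100, 100))   # 5 cm / 0.05 s

  # paw never leaves the floor: swing speed undefined
  run <- make_run(paw = rep("RH", 2), t_on = c(0, 0.2), t_off = c(0.2, 0.4),
                  x = c(0, 5))
  expect_true(is.na(stride_and_speed(run, "RH")$swing_speed))
})

test_that("cadence counts all four paws over the run duration", {
  run <- make_run(paw = rep(c("LF", "RF", "LH", "RH"), 5),
                  t_on = seq(0, 0.95, by = 0.05),
                  t_off = seq(0, 0.95, by = 0.05) + 0.049)
  expect_equal(cadence(run), 20 / run_duration(run))

  # zero-noise closed form: 4n placements over (n - 1 + phi_max + duty) * T
  p <- zero_noise(control_params)
  run <- simulate_run(p, seed = 2)
  n <- sum(run$events$paw == "LF")
  D <- (n - 1 + max(p$phase_offsets) + p$duty_factor) * p$step_cycle_mean
  expect_equal(run_duration(run), D, tolerance = 1e-9)
  expect_equal(cadence(run), 4 * n / D, tolerance = 1e-9)
})

test_that("coef_variation uses the population SD convention", {
  expect_equal(coef_variation(rep(c(4, 6), 10)), 20)
  expect_equal(coef_variation(rep(3, 5)), 0)
  expect_error(coef_variation(c(-1, 1)), "positive")
})

test_that("speed variation vanishes for a constant-speed gait", {
  # exactly periodic configuration: the cycle window cancels the staircase
  run <- simulate_run(canonical_params(), seed = 3)
  expect_lt(speed_variation(run), 1e-6)
  # zero-noise presets: only the residual window/period aliasing remains
  expect_lt(speed_variation(simulate_run(zero_noise(control_params),
                                         seed = 3)), 4)
  expect_lt(speed_variation(simulate_run(zero_noise(mptp_params),
                                         seed = 3)), 4)
})

test_that("speed variation increases with configured speed noise", {
  lo <- mean(vapply(1:6, function(s) {
    speed_variation(simulate_run(zero_noise(control_params,
                                            body_speed_cv = 0.1), seed = s))
  }, numeric(1)))
  hi <- mean(vapply(1:6, function(s) {
    speed_variation(simulate_run(zero_noise(control_params,
                                            body_speed_cv = 0.4), seed = s))
  }, numeric(1)))
  expect_gt(hi, lo)
})

test_that("base of support is the lateral left-right print distance", {
  run <- make_run(paw = rep(c("LH", "RH"), 3),
                  t_on = seq(0, 0.5, by = 0.1),
                  t_off = seq(0, 0.5, by = 0.1) + 0.09,
                  x = cumsum(rep(2, 6)), y = rep(c(2, -2), 3))
  expect_equal(base_of_support(run, "hind"), 4)
  expect_error(base_of_support(run, "fore"), "one-sided")

  run <- simulate_run(zero_noise(control_params, bos_hind = 3.63), seed = 4)
  expect_equal(base_of_support(run, "hind"), 3.63, tolerance = 1e-12)
  expect_equal(base_of_support(run, "fore"),
               control_params()$bos_fore, tolerance = 1e-12)
})

test_that("support profile matches hand-computed interval algebra", {
  # all four paws down the whole run
  run <- make_run(paw = c("LF", "RF", "LH", "RH"), t_on = rep(0, 4),
                  t_off = rep(2, 4))
  sp <- support_profile(run)
  expect_equal(sp[["four"]], 100)
  expect_equal(sum(sp), 100)

  # LF on [0,2), RH on [1,3): single 2/3, diagonal 1/3
  run <- make_run(paw = c("LF", "RH"), t_on = c(0, 1), t_off = c(2, 3))
  sp <- support_profile(run)
  expect_equal(sp[["single"]], 200 / 3)
  expect_equal(sp[["diagonal"]], 100 / 3)

  # girdle and lateral pairs
  run <- make_run(paw = c("LF", "RF"), t_on = c(0, 0), t_off = c(1, 1))
  expect_equal(support_profile(run)[["girdle"]], 100)
  run <- make_run(paw = c("LF", "LH"), t_on = c(0, 0), t_off = c(1, 1))
  expect_equal(support_profile(run)[["lateral"]], 100)
})

test_that("support fractions sum to 100 and match the brute-force oracle", {
  for (s in 1:25) {
    run <- random_run(300 + s)
    sp <- support_profile(run)
    expect_equal(sum(sp), 100, tolerance = 1e-9)
    expect_lt(max(abs(unclass(sp) - support_oracle(run))), 0.2)
  }
})

test_that("dual stances follow the overlap definitions", {
  # contralateral paw never concurrently down
  run <- make_run(paw = c("LH", "RH", "LH", "RH"),
                  t_on = c(0, 0.5, 1.0, 1.5), t_off = c(0.4, 0.9, 1.4, 1.9),
                  x = 1:4)
  d <- dual_stances(run, "LH")
  expect_equal(d$initial_dual_stance, c(0, 0))
  expect_equal(d$terminal_dual_stance, c(0, 0))

  # LH [0,1); RH [-0.2,0.3) and [0.7,1.4): initial 0.3 s, terminal 0.3 s
  run <- make_run(paw = c("RH", "LH", "RH"), t_on = c(-0.2, 0, 0.7),
                  t_off = c(0.3, 1.0, 1.4), x = 1:3)
  d <- dual_stances(run, "LH")
  expect_equal(d$initial_dual_stance, 0.3)
  expect_equal(d$terminal_dual_stance, 0.3)

  # an overlap spanning the whole stance counts as initial only
  run <- make_run(paw = c("RH", "LH"), t_on = c(-1, 0), t_off = c(3, 1),
                  x = 1:2)
  d <- dual_stances(run, "LH")
  expect_equal(d$initial_dual_stance, 1)
  expect_equal(d$terminal_dual_stance, 0)
})

test_that("footfalls sort by onset with the fixed tie order", {
  run <- make_run(paw = c("RH", "LF", "RF"), t_on = c(0.1, 0.1, 0),
                  t_off = c(0.3, 0.3, 0.2), x = 1:3)
  expect_identical(footfalls(run), c("RF", "LF", "RH"))
  empty <- gait_run(tibble::tibble(paw = character(), t_on = numeric(),
                                   t_off = numeric(), x = numeric(),
                                   y = numeric(), max_area = numeric(),
                                   max_intensity = numeric()),
                    60, 100, validate = FALSE)
  expect_identical(footfalls(empty), character(0))
})

test_that("step-pattern classification tiles greedily and exactly", {
  expect_error(classify_step_patterns(c("LF", "RH")), "at least 4")

  counts <- classify_step_patterns(rep(c("LF", "RH", "RF", "LH"), 2))
  expect_identical(unname(counts[["Ab"]]), 2L)
  expect_identical(sum(counts) - counts[["Ab"]], 0L)

  expect_identical(
    unname(classify_step_patterns(c("RF", "RH", "LF", "LH"))[["Aa"]]), 1L)
  expect_identical(
    unname(classify_step_patterns(c("LF", "RF", "RH", "LH"))[["Rb"]]), 1L)

  # double placement: first window lacks LH -> other; one trailing footfall
  counts <- classify_step_patterns(c("LF", "LF", "RH", "RF", "LH"))
  expect_identical(unname(counts[["other"]]), 1L)
  expect_identical(sum(counts), 1L)
  expect_identical(attr(counts, "trailing"), 1L)
})

test_that("regularity index scores perfect and broken patterns", {
  pure <- rep(c("LF", "RH", "RF", "LH"), 3)
  expect_equal(regularity_index(pure), 100)

  broken <- c(pure[1:8], "LF", "LF", "RH", "RF")  # third tile unmatched
  expect_equal(regularity_index(broken), 100 * 8 / 12)
})

test_that("regularity index is 100 exactly iff every window matches", {
  set.seed(42)
  for (i in 1:20) {
    ff <- unlist(lapply(seq_len(sample(3:6, 1)), function(k) {
      mousegait:::step_patterns[[sample(6, 1)]]
    }))
    if (i %% 2 == 0) ff[2:3] <- ff[3:2]  # may or may not break a window
    counts <- classify_step_patterns(ff)
    ri <- regularity_index(ff)
    if (counts[["other"]] == 0L && attr(counts, "trailing") == 0L) {
      expect_equal(ri, 100)
    } else {
      expect_lt(ri, 100)
    }
  }
})

test_that("per-cycle consistency identities hold on noisy runs", {
  for (s in 1:5) {
    run <- simulate_run(mptp_params(), seed = 400 + s)
    for (paw in c("LF", "RF", "LH", "RH")) {
      tp <- temporal_phases(run, paw)
      expect_equal(tp$stance + tp$swing, tp$step_cycle, tolerance = 1e-9)
      ss <- stride_and_speed(run, paw)
      ok <- !is.na(ss$swing_speed)
      expect_equal((ss$swing_speed * tp$swing)[ok], ss$stride_length[ok],
                   tolerance = 1e-9)
    }
  }
})

test_that("gait_profile collects every readout and tidies to a table", {
  run <- simulate_run(control_params(), seed = 5)
  prof <- gait_profile(run)
  tab <- profile_table(prof)
  expect_true(all(c("run_duration", "cadence", "speed_variation", "bos_hind",
                    "regularity_index", "support_diagonal", "stance",
                    "stride_length", "initial_dual_stance") %in%
                    tab$parameter))
  expect_identical(sum(tab$parameter == "stride_length"), 4L)
  expect_equal(tab$value[tab$parameter == "run_duration"],
               run_duration(run))
})
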