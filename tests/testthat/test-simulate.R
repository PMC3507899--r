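test_that("deterministic limit reproduces the configured kinematics exactly", {
  p <- gait_params(step_cycle_mean = 0.2, duty_factor = 0.5,
                   stride_length_mean = 5, start_jitter = 0)
  run <- simulate_run(p, seed = 1)
  for (paw in c("LF", "RF", "LH", "RH")) {
    tp <- temporal_phases(run, paw)
    expect_equal(tp$stance, rep(0.1, nrow(tp)), tolerance = 1e-12)
    expect_equal(tp$step_cycle, rep(0.2, nrow(tp)), tolerance = 1e-12)
    ss <- stride_and_speed(run, paw)
    expect_equal(ss$stride_length, rep(5, nrow(ss)), tolerance = 1e-12)
  }
})

test_that("zero pattern noise yields a pure Ab footfall sequence", {
  run <- simulate_run(zero_noise(control_params), seed = 2)
  ff <- footfalls(run)
  expect_identical(ff, rep(c("LF", "RH", "RF", "LH"), length(ff) / 4))
  counts <- classify_step_patterns(ff)
  expect_identical(unname(counts[["Ab"]]), as.integer(length(ff) / 4))
  expect_identical(sum(counts) - counts[["Ab"]], 0L)
})

test_that("runs are reproducible under a seed and vary across seeds", {
  a <- simulate_run(control_params(), seed = 7)
  b <- simulate_run(control_params(), seed = 7)
  c <- simulate_run(control_params(), seed = 8)
  expect_identical(a$events, b$events)
  expect_false(identical(a$events, c$events))
})

test_that("empirical step cycle matches the configured mean (Monte Carlo)", {
  p <- control_params()
  sc <- unlist(lapply(1:20, function(s) {
    run <- simulate_run(p, seed = s)
    unlist(lapply(c("LF", "RF", "LH", "RH"),
                  function(pw) temporal_phases(run, pw)$step_cycle))
  }))
  se <- sd(sc) / sqrt(length(sc))
  expect_lt(abs(mean(sc) - p$step_cycle_mean), 3 * se + 1e-4)
})

test_that("per-paw contacts never overlap and placements advance", {
  for (s in 1:10) {
    run <- simulate_run(mptp_params(), seed = s)
    expect_silent(validate_run(run))
  }
})

test_that("footfall order is invariant to frame rate and runway length", {
  base <- zero_noise(control_params)
  long <- zero_noise(control_params, runway_length = 90)
  fast <- zero_noise(control_params, frame_rate = 250)
  ff <- lapply(list(base, long, fast),
               function(p) footfalls(simulate_run(p, seed = 3)))
  n <- min(lengths(ff))
  expect_identical(ff[[1]][1:n], ff[[2]][1:n])
  expect_identical(ff[[1]][1:n], ff[[3]][1:n])
})

test_that("TH and latent severity are monotonically coupled", {
  co <- simulate_cohort(cohort = cohort_params(n_per_group = 10,
                                               runs_per_animal = 1,
                                               th_noise_sd = 0, seed = 5))
  expect_equal(cor(co$animals$severity, co$animals$th_sn,
                   method = "spearman"), -1)
})

test_that("TH group means yield the configured percent loss", {
  co <- simulate_cohort(cohort = cohort_params(n_per_group = 6,
                                               runs_per_animal = 1,
                                               th_noise_sd = 0,
                                               severity_sd = 0, seed = 1))
  th <- split(co$animals$th_sn, co$animals$group)
  expect_equal(percent_loss(th$mptp, th$control), 57.04, tolerance = 1e-8)
})

test_that("decoupled cohorts show no systematic gait-TH correlation", {
  # decoupled limit: no gait-TH mechanism at all (both groups walk with the
  # same preset and no block follows the latent severity)
  rs <- vapply(1:25, function(s) {
    co <- simulate_cohort(control_params(), control_params(),
                          cohort_params(
      n_per_group = 10, runs_per_animal = 1,
      gait_th_coupling = c(timing = 0, stride = 0, posture = 0,
                           speed = 0, bos = 0),
      openfield_th_coupling = 0, seed = s))
    stride <- vapply(co$runs, function(rr) {
      mean(stride_and_speed(rr[[1]], "LF")$stride_length)
    }, numeric(1))
    cor(stride, co$animals$th_sn)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("cohort group means converge to the preset means", {
  # low speed noise: strides then never hit the runway's physical ceiling
  # (censoring by the walkway length is a separate, documented effect)
  co <- simulate_cohort(control_params(body_speed_cv = 0.1),
                        mptp_params(body_speed_cv = 0.1),
                        cohort_params(
    n_per_group = 200, runs_per_animal = 1,
    gait_th_coupling = c(timing = 1, stride = 1, posture = 1, speed = 1,
                         bos = 1),
    seed = 9))
  stride <- vapply(seq_len(nrow(co$animals)), function(a) {
    mean(stride_and_speed(co$runs[[a]][[1]], "LF")$stride_length)
  }, numeric(1))
  m <- tapply(stride, co$animals$group, mean)
  expect_equal(unname(m[["control"]]),
               control_params()$stride_length_mean, tolerance = 0.02)
  expect_equal(unname(m[["mptp"]]),
               mptp_params()$stride_length_mean, tolerance = 0.02)
})

test_that("open-field trajectories behave in the closed-form limits", {
  expect_equal(path_length(simulate_open_field(0, duration = 10,
                                               seed = 1))$total_distance, 0)
  # unbounded straight line: exact closed form (no wall encounter)
  tr <- simulate_open_field(5, duration = 10, turn_sd = 0, speed_cv = 0,
                            arena = 500, seed = 2)
  expect_equal(path_length(tr, arena = 500)$total_distance, 50,
               tolerance = 1e-9)
  # bounded walk: reflections keep nearly all path length inside the arena
  tr <- simulate_open_field(5, duration = 10, turn_sd = 0, speed_cv = 0,
                            seed = 2)
  expect_gt(path_length(tr)$total_distance, 49)
  expect_error(simulate_open_field(5, duration = -1), "duration")
  # samples stay inside the arena and time is strictly increasing
  expect_true(all(tr$x >= 0 & tr$x <= 50 & tr$y >= 0 & tr$y <= 50))
  expect_true(all(diff(tr$t) > 0))
})

test_that("lesioned animals travel less in the open field", {
  worse <- vapply(1:40, function(s) {
    co <- cohort_params(n_per_group = 8, seed = s)
    ctrl <- vapply(1:8, function(i) {
      path_length(simulate_open_field(co$openfield_speed_control,
                                      duration = 120,
                                      seed = s * 100 + i))$total_distance
    }, numeric(1))
    mptp <- vapply(1:8, function(i) {
      path_length(simulate_open_field(co$openfield_speed_mptp,
                                      duration = 120,
                                      seed = s * 100 + 50 + i))$total_distance
    }, numeric(1))
    mean(mptp) < mean(ctrl)
  }, logical(1))
  expect_gte(mean(worse), 0.95)
})
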