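test_that("one noiseless threshold step matches hand evaluation", {
  p <- conv2_params()
  s1 <- threshold_step(list(T_current = 340, D = 0), p, noiseless = TRUE)
  expect_equal(s1$T_current, 337.6, tolerance = 1e-10) # decrement 2.4 at D=0
  expect_equal(s1$D, 1)

  s2 <- threshold_step(list(T_current = 200, D = 100), p, noiseless = TRUE)
  expect_equal(200 - s2$T_current, 2.4 * exp(-1), tolerance = 1e-10) # 0.8829
})

test_that("huge alpha approaches the noiseless step", {
  p_big <- threshold_params(340, 100, 100, alpha = 1e12)
  set.seed(1)
  s <- threshold_step(list(T_current = 340, D = 0), p_big)
  expect_equal(s$T_current, 337.6, tolerance = 1e-6)
})

test_that("noiseless trajectory decreases monotonically to the closed-form floor", {
  for (p in list(conv2_params(), threshold_params(0.55, 0.15, 100, 50),
                 conv2_params(attention_C = 2))) {
    st <- list(T_current = p$attention_C * p$T_max, D = 0)
    traj <- numeric(2500)
    for (i in seq_len(2500)) {
      st <- threshold_step(st, p, noiseless = TRUE)
      traj[i] <- st$T_current
    }
    expect_true(all(diff(traj) < 0))
    expect_equal(traj[2500], threshold_floor(p), tolerance = 1e-6)
  }
  # geometric-series floor for the conv2 defaults sits near 98.8
  expect_equal(threshold_floor(conv2_params()),
               340 - 240 / (100 * (1 - exp(-1 / 100))), tolerance = 1e-12)
})

test_that("detection handles degenerate distance series", {
  p <- conv2_params()
  zeros <- as_distance_series(list(conv2 = rep(0, 300)))
  expect_length(detect_salient_events(zeros, p, noiseless = TRUE)$conv2, 0)

  supra <- as_distance_series(list(conv2 = rep(350, 120))) # > T_max = 340
  ev <- detect_salient_events(supra, p, seed = 4)
  expect_equal(ev$conv2, 1:120) # event at every timestep

  # constant 50 never crosses: the noiseless floor stays near 98.8
  sub <- as_distance_series(list(conv2 = rep(50, 3000)))
  expect_length(detect_salient_events(sub, p, noiseless = TRUE)$conv2, 0)
})

test_that("detection agrees bitwise with an independent R loop, noise on and off", {
  set.seed(20)
  d <- runif(400, 0, 450)
  ds <- as_distance_series(list(conv2 = d))
  for (p in list(conv2_params(), conv2_params(attention_C = 1.5),
                 conv2_params(noise_as_variance = TRUE))) {
    expect_identical(detect_salient_events(ds, p, noiseless = TRUE)$conv2,
                     r_detect_oracle(d, p, noiseless = TRUE))
    expect_identical(detect_salient_events(ds, p, seed = 77)$conv2,
                     r_detect_oracle(d, p, seed = 77, noiseless = FALSE))
  }
})

test_that("static mode counts equal a direct threshold comparison", {
  set.seed(8)
  d <- runif(500, 0, 500)
  for (C in c(0.5, 1, 2)) {
    p <- conv2_params(static_mode = TRUE, attention_C = C)
    ev <- detect_salient_events(as_distance_series(list(conv2 = d)), p,
                                seed = 1)
    expect_equal(length(ev$conv2), sum(d > C * 340))
  }
})

test_that("noiseless event counts are monotone in the distance series", {
  set.seed(9)
  d <- runif(600, 0, 400)
  p <- conv2_params()
  n1 <- length(detect_salient_events(as_distance_series(list(conv2 = d)), p,
                                     noiseless = TRUE)$conv2)
  n2 <- length(detect_salient_events(
    as_distance_series(list(conv2 = d + 30)), p, noiseless = TRUE)$conv2)
  expect_gte(n2, n1)
})

test_that("noiseless detection is scale-equivariant under joint scaling", {
  set.seed(10)
  d <- runif(500, 0, 420)
  p <- conv2_params()
  base <- detect_salient_events(as_distance_series(list(conv2 = d)), p,
                                noiseless = TRUE)$conv2
  for (f in c(0.25, 3)) {
    scaled <- detect_salient_events(
      as_distance_series(list(conv2 = f * d)), scale_attention(p, f),
      noiseless = TRUE)$conv2
    expect_identical(scaled, base)
  }
})

test_that("stochastic detection is seed-reproducible yet varies across seeds", {
  set.seed(30)
  d <- runif(800, 60, 360)
  ds <- as_distance_series(list(conv2 = d))
  p <- conv2_params()
  expect_identical(detect_salient_events(ds, p, seed = 5)$conv2,
                   detect_salient_events(ds, p, seed = 5)$conv2)
  counts <- vapply(1:20, function(s)
    length(detect_salient_events(ds, p, seed = s)$conv2), 1L)
  expect_gt(var(counts), 0)
})

test_that("attention scaling transforms parameters and suppresses counts", {
  p <- conv2_params()
  expect_equal(scale_attention(p, 1), p)
  p2 <- scale_attention(p, 2)
  expect_equal(p2$attention_C * p2$T_max, 680)
  expect_equal(p2$attention_C * p2$T_min, 200)
  expect_error(scale_attention(p, 0), "> 0")
  expect_error(scale_attention(p, -1), "> 0")

  # on a fixed stochastic stream, mean count is non-increasing in C
  set.seed(14)
  d <- as_distance_series(list(conv2 = runif(1500, 0, 380)))
  mean_count <- vapply(c(0.5, 1, 2), function(C) {
    cs <- vapply(1:10, function(s)
      length(detect_salient_events(d, scale_attention(p, C),
                                   seed = s)$conv2), 1L)
    mean(cs)
  }, numeric(1))
  expect_true(all(diff(mean_count) <= 0))
})

test_that("accumulators are per-trial independent and definitionally counted", {
  design <- trial_design(c(2, 4), repetitions = 2, scene_types = "synthetic",
                         seed = 1)
  streams <- synth_streams(design, list(synthetic = scene_spec("synthetic",
                                                               0.8)),
                           params = list(conv2 = conv2_params()), seed = 3)
  acc1 <- run_accumulators(streams, list(conv2 = conv2_params()), design,
                           seed = 9)
  acc2 <- run_accumulators(streams, list(conv2 = conv2_params()), design,
                           seed = 9)
  expect_identical(acc1$count, acc2$count) # no state leaks between runs

  # counts equal event-train lengths trial by trial
  for (id in design$trial_id) {
    ev <- detect_salient_events(streams[[id]], list(conv2 = conv2_params()),
                                seed = perceptime:::trial_seed(9, id))
    expect_equal(acc1$count[acc1$trial_id == id], length(ev$conv2))
  }

  # empty distance series -> zero counts
  empty <- list(t0 = as_distance_series(list(conv2 = numeric(0)), "t0"))
  acc0 <- run_accumulators(empty, list(conv2 = conv2_params()))
  expect_equal(acc0$count, 0L)
})

test_that("cumulative curves end at the trial counts", {
  design <- trial_design(c(4, 8), repetitions = 2, scene_types = "synthetic",
                         seed = 2)
  streams <- synth_streams(design, list(synthetic = scene_spec("synthetic",
                                                               1)),
                           params = list(conv2 = conv2_params()), seed = 5)
  acc <- run_accumulators(streams, list(conv2 = conv2_params()), design,
                          seed = 5, keep_curves = TRUE)
  curves <- attr(acc, "curves")
  for (id in design$trial_id) {
    cc <- curves[curves$trial_id == id, ]
    expect_equal(max(cc$cumulative_count),
                 acc$count[acc$trial_id == id])
    expect_true(all(diff(cc$cumulative_count) >= 0))
  }
})
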