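test_that("cross-validation partition honours the fold contract", {
  # balanced design and a deliberately awkward n
  for (reps in c(20, 7)) {
    w <- proportional_counts(repetitions = reps)
    est <- calibrate_durations(w, calibration_spec())
    expect_equal(nrow(est), nrow(w))
    expect_equal(sort(unique(est$fold)), 1:10)
    expect_equal(anyDuplicated(est$trial_id), 0L) # one test fold per trial
    expect_lte(diff(range(table(est$fold))), 1)   # sizes differ by <= 1
  }
  expect_error(calibrate_durations(proportional_counts(repetitions = 20)[1:5, ],
                                   calibration_spec()), "folds")
})

test_that("counts proportional to duration are recovered monotonically", {
  w <- proportional_counts()
  est <- calibrate_durations(w, calibration_spec())
  expect_gt(cor(est$predicted_s, est$true_s, method = "spearman"), 0.95)
  expect_true(all(is.finite(est$predicted_s)))
})

test_that("estimates are invariant to trial ordering", {
  w <- proportional_counts(repetitions = 5)
  est1 <- calibrate_durations(w, calibration_spec())
  set.seed(2)
  w2 <- w[sample.int(nrow(w)), ]
  est2 <- calibrate_durations(w2, calibration_spec())
  idx <- match(est1$trial_id, est2$trial_id)
  expect_equal(est1$predicted_s, est2$predicted_s[idx])
  expect_equal(est1$fold, est2$fold[idx])
})

test_that("constant features predict inside the training target range", {
  d <- trial_design(standard_durations(), 3, scene_types = "synthetic",
                    seed = 1)
  w <- data.frame(trial_id = d$trial_id, count_a = 5, count_b = 5,
                  duration_s = d$duration_s, scene_type = d$scene_type)
  est <- calibrate_durations(w, calibration_spec())
  expect_true(all(est$predicted_s >= min(d$duration_s)))
  expect_true(all(est$predicted_s <= max(d$duration_s)))
})

test_that("normalised mean error matches hand arithmetic", {
  mk <- function(true_s, pred) {
    structure(data.frame(trial_id = seq_along(true_s), regime = "stream",
                         scene_type = "s", true_s = true_s,
                         predicted_s = pred,
                         predicted_clamped_s = pmax(pred, 0), fold = 1L),
              class = c("estimate_set", "data.frame"))
  }
  perfect <- mk(c(1, 2, 4), c(1, 2, 4))
  expect_equal(compute_nme(perfect)$overall, 0)
  expect_equal(compute_nme(perfect)$per_duration$nme, c(0, 0, 0))

  doubled <- mk(c(1, 2, 4), 2 * c(1, 2, 4))
  expect_equal(compute_nme(doubled)$overall, 1.0)

  toy <- mk(c(1, 4), c(2, 2)) # per-trial errors +1.0 and -0.5
  expect_equal(toy$predicted_s / toy$true_s - 1, c(1, -0.5))
  expect_equal(compute_nme(toy)$overall, mean(c(1, -0.5)))

  expect_error(compute_nme(mk(c(0, 1), c(1, 1))), "zero true duration")
})

test_that("RMSE matches trivial cases and checks reference length", {
  mk <- function(true_s, pred)
    structure(data.frame(trial_id = seq_along(true_s), regime = "stream",
                         scene_type = "s", true_s = true_s,
                         predicted_s = pred,
                         predicted_clamped_s = pmax(pred, 0), fold = 1L),
              class = c("estimate_set", "data.frame"))
  expect_equal(compute_rmse(mk(1:5, 1:5)), 0)
  expect_equal(compute_rmse(mk(1:5, 1:5 + 1)), 1.0)
  # external reference series (e.g. observer reports) replaces the truths
  expect_equal(compute_rmse(mk(1:4, c(2, 3, 4, 5)), reference = c(2, 3, 4, 5)),
               0)
  expect_error(compute_rmse(mk(1:4, 1:4), reference = 1:3), "reference")
})

test_that("scene bias deviations match hand arithmetic and sum to zero", {
  durs <- c(2, 8)
  base <- expand.grid(scene_type = c("A", "B"), rep = 1:6, true_s = durs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # scene A uniformly 1.10x the grand mean at every duration (B at 0.90x,
  # equal trial counts, so the grand mean is the duration itself)
  base$predicted_s <- ifelse(base$scene_type == "A", 1.10, 0.90) * base$true_s
  est <- structure(
    data.frame(trial_id = seq_len(nrow(base)), regime = "stream",
               scene_type = base$scene_type, true_s = base$true_s,
               predicted_s = base$predicted_s,
               predicted_clamped_s = base$predicted_s, fold = 1L),
    class = c("estimate_set", "data.frame"))
  sb <- scene_bias(est)
  expect_equal(sb$per_scene$deviation_pct[sb$per_scene$scene_type == "A"],
               10, tolerance = 1e-10)
  expect_equal(sb$ordering, c("A", "B"))

  # trial-count-weighted deviations cancel at each duration level
  for (cell in split(sb$per_cell, sb$per_cell$duration_s)) {
    n_sc <- table(est$scene_type[est$true_s == cell$duration_s[1]])
    means <- cell$deviation_pct[match(names(n_sc), cell$scene_type)]
    expect_equal(sum(means * as.integer(n_sc)) / sum(n_sc), 0,
                 tolerance = 1e-10)
  }

  # identical estimate distributions across scenes -> zero deviations
  est0 <- est; est0$predicted_s <- est0$true_s
  expect_true(all(abs(scene_bias(est0)$per_scene$deviation_pct) < 1e-12))
})

test_that("pooled scene bias is available as the alternative summary", {
  est <- structure(
    data.frame(trial_id = 1:4, regime = "stream",
               scene_type = c("A", "A", "B", "B"), true_s = c(2, 2, 2, 2),
               predicted_s = c(3, 3, 1, 1), predicted_clamped_s = 0,
               fold = 1L),
    class = c("estimate_set", "data.frame"))
  sb <- scene_bias(est, method = "pooled")
  expect_equal(sb$per_scene$deviation_pct, c(50, -50))
})

test_that("variance by duration captures scalar variability", {
  mk <- function(true_s, pred)
    structure(data.frame(trial_id = seq_along(true_s), regime = "stream",
                         scene_type = "s", true_s = true_s,
                         predicted_s = pred, predicted_clamped_s = pred,
                         fold = 1L),
              class = c("estimate_set", "data.frame"))
  # identical estimates within duration -> SD 0 everywhere
  t0 <- mk(rep(c(1, 4), each = 3), rep(c(2, 5), each = 3))
  v0 <- variance_by_duration(t0)
  expect_equal(v0$per_duration$sd_est, c(0, 0))

  # estimates duration*(1+e), e ~ N(0, 0.1^2): SD-vs-mean slope ~ 0.1
  set.seed(33)
  durs <- rep(standard_durations(), each = 1000)
  est <- mk(durs, durs * (1 + rnorm(length(durs), 0, 0.1)))
  v <- variance_by_duration(est)
  expect_lt(abs(v$slope - 0.1), 3 * v$slope_se)

  # doubling all estimates doubles every per-duration SD
  est2 <- est; est2$predicted_s <- 2 * est$predicted_s
  v2 <- variance_by_duration(est2)
  expect_equal(v2$per_duration$sd_est, 2 * v$per_duration$sd_est)
})

test_that("training on a duration subset pulls estimates toward that range", {
  w <- proportional_counts()
  est <- calibrate_durations(w, calibration_spec(),
                             train_durations = c(1, 1.5, 2, 3, 4, 6, 8))
  above <- est$true_s > 8
  expect_lt(mean(est$predicted_s[above]), mean(est$true_s[above]))
  expect_true(all(est$predicted_s[above] < est$true_s[above]))
})

test_that("re-applying a calibration to new counts uses out-of-fold models", {
  w <- proportional_counts(repetitions = 5)
  cal <- calibrate_durations(w, calibration_spec())
  again <- predict_durations(cal, w)
  expect_equal(again$predicted_s, cal$predicted_s) # same counts, same result
  expect_equal(again$fold, cal$fold)

  w_less <- w
  cnt <- grep("^count_", names(w_less))
  w_less[cnt] <- lapply(w_less[cnt], function(x) pmax(x - 5, 0))
  fewer <- predict_durations(cal, w_less)
  expect_lte(mean(fewer$predicted_s), mean(cal$predicted_s))
})
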