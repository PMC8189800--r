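test_that("target sequences respect range, step and reproducibility", {
  s <- generate_target_sequence(50, seed = 3)
  p <- s$positions
  expect_true(all(abs(p[, 1]) <= 15))
  expect_true(all(abs(p[, 2]) <= 9))
  steps <- sqrt(rowSums(diff(p)^2))
  expect_true(all(steps >= 2))
  expect_identical(p, generate_target_sequence(50, seed = 3)$positions)
  expect_false(identical(p, generate_target_sequence(50, seed = 4)$positions))
  expect_error(generate_target_sequence(2, ranges = c(1, 1), min_step = 10),
               "infeasible")
})

test_that("mixture specs are validated", {
  expect_error(synthetic_scenario(components = list(means = c(1, 2),
                                                    sds = c(0.1, 0.1),
                                                    weights = c(0.5, 0.4))),
               "sum to 1")
  expect_error(synthetic_scenario(components = list(means = 1, sds = -0.1,
                                                    weights = 1)))
  expect_error(generate_offset_sample(list(means = 1, sds = 0, weights = 1),
                                      10), "positive")
})

test_that("mixture offset samples are nonnegative with correct moments", {
  comp <- list(means = c(0.5, 2), sds = c(0.05, 0.05), weights = c(0.7, 0.3))
  x <- generate_offset_sample(comp, 5000, seed = 9)
  expect_true(all(x >= 0))
  expect_equal(mean(x < 1.25), 0.7, tolerance = 0.03)
  expect_equal(mean(x[x < 1.25]), 0.5, tolerance = 0.01)
  expect_equal(mean(x[x > 1.25]), 2, tolerance = 0.01)
  expect_identical(x, generate_offset_sample(comp, 5000, seed = 9))
})

test_that("recordings have the right shape and planted latencies", {
  seqs <- generate_target_sequence(5, seed = 7)
  sc <- synthetic_scenario(seed = 7)
  rec <- generate_recording(seqs, sc)
  expect_s3_class(rec, "gaze_recording")
  expect_equal(length(rec), 5000)
  gt <- attr(rec, "ground_truth")
  expect_equal(length(gt$latency_ms), 5)
  expect_true(all(gt$latency_ms >= 192 & gt$latency_ms <= 316))
  # fixed latency scenario
  sc0 <- synthetic_scenario(seed = 7, latency_sd = 0)
  gt0 <- attr(generate_recording(seqs, sc0), "ground_truth")
  expect_true(all(gt0$latency_ms == 237))
})

test_that("recordings are reproducible per (seed, subject, session)", {
  seqs <- generate_target_sequence(3, seed = 2)
  sc <- synthetic_scenario(seed = 2)
  r1 <- generate_recording(seqs, sc, subject = 4, session = 1)
  r2 <- generate_recording(seqs, sc, subject = 4, session = 1)
  r3 <- generate_recording(seqs, sc, subject = 5, session = 1)
  expect_identical(r1$gx, r2$gx)
  expect_false(identical(r1$gx, r3$gx))
})

test_that("blinks appear as NaN blocks matching the ground truth", {
  seqs <- generate_target_sequence(6, seed = 11)
  sc <- synthetic_scenario(seed = 11, blink_rate = 1)
  rec <- generate_recording(seqs, sc)
  gt <- attr(rec, "ground_truth")
  expect_gt(length(gt$blinks), 0)
  for (b in gt$blinks) {
    expect_true(all(is.na(rec$gx[b["start"]:b["end"]])))
  }
})

test_that("anticipatory saccades are planted and park gaze at the next target", {
  seqs <- generate_target_sequence(6, seed = 13)
  sc <- synthetic_scenario(seed = 13, anticipatory_hazard_slope = 1,
                           fixation_noise_sd = 0)
  rec <- generate_recording(seqs, sc)
  gt <- attr(rec, "ground_truth")
  expect_gt(length(gt$anticipatory), 0)
  ev <- gt$anticipatory[[1]]
  t <- ev["trial"]
  # by the end of trial t, gaze sits near the NEXT target, not the current one
  i_end <- t * 1000
  d_next <- euclidean_distance(rec$gx[i_end], rec$gy[i_end],
                               rec$tx[i_end + 1], rec$ty[i_end + 1])
  expect_lt(d_next, 1.5)
})

test_that("main-sequence saccades exceed the 55 deg/s peak-velocity mark", {
  seqs <- generate_target_sequence(6, seed = 17)
  sc <- synthetic_scenario(seed = 17, fixation_noise_sd = 0)
  rec <- generate_recording(seqs, sc)
  gt <- attr(rec, "ground_truth")
  vel <- compute_velocity(rec)
  for (s in gt$saccades) {
    expect_gt(max(vel$radial[s["start"]:s["end"]], na.rm = TRUE), 55)
  }
})

test_that("the planted latency marks the saccade midpoint", {
  seqs <- generate_target_sequence(4, seed = 19)
  sc <- synthetic_scenario(seed = 19, latency_sd = 0, fixation_noise_sd = 0)
  rec <- generate_recording(seqs, sc)
  gt <- attr(rec, "ground_truth")
  for (i in seq_along(gt$saccades)) {
    s <- gt$saccades[[i]]
    mid <- (s["start"] + s["end"]) / 2
    within_trial <- mid - 1000 * ((s["start"] - 1) %/% 1000)
    expect_lt(abs(within_trial - 237), 2)
  }
})
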