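test_that("na_runs finds maximal runs", {
  r <- fixmodal:::na_runs(c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(unname(r), cbind(c(2, 5), c(3, 5)))
  expect_equal(nrow(fixmodal:::na_runs(rep(FALSE, 4))), 0)
  expect_equal(unname(fixmodal:::na_runs(rep(TRUE, 3))), cbind(1, 3))
})

test_that("latency is recovered exactly on a pure-delay recording", {
  for (L in c(192L, 237L, 316L)) {
    rec <- pure_delay_recording(n_targets = 3, delay = L, seed = L)
    expect_identical(estimate_latency(rec), L)
  }
})

test_that("latency ties go to the smallest shift", {
  # constant gaze on a constant target: every shift gives zero mean offset
  n <- 1200
  rec <- gaze_recording(seq_len(n) - 1, rep(1, n), rep(2, n),
                        rep(1, n), rep(2, n))
  expect_identical(estimate_latency(rec), 1L)
})

test_that("shift_gaze advances gaze and truncates the tail", {
  rec <- pure_delay_recording(n_targets = 2, delay = 100, seed = 1)
  sh <- shift_gaze(rec, 100)
  expect_equal(length(sh), length(rec) - 100)
  expect_equal(sh$gx, sh$tx)   # perfectly aligned after the true shift
  expect_error(shift_gaze(rec, 0))
})

test_that("mean_offset_curve excludes NaN and >60 degree fixations", {
  m <- rbind(c(1, 2, 3), c(NA, 2, 3), c(1, 2, 61), c(3, 4, 5))
  curve <- mean_offset_curve(m)
  expect_equal(as.numeric(curve), c(2, 3, 4))
  expect_equal(attr(curve, "n_contributing"), 2)
  expect_error(mean_offset_curve(rbind(c(NA, 1))), "no fixations")
})

test_that("select_analysis_window matches brute force and prefers early ties", {
  for (s in 1:10) {
    set.seed(s)
    curve <- cumsum(rnorm(300)) + runif(1, 0, 5)
    expect_equal(select_analysis_window(curve, 50), brute_window(curve, 50))
  }
  flat <- rep(1, 100)
  expect_equal(unname(select_analysis_window(flat, 10)), c(1, 10))
  expect_error(select_analysis_window(rep(1, 5), 10), "shorter")
})

test_that("compute_velocity recovers the slope of a ramp per segment", {
  n <- 200
  gx <- 0.01 * seq_len(n)         # 10 deg/s at 1000 Hz
  gy <- rep(0, n)
  gx[90:110] <- NA
  rec <- gaze_recording(seq_len(n) - 1, gx, gy, rep(0, n), rep(0, n))
  vel <- compute_velocity(rec)
  expect_equal(vel$vx[20:60], rep(10, 41), tolerance = 1e-9)
  expect_equal(vel$vx[150:190], rep(10, 41), tolerance = 1e-9)
  expect_true(all(is.na(vel$vx[90:110])))
  expect_equal(vel$radial[30], 10, tolerance = 1e-9)
})

test_that("FixVelT pools eligible blocks only", {
  # radial velocity: a clean 100-sample fixation block at 1..100 centi-deg/s
  rad <- c(rep(100, 10),              # saccade stretch (> 55): removed
           seq(0.01, 1, length.out = 100),
           rep(100, 5),
           rep(0.5, 20))              # 20 ms block < 40 ms: rejected
  vel <- list(radial = rad)
  got <- fixation_velocity_threshold(vel, fs = 1000)
  expected <- unname(quantile(seq(0.01, 1, length.out = 100)[5:96], 0.9))
  expect_equal(got, expected)
  expect_error(fixation_velocity_threshold(list(radial = rep(100, 50))),
               "no fixation samples")
})

test_that("blink-saccade removal NaNs the flanks up to the marks", {
  set.seed(41)
  n <- 400
  gx <- rnorm(n, 0, 0.01); gy <- rnorm(n, 0, 0.01)
  # blink at 200..250 with fast flanks 180..199 and 251..270
  gy[180:199] <- seq(0, 5, length.out = 20)
  gy[251:270] <- seq(5, 0, length.out = 20)
  gx[200:250] <- NA; gy[200:250] <- NA
  rec <- gaze_recording(seq_len(n) - 1, gx, gy, rep(0, n), rep(0, n))
  vel <- compute_velocity(rec)
  out <- remove_blink_saccades(rec, vel, fixvelt = 20)
  # the flank samples adjacent to the block must be gone
  expect_true(all(is.na(out$gx[185:265])))
  # quiet samples well before/after the flank survive
  expect_false(anyNA(out$gx[1:170]))
  expect_false(anyNA(out$gx[285:n]))
})

test_that("blink blocks at a recording boundary are removed to the edge", {
  set.seed(42)
  n <- 200
  gx <- rnorm(n, 0, 0.01); gy <- rnorm(n, 0, 0.01)
  gx[1:30] <- NA; gy[1:30] <- NA
  gy[31:45] <- seq(4, 0, length.out = 15)   # fast flank right after the block
  rec <- gaze_recording(seq_len(n) - 1, gx, gy, rep(0, n), rep(0, n))
  vel <- compute_velocity(rec)
  out <- remove_blink_saccades(rec, vel, fixvelt = 20)
  expect_true(all(is.na(out$gx[1:40])))
  expect_false(anyNA(out$gx[60:n]))
})

test_that("velocity saccade removal expands to sub-30 deg/s local minima", {
  set.seed(43)
  n <- 600
  gx <- rep(0, n)
  # min-jerk 10-degree saccade over 40 ms starting at 300
  tau <- (1:40) / 40
  gx[301:340] <- 10 * fixmodal:::min_jerk(tau)
  gx[341:n] <- 10
  gx <- gx + rnorm(n, 0, 0.005)
  rec <- gaze_recording(seq_len(n) - 1, gx, rep(0, n), rep(0, n), rep(0, n))
  vel <- compute_velocity(rec)
  out <- remove_saccades_velocity(rec, vel)
  expect_true(all(is.na(out$gx[305:335])))       # core of the saccade
  expect_false(anyNA(out$gx[1:280]))             # fixation before survives
  expect_false(anyNA(out$gx[370:n]))             # fixation after survives
})

test_that("quadratic windows flag parabolas but not slow ramps or noise", {
  w <- 27
  # pure parabola on the window index: r2 = 1, beta*1000 = 1 > 0.55
  y <- 0.001 * (seq_len(200))^2
  f <- fixmodal:::quad_flags(y, w)
  expect_true(all(f))
  # slow linear ramp: high r2 but beta*1000 ~ 0.035 < 0.55
  yr <- 0.001 * seq_len(200)
  expect_false(any(fixmodal:::quad_flags(yr, w)))
  # white noise: (near-)zero flag rate
  set.seed(4)
  yn <- rnorm(5000, 0, 0.01)
  expect_lt(mean(fixmodal:::quad_flags(yn, w)), 0.001)
  # NaN windows are never flagged
  y[50] <- NA
  fn <- fixmodal:::quad_flags(y, w)
  expect_false(any(fn[(50 - w + 1):50]))
})

test_that("quad_flags agrees with lm() on random windows", {
  set.seed(8)
  y <- cumsum(rnorm(120, 0, 0.05))
  w <- 27
  f <- fixmodal:::quad_flags(y, w)
  x2 <- (1:w)^2
  for (s in c(1, 10, 40, 94)) {
    fit <- lm(y[s:(s + w - 1)] ~ x2)
    r2 <- summary(fit)$r.squared
    beta <- coef(fit)[2]
    expect_identical(unname(f[s]), r2 > 0.6 && abs(beta) * 1000 > 0.55)
  }
})

test_that("remove_saccades_quadratic NaNs the union of both channels", {
  set.seed(44)
  n <- 300
  gx <- rnorm(n, 0, 0.005); gy <- rnorm(n, 0, 0.005)
  gx[100:126] <- 0.001 * (1:27)^2 + gx[100:126]
  rec <- gaze_recording(seq_len(n) - 1, gx, gy, rep(0, n), rep(0, n))
  out <- remove_saccades_quadratic(rec)
  expect_true(all(is.na(out$gx[100:126])))
  expect_true(all(is.na(out$gy[100:126])))   # both channels NaN'd together
  expect_false(anyNA(out$gx[1:60]))
})

test_that("anticipatory plateaus are removed only when long and in-window", {
  set.seed(45)
  n <- 2000  # two trials
  gx <- rnorm(n, 0, 0.01); gy <- rnorm(n, 0, 0.01)
  tx <- rep(0, n); ty <- rep(0, n)
  gx[1300:1500] <- 5          # 201 ms plateau inside window 192..691 of trial 2
  gx[801:850] <- 5            # 50 ms run in trial 1: too short
  gy[1:120] <- 5              # long run in trial 1 but entirely pre-window?
  rec <- gaze_recording(seq_len(n) - 1, gx, gy, tx, ty)
  res <- remove_anticipatory(rec, analysis_window = c(192, 691))
  expect_true(all(is.na(res$rec$gx[1300:1500])))
  expect_false(anyNA(res$rec$gx[801:850]))
  expect_false(anyNA(res$rec$gy[1:120]))  # does not overlap the window
  expect_equal(res$as_log$trial, 2)
  expect_equal(res$as_log$start, 300)
})

test_that("segment/inclusion accounting follows the two rules", {
  off <- rep(1, 500)
  s <- segment_and_include(off)
  expect_true(s$included)
  expect_equal(s$n_segments, 1)
  off2 <- off
  off2[c(50, 150, 250, 350, 450)] <- NA   # 5 NaN blocks
  s2 <- segment_and_include(off2)
  expect_equal(s2$n_nan_blocks, 5)
  expect_false(s2$included)
  off3 <- off
  off3[1:101] <- NA                        # 399 valid < 400
  s3 <- segment_and_include(off3)
  expect_equal(s3$n_valid, 399)
  expect_false(s3$included)
  off4 <- off
  off4[c(100:110, 300:310)] <- NA
  s4 <- segment_and_include(off4)
  expect_true(s4$included)
  expect_equal(s4$n_segments, 3)
})

test_that("preprocess_recording cleans a synthetic recording end to end", {
  seqs <- generate_target_sequence(8, seed = 21)
  sc <- synthetic_scenario(seed = 21)
  rec <- generate_recording(seqs, sc)
  gt <- attr(rec, "ground_truth")
  cfg <- pipeline_config(fixed_window = c(192, 691))
  pp <- preprocess_recording(rec, cfg)
  expect_equal(dim(pp$offsets), c(7, 500))    # last trial dropped by the shift
  expect_equal(pp$window, c(192, 691))
  expect_true(pp$latency >= 192 && pp$latency <= 316)
  expect_true(all(pp$trials$included))
  # offsets in the analysis window are small (near the planted 0.7 degrees)
  expect_lt(max(pp$offsets, na.rm = TRUE), 2)
  expect_gt(mean(pp$offsets, na.rm = TRUE), 0.2)
})

test_that("saccade cleaning removes planted saccades, sparing fixation", {
  # calibration over seeds: >= 95% of planted saccade samples removed,
  # <= 2% of fixation samples falsely removed
  for (s in 1:3) {
    seqs <- generate_target_sequence(8, seed = 30 + s)
    sc <- synthetic_scenario(seed = 30 + s)
    rec <- generate_recording(seqs, sc)
    gt <- attr(rec, "ground_truth")
    lat <- estimate_latency(rec)
    shifted <- shift_gaze(rec, lat)
    cfg <- pipeline_config()
    vel <- compute_velocity(shifted, cfg$sg_order, cfg$sg_window)
    fixvelt <- fixation_velocity_threshold(vel)
    cleaned <- remove_blink_saccades(shifted, vel, fixvelt)
    cleaned <- remove_saccades_velocity(cleaned, vel)
    cleaned <- remove_saccades_quadratic(cleaned)
    n <- cleaned$n_samples
    # map ground truth (raw indices) to shifted indices: raw i -> i - lat
    sacc <- rep(FALSE, length(rec$gx))
    for (sp in gt$saccades) sacc[sp["start"]:sp["end"]] <- TRUE
    sacc_sh <- sacc[(1:n) + lat]
    removed <- is.na(cleaned$gx)
    # fixation reference: labelled samples (NA labels = transition/saccade)
    fix_sh <- !is.na(attr(rec, "ground_truth")$labels[(1:n) + lat])
    expect_gte(mean(removed[sacc_sh]), 0.95)
    expect_lte(mean(removed[fix_sh]), 0.02)
  }
})
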