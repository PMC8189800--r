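# Preprocessing chain for random-saccade-task recordings:
#   step 1  remove average saccade latency (global per-recording shift)
#   step 2  remove blink saccades (NaN-block flanks, FixVelT march)
#   step 3  remove saccades by velocity (55 deg/s peaks, 30 deg/s minima)
#   step 4  remove residual saccade pieces by sliding quadratic regression
#   step 5  remove post-anticipatory-saccade plateaus
# followed by analysis-window selection and per-fixation inclusion rules.
# Cleaning only ever turns samples into NaN; retained values are untouched.

na_runs <- function(isna) {
  # maximal runs of TRUE; returns matrix with columns start, end (possibly 0 rows)
  r <- rle(isna)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Estimate the average saccade latency of a recording
#'
#' Searches integer shifts of 1..\code{max_shift} samples, advancing the gaze
#' signal relative to the target, and returns the shift minimizing the mean
#' angular offset (NaNs ignored). Ties go to the smallest shift.
#'
#' @param rec A \code{gaze_recording}.
#' @param max_shift Largest shift searched, samples (default 800).
#' @return Integer shift in samples (= ms at 1000 Hz).
#' @export
estimate_latency <- function(rec, max_shift = 800) {
  stopifnot(inherits(rec, "gaze_recording"))
  n <- rec$n_samples
  if (n <= max_shift + 1) stop("recording too short for the latency search")
  if (all(is.na(rec$gx))) stop("all gaze samples are NaN")
  vg <- to_direction(rec$gx, rec$gy)
  vt <- to_direction(rec$tx, rec$ty)
  best <- Inf; best_s <- NA_integer_
  for (s in seq_len(max_shift)) {
    i <- seq_len(n - s)
    d <- vg[i + s, 1] * vt[i, 1] + vg[i + s, 2] * vt[i, 2] +
         vg[i + s, 3] * vt[i, 3]
    m <- mean(acos(pmin(1, pmax(-1, d))), na.rm = TRUE) * 180 / pi
    if (!is.nan(m) && m < best - 1e-12) { best <- m; best_s <- s }
  }
  best_s
}

#' Apply a latency shift to a recording
#'
#' Gaze is advanced by \code{shift} samples so gaze and target align; the
#' recording is truncated by \code{shift} samples at the end (the final,
#' shortened fixation is dropped downstream).
#'
#' @param rec A \code{gaze_recording}.
#' @param shift Shift in samples, from \code{\link{estimate_latency}}.
#' @return A shorter \code{gaze_recording}.
#' @export
shift_gaze <- function(rec, shift) {
  stopifnot(shift >= 1, shift < rec$n_samples)
  n <- rec$n_samples
  i <- seq_len(n - shift)
  gaze_recording(time = rec$time[i], gx = rec$gx[i + shift],
                 gy = rec$gy[i + shift], tx = rec$tx[i], ty = rec$ty[i],
                 fs = rec$fs, meta = rec$meta)
}

#' Mean angular offset per within-trial sample across fixations
#'
#' Fixations containing any NaN, or any sample with offset above 60 degrees,
#' are excluded from the average.
#'
#' @param offset_mat Matrix of angular offsets, one row per fixation, one
#'   column per within-trial sample.
#' @return Numeric curve of length \code{ncol(offset_mat)} with attribute
#'   \code{"n_contributing"}.
#' @export
mean_offset_curve <- function(offset_mat) {
  ok <- apply(offset_mat, 1, function(r) !anyNA(r) && all(r <= 60))
  if (!any(ok)) stop("no fixations contribute to the mean offset curve")
  curve <- colMeans(offset_mat[ok, , drop = FALSE])
  attr(curve, "n_contributing") <- sum(ok)
  curve
}

#' Select the analysis window with the lowest mean offset
#'
#' @param curve Per-sample mean offset curve.
#' @param width Window width in samples (default 500).
#' @return \code{c(start, end)}, 1-based inclusive; ties go to the earliest
#'   start.
#' @export
select_analysis_window <- function(curve, width = 500) {
  n <- length(curve)
  if (n < width) stop("curve shorter than the window width")
  cs <- c(0, cumsum(curve))
  sums <- cs[(width + 1):(n + 1)] - cs[1:(n - width + 1)]
  s <- which.min(sums)  # which.min takes the first minimum: earliest start
  c(start = s, end = s + width - 1)
}

#' Savitzky-Golay velocity of a recording
#'
#' Centered (delay-free) smoothed first derivative of each position channel,
#' scaled to deg/s, computed independently on each contiguous non-NaN
#' segment. Segments shorter than the filter window get NaN velocity.
#'
#' @param rec A \code{gaze_recording}.
#' @param order Polynomial order (default 2).
#' @param window Filter length in samples, odd (default 7).
#' @return List with \code{vx}, \code{vy}, \code{radial} (deg/s), NaN where
#'   position is NaN.
#' @export
compute_velocity <- function(rec, order = 2, window = 7) {
  n <- rec$n_samples
  if (n < window) stop("recording shorter than the filter window")
  deriv_chan <- function(x) {
    v <- rep(NA_real_, n)
    runs <- na_runs(!is.na(x))
    if (nrow(runs)) {
      for (r in seq_len(nrow(runs))) {
        i <- runs[r, 1]:runs[r, 2]
        if (length(i) >= window) {
          v[i] <- signal::sgolayfilt(x[i], p = order, n = window, m = 1,
                                     ts = 1 / rec$fs)
        }
      }
    }
    v
  }
  vx <- deriv_chan(rec$gx)
  vy <- deriv_chan(rec$gy)
  list(vx = vx, vy = vy, radial = sqrt(vx^2 + vy^2))
}

#' Per-recording fixation velocity threshold (FixVelT)
#'
#' Stretches of radial velocity whose peak exceeds
#' \code{saccade_peak_velocity} are removed; remaining contiguous blocks
#' shorter than \code{min_block_ms} are rejected; the first and last
#' \code{skip} samples of surviving blocks are skipped; FixVelT is the
#' \code{percentile} of the pooled remaining radial velocity.
#'
#' @param vel Velocity list from \code{\link{compute_velocity}}.
#' @param saccade_peak_velocity deg/s (default 55).
#' @param min_block_ms Minimum block length, ms (default 40).
#' @param skip Samples skipped at block ends (default 4).
#' @param percentile Pooled percentile (default 0.9).
#' @param fs Sampling rate, Hz.
#' @return FixVelT in deg/s.
#' @export
fixation_velocity_threshold <- function(vel, saccade_peak_velocity = 55,
                                        min_block_ms = 40, skip = 4,
                                        percentile = 0.9, fs = 1000) {
  rad <- vel$radial
  keep <- !is.na(rad) & rad <= saccade_peak_velocity
  runs <- na_runs(keep)
  min_len <- round(min_block_ms * fs / 1000)
  pooled <- numeric(0)
  if (nrow(runs)) {
    for (r in seq_len(nrow(runs))) {
      len <- runs[r, 2] - runs[r, 1] + 1
      if (len < min_len) next
      i <- (runs[r, 1] + skip):(runs[r, 2] - skip)
      if (length(i)) pooled <- c(pooled, rad[i])
    }
  }
  if (!length(pooled)) stop("no fixation samples survive for FixVelT")
  unname(stats::quantile(pooled, percentile, type = 7))
}

#' Remove blink saccades around NaN blocks
#'
#' For each NaN block: starting at the last good sample before the block,
#' march backward until three contiguous samples are below FixVelT; the
#' sample of the three closest to the block marks the end of the prior
#' fixation. Mirror forward after the block. Samples strictly between the two
#' marks (the blink-saccade flanks) are set to NaN. At recording boundaries,
#' or when no qualifying triple exists, the whole stretch to the boundary is
#' removed.
#'
#' @param rec A \code{gaze_recording}.
#' @param vel Velocity list (computed on \code{rec}).
#' @param fixvelt FixVelT, deg/s.
#' @return The recording with blink-saccade samples set to NaN.
#' @export
remove_blink_saccades <- function(rec, vel, fixvelt) {
  gx <- rec$gx; gy <- rec$gy
  rad <- vel$radial
  n <- rec$n_samples
  blocks <- na_runs(is.na(rec$gx) | is.na(rec$gy))
  if (nrow(blocks)) {
    for (b in seq_len(nrow(blocks))) {
      b0 <- blocks[b, 1]; b1 <- blocks[b, 2]
      if (b0 > 1) {
        # backward: triples (i-2, i-1, i), i moving away from the block
        mark <- NA_integer_
        if (b0 - 1 >= 3) {
          for (i in (b0 - 1):3) {
            if (all(!is.na(rad[(i - 2):i])) && all(rad[(i - 2):i] < fixvelt)) {
              mark <- i; break
            }
          }
        }
        rmv <- if (is.na(mark)) 1:(b0 - 1) else
          if (mark + 1 <= b0 - 1) (mark + 1):(b0 - 1) else integer(0)
        gx[rmv] <- NA; gy[rmv] <- NA
      }
      if (b1 < n) {
        mark <- NA_integer_
        if (b1 + 1 <= n - 2) {
          for (i in (b1 + 1):(n - 2)) {
            if (all(!is.na(rad[i:(i + 2)])) && all(rad[i:(i + 2)] < fixvelt)) {
              mark <- i; break
            }
          }
        }
        rmv <- if (is.na(mark)) (b1 + 1):n else
          if (b1 + 1 <= mark - 1) (b1 + 1):(mark - 1) else integer(0)
        gx[rmv] <- NA; gy[rmv] <- NA
      }
    }
  }
  gaze_recording(rec$time, gx, gy, rec$tx, rec$ty, rec$fs, rec$meta)
}

#' Remove saccades by peak velocity (step 1)
#'
#' Every block of radial velocity above \code{peak} deg/s is expanded
#' backward and forward to the nearest local minimum below \code{offset_v}
#' deg/s; the expanded span (minima included) is set to NaN. Recording and
#' NaN boundaries count as terminating minima.
#'
#' @param rec A \code{gaze_recording}.
#' @param vel Velocity list.
#' @param peak Peak threshold, deg/s (default 55).
#' @param offset_v Onset/offset threshold, deg/s (default 30).
#' @return The recording with saccade spans set to NaN.
#' @export
remove_saccades_velocity <- function(rec, vel, peak = 55, offset_v = 30) {
  rad <- vel$radial
  n <- rec$n_samples
  gx <- rec$gx; gy <- rec$gy
  is_min <- function(i) {
    lo <- if (i > 1) !is.na(rad[i - 1]) else FALSE
    hi <- if (i < n) !is.na(rad[i + 1]) else FALSE
    (!lo || rad[i] <= rad[i - 1]) && (!hi || rad[i] <= rad[i + 1])
  }
  blocks <- na_runs(!is.na(rad) & rad > peak)
  if (nrow(blocks)) {
    for (b in seq_len(nrow(blocks))) {
      s <- blocks[b, 1]; e <- blocks[b, 2]
      i <- s - 1
      while (i >= 1 && !is.na(rad[i]) && !(rad[i] < offset_v && is_min(i))) {
        i <- i - 1
      }
      start <- max(1, i)
      if (i >= 1 && is.na(rad[i])) start <- i + 1
      j <- e + 1
      while (j <= n && !is.na(rad[j]) && !(rad[j] < offset_v && is_min(j))) {
        j <- j + 1
      }
      end <- min(n, j)
      if (j <= n && is.na(rad[j])) end <- j - 1
      gx[start:end] <- NA; gy[start:end] <- NA
    }
  }
  gaze_recording(rec$time, gx, gy, rec$tx, rec$ty, rec$fs, rec$meta)
}

# Sliding quadratic regression of one channel: returns logical flag per
# window start (window i .. i+window-1). Windows containing NaN are never
# flagged.
quad_flags <- function(y, window = 27, r2_min = 0.6, beta_min = 0.55) {
  n <- length(y)
  if (n < window) stop("signal shorter than the quadratic-detector window")
  x <- (seq_len(window))^2
  sx <- sum(x); sxx_c <- sum(x^2) - sx^2 / window
  w1 <- rep(1, window)
  roll <- function(v, f) {
    r <- stats::filter(v, f, method = "convolution", sides = 1)
    as.numeric(r)[window:n]
  }
  sy <- roll(y, w1)
  syy <- roll(y^2, w1)
  sxy <- roll(y, rev(x))
  beta <- (sxy - sx * sy / window) / sxx_c
  sst <- syy - sy^2 / window
  r2 <- ifelse(sst > 0, beta^2 * sxx_c / sst, 0)
  flag <- !is.na(r2) & !is.na(beta) & r2 > r2_min & abs(beta) * 1000 > beta_min
  flag
}

#' Remove residual saccade pieces by sliding quadratic regression (step 2)
#'
#' In every 27-sample window, each position channel is regressed on the
#' squared within-window sample index (1^2 .. 27^2, i.e. 1 .. 729) with an
#' intercept. Windows with r-squared above \code{r2_min} and |beta| x 1000
#' above \code{beta_min} contain parabolic (saccade-like) structure; the
#' union of all flagged windows, across both channels, is set to NaN.
#'
#' @param rec A \code{gaze_recording}.
#' @param window Window length, odd (default 27, centered at sample 14).
#' @param r2_min r-squared gate (default 0.6).
#' @param beta_min |beta| x 1000 gate (default 0.55).
#' @return The recording with flagged windows set to NaN.
#' @export
remove_saccades_quadratic <- function(rec, window = 27, r2_min = 0.6,
                                      beta_min = 0.55) {
  n <- rec$n_samples
  fx <- quad_flags(rec$gx, window, r2_min, beta_min)
  fy <- quad_flags(rec$gy, window, r2_min, beta_min)
  flag <- fx | fy
  bad <- rep(FALSE, n)
  starts <- which(flag)
  for (s in starts) bad[s:(s + window - 1)] <- TRUE
  gx <- rec$gx; gy <- rec$gy
  gx[bad] <- NA; gy[bad] <- NA
  gaze_recording(rec$time, gx, gy, rec$tx, rec$ty, rec$fs, rec$meta)
}

#' Remove post-anticipatory-saccade plateaus (step 5)
#'
#' Within each fixation trial, contiguous runs where the absolute horizontal
#' or vertical offset from target exceeds \code{threshold} degrees are
#' candidate post-AS fixations. Runs shorter than \code{min_ms} are ignored;
#' runs at least \code{min_ms} long that overlap the analysis window (even
#' partially) are set to NaN. Run starts are logged.
#'
#' @param rec A latency-shifted \code{gaze_recording}.
#' @param trial_length Samples per fixation trial (default 1000).
#' @param analysis_window \code{c(start, end)} within-trial, 1-based inclusive.
#' @param threshold Per-channel offset threshold, degrees (default 2).
#' @param min_ms Minimum run length, ms (default 100).
#' @return List: \code{rec} (cleaned recording) and \code{as_log}
#'   (data.frame with \code{trial}, \code{start} of each removed run,
#'   within-trial samples).
#' @export
remove_anticipatory <- function(rec, trial_length = 1000,
                                analysis_window = c(192, 691),
                                threshold = 2, min_ms = 100) {
  n <- rec$n_samples
  n_trials <- n %/% trial_length
  gx <- rec$gx; gy <- rec$gy
  min_len <- round(min_ms * rec$fs / 1000)
  log_tr <- integer(0); log_st <- integer(0)
  for (t in seq_len(n_trials)) {
    i0 <- (t - 1) * trial_length
    idx <- (i0 + 1):(i0 + trial_length)
    hx <- abs(gx[idx] - rec$tx[idx])
    hy <- abs(gy[idx] - rec$ty[idx])
    over <- !is.na(hx) & !is.na(hy) & (hx > threshold | hy > threshold)
    runs <- na_runs(over)
    if (!nrow(runs)) next
    for (r in seq_len(nrow(runs))) {
      len <- runs[r, 2] - runs[r, 1] + 1
      if (len < min_len) next
      if (runs[r, 2] < analysis_window[1] || runs[r, 1] > analysis_window[2]) {
        next
      }
      rmv <- i0 + (runs[r, 1]:runs[r, 2])
      gx[rmv] <- NA; gy[rmv] <- NA
      log_tr <- c(log_tr, t); log_st <- c(log_st, runs[r, 1])
    }
  }
  list(rec = gaze_recording(rec$time, gx, gy, rec$tx, rec$ty, rec$fs,
                            rec$meta),
       as_log = data.frame(trial = log_tr, start = log_st))
}

#' Segment counts and inclusion flag for one fixation's analysis window
#'
#' @param offsets Angular offsets of the analysis window (NaN-masked).
#' @param min_valid Minimum valid samples (default 400).
#' @param max_nan_blocks Maximum blocks of contiguous NaNs (default 4).
#' @return List: \code{n_valid}, \code{n_nan_blocks}, \code{n_segments}
#'   (maximal contiguous non-NaN runs), \code{included}.
#' @export
segment_and_include <- function(offsets, min_valid = 400, max_nan_blocks = 4) {
  isna <- is.na(offsets)
  n_valid <- sum(!isna)
  n_nan_blocks <- nrow(na_runs(isna))
  n_segments <- nrow(na_runs(!isna))
  list(n_valid = n_valid, n_nan_blocks = n_nan_blocks,
       n_segments = n_segments,
       included = n_valid >= min_valid && n_nan_blocks <= max_nan_blocks)
}

#' Preprocess one recording through the full cleaning chain
#'
#' Steps, in order: latency shift; blink-saccade removal; velocity-based
#' saccade removal; quadratic-window removal; anticipatory-saccade removal;
#' then per-trial windowing and inclusion. The last (shift-truncated)
#' fixation is dropped.
#'
#' @param rec A raw \code{gaze_recording}.
#' @param cfg A \code{\link{pipeline_config}}.
#' @param analysis_window \code{c(start, end)} within-trial; \code{NULL} uses
#'   \code{cfg$fixed_window}, or, failing that, recomputes the window from
#'   this recording's own mean offset curve.
#' @param trial_length Samples per trial (default 1000).
#' @param latency Optional precomputed latency shift (samples); estimated
#'   when \code{NULL}.
#' @return List: \code{trials} (data.frame: trial, n_valid, n_nan_blocks,
#'   n_segments, included), \code{offsets} (matrix, one row per trial,
#'   analysis-window columns), \code{latency}, \code{fixvelt},
#'   \code{window}, \code{as_log}.
#' @export
preprocess_recording <- function(rec, cfg = pipeline_config(),
                                 analysis_window = NULL,
                                 trial_length = 1000, latency = NULL) {
  lat <- if (is.null(latency)) estimate_latency(rec, cfg$max_shift) else
    as.integer(latency)
  shifted <- shift_gaze(rec, lat)
  n_trials <- shifted$n_samples %/% trial_length

  if (is.null(analysis_window)) {
    if (!is.null(cfg$fixed_window)) {
      analysis_window <- cfg$fixed_window
    } else {
      raw_off <- offset_series(shifted)
      om <- matrix(raw_off[seq_len(n_trials * trial_length)],
                   nrow = n_trials, byrow = TRUE)
      analysis_window <- select_analysis_window(mean_offset_curve(om),
                                                cfg$window_width)
    }
  }

  vel <- compute_velocity(shifted, cfg$sg_order, cfg$sg_window)
  fixvelt <- fixation_velocity_threshold(
    vel, cfg$saccade_peak_velocity, cfg$min_fix_block_ms,
    cfg$fix_block_skip, cfg$fixvelt_percentile, shifted$fs)
  cleaned <- remove_blink_saccades(shifted, vel, fixvelt)
  cleaned <- remove_saccades_velocity(cleaned, vel,
                                      cfg$saccade_peak_velocity,
                                      cfg$saccade_offset_velocity)
  cleaned <- remove_saccades_quadratic(cleaned, cfg$quad_window,
                                       cfg$quad_r2, cfg$quad_beta)
  asr <- remove_anticipatory(cleaned, trial_length, analysis_window,
                             cfg$as_threshold, cfg$as_min_ms)
  cleaned <- asr$rec

  off <- offset_series(cleaned)
  w <- analysis_window[1]:analysis_window[2]
  offmat <- matrix(NA_real_, n_trials, length(w))
  stats_l <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    offmat[t, ] <- off[(t - 1) * trial_length + w]
    stats_l[[t]] <- segment_and_include(offmat[t, ], cfg$min_valid,
                                        cfg$max_nan_blocks)
  }
  trials <- data.frame(
    trial = seq_len(n_trials),
    n_valid = vapply(stats_l, `[[`, 0L, "n_valid"),
    n_nan_blocks = vapply(stats_l, `[[`, 0L, "n_nan_blocks"),
    n_segments = vapply(stats_l, `[[`, 0L, "n_segments"),
    included = vapply(stats_l, `[[`, FALSE, "included")
  )
  list(trials = trials, offsets = offmat, latency = lat, fixvelt = fixvelt,
       window = analysis_window, as_log = asr$as_log)
}
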