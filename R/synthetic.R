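# Seeded synthetic random-saccade-task generator. Emulates the task geometry
# (targets uniform over +/-15 x +/-9 degrees, >= 2 degree steps, 1 s dwell),
# per-trial saccade latency, minimum-jerk saccades, blinks as NaN blocks with
# blink-saccade transients, anticipatory saccades with a hazard that grows
# over the task, fixation noise, sinusoidal drift, and (optionally)
# within-fixation multimodal offset structure — with full ground truth, so
# every downstream stage is testable without recorded data.

#' Generate a random target sequence
#'
#' Target positions are drawn uniformly over the rectangle
#' \code{[-ranges[1], ranges[1]] x [-ranges[2], ranges[2]]}, rejection-sampled
#' so consecutive targets are at least \code{min_step} degrees apart.
#'
#' @param n_targets Number of targets (>= 1).
#' @param ranges Half-ranges \code{c(x, y)} in degrees (default \code{c(15, 9)}).
#' @param min_step Minimum Euclidean displacement between consecutive targets,
#'   degrees (default 2).
#' @param dwell_ms Dwell per target, milliseconds (default 1000).
#' @param seed Integer seed.
#' @return A \code{target_sequence}: list with \code{positions} (n x 2 matrix),
#'   \code{dwell_ms}, \code{n_targets}.
#' @export
generate_target_sequence <- function(n_targets, ranges = c(15, 9),
                                     min_step = 2, dwell_ms = 1000,
                                     seed = 1) {
  stopifnot(n_targets >= 1, length(ranges) == 2, all(ranges > 0))
  if (min_step >= sqrt(sum((2 * ranges)^2))) {
    stop("min_step exceeds the diagonal of the target range: infeasible")
  }
  pos <- with_seed(seed, {
    out <- matrix(NA_real_, n_targets, 2)
    out[1, ] <- c(runif(1, -ranges[1], ranges[1]),
                  runif(1, -ranges[2], ranges[2]))
    if (n_targets > 1) {
      for (i in 2:n_targets) {
        repeat {
          cand <- c(runif(1, -ranges[1], ranges[1]),
                    runif(1, -ranges[2], ranges[2]))
          if (sqrt(sum((cand - out[i - 1, ])^2)) >= min_step) break
        }
        out[i, ] <- cand
      }
    }
    out
  })
  structure(list(positions = pos, dwell_ms = dwell_ms, n_targets = n_targets,
                 ranges = ranges, min_step = min_step, seed = seed),
            class = "target_sequence")
}

#' Synthetic recording scenario
#'
#' Bundles every knob of the generator. Defaults emulate the study
#' conditions: saccade latency N(237, 17) ms truncated to [192, 316], 1000 Hz
#' sampling, quiet fixation noise, and a single near-target offset component.
#'
#' @param seed Master seed for the scenario.
#' @param latency_mean,latency_sd,latency_min,latency_max Per-trial saccade
#'   latency distribution, ms (normal, truncated).
#' @param fixation_noise_sd White positional noise during the whole
#'   recording, degrees.
#' @param components List with \code{means}, \code{sds}, \code{weights}:
#'   Gaussian-mixture spec for the per-fixation offset magnitude (degrees,
#'   truncated at 0). Weights must sum to 1.
#' @param drift_amplitude Amplitude of a sinusoidal within-fixation drift of
#'   the offset magnitude, degrees (0 disables).
#' @param drift_freq_hz Drift frequency, Hz.
#' @param blink_rate Blink hazard, events per second (0 disables).
#' @param anticipatory_hazard_slope Per-trial increase in the probability of
#'   an anticipatory saccade; trial t has AS probability
#'   \code{min(1, slope * t)}.
#' @param saccade_ms_per_deg,saccade_min_ms Main-sequence duration rule:
#'   duration = \code{saccade_min_ms + saccade_ms_per_deg * amplitude}.
#' @return A validated \code{synthetic_scenario} list.
#' @export
synthetic_scenario <- function(seed = 1,
                               latency_mean = 237, latency_sd = 17,
                               latency_min = 192, latency_max = 316,
                               fixation_noise_sd = 0.05,
                               components = list(means = 0.7, sds = 0.15,
                                                 weights = 1),
                               drift_amplitude = 0, drift_freq_hz = 1.95,
                               blink_rate = 0,
                               anticipatory_hazard_slope = 0,
                               saccade_ms_per_deg = 2.2, saccade_min_ms = 21) {
  stopifnot(latency_sd >= 0, latency_min <= latency_mean,
            latency_mean <= latency_max,
            fixation_noise_sd >= 0, drift_amplitude >= 0, drift_freq_hz > 0,
            blink_rate >= 0, anticipatory_hazard_slope >= 0)
  validate_mixture(components, allow_zero_sd = TRUE)
  structure(as.list(environment()), class = "synthetic_scenario")
}

validate_mixture <- function(components, allow_zero_sd = FALSE) {
  m <- components$means; s <- components$sds; w <- components$weights
  if (is.null(m) || is.null(s) || is.null(w) ||
      length(m) != length(s) || length(m) != length(w) || length(m) < 1) {
    stop("mixture spec needs equal-length means, sds, weights")
  }
  if (abs(sum(w) - 1) > 1e-9) stop("mixture weights must sum to 1")
  if (any(w < 0)) stop("mixture weights must be nonnegative")
  if (any(s < 0) || (!allow_zero_sd && any(s <= 0))) {
    stop("mixture sds must be positive")
  }
  invisible(TRUE)
}

# Minimum-jerk displacement profile on [0, 1].
min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# Truncated-at-zero normal draws (offsets are distances); mean/sd recycled.
rnorm_trunc0 <- function(n, mean, sd) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  x <- ifelse(sd == 0, mean, rnorm(n, mean, sd))
  while (any(bad <- x < 0)) {
    x[bad] <- ifelse(sd[bad] == 0, mean[bad], rnorm(sum(bad), mean[bad], sd[bad]))
  }
  x
}

#' Draw i.i.d. offsets from a Gaussian mixture truncated at zero
#'
#' Unit-test input for the multimodality machinery: angular offsets are
#' distances, hence nonnegative; negative mixture draws are resampled.
#'
#' @param components List with \code{means}, \code{sds}, \code{weights}.
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of length \code{n} (degrees).
#' @export
generate_offset_sample <- function(components, n, seed = 1) {
  validate_mixture(components)
  if (n < 1) stop("n must be >= 1")
  with_seed(seed, {
    lab <- sample.int(length(components$weights), n, replace = TRUE,
                      prob = components$weights)
    rnorm_trunc0(n, components$means[lab], components$sds[lab])
  })
}

#' Generate a synthetic gaze recording with ground truth
#'
#' The gaze trace follows the target with a per-trial latency; saccades have
#' minimum-jerk position profiles (peak radial velocity exceeds 55 deg/s for
#' amplitudes of 2 degrees and above under the default duration rule);
#' fixation position sits at target plus a mixture-sampled offset, white
#' noise, and an optional sinusoidal drift; blinks are NaN blocks flanked by
#' fast transients; anticipatory saccades move gaze to the next target before
#' the jump with a hazard increasing over trials.
#'
#' Within a trial, a multi-component offset spec is realised as contiguous
#' blocks (one per component, lengths proportional to the weights, joined by
#' 60 ms smooth ramps), so the within-fixation offset distribution is the
#' requested mixture.
#'
#' @param seq A \code{target_sequence}.
#' @param scenario A \code{synthetic_scenario}.
#' @param subject,session Integer tags; combined with \code{scenario$seed}
#'   into the recording's private RNG stream.
#' @return A \code{gaze_recording} with attribute \code{"ground_truth"}: list
#'   with per-trial latency (ms), saccade sample spans, per-sample component
#'   labels (NA outside fixation), blink spans, and anticipatory-saccade
#'   events (trial, start sample).
#' @export
generate_recording <- function(seq, scenario, subject = 1, session = 1) {
  stopifnot(inherits(seq, "target_sequence"),
            inherits(scenario, "synthetic_scenario"))
  sc <- scenario
  fs <- 1000
  dwell <- seq$dwell_ms
  nt <- seq$n_targets
  n <- nt * dwell
  pos <- seq$positions
  rec_seed <- derive_seed(sc$seed, subject, session)

  with_seed(rec_seed, {
    tx <- rep(pos[, 1], each = dwell)
    ty <- rep(pos[, 2], each = dwell)
    gx <- numeric(n); gy <- numeric(n)
    labels <- rep(NA_integer_, n)
    truth <- list(latency_ms = numeric(nt), saccades = list(),
                  blinks = list(), anticipatory = list())

    k <- length(sc$components$weights)
    # per-trial fixation offset geometry: direction + per-component magnitudes
    trial_theta <- runif(nt, 0, 2 * pi)
    trial_mag <- matrix(0, nt, k)
    for (c_i in seq_len(k)) {
      trial_mag[, c_i] <- rnorm_trunc0(nt, sc$components$means[c_i],
                                       sc$components$sds[c_i])
    }
    drift_phase <- runif(nt, 0, 2 * pi)

    lat <- if (sc$latency_sd == 0) rep(sc$latency_mean, nt) else {
      l <- rnorm(nt, sc$latency_mean, sc$latency_sd)
      while (any(bad <- l < sc$latency_min | l > sc$latency_max)) {
        l[bad] <- rnorm(sum(bad), sc$latency_mean, sc$latency_sd)
      }
      l
    }
    lat <- round(lat)
    truth$latency_ms <- lat

    # fixation-position curve for trial t at within-trial sample j (1..dwell):
    # target + offset along trial direction; offset magnitude steps through the
    # mixture components in contiguous blocks, with smooth 60 ms ramps.
    ramp_len <- 60
    fix_curve <- function(t, idx) {
      w <- sc$components$weights
      bnd <- round(cumsum(w) * dwell)   # block ends within trial
      mag <- numeric(length(idx))
      start <- 1
      for (c_i in seq_len(k)) {
        seg <- idx >= start & idx <= bnd[c_i]
        mag[seg] <- trial_mag[t, c_i]
        labels[(t - 1) * dwell + idx[seg]] <<- c_i
        if (c_i < k) {
          # ramp into next block
          r0 <- bnd[c_i] - ramp_len %/% 2
          r1 <- bnd[c_i] + ramp_len %/% 2
          rseg <- idx >= r0 & idx <= r1
          tau <- (idx[rseg] - r0) / (r1 - r0)
          mag[rseg] <- trial_mag[t, c_i] +
            min_jerk(tau) * (trial_mag[t, c_i + 1] - trial_mag[t, c_i])
          labels[(t - 1) * dwell + idx[rseg]] <<- NA_integer_
        }
        start <- bnd[c_i] + 1
      }
      if (sc$drift_amplitude > 0) {
        mag <- mag + sc$drift_amplitude *
          sin(2 * pi * sc$drift_freq_hz * idx / fs + drift_phase[t])
      }
      cbind(pos[t, 1] + mag * cos(trial_theta[t]),
            pos[t, 2] + mag * sin(trial_theta[t]))
    }

    # Build gaze trial by trial: hold previous fixation until latency elapses,
    # then saccade (minimum jerk) to this trial's fixation curve.
    prev_fix <- fix_curve(1, 1L)[1, ]
    gx[] <- NA; gy[] <- NA
    as_pending <- FALSE  # gaze already parked at this trial's target by an AS
    for (t in seq_len(nt)) {
      t0 <- (t - 1) * dwell + 1
      idx_all <- seq_len(dwell)
      fc <- fix_curve(t, idx_all)
      if (t == 1 || as_pending) {
        gx[t0:(t0 + dwell - 1)] <- fc[, 1]
        gy[t0:(t0 + dwell - 1)] <- fc[, 2]
        as_pending <- FALSE
      } else {
        # the planted latency is the target-jump-to-saccade-midpoint delay:
        # the saccade (min-jerk, hence time-symmetric) is centered on L, so
        # the cohort-level alignment shift recovers L itself
        L <- lat[t]
        amp <- sqrt(sum((fc[min(L + 1, dwell), ] - prev_fix)^2))
        dur <- max(2, round(sc$saccade_min_ms + sc$saccade_ms_per_deg * amp))
        onset <- max(1, min(L - dur %/% 2, dwell - 1))
        pre <- seq_len(onset)
        gx[t0 - 1 + pre] <- prev_fix[1]
        gy[t0 - 1 + pre] <- prev_fix[2]
        labels[t0 - 1 + pre] <- NA_integer_
        s_end <- min(onset + dur, dwell)
        sidx <- (onset + 1):s_end
        tau <- (sidx - onset) / dur
        land <- fc[min(s_end + 1, dwell), ]
        gx[t0 - 1 + sidx] <- prev_fix[1] + min_jerk(tau) * (land[1] - prev_fix[1])
        gy[t0 - 1 + sidx] <- prev_fix[2] + min_jerk(tau) * (land[2] - prev_fix[2])
        labels[t0 - 1 + sidx] <- NA_integer_
        truth$saccades[[length(truth$saccades) + 1]] <-
          c(start = t0 + onset, end = t0 - 1 + s_end)
        if (s_end < dwell) {
          fidx <- (s_end + 1):dwell
          gx[t0 - 1 + fidx] <- fc[fidx, 1]
          gy[t0 - 1 + fidx] <- fc[fidx, 2]
        }
      }
      prev_fix <- fc[dwell, ]

      # anticipatory saccade toward the NEXT target near the end of the trial
      if (t < nt && sc$anticipatory_hazard_slope > 0 &&
          runif(1) < min(1, sc$anticipatory_hazard_slope * t)) {
        as_start <- t0 - 1 + sample(seq(dwell - 300, dwell - 150), 1)
        nxt <- fix_curve(t + 1, 1L)[1, ]
        cur <- c(gx[as_start], gy[as_start])
        amp <- sqrt(sum((nxt - cur)^2))
        dur <- max(2, round(sc$saccade_min_ms + sc$saccade_ms_per_deg * amp))
        s_end <- min(as_start + dur, t0 - 1 + dwell)
        tau <- (seq(as_start + 1, s_end) - as_start) / dur
        gx[(as_start + 1):s_end] <- cur[1] + min_jerk(tau) * (nxt[1] - cur[1])
        gy[(as_start + 1):s_end] <- cur[2] + min_jerk(tau) * (nxt[2] - cur[2])
        if (s_end < t0 - 1 + dwell) {
          gx[(s_end + 1):(t0 - 1 + dwell)] <- nxt[1]
          gy[(s_end + 1):(t0 - 1 + dwell)] <- nxt[2]
        }
        labels[(as_start + 1):(t0 - 1 + dwell)] <- NA_integer_
        truth$saccades[[length(truth$saccades) + 1]] <-
          c(start = as_start + 1, end = s_end)
        truth$anticipatory[[length(truth$anticipatory) + 1]] <-
          c(trial = t, start = as_start + 1)
        prev_fix <- nxt
        as_pending <- TRUE
      }
    }

    if (sc$fixation_noise_sd > 0) {
      gx <- gx + rnorm(n, 0, sc$fixation_noise_sd)
      gy <- gy + rnorm(n, 0, sc$fixation_noise_sd)
    }

    # blinks: NaN block flanked by +/-3..10 degree transients over ~20 ms
    if (sc$blink_rate > 0) {
      n_blinks <- rpois(1, sc$blink_rate * n / fs)
      if (n_blinks > 0) {
        for (b in seq_len(n_blinks)) {
          bdur <- sample(50:300, 1)
          bstart <- sample(seq(40, n - bdur - 40), 1)
          flank <- 20
          amp_b <- runif(1, 3, 10) * sample(c(-1, 1), 1)
          up <- (bstart - flank):(bstart - 1)
          gy[up] <- gy[up] + amp_b * min_jerk(seq_along(up) / flank)
          dn <- (bstart + bdur):(bstart + bdur + flank - 1)
          gy[dn] <- gy[dn] + amp_b * min_jerk(rev(seq_along(dn)) / flank)
          gx[bstart:(bstart + bdur - 1)] <- NA
          gy[bstart:(bstart + bdur - 1)] <- NA
          labels[(bstart - flank):(bstart + bdur + flank - 1)] <- NA_integer_
          truth$blinks[[length(truth$blinks) + 1]] <-
            c(start = bstart, end = bstart + bdur - 1)
        }
      }
    }

    truth$labels <- labels
    rec <- gaze_recording(time = seq_len(n) - 1, gx = gx, gy = gy,
                          tx = tx, ty = ty, fs = fs,
                          meta = list(subject = subject, session = session,
                                      seed = rec_seed))
    attr(rec, "ground_truth") <- truth
    rec
  })
}
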