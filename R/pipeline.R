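# End-to-end orchestration: preprocessing in the documented step order,
# inclusion rules, per-fixation multimodality / normality / accuracy / drift,
# and the cohort summary table (per-segment-count evidence percentages).

#' Run the full analysis pipeline over a cohort of recordings
#'
#' Per recording: latency shift, blink-saccade removal, velocity saccade
#' removal, quadratic-window removal, anticipatory-saccade removal, analysis
#' windowing, inclusion rules. Unless a fixed window is configured, the
#' analysis window is selected once from the cohort's pooled mean offset
#' curve. Subjects with any session having fewer than
#' \code{cfg$min_good_fixations} included fixations are excluded. Each
#' included fixation then gets a mixture fit (log Bayes factor, evidence
#' class), optionally the excess-mass test, the normality screen, the four
#' accuracy metrics, and (single-segment, full-length fixations only) the
#' drift statistic.
#'
#' @param recordings List of \code{gaze_recording} objects (carrying
#'   \code{meta$subject} and \code{meta$session}).
#' @param cfg A \code{\link{pipeline_config}}.
#' @param limits Optional precomputed \code{normality_limits}; computed from
#'   \code{cfg} when \code{NULL}.
#' @param run_acr Run the excess-mass test per fixation (default
#'   \code{TRUE}).
#' @param acr_boot Bootstrap replicates for the excess-mass test.
#' @param trial_length Samples per fixation trial (default 1000).
#' @return List: \code{fixations} (one row per fixation trial),
#'   \code{summary} (cohort summary, see \code{\link{cohort_summary}}),
#'   \code{window}, \code{latencies}, \code{exclusions} (log of excluded
#'   trials/subjects with reasons), \code{limits}.
#' @export
run_pipeline <- function(recordings, cfg = pipeline_config(), limits = NULL,
                         run_acr = TRUE, acr_boot = 200,
                         trial_length = 1000) {
  if (!length(recordings)) stop("no recordings supplied")
  stopifnot(all(vapply(recordings, inherits, logical(1), "gaze_recording")))

  lats <- vapply(recordings, estimate_latency, 0L, max_shift = cfg$max_shift)

  window <- cfg$fixed_window
  if (is.null(window)) {
    mats <- lapply(seq_along(recordings), function(i) {
      sh <- shift_gaze(recordings[[i]], lats[i])
      nt <- sh$n_samples %/% trial_length
      off <- offset_series(sh)
      matrix(off[seq_len(nt * trial_length)], nrow = nt, byrow = TRUE)
    })
    curve <- mean_offset_curve(do.call(rbind, mats))
    window <- select_analysis_window(curve, cfg$window_width)
  }

  if (is.null(limits)) {
    limits <- simulate_limits(cfg$normality_n, cfg$normality_reps,
                              seed = derive_seed(cfg$seed, 7L))
  }

  excl <- list()
  note <- function(...) excl[[length(excl) + 1]] <<- data.frame(...)

  rows <- list()
  for (ri in seq_along(recordings)) {
    rec <- recordings[[ri]]
    meta <- rec$meta
    subj <- if (!is.null(meta$subject)) meta$subject else ri
    sess <- if (!is.null(meta$session)) meta$session else 1L
    pp <- preprocess_recording(rec, cfg, analysis_window = window,
                               trial_length = trial_length, latency = lats[ri])
    for (t in seq_len(nrow(pp$trials))) {
      tr <- pp$trials[t, ]
      row <- data.frame(subject = subj, session = sess, trial = tr$trial,
                        n_valid = tr$n_valid, n_nan_blocks = tr$n_nan_blocks,
                        n_segments = tr$n_segments, included = tr$included,
                        log_bf = NA_real_, evidence = NA_character_,
                        k_modal = NA_integer_, acr_p = NA_real_,
                        classic = NA_real_, max_comp_mean = NA_real_,
                        median_acc = NA_real_, mean_acc = NA_real_,
                        normal = NA, drift_r2 = NA_real_,
                        latency = pp$latency, fixvelt = pp$fixvelt)
      if (!tr$included) {
        note(subject = subj, session = sess, trial = tr$trial,
             reason = sprintf("excluded: n_valid=%d, n_nan_blocks=%d",
                              tr$n_valid, tr$n_nan_blocks))
        rows[[length(rows) + 1]] <- row
        next
      }
      off <- pp$offsets[t, ]
      fseed <- derive_seed(cfg$seed, ri, t)
      post <- fit_rjmcmc(off, prior_spec(kmax = cfg$kmax),
                         n_iter = cfg$n_iter, burn_in = cfg$burn_in,
                         seed = fseed)
      norm_flag <- is_normal(off, limits)
      am <- accuracy_metrics(off, post, norm_flag)
      row$log_bf <- post$log_bf
      row$evidence <- as.character(post$evidence)
      row$k_modal <- post$k_modal
      row$classic <- am$classic
      row$max_comp_mean <- am$max_comp_mean
      row$median_acc <- am$median_acc
      row$mean_acc <- am$mean_acc
      row$normal <- norm_flag
      if (run_acr) {
        row$acr_p <- acr_test(off, n_boot = acr_boot,
                              seed = derive_seed(fseed, 3L))$p_value
      }
      dr <- drift_r2(off, fs = rec$fs, fft_length = cfg$fft_length,
                     segment_length = cfg$window_width)
      if (!is.null(dr)) row$drift_r2 <- dr$r2
      rows[[length(rows) + 1]] <- row
    }
  }
  fix <- do.call(rbind, rows)

  # session-level rule: drop subjects with any session under the minimum
  good <- stats::aggregate(included ~ subject + session, fix, sum)
  bad_subj <- unique(good$subject[good$included < cfg$min_good_fixations])
  if (length(bad_subj)) {
    for (s in bad_subj) {
      note(subject = s, session = NA, trial = NA,
           reason = sprintf("subject excluded: a session has < %d included fixations",
                            cfg$min_good_fixations))
    }
    fix$included[fix$subject %in% bad_subj] <- FALSE
  }

  list(fixations = fix, summary = cohort_summary(fix), window = window,
       latencies = lats,
       exclusions = if (length(excl)) do.call(rbind, excl) else NULL,
       limits = limits)
}

#' Cohort summary by number of fixation segments
#'
#' One row per segment count (1..5) plus a total row: number of included
#' fixations and the percentage in each Bayes-factor evidence class. Row
#' percentages sum to 100.
#'
#' @param fixations Per-fixation data.frame from \code{\link{run_pipeline}}.
#' @return A \code{data.frame} with columns \code{n_segments, n_fixations,
#'   pct_unimodal, pct_positive, pct_strong, pct_very_strong}.
#' @export
cohort_summary <- function(fixations) {
  f <- fixations[fixations$included & !is.na(fixations$evidence), ]
  lv <- c("unimodal", "positive", "strong", "very_strong")
  row_for <- function(sub, label) {
    n <- nrow(sub)
    p <- if (n) 100 * vapply(lv, function(l) mean(sub$evidence == l),
                             0, USE.NAMES = FALSE) else rep(NA_real_, 4)
    data.frame(n_segments = label, n_fixations = n,
               pct_unimodal = p[1], pct_positive = p[2],
               pct_strong = p[3], pct_very_strong = p[4])
  }
  out <- rbind(do.call(rbind, lapply(1:5, function(s)
    row_for(f[f$n_segments == s, ], as.character(s)))),
    row_for(f, "total"))
  rownames(out) <- NULL
  out
}

#' Histogram report with Bayes-factor infinity policy
#'
#' Before binning, +Inf values are replaced by the highest finite value in
#' the batch and -Inf by log(0.003). Returns counts and bin edges, with a
#' log10(count) variant.
#'
#' @param values Numeric vector (log Bayes factors or any metric).
#' @param breaks Passed to \code{hist} (default \code{"Sturges"}).
#' @return List: \code{values} (after sentinel replacement), \code{counts},
#'   \code{breaks}, \code{mids}, \code{log_counts}.
#' @export
histogram_report <- function(values, breaks = "Sturges") {
  v <- values
  v[v == -Inf] <- log(0.003)
  if (any(is.infinite(v))) {
    finite_max <- suppressWarnings(max(v[is.finite(v)]))
    if (!is.finite(finite_max)) stop("no finite values to anchor +Inf")
    v[v == Inf] <- finite_max
  }
  h <- graphics::hist(v[!is.na(v)], breaks = breaks, plot = FALSE)
  list(values = v, counts = h$counts, breaks = h$breaks, mids = h$mids,
       log_counts = ifelse(h$counts > 0, log10(h$counts), NA_real_))
}
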