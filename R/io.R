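# Readers/writers for the pipeline's CSV dialect: one file per
# (subject, session), long format, one row per sample, positions in degrees,
# missing samples as NaN.

#' Read a gaze recording from CSV
#'
#' @param path CSV file with per-sample columns mappable to time (ms),
#'   gaze x/y and target x/y (degrees). Missing data may be empty or any of
#'   \code{NaN}, \code{NA}, \code{nan}.
#' @param column_map Named character vector mapping canonical names
#'   \code{time, gx, gy, tx, ty} to the file's column names.
#' @param fs Sampling rate in Hz; checked against the time column.
#' @return A \code{gaze_recording}.
#' @export
read_gaze_csv <- function(path,
                          column_map = c(time = "time", gx = "gx", gy = "gy",
                                         tx = "tx", ty = "ty"),
                          fs = 1000) {
  d <- utils::read.csv(path, na.strings = c("NA", "NaN", "nan", ""))
  need <- c("time", "gx", "gy", "tx", "ty")
  miss <- setdiff(column_map[need], names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  gaze_recording(time = d[[column_map["time"]]],
                 gx = d[[column_map["gx"]]], gy = d[[column_map["gy"]]],
                 tx = d[[column_map["tx"]]], ty = d[[column_map["ty"]]],
                 fs = fs)
}

#' Write a gaze recording (and its ground truth, if present) to disk
#'
#' @param rec A \code{gaze_recording}.
#' @param path Output CSV path. If the recording carries a
#'   \code{"ground_truth"} attribute it is written as JSON next to the CSV
#'   (\code{<path>.truth.json}).
#' @return \code{path}, invisibly.
#' @export
write_gaze_csv <- function(rec, path) {
  stopifnot(inherits(rec, "gaze_recording"))
  d <- data.frame(time = rec$time, gx = rec$gx, gy = rec$gy,
                  tx = rec$tx, ty = rec$ty)
  utils::write.csv(d, path, row.names = FALSE, na = "NaN")
  gt <- attr(rec, "ground_truth")
  if (!is.null(gt)) {
    jsonlite::write_json(gt, paste0(path, ".truth.json"),
                         auto_unbox = FALSE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every threshold of the preprocessing and analysis chain, with the
#' study defaults. Units are degrees, degrees/second, milliseconds and
#' samples at 1000 Hz as noted.
#'
#' @param saccade_peak_velocity Peak radial velocity marking saccades, deg/s.
#' @param saccade_offset_velocity Local-minimum velocity ending a saccade
#'   span, deg/s.
#' @param min_fix_block_ms Minimum surviving fixation-block length used for
#'   the fixation velocity threshold, ms.
#' @param fix_block_skip Samples skipped at each end of surviving blocks.
#' @param fixvelt_percentile Percentile of pooled fixation radial velocity.
#' @param sg_order,sg_window Savitzky-Golay differentiator order and window
#'   length (samples; odd).
#' @param quad_window,quad_r2,quad_beta Sliding quadratic-detector window
#'   (samples), r-squared gate and |beta|*1000 gate.
#' @param as_threshold,as_min_ms Anticipatory-saccade offset threshold
#'   (degrees, per channel) and minimum run length (ms).
#' @param min_valid,max_nan_blocks,min_good_fixations Fixation inclusion
#'   rules: minimum valid samples in the analysis window, maximum NaN blocks,
#'   and minimum included fixations per session before a subject is dropped.
#' @param window_width Analysis-window width, samples.
#' @param fixed_window Optional fixed analysis window \code{c(start, end)}
#'   (1-based, inclusive); \code{NULL} recomputes it from the cohort's mean
#'   offset curve.
#' @param max_shift Maximum latency search shift, samples.
#' @param kmax,n_iter,burn_in Mixture fit: maximum components, retained MCMC
#'   iterations, burn-in.
#' @param fft_length Drift reconstruction transform length (zero-padded).
#' @param normality_n,normality_reps Normality-band simulation size.
#' @param seed Master seed fanned out to all randomized stages.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(saccade_peak_velocity = 55,
                            saccade_offset_velocity = 30,
                            min_fix_block_ms = 40,
                            fix_block_skip = 4,
                            fixvelt_percentile = 0.9,
                            sg_order = 2, sg_window = 7,
                            quad_window = 27, quad_r2 = 0.6, quad_beta = 0.55,
                            as_threshold = 2, as_min_ms = 100,
                            min_valid = 400, max_nan_blocks = 4,
                            min_good_fixations = 20,
                            window_width = 500,
                            fixed_window = NULL,
                            max_shift = 800,
                            kmax = 5, n_iter = 2000, burn_in = 500,
                            fft_length = 512,
                            normality_n = 500, normality_reps = 10000,
                            seed = 1) {
  cfg <- as.list(environment())
  stopifnot(all(vapply(cfg[c("saccade_peak_velocity", "saccade_offset_velocity",
                             "min_fix_block_ms", "fixvelt_percentile",
                             "sg_window", "quad_window", "quad_r2",
                             "quad_beta", "as_threshold", "as_min_ms",
                             "min_valid", "window_width", "max_shift",
                             "kmax", "n_iter", "fft_length")],
                        function(v) is.numeric(v) && v > 0, logical(1))))
  if (sg_window %% 2 == 0) stop("sg_window must be odd")
  if (quad_window %% 2 == 0) stop("quad_window must be odd")
  structure(cfg, class = "pipeline_config")
}
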