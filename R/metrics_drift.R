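# Accuracy metrics per fixation and the low-frequency drift statistic.
#
# Four accuracy measures: ClassicAccuracy (mean offset, always),
# MaxCompMean (mean of the heaviest mixture component, always),
# MedianAccuracy (median, unimodal fixations only), MeanAccuracy (mean,
# unimodal and normal fixations only).
#
# Drift: for single-segment 500-sample fixations, the offset series is
# zero-padded to a 512-point FFT; the DC bin and the two slowest nonzero bins
# (1.95 Hz and 3.91 Hz at 1000 Hz sampling) are retained and inverted; the
# offsets are regressed on this reconstruction plus a linear time term; the
# r-squared of that fit is the drift measure.

#' Accuracy metrics for one fixation
#'
#' @param offsets Analysis-window angular offsets (degrees, NaN-masked).
#' @param posterior A \code{mixture_posterior} for these offsets.
#' @param normal Logical: did the fixation pass the normality screen?
#' @return List: \code{classic} (NaN-ignoring mean), \code{max_comp_mean},
#'   \code{median_acc} (NA unless evidence is unimodal), \code{mean_acc}
#'   (NA unless unimodal and normal), \code{evidence}, \code{normal}.
#' @export
accuracy_metrics <- function(offsets, posterior, normal = FALSE) {
  v <- offsets[!is.na(offsets)]
  if (!length(v)) stop("no valid samples")
  uni <- posterior$evidence == "unimodal"
  list(classic = mean(v),
       max_comp_mean = max_weight_component(posterior$point_fit)$mean,
       median_acc = if (uni) stats::median(v) else NA_real_,
       mean_acc = if (uni && normal) mean(v) else NA_real_,
       evidence = as.character(posterior$evidence),
       normal = normal)
}

#' Low-frequency drift statistic for a single-segment fixation
#'
#' @param offsets Angular offsets; must be a single contiguous segment of
#'   exactly \code{segment_length} valid samples, else the fixation is
#'   ineligible and \code{NULL} is returned (with a message attribute absent;
#'   callers log the skip).
#' @param fs Sampling rate, Hz (default 1000).
#' @param fft_length Transform length; the series is zero-padded to it
#'   (default 512, making the two retained nonzero bins 1.95 and 3.91 Hz).
#' @param segment_length Required valid length (default 500).
#' @return A \code{drift_result}: list with \code{r2}, \code{reconstruction}
#'   (length of the offsets), \code{coefficients} (scale, linear slope,
#'   intercept); or \code{NULL} if ineligible.
#' @export
drift_r2 <- function(offsets, fs = 1000, fft_length = 512,
                     segment_length = 500) {
  ok <- !is.na(offsets)
  if (sum(ok) != segment_length || length(offsets) != segment_length ||
      !all(ok)) {
    return(NULL)
  }
  x <- offsets
  # DC is carried as the sample mean; the mean-removed series is zero-padded
  # (padding the raw series would leak the DC step into every bin)
  m <- mean(x)
  padded <- c(x - m, rep(0, fft_length - segment_length))
  X <- stats::fft(padded)
  keep <- rep(0 + 0i, fft_length)
  bins <- c(2, 3)                          # fs/512 and 2*fs/512 (1.95, 3.91 Hz)
  keep[bins] <- X[bins]
  keep[fft_length + 2 - bins] <- X[fft_length + 2 - bins]
  recon <- m + Re(stats::fft(keep, inverse = TRUE))[seq_len(segment_length)] /
    fft_length
  tt <- seq_len(segment_length)
  fit <- stats::lm(x ~ recon + tt)
  r2 <- summary(fit)$r.squared
  structure(list(r2 = r2, reconstruction = recon,
                 coefficients = c(scale = unname(stats::coef(fit)["recon"]),
                                  slope = unname(stats::coef(fit)["tt"]),
                                  intercept = unname(stats::coef(fit)[1]))),
            class = "drift_result")
}

#' Regression of multimodality on drift
#'
#' Ordinary least squares of log Bayes factor on the drift r-squared across
#' fixations.
#'
#' @param drift_r2 Numeric vector of per-fixation drift r-squared values.
#' @param log_bf Matching log Bayes factors (finite; apply sentinel
#'   replacement first, see \code{\link{histogram_report}}).
#' @return List: \code{slope}, \code{variance_explained} (r-squared),
#'   \code{p_value}, \code{n}.
#' @export
drift_vs_multimodality <- function(drift_r2, log_bf) {
  ok <- is.finite(drift_r2) & is.finite(log_bf)
  if (sum(ok) < 10) stop("need at least 10 eligible fixations")
  x <- drift_r2[ok]; ybf <- log_bf[ok]
  if (stats::var(x) == 0) stop("degenerate predictor")
  fit <- stats::lm(ybf ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       variance_explained = s$r.squared,
       p_value = s$coefficients[2, 4],
       n = sum(ok))
}
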