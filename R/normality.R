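# Simulation-based normality screen. Formal tests reject trivially at n ~ 500,
# so acceptance bands for sample skewness and kurtosis are built by resampling
# standard-normal samples of the study's fixation length; a distribution
# within both bands is treated as normal.

sample_skewness <- function(x) e1071::skewness(x, type = 1)
sample_kurtosis <- function(x) e1071::kurtosis(x, type = 1) + 3  # normal = 3

#' Simulate skewness/kurtosis acceptance bands for normal samples
#'
#' Draws \code{reps} standard-normal samples of size \code{n}, computes
#' moment-based sample skewness and (non-excess) kurtosis for each, and
#' returns the 5th and 95th empirical percentiles of each statistic.
#'
#' @param n Sample size (default 500, the plurality fixation length).
#' @param reps Number of simulated samples (default 10000).
#' @param seed Integer seed.
#' @param probs Percentile pair (default \code{c(0.05, 0.95)}).
#' @return A \code{normality_limits} list: \code{skew_lo, skew_hi, kurt_lo,
#'   kurt_hi, n, reps, seed, probs}.
#' @export
simulate_limits <- function(n = 500, reps = 10000, seed = 1,
                            probs = c(0.05, 0.95)) {
  stopifnot(n >= 10, reps >= 1000)
  sk <- numeric(reps); ku <- numeric(reps)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      x <- stats::rnorm(n)
      sk[r] <- sample_skewness(x)
      ku[r] <- sample_kurtosis(x)
    }
  })
  qs <- stats::quantile(sk, probs, type = 7)
  qk <- stats::quantile(ku, probs, type = 7)
  structure(list(skew_lo = unname(qs[1]), skew_hi = unname(qs[2]),
                 kurt_lo = unname(qk[1]), kurt_hi = unname(qk[2]),
                 n = n, reps = reps, seed = seed, probs = probs),
            class = "normality_limits")
}

#' @export
print.normality_limits <- function(x, ...) {
  cat(sprintf("<normality_limits> n=%d, reps=%d: skewness [%.4f, %.4f], kurtosis [%.4f, %.4f]\n",
              x$n, x$reps, x$skew_lo, x$skew_hi, x$kurt_lo, x$kurt_hi))
  invisible(x)
}

#' Persist / load normality limits
#'
#' @param limits A \code{normality_limits}.
#' @param path JSON file path.
#' @return \code{path} (write) or a \code{normality_limits} (read).
#' @export
write_limits <- function(limits, path) {
  jsonlite::write_json(unclass(limits), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_limits
#' @export
read_limits <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(l, class = "normality_limits")
}

#' Screen a sample against the normality bands
#'
#' @param x Offsets (degrees); NaNs dropped.
#' @param limits A \code{normality_limits}.
#' @return \code{TRUE} iff sample skewness and kurtosis both fall within the
#'   bands.
#' @export
is_normal <- function(x, limits) {
  x <- x[!is.na(x)]
  if (length(x) < 4 || stats::var(x) == 0) stop("degenerate sample")
  s <- sample_skewness(x)
  k <- sample_kurtosis(x)
  s >= limits$skew_lo && s <= limits$skew_hi &&
    k >= limits$kurt_lo && k <= limits$kurt_hi
}
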