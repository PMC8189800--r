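#' Gaze recording container
#'
#' A per-sample gaze/target time series for one session of a random-saccade
#' task. All positions are in degrees of visual angle; missing samples
#' (blinks, removed artifacts) are NA. Sampling is uniform at \code{fs} Hz.
#'
#' @param time Sample times in milliseconds (monotone increasing, uniform).
#' @param gx,gy Gaze position, degrees.
#' @param tx,ty Target position, degrees.
#' @param fs Sampling rate, Hz (default 1000).
#' @param meta Optional list of metadata (subject, session, ...).
#' @return An object of class \code{gaze_recording}: a list with the above
#'   fields plus \code{n_samples}.
#' @export
gaze_recording <- function(time, gx, gy, tx, ty, fs = 1000, meta = list()) {
  n <- length(time)
  if (!all(lengths(list(gx, gy, tx, ty)) == n)) {
    stop("time, gaze and target vectors must have equal length")
  }
  dt <- diff(time)
  if (n > 1 && (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6)) {
    stop("time must be uniformly increasing")
  }
  ok <- !is.na(gx) & !is.na(gy)
  if (any(abs(gx[ok]) >= 90) || any(abs(gy[ok]) >= 90)) {
    stop("gaze positions must be within (-90, 90) degrees")
  }
  structure(
    list(time = as.numeric(time), gx = as.numeric(gx), gy = as.numeric(gy),
         tx = as.numeric(tx), ty = as.numeric(ty), fs = fs,
         n_samples = n, meta = meta),
    class = "gaze_recording"
  )
}

#' @export
print.gaze_recording <- function(x, ...) {
  nan <- sum(is.na(x$gx) | is.na(x$gy))
  cat(sprintf("<gaze_recording> %d samples @ %g Hz (%.1f s), %d NA gaze samples\n",
              x$n_samples, x$fs, x$n_samples / x$fs, nan))
  invisible(x)
}

#' @export
length.gaze_recording <- function(x) x$n_samples

# Evaluate expr under a temporary RNG state; the caller's stream is restored.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic sub-seed derived from a master seed and integer tags,
# kept below 2^31.
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  s <- 0
  for (t in tags) s <- (s * 69069 + (t %% 2147483647) + 1) %% 2147483647
  as.integer(s)
}
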