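#' ROI time-series container
#'
#' @param data Numeric matrix, frames x ROIs.
#' @param tr_seconds Repetition time in seconds.
#' @param fd_trace Optional per-frame framewise displacement (mm).
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, tr_seconds, fd_trace = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("time series needs at least 2 frames", call. = FALSE)
  if (tr_seconds <= 0) stop("tr_seconds must be positive", call. = FALSE)
  if (!is.null(fd_trace) && length(fd_trace) != nrow(data))
    stop("fd_trace length must equal the number of frames", call. = FALSE)
  structure(list(data = data, tr_seconds = tr_seconds, fd_trace = fd_trace),
            class = "roi_timeseries")
}

#' Regress nuisance confounds out of ROI time series
#'
#' Ordinary least squares of each ROI on an intercept, a linear trend, and
#' the supplied confound columns (head-motion parameters, tissue signals,
#' their derivatives, ...); returns the residuals. Linear detrending is
#' part of the design rather than a separate pass.
#'
#' @param ts A [roi_timeseries()].
#' @param confounds Numeric matrix or data.frame, frames x k, named columns.
#' @return A `roi_timeseries` of residuals (fd trace carried through).
#' @export
regress_confounds <- function(ts, confounds) {
  X0 <- as.matrix(confounds)
  if (nrow(X0) != nrow(ts$data))
    stop("confound table length must match the time series", call. = FALSE)
  if (any(!is.finite(X0))) stop("confounds must be finite", call. = FALSE)
  n <- nrow(X0)
  design <- cbind(intercept = 1, trend = seq_len(n) - (n + 1) / 2, X0)
  q <- qr(design)
  if (q$rank < ncol(design)) {
    dropped <- colnames(design)[q$pivot[(q$rank + 1):ncol(design)]]
    stop("rank-deficient confound design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  resid <- ts$data - design %*% qr.coef(q, ts$data)
  roi_timeseries(resid, ts$tr_seconds, ts$fd_trace)
}

# --- Butterworth band-pass -------------------------------------------------
# Second-order Butterworth prototype mapped to a band-pass via the analog
# lowpass->bandpass transform, discretized with a prewarped bilinear
# transform. Returns filter coefficients (b, a).
butter_bandpass <- function(low_hz, high_hz, fs, order = 2) {
  # prewarp edges
  w1 <- 2 * fs * tan(pi * low_hz / fs)
  w2 <- 2 * fs * tan(pi * high_hz / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  # Butterworth lowpass prototype poles (cutoff 1 rad/s)
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # lowpass -> bandpass: each pole p maps to two roots of s^2 - p*bw*s + w0^2
  p_bp <- c()
  for (p in p_lp) {
    disc <- sqrt((p * bw / 2)^2 - w0^2 + 0i)
    p_bp <- c(p_bp, p * bw / 2 + disc, p * bw / 2 - disc)
  }
  z_bp <- rep(0 + 0i, order)          # 'order' zeros at s = 0
  gain <- bw^order
  # bilinear transform s = 2*fs*(z-1)/(z+1)
  fs2 <- 2 * fs
  pz <- (1 + p_bp / fs2) / (1 - p_bp / fs2)
  zz <- (1 + z_bp / fs2) / (1 - z_bp / fs2)
  # zeros at infinity map to z = -1
  zz <- c(zz, rep(-1 + 0i, length(p_bp) - length(z_bp)))
  gain_z <- Re(gain * prod(fs2 - z_bp) / prod(fs2 - p_bp))
  b <- Re(gain_z * poly_from_roots(zz))
  a <- Re(poly_from_roots(pz))
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (x in r) p <- c(p, 0) - c(0, p * x)
  p
}

# Steady-state initial filter state for a step of unit height (per unit of
# the first input sample); removes startup transients of the forward and
# backward passes.
lfilter_zi <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  n <- length(a)
  CT <- matrix(0, n - 1, n - 1)
  CT[, 1] <- -a[-1]
  if (n > 2) CT[cbind(seq_len(n - 2), seq_len(n - 2) + 1)] <- 1
  solve(diag(n - 1) - CT, b[-1] - a[-1] * b[1])
}

# Direct-form II transposed IIR filter; x may be a matrix (filtered
# column-wise in one pass). `zi` scales the steady-state initial state by
# the first sample of each column.
iir_filter <- function(b, a, x, zi = NULL) {
  x <- as.matrix(x)
  b <- b / a[1]; a <- a / a[1]
  n <- length(a)
  z <- if (is.null(zi)) matrix(0, n - 1, ncol(x))
       else zi %o% x[1, ]
  y <- x
  for (t in seq_len(nrow(x))) {
    xt <- x[t, ]
    yt <- b[1] * xt + z[1, ]
    for (k in seq_len(n - 2))
      z[k, ] <- b[k + 1] * xt + z[k + 1, ] - a[k + 1] * yt
    z[n - 1, ] <- b[n] * xt - a[n] * yt
    y[t, ] <- yt
  }
  y
}

# Zero-phase filtering: odd-reflection padding, forward pass, backward pass.
filtfilt_matrix <- function(b, a, x) {
  x <- as.matrix(x)
  npad <- 3 * (max(length(a), length(b)) - 1)
  if (nrow(x) <= npad)
    stop("time series too short for the filter (need > ", npad, " frames)",
         call. = FALSE)
  pre <- 2 * matrix(x[1, ], npad, ncol(x), byrow = TRUE) -
    x[npad:1 + 1, , drop = FALSE]
  post <- 2 * matrix(x[nrow(x), ], npad, ncol(x), byrow = TRUE) -
    x[nrow(x) - (1:npad), , drop = FALSE]
  ext <- rbind(pre, x, post)
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, ext, zi = zi)
  y <- iir_filter(b, a, y[nrow(y):1, , drop = FALSE], zi = zi)
  y <- y[nrow(y):1, , drop = FALSE]
  y[(npad + 1):(npad + nrow(x)), , drop = FALSE]
}

#' Band-pass filter ROI time series
#'
#' Zero-phase (forward-backward) second-order Butterworth band-pass with
#' the conventional resting-state band 0.008-0.1 Hz. The testable contract
#' is the frequency response: at TR = 2 s a 0.05 Hz sinusoid passes with
#' less than 1 dB loss while 0.2 Hz is attenuated by more than 20 dB, and
#' passband sinusoids emerge with no phase lag.
#'
#' @param ts A [roi_timeseries()].
#' @param low_hz,high_hz Band edges in Hz; `high_hz` must lie below the
#'   Nyquist frequency `1 / (2 * tr_seconds)`.
#' @return A filtered `roi_timeseries`.
#' @export
bandpass <- function(ts, low_hz = 0.008, high_hz = 0.1) {
  fs <- 1 / ts$tr_seconds
  if (low_hz <= 0 || high_hz <= low_hz || high_hz >= fs / 2)
    stop("configuration error: band must satisfy 0 < low < high < Nyquist = ",
         fs / 2, " Hz", call. = FALSE)
  co <- butter_bandpass(low_hz, high_hz, fs)
  roi_timeseries(filtfilt_matrix(co$b, co$a, ts$data), ts$tr_seconds,
                 ts$fd_trace)
}

# |H(f)|^2 of the forward-backward filter, from the coefficients; used by
# tests as the analytic oracle for the realized response.
filter_gain <- function(b, a, f_hz, fs) {
  w <- 2 * pi * f_hz / fs
  H <- vapply(w, function(wi) {
    z <- exp(-1i * wi * (seq_along(b) - 1))
    num <- sum(b * z)
    den <- sum(a * exp(-1i * wi * (seq_along(a) - 1)))
    Mod(num / den)
  }, numeric(1))
  H^2
}

#' Censor high-motion frames
#'
#' Removes frames whose framewise displacement strictly exceeds the
#' threshold (default 0.5 mm).
#'
#' @param ts A [roi_timeseries()] with an fd trace.
#' @param threshold Censoring threshold in mm.
#' @param min_frames Minimum surviving frames below which a quality error
#'   is raised (exclusion floors differ between studies; 50 is a default,
#'   not a canonical value).
#' @return A `roi_timeseries` of surviving frames; the number removed is
#'   attached as `attr(, "n_censored")`.
#' @export
scrub_frames <- function(ts, threshold = 0.5, min_frames = 50) {
  if (is.null(ts$fd_trace))
    stop("fd trace required for scrubbing", call. = FALSE)
  keep <- ts$fd_trace <= threshold
  if (sum(keep) < max(min_frames, 2))
    stop("quality error: only ", sum(keep), " frames survive FD <= ",
         threshold, " (minimum ", min_frames, ")", call. = FALSE)
  out <- roi_timeseries(ts$data[keep, , drop = FALSE], ts$tr_seconds,
                        ts$fd_trace[keep])
  attr(out, "n_censored") <- sum(!keep)
  out
}

#' Fisher-z connectivity vector from ROI time series
#'
#' Pearson correlation for every unordered ROI pair, Fisher r-to-z
#' transformed, ordered by [edge_index()]. Correlations are clipped to
#' |r| <= 1 - 1e-7 before `atanh` so degenerate (perfectly correlated)
#' pairs stay finite.
#'
#' @param ts A [roi_timeseries()] with at least 3 frames.
#' @return Numeric vector of length `edge_count(ncol(ts$data))`.
#' @export
timeseries_to_fc <- function(ts) {
  X <- ts$data
  if (nrow(X) < 3) stop("need at least 3 frames for correlation", call. = FALSE)
  v <- apply(X, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance ROI(s): ", paste(which(v == 0) - 1L, collapse = ", "),
         call. = FALSE)
  r <- stats::cor(X)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(upper_tri_vector(r))
  names(z) <- edge_labels(ncol(X))
  z
}

#' Full time-series to connectivity pipeline for one subject
#'
#' Stage order: nuisance regression (with intercept and linear trend),
#' band-pass on the residuals, motion scrubbing, correlation. Censoring
#' after filtering avoids the discontinuity artifacts that filtering a
#' gapped series would create.
#'
#' @param ts A [roi_timeseries()].
#' @param confounds Optional confound table; skipped when `NULL`.
#' @param low_hz,high_hz Band edges.
#' @param fd_threshold Scrubbing threshold (mm).
#' @param min_frames Minimum surviving frames.
#' @return Fisher-z edge vector as in [timeseries_to_fc()].
#' @export
ts_pipeline <- function(ts, confounds = NULL, low_hz = 0.008, high_hz = 0.1,
                        fd_threshold = 0.5, min_frames = 50) {
  if (!is.null(confounds)) ts <- regress_confounds(ts, confounds)
  ts <- bandpass(ts, low_hz, high_hz)
  if (!is.null(ts$fd_trace)) ts <- scrub_frames(ts, fd_threshold, min_frames)
  timeseries_to_fc(ts)
}
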