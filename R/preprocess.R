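# Edge trimming, FIR band-pass design/application, decimation,
# spherical-spline surface Laplacian (CSD), and spectral quality checks.

#' Oscillation band definitions
#'
#' Carrier bands: theta 3-7 Hz, alpha 8-12 Hz, beta 17-25 Hz. Envelope bands:
#' infraslow 0.05-0.1 Hz, slow 0.1-1 Hz.
#'
#' @return named list of `c(f_lo, f_hi)` in Hz.
#' @export
carrier_bands <- function() list(theta = c(3, 7), alpha = c(8, 12),
                                 beta = c(17, 25))

#' @rdname carrier_bands
#' @export
envelope_bands <- function() list(infraslow = c(0.05, 0.1), slow = c(0.1, 1))

band_center <- function(band) mean(band)

#' Trim the recording edges
#'
#' Removes the initial and final `margin_s` seconds (where start/end
#' artifacts concentrate) and shifts/crops the condition intervals
#' consistently.
#'
#' @param rec an `eeg_recording`.
#' @param margin_s margin in seconds removed at each end (default 10).
#' @return The trimmed `eeg_recording`.
#' @export
trim_edges <- function(rec, margin_s = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  dur <- rec_duration(rec)
  if (dur <= 2 * margin_s)
    stop("recording too short to trim: ", format(dur), " s <= 2 x ",
         margin_s, " s")
  keep <- seq.int(floor(margin_s * rec$fs) + 1L,
                  ncol(rec$data) - floor(margin_s * rec$fs))
  iv <- rec$intervals
  if (nrow(iv) > 0L) {
    iv$start <- pmax(iv$start - margin_s, 0)
    iv$end <- pmin(iv$end - margin_s, length(keep) / rec$fs)
    iv <- iv[iv$end > iv$start, , drop = FALSE]
  }
  recording(rec$data[, keep, drop = FALSE], rec$fs, rec$channel_labels,
            intervals = iv,
            reference_note = paste0(rec$reference_note,
                                    " [trimmed ", margin_s, "s edges]"))
}

#' Design the band-pass FIR filter
#'
#' Hamming-window linear-phase FIR band-pass with order
#' `7 * floor(fs / f_lo)` and normalised cutoffs `2 * f / fs` (so the theta
#' band at 500 Hz gives 1163 coefficients). The coefficient vector is
#' palindromic, hence exactly linear phase.
#'
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi < fs/2`.
#' @param fs sampling rate in Hz.
#' @return Object of class `fir_spec`: list with `b` (coefficients), `f_lo`,
#'   `f_hi`, `fs`, `n_taps`.
#' @export
design_bandpass <- function(f_lo, f_hi, fs) {
  if (f_lo <= 0) stop("f_lo must be > 0")
  if (f_hi >= fs / 2) stop("f_hi must be below the Nyquist frequency")
  if (f_lo >= f_hi) stop("need f_lo < f_hi")
  ord <- as.integer(7 * floor(fs / f_lo))
  b <- signal::fir1(ord, c(f_lo, f_hi) * 2 / fs, type = "pass")
  structure(list(b = as.numeric(b), f_lo = f_lo, f_hi = f_hi, fs = fs,
                 n_taps = ord + 1L),
            class = "fir_spec")
}

#' @export
print.fir_spec <- function(x, ...) {
  cat("<fir_spec> Hamming FIR band-pass ", x$f_lo, "-", x$f_hi, " Hz @ ",
      x$fs, " Hz, ", x$n_taps, " taps\n", sep = "")
  invisible(x)
}

#' Frequency response of an FIR filter
#'
#' @param b numeric coefficient vector (or a `fir_spec`).
#' @param f frequencies (Hz) at which to evaluate.
#' @param fs sampling rate in Hz (taken from a `fir_spec` if given).
#' @return complex response at `f`.
#' @export
fir_response <- function(b, f, fs = NULL) {
  if (inherits(b, "fir_spec")) { fs <- b$fs; b <- b$b }
  if (is.null(fs)) stop("'fs' required")
  vapply(f, function(fi)
    sum(b * exp(-2i * pi * fi / fs * (seq_along(b) - 1))), complex(1))
}

# FFT linear convolution machinery: zero-phase (forward-backward)
# filtering is one circular multiplication by |B|^2 after mirror padding.
.filtfilt_core <- function(X, b, pad) {
  # X: samples x channels matrix (already mirror padded); returns same shape
  m <- nrow(X); nb <- length(b)
  L <- stats::nextn(m + 2L * (nb - 1L), c(2, 3, 5))
  B <- stats::fft(c(b, numeric(L - nb)))
  XP <- rbind(X, matrix(0, L - m, ncol(X)))
  Y <- stats::mvfft(XP) * Mod(B)^2
  Re(stats::mvfft(Y, inverse = TRUE))[seq_len(m), , drop = FALSE] / L
}

#' Zero-phase (forward-backward) FIR filtering
#'
#' Applies the filter forward and backward, giving zero phase shift and the
#' squared magnitude response. Edges are mirror-padded (odd reflection about
#' the end samples) by `min(3 * n_taps, n - 1)` samples before filtering.
#'
#' @param x numeric vector, or channels x samples matrix.
#' @param b filter coefficients or a `fir_spec`.
#' @param pad padding length in samples (capped at `n - 1`).
#' @return Filtered signal, same shape as `x`.
#' @export
filtfilt_zero_phase <- function(x, b, pad = NULL) {
  if (inherits(b, "fir_spec")) b <- b$b
  b <- as.numeric(b)
  mat <- is.matrix(x)
  X <- if (mat) t(x) else matrix(as.numeric(x), ncol = 1L)
  n <- nrow(X); nb <- length(b)
  if (n <= nb)
    stop("signal (", n, " samples) must be longer than the filter (", nb,
         " taps); lower the band's low cutoff or lengthen the data")
  if (is.null(pad)) pad <- 3L * nb
  pad <- min(pad, n - 1L)
  head_pad <- 2 * X[rep(1L, pad), , drop = FALSE] - X[(pad + 1L):2L, , drop = FALSE]
  tail_pad <- 2 * X[rep(n, pad), , drop = FALSE] - X[(n - 1L):(n - pad), , drop = FALSE]
  Y <- .filtfilt_core(rbind(head_pad, X, tail_pad), b, pad)
  Y <- Y[(pad + 1L):(pad + n), , drop = FALSE]
  if (mat) t(Y) else Y[, 1L]
}

# zero-phase second-order cascaded boxcar (CIC^2) smoother of width k:
# kernel conv(rep(1,k), rep(1,k))/k^2, group delay k-1 samples, compensated.
# Nulls at multiples of fs/k make it the standard predecimation stage.
cic2_smooth <- function(v, k) {
  n <- length(v)
  box <- function(u) {
    cs <- cumsum(u)
    s <- (cs - c(rep(0, k), cs[seq_len(n - k)])) / k
    # growing-window warm-up: a constant input stays constant at the edge
    s[seq_len(k - 1L)] <- cs[seq_len(k - 1L)] / seq_len(k - 1L)
    s
  }
  s <- box(box(v))
  # causal delay is k-1 samples; shift back, hold the tail edge
  c(s[k:n], rep(s[n], k - 1L))
}

#' Anti-aliased decimation
#'
#' Low-pass filters (zero-phase) and keeps every `fs / fs_target`-th sample;
#' the decimation factor must be an integer. For large factors the
#' decimation is two-stage: a cascaded-boxcar (CIC^2) predecimation with
#' nulls on the aliasing bands, then a Hamming FIR with cutoff
#' `0.2 * fs_target` at the intermediate rate. Used to bring amplitude
#' envelopes to a rate where the infraslow filter is practical; content
#' below 1 Hz is preserved.
#'
#' @param x numeric vector or channels x samples matrix at rate `fs`.
#' @param fs input sampling rate (Hz).
#' @param fs_target output rate (Hz), divides `fs`.
#' @return list with `values` (same shape convention as `x`), `fs`
#'   (= `fs_target`) and `n_edge` (per-side length, in output samples, of the
#'   anti-aliasing filter transient).
#' @export
decimate_signal <- function(x, fs, fs_target = 10) {
  r <- fs / fs_target
  if (abs(r - round(r)) > 1e-9)
    stop("fs (", fs, ") must be an integer multiple of fs_target (",
         fs_target, ")")
  r <- as.integer(round(r))
  if (r == 1L)
    return(list(values = x, fs = fs_target, n_edge = 0L))
  edge1 <- 0L
  if (r >= 20L && r %% 5L == 0L) {
    r1 <- r %/% 5L
    if (is.matrix(x)) {
      keep1 <- seq.int(1L, ncol(x), by = r1)
      y1 <- matrix(0, nrow(x), length(keep1))
      for (ci in seq_len(nrow(x)))
        y1[ci, ] <- cic2_smooth(x[ci, ], r1)[keep1]
      rownames(y1) <- rownames(x)
      x <- y1
    } else {
      x <- cic2_smooth(x, r1)
      x <- x[seq.int(1L, length(x), by = r1)]
    }
    fs <- fs / r1
    r <- 5L
    edge1 <- 1L   # boxcar transient, in output samples
  }
  fc <- 0.2 * fs_target
  ord <- as.integer(7 * floor(fs / fc))
  b <- as.numeric(signal::fir1(ord, 2 * fc / fs, type = "low"))
  y <- filtfilt_zero_phase(x, b)
  keep <- seq.int(1L, if (is.matrix(y)) ncol(y) else length(y), by = r)
  out <- if (is.matrix(y)) y[, keep, drop = FALSE] else y[keep]
  list(values = out, fs = fs_target,
       n_edge = as.integer(ceiling((ord / 2) / r)) + edge1)
}

# ---------------------------------------------------------------------------
# Surface Laplacian (spherical-spline current source density)

legendre_sum <- function(x, nterms, weights) {
  # sum_l weights[l] * P_l(x) elementwise, P_l by the three-term recurrence
  pm1 <- rep(1, length(x)); p <- x
  acc <- weights[1L] * p
  for (l in 2:nterms) {
    pn <- ((2 * l - 1) * x * p - (l - 1) * pm1) / l
    acc <- acc + weights[l] * pn
    pm1 <- p; p <- pn
  }
  acc
}

#' Spherical-spline surface Laplacian transform matrix
#'
#' Builds the linear operator that maps scalp potentials at the given
#' electrode positions to their current-source-density estimate (Perrin-style
#' spherical spline: fit `v = c0 + G c` with `sum(c) = 0` and ridge
#' `lambda`, output `H c`). Unit-sphere convention, no head-radius rescaling
#' (scale cancels in phase-based statistics downstream).
#'
#' @param positions unit-sphere electrode positions (n x 3, labelled rows).
#' @param m spline flexibility (integer >= 2, default 4).
#' @param lambda ridge regularisation (default 1e-5).
#' @param legendre_terms Legendre series truncation (default 50, >= 20).
#' @return n x n transform matrix.
#' @export
csd_transform_matrix <- function(positions, m = 4, lambda = 1e-5,
                                 legendre_terms = 50) {
  stopifnot(m >= 2, lambda >= 0, legendre_terms >= 20)
  n <- nrow(positions)
  cosang <- tcrossprod(positions)
  cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
  off <- cosang[upper.tri(cosang, diag = FALSE)]
  if (any(off > 1 - 1e-10))
    stop("coincident electrode positions")
  l <- seq_len(legendre_terms)
  wg <- (2 * l + 1) / (l * (l + 1))^m / (4 * pi)
  # sign convention: a local potential maximum maps to positive CSD (source)
  wh <- (2 * l + 1) / (l * (l + 1))^(m - 1) / (4 * pi)
  G <- matrix(legendre_sum(as.vector(cosang), legendre_terms, wg), n, n)
  H <- matrix(legendre_sum(as.vector(cosang), legendre_terms, wh), n, n)
  Gi <- solve(G + diag(lambda, n))
  rs <- rowSums(Gi)
  Tm <- Gi - outer(rs, rs) / sum(rs)
  out <- H %*% Tm
  dimnames(out) <- list(rownames(positions), rownames(positions))
  out
}

#' Surface Laplacian (current source density) of a recording
#'
#' Applies the spherical-spline surface Laplacian channel transform,
#' attenuating volume-conduction blur before spatial-correlation analysis.
#' A spatially constant potential maps to (numerically) zero.
#'
#' @param rec an `eeg_recording`; every channel must have a montage position.
#' @param montage an `eeg_montage`.
#' @param m,lambda,legendre_terms see [csd_transform_matrix()].
#' @return The CSD-transformed `eeg_recording` (same channels and order).
#' @export
surface_laplacian <- function(rec, montage, m = 4, lambda = 1e-5,
                              legendre_terms = 50) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(montage, "eeg_montage"))
  absent <- setdiff(rec$channel_labels, rownames(montage$positions))
  if (length(absent))
    stop("no montage position for channel(s): ", paste(absent, collapse = ", "))
  P <- montage$positions[rec$channel_labels, , drop = FALSE]
  M <- csd_transform_matrix(P, m = m, lambda = lambda,
                            legendre_terms = legendre_terms)
  recording(M %*% rec$data, rec$fs, rec$channel_labels,
            intervals = rec$intervals,
            reference_note = paste0(rec$reference_note, " [CSD m=", m,
                                    " lambda=", format(lambda), "]"))
}

# ---------------------------------------------------------------------------
# Spectral quality checks

#' One-sided amplitude spectrum
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @return list with `freq` (Hz, 0..fs/2) and `magnitude` (|FFT|).
#' @export
amplitude_spectrum <- function(x, fs) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  X <- stats::fft(x)
  k <- seq_len(floor(n / 2) + 1L)
  list(freq = (k - 1L) * fs / n, magnitude = Mod(X[k]))
}

.band_check_sets <- list(
  theta = list(central = 4:5, peripheral = c(3, 6, 7)),
  alpha = list(central = 9:11, peripheral = c(8, 12)),
  beta = list(central = 20:22, peripheral = c(17, 18, 19, 23, 24, 25)))

#' Band peak quality check
#'
#' Tests whether a band's central frequencies carry more power than its
#' peripheral frequencies, the typical human-EEG property (theta: 4-5 Hz vs
#' 3, 6-7 Hz; alpha: 9-11 Hz vs 8, 12 Hz; beta: 20-22 Hz vs 17-19,
#' 23-25 Hz). Spectrum bins are assigned to integer frequencies by rounding;
#' the comparison is a strict inequality of mean magnitudes (ties fail).
#'
#' @param freq,magnitude one-sided spectrum as from [amplitude_spectrum()].
#' @param band `"theta"`, `"alpha"` or `"beta"`.
#' @return `TRUE` iff mean central magnitude strictly exceeds mean peripheral
#'   magnitude.
#' @export
band_peak_check <- function(freq, magnitude, band = c("theta", "alpha", "beta")) {
  band <- match.arg(band)
  sets <- .band_check_sets[[band]]
  rf <- round(freq)
  central <- magnitude[rf %in% sets$central]
  peripheral <- magnitude[rf %in% sets$peripheral]
  if (!length(central) || !length(peripheral))
    stop("spectrum does not cover the ", band, " band")
  mean(central) > mean(peripheral)
}
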