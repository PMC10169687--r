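# Amplitude envelopes of band-limited oscillations and the instantaneous
# phase of their infraslow / slow fluctuations.

# Fused zero-phase band-pass + analytic signal for a whole channel matrix:
# one shared forward FFT, one inverse per band. Numerically equivalent to
# filtfilt_zero_phase() followed by hilbert_analytic(), with shared mirror
# padding sized for the longest filter. Input channels x samples; output
# complex matrices in samples x channels layout (cheaper to slice).
#
# With fs_out < fs (an integer divisor whose Nyquist clears every band's
# upper edge), the analytic signal is decimated in the frequency domain:
# the one-sided spectrum after |B|^2 is confined to [f_lo, f_hi] (stopband
# residue is ~-100 dB), so keeping the first L/r bins and inverting at
# length L/r yields the exactly subsampled analytic signal at a fraction of
# the inverse-transform cost.
band_analytic <- function(X, fs, specs, fs_out = fs) {
  n <- ncol(X)
  nb_max <- max(vapply(specs, function(s) s$n_taps, integer(1)))
  if (n <= nb_max)
    stop("signal (", n, " samples) must be longer than the filter (",
         nb_max, " taps)")
  r <- fs / fs_out
  if (abs(r - round(r)) > 1e-9)
    stop("fs_out must divide fs")
  r <- as.integer(round(r))
  f_hi_max <- max(vapply(specs, function(s) s$f_hi, numeric(1)))
  if (fs_out < 2.2 * f_hi_max)
    stop("fs_out (", fs_out, " Hz) too low for a band reaching ", f_hi_max,
         " Hz")
  pad <- min(3L * nb_max, n - 1L)
  pad <- as.integer(ceiling(pad / r) * r)   # keep output on the input lattice
  Xt <- t(X)                                # samples x channels
  L <- stats::nextn(n + 2L * pad + 2L * (nb_max - 1L), c(2, 3, 5))
  while (L %% r != 0L) L <- stats::nextn(L + 1L, c(2, 3, 5))
  XP <- matrix(0, L, ncol(Xt))
  XP[pad + seq_len(n), ] <- Xt
  XP[pad:1, ] <- 2 * rep(Xt[1L, ], each = pad) - Xt[2L:(pad + 1L), ]
  XP[pad + n + seq_len(pad), ] <- 2 * rep(Xt[n, ], each = pad) -
    Xt[(n - 1L):(n - pad), ]
  Fw <- stats::mvfft(XP)
  L2 <- L %/% r
  n2 <- (n - 1L) %/% r + 1L
  h2 <- c(1, rep(2, L2 - 1L))   # one-sided doubling on the retained bins
  out <- vector("list", length(specs))
  names(out) <- names(specs)
  for (k in seq_along(specs)) {
    b <- specs[[k]]$b
    B <- stats::fft(c(b, numeric(L - length(b))))[seq_len(L2)]
    A <- stats::mvfft(Fw[seq_len(L2), , drop = FALSE] * (Mod(B)^2 * h2),
                      inverse = TRUE) / L
    out[[k]] <- A[pad %/% r + seq_len(n2), , drop = FALSE]
  }
  list(analytic = out, fs = fs_out, n = n2)
}

# smallest divisor of fs that is a multiple of fs_env and comfortably above
# twice the highest band edge (NULL if none: stay at fs)
choose_envelope_rate <- function(fs, fs_env, f_hi_max) {
  cand <- fs_env * seq_len(floor(fs / fs_env))
  cand <- cand[fs %% cand == 0 & cand >= 2.2 * f_hi_max]
  if (length(cand)) min(cand) else fs
}

# Analytic signal via the FFT method (one-sided spectrum doubling).
hilbert_analytic <- function(x) {
  mat <- is.matrix(x)
  X <- if (mat) t(x) else matrix(as.numeric(x), ncol = 1L)
  n <- nrow(X)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  A <- stats::mvfft(stats::mvfft(X) * h, inverse = TRUE) / n
  if (mat) t(A) else A[, 1L]
}

#' Amplitude envelope of a band-limited signal
#'
#' The envelope is the modulus of the analytic (Hilbert-transformed) signal.
#' The input must already be band-passed (zero-mean); length is preserved.
#'
#' @param x band-passed numeric vector, or channels x samples matrix.
#' @param fs sampling rate (Hz).
#' @param channel,carrier_band optional labels carried along.
#' @return An `envelope_series`: list with `values` (non-negative, same shape
#'   as `x`), `fs`, `channel`, `carrier_band`.
#' @export
analytic_envelope <- function(x, fs, channel = NA_character_,
                              carrier_band = NA_character_) {
  values <- Mod(hilbert_analytic(x))
  structure(list(values = values, fs = fs, channel = channel,
                 carrier_band = carrier_band),
            class = "envelope_series")
}

#' @export
print.envelope_series <- function(x, ...) {
  n <- if (is.matrix(x$values)) ncol(x$values) else length(x$values)
  cat("<envelope_series> ", n, " samples @ ", x$fs, " Hz",
      if (!is.na(x$carrier_band)) paste0(", band ", x$carrier_band), "\n",
      sep = "")
  invisible(x)
}

#' Instantaneous phase of envelope-band fluctuations
#'
#' Band-passes the amplitude envelope inside the requested envelope band and
#' takes the Hilbert phase. The envelope is decimated first (anti-aliased,
#' default 10 Hz) so the band-pass design rule yields a practical filter
#' length; the standard design rule (order `7 * floor(fs / f_lo)`) is applied at
#' the decimated rate. The band-passed fluctuation is zero-mean by
#' construction.
#'
#' Validity flags: samples closer to either end than half a filter length
#' (envelope-band filter, plus the propagated carrier-filter and
#' anti-aliasing transients) are marked invalid and excluded from downstream
#' medians. Samples whose fluctuation amplitude falls below
#' `low_amp_frac` of the series s.d. are flagged `low_amp` (kept, but
#' available for sensitivity analyses).
#'
#' @param env an `envelope_series` (vector or matrix values).
#' @param envelope_band `"infraslow"` (0.05-0.1 Hz) or `"slow"` (0.1-1 Hz),
#'   or a numeric `c(f_lo, f_hi)`.
#' @param fs_target decimated rate in Hz (default 10; use `env$fs` to skip
#'   decimation).
#' @param n_edge_invalid extra per-side invalid samples (at `env$fs`)
#'   propagated from earlier filtering stages, e.g. half the carrier filter
#'   length.
#' @param low_amp_frac threshold for the low-amplitude flag, as a fraction of
#'   the fluctuation s.d. (default 0.01).
#' @return A `phase_series`: list with `values` (radians in (-pi, pi], same
#'   channel layout as the input), `fs`, `valid`, `low_amp`, `t0` (time of
#'   first sample, seconds), `channel`, `carrier_band`, `envelope_band`.
#' @export
envelope_band_phase <- function(env, envelope_band = "infraslow",
                                fs_target = 10, n_edge_invalid = 0L,
                                low_amp_frac = 0.01) {
  stopifnot(inherits(env, "envelope_series"))
  if (is.character(envelope_band)) {
    band_name <- match.arg(envelope_band, names(envelope_bands()))
    band <- envelope_bands()[[band_name]]
  } else {
    band <- envelope_band; band_name <- paste(band, collapse = "-")
  }
  dec <- decimate_signal(env$values, env$fs, fs_target)
  x <- dec$values
  n <- if (is.matrix(x)) ncol(x) else length(x)
  spec <- design_bandpass(band[1], band[2], dec$fs)
  if (n <= spec$n_taps)
    stop("envelope too short for the ", band_name, " filter: ", n,
         " samples at ", dec$fs, " Hz, need > ", spec$n_taps,
         " (about ", ceiling(spec$n_taps / dec$fs), " s)")
  # demean first: the finite stop-band would otherwise leak a trace of the
  # envelope's large DC level into the fluctuation
  mean_level <- if (is.matrix(x)) rowMeans(x) else mean(x)
  x <- x - mean_level
  fluct <- filtfilt_zero_phase(x, spec)
  a <- hilbert_analytic(fluct)
  phase <- Arg(a)
  amp <- Mod(a)
  half <- ceiling(spec$n_taps / 2)
  carried <- ceiling(n_edge_invalid * dec$fs / env$fs) + dec$n_edge
  edge <- half + carried
  valid_vec <- rep(TRUE, n)
  valid_vec[seq_len(min(edge, n))] <- FALSE
  valid_vec[seq.int(max(1L, n - edge + 1L), n)] <- FALSE
  # threshold scale: the fluctuation s.d. over the valid interior (edge
  # transients excluded), floored at a small fraction of the envelope's
  # mean level so that a (near-)constant envelope is flagged throughout
  # rather than judged against its own numerical noise
  sd_idx <- if (any(valid_vec)) valid_vec else rep(TRUE, n)
  if (is.matrix(x)) {
    valid <- matrix(valid_vec, nrow = nrow(x), ncol = n, byrow = TRUE,
                    dimnames = dimnames(x))
    scale <- pmax(apply(fluct[, sd_idx, drop = FALSE], 1L, stats::sd),
                  1e-3 * abs(mean_level))
    low_amp <- sweep(amp, 1L, low_amp_frac * scale, `<`)
  } else {
    valid <- valid_vec
    scale <- max(stats::sd(fluct[sd_idx]), 1e-3 * abs(mean_level))
    low_amp <- amp < low_amp_frac * scale
  }
  structure(list(values = phase, fs = dec$fs, valid = valid,
                 low_amp = low_amp, t0 = 0,
                 channel = env$channel, carrier_band = env$carrier_band,
                 envelope_band = band_name),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  n <- if (is.matrix(x$values)) ncol(x$values) else length(x$values)
  nv <- sum(if (is.matrix(x$valid)) x$valid[1L, ] else x$valid)
  cat("<phase_series> ", n, " samples @ ", x$fs, " Hz (", nv, " valid), ",
      "carrier ", x$carrier_band, ", envelope ", x$envelope_band, "\n",
      sep = "")
  invisible(x)
}
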