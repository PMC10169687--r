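# The instantaneous spatial-correlation statistic psi and its per-condition
# median M-psi, for single pairs and for whole channel sets.

# circular absolute phase difference, wrapped into [0, pi]
wrap_phase_diff <- function(theta1, theta2) {
  d <- abs(theta1 - theta2) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Instantaneous spatial correlation psi of two phase series
#'
#' `psi_t = 1 - delta_t / pi`, where `delta_t` is the circular absolute
#' difference of the two envelope-band phases wrapped into `[0, pi]`.
#' Identical phases give 1, antiphase gives 0. Symmetric in its arguments
#' and invariant under a common phase offset.
#'
#' @param theta1,theta2 `phase_series` objects (vector values) with equal
#'   length, rate and envelope band.
#' @return A `psi_series`: list with `values` in `[0, 1]`, `valid` (AND of
#'   the input masks), `fs`, `t0`, `pair`, `carrier_band`, `envelope_band`.
#' @export
psi <- function(theta1, theta2) {
  stopifnot(inherits(theta1, "phase_series"), inherits(theta2, "phase_series"))
  if (length(theta1$values) != length(theta2$values))
    stop("phase series have different lengths")
  if (theta1$fs != theta2$fs) stop("phase series have different rates")
  if (!identical(theta1$envelope_band, theta2$envelope_band))
    stop("phase series have different envelope bands")
  vals <- 1 - wrap_phase_diff(theta1$values, theta2$values) / pi
  structure(list(values = vals, valid = theta1$valid & theta2$valid,
                 fs = theta1$fs, t0 = theta1$t0,
                 pair = c(theta1$channel, theta2$channel),
                 carrier_band = theta1$carrier_band,
                 envelope_band = theta1$envelope_band),
            class = "psi_series")
}

#' @export
print.psi_series <- function(x, ...) {
  cat("<psi_series> pair ", paste(x$pair, collapse = "-"), ", ",
      length(x$values), " samples @ ", x$fs, " Hz, carrier ",
      x$carrier_band, ", envelope ", x$envelope_band, "\n", sep = "")
  invisible(x)
}

# sample times of a psi/phase series
series_times <- function(s) s$t0 + (seq_along(s$values) - 1L) / s$fs

# logical mask: which times fall inside any interval of the given condition
in_condition <- function(times, intervals, condition) {
  keep <- rep(FALSE, length(times))
  sub <- intervals[intervals$condition == condition, , drop = FALSE]
  for (i in seq_len(nrow(sub)))
    keep <- keep | (times >= sub$start[i] & times < sub$end[i])
  keep
}

#' Median spatial correlation over a condition
#'
#' Median of the valid psi samples falling inside all intervals of one task
#' condition. For an even number of samples the median is the midpoint of
#' the two central order statistics.
#'
#' @param psi a `psi_series`.
#' @param intervals condition intervals (`start`, `end`, `condition`).
#' @param condition `"eyes_closed"` or `"eyes_open"`.
#' @return list with `m_psi` and `n_samples`.
#' @export
m_psi <- function(psi, intervals, condition) {
  stopifnot(inherits(psi, "psi_series"))
  keep <- psi$valid & in_condition(series_times(psi), intervals, condition)
  if (!any(keep))
    stop("no valid psi samples for pair ", paste(psi$pair, collapse = "-"),
         " in condition '", condition, "'")
  list(m_psi = stats::median(psi$values[keep]), n_samples = sum(keep))
}

# ---------------------------------------------------------------------------
# Whole-recording driver

#' Envelope-band phases for every channel of a recording
#'
#' Runs the per-channel signal chain: carrier band-pass (zero-phase Hamming
#' FIR), Hilbert envelope, anti-aliased decimation, envelope-band band-pass
#' and Hilbert phase. Returns one phase matrix per (carrier band, envelope
#' band).
#'
#' @param rec an `eeg_recording` (already trimmed / CSD-transformed as
#'   desired).
#' @param bands character vector of carrier band names (see
#'   [carrier_bands()]).
#' @param env_bands character vector of envelope band names (see
#'   [envelope_bands()]).
#' @param fs_env decimated envelope rate in Hz (default 10).
#' @return Nested list `phases[[band]][[env_band]]`, each a `phase_series`
#'   with matrix values (channels x samples).
#' @export
recording_phases <- function(rec, bands = c("theta", "alpha", "beta"),
                             env_bands = c("infraslow", "slow"),
                             fs_env = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  bands <- match.arg(bands, names(carrier_bands()), several.ok = TRUE)
  env_bands <- match.arg(env_bands, names(envelope_bands()), several.ok = TRUE)
  specs <- lapply(carrier_bands()[bands], function(rng)
    design_bandpass(rng[1], rng[2], rec$fs))
  f_hi_max <- max(vapply(specs, function(s) s$f_hi, numeric(1)))
  env_rate <- choose_envelope_rate(rec$fs, fs_env, f_hi_max)
  ba <- band_analytic(rec$data, rec$fs, specs, fs_out = env_rate)
  r <- rec$fs / ba$fs
  out <- list()
  for (bd in bands) {
    env <- structure(list(values = t(Mod(ba$analytic[[bd]])), fs = ba$fs,
                          channel = NA_character_, carrier_band = bd),
                     class = "envelope_series")
    out[[bd]] <- list()
    for (eb in env_bands) {
      ph <- envelope_band_phase(env, eb, fs_target = fs_env,
                                n_edge_invalid = ceiling(specs[[bd]]$n_taps / 2 / r))
      rownames(ph$values) <- rec$channel_labels
      out[[bd]][[eb]] <- ph
    }
  }
  out
}

# single-channel phase_series view into a matrix phase_series
phase_row <- function(ph, channel) {
  i <- match(channel, rownames(ph$values))
  if (is.na(i)) stop("no phase series for channel ", channel)
  structure(list(values = ph$values[i, ], fs = ph$fs,
                 valid = ph$valid[i, ], low_amp = ph$low_amp[i, ],
                 t0 = ph$t0, channel = channel,
                 carrier_band = ph$carrier_band,
                 envelope_band = ph$envelope_band),
            class = "phase_series")
}

#' Pairwise M-psi table from per-channel phases
#'
#' Computes psi and its per-condition median for every requested channel
#' pair, carrier band, envelope band and condition. The table is complete:
#' any pair/condition without valid samples raises an error rather than
#' being dropped silently.
#'
#' @param phases nested phase list from [recording_phases()].
#' @param pairs data frame with columns `channel_a`, `channel_b` (no
#'   duplicated channel within a pair), or `NULL` for all pairs of available
#'   channels.
#' @param intervals condition intervals of the recording the phases came
#'   from.
#' @param conditions conditions to summarise (default both).
#' @param participant participant id stamped on the rows.
#' @return data frame with columns `participant`, `channel_a`, `channel_b`,
#'   `carrier_band`, `envelope_band`, `condition`, `m_psi`, `n_samples`.
#' @export
pairwise_mpsi <- function(phases, pairs = NULL, intervals,
                          conditions = c("eyes_closed", "eyes_open"),
                          participant = NA_character_) {
  first <- phases[[1L]][[1L]]
  chans <- rownames(first$values)
  if (is.null(pairs)) pairs <- all_channel_pairs(chans)
  if (any(pairs$channel_a == pairs$channel_b))
    stop("duplicated channel within a pair")
  missing <- setdiff(unique(c(pairs$channel_a, pairs$channel_b)), chans)
  if (length(missing))
    stop("no phases for channel(s): ", paste(missing, collapse = ", "))
  times <- series_times(list(values = first$values[1L, ], fs = first$fs,
                             t0 = first$t0))
  cond_masks <- lapply(conditions, function(cd)
    in_condition(times, intervals, cd))
  names(cond_masks) <- conditions
  blocks <- list()
  np <- nrow(pairs)
  for (bd in names(phases)) for (eb in names(phases[[bd]])) {
    ph <- phases[[bd]][[eb]]
    ia <- match(pairs$channel_a, rownames(ph$values))
    ib <- match(pairs$channel_b, rownames(ph$values))
    for (cd in conditions) {
      mv <- numeric(np); ns <- integer(np)
      for (k in seq_len(np)) {
        d <- wrap_phase_diff(ph$values[ia[k], ], ph$values[ib[k], ])
        keep <- ph$valid[ia[k], ] & ph$valid[ib[k], ] & cond_masks[[cd]]
        if (!any(keep))
          stop("no valid psi samples for pair ", pairs$channel_a[k], "-",
               pairs$channel_b[k], " (", bd, "/", eb, ") in condition '",
               cd, "'")
        mv[k] <- stats::median(1 - d[keep] / pi)
        ns[k] <- sum(keep)
      }
      blocks[[length(blocks) + 1L]] <- data.frame(
        participant = participant,
        channel_a = pairs$channel_a, channel_b = pairs$channel_b,
        carrier_band = bd, envelope_band = eb, condition = cd,
        m_psi = mv, n_samples = ns, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Per-recording M-psi computation (trim, CSD, filter, envelope, psi)
#'
#' Convenience driver for one participant: trims the recording edges,
#' optionally applies the surface Laplacian, extracts envelope-band phases
#' and tabulates pairwise M-psi.
#'
#' @param rec an `eeg_recording`.
#' @param montage an `eeg_montage`, required when `csd = TRUE`.
#' @param bands,env_bands,fs_env see [recording_phases()].
#' @param pairs channel pairs (default: all pairs).
#' @param conditions conditions to summarise.
#' @param trim_margin_s edge trim in seconds (default 10; 0 skips).
#' @param csd apply the surface Laplacian first (default: montage given).
#' @param participant participant id stamped on the rows.
#' @return M-psi table as from [pairwise_mpsi()].
#' @export
compute_mpsi <- function(rec, montage = NULL,
                         bands = c("theta", "alpha"),
                         env_bands = "infraslow", fs_env = 10,
                         pairs = NULL,
                         conditions = c("eyes_closed", "eyes_open"),
                         trim_margin_s = 10, csd = !is.null(montage),
                         participant = NA_character_) {
  if (trim_margin_s > 0) rec <- trim_edges(rec, trim_margin_s)
  if (csd) {
    if (is.null(montage)) stop("'montage' required when csd = TRUE")
    rec <- surface_laplacian(rec, montage)
  }
  if (!is.null(pairs)) {
    # only channels appearing in a requested pair need phases
    need <- unique(c(pairs$channel_a, pairs$channel_b))
    missing <- setdiff(need, rec$channel_labels)
    if (length(missing))
      stop("recording lacks channel(s): ", paste(missing, collapse = ", "))
    keep <- rec$channel_labels %in% need
    rec <- recording(rec$data[keep, , drop = FALSE], rec$fs,
                     rec$channel_labels[keep], intervals = rec$intervals,
                     reference_note = rec$reference_note)
  }
  phases <- recording_phases(rec, bands = bands, env_bands = env_bands,
                             fs_env = fs_env)
  pairwise_mpsi(phases, pairs = pairs, intervals = rec$intervals,
                conditions = conditions, participant = participant)
}

#' Write / read an M-psi table as CSV
#'
#' Fixed column order: participant, channel_a, channel_b, carrier_band,
#' envelope_band, condition, m_psi, n_samples.
#'
#' @param mpsi M-psi data frame.
#' @param path CSV path.
#' @return the path (write) or the table (read).
#' @export
write_mpsi <- function(mpsi, path) {
  cols <- c("participant", "channel_a", "channel_b", "carrier_band",
            "envelope_band", "condition", "m_psi", "n_samples")
  utils::write.csv(mpsi[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mpsi
#' @export
read_mpsi <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
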