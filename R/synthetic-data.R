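# Synthetic resting-state EEG with controllable infraslow envelope-phase
# coupling: single recordings and whole cohorts with group-specific deficits.

#' Coupling rule for the synthetic generator
#'
#' A rule assigns a von Mises concentration `kappa` to a set of channels for
#' one carrier band, in one condition or both. Channels covered by a rule
#' keep their envelope phase as a wrapped Ornstein-Uhlenbeck offset around
#' the band's shared latent infraslow phase, with stationary distribution
#' von Mises(0, kappa): `kappa = 0` means a free phase random walk
#' (independent channels), large `kappa` means near-locked phases.
#'
#' @param band carrier band name the rule applies to.
#' @param kappa von Mises concentration (>= 0).
#' @param regions character vector of region names (resolved against the
#'   standard montage), and/or
#' @param channels explicit channel labels.
#' @param condition `"eyes_closed"`, `"eyes_open"` or `NULL` (both).
#' @return list of class `coupling_rule`.
#' @export
coupling_rule <- function(band, kappa, regions = NULL, channels = NULL,
                          condition = NULL) {
  if (is.null(regions) && is.null(channels))
    stop("give 'regions' and/or 'channels'")
  if (kappa < 0) stop("kappa must be >= 0")
  if (!is.null(condition))
    condition <- match.arg(condition, c("eyes_closed", "eyes_open"))
  structure(list(band = band, kappa = kappa, regions = regions,
                 channels = channels, condition = condition),
            class = "coupling_rule")
}

#' Simulation configuration for a single synthetic recording
#'
#' The generated signal per channel is a sum over carrier bands of
#' amplitude-modulated sinusoids riding on 1/f noise:
#' `x_c(t) = sum_b A_b [1 + m cos(eta_cb(t))] cos(2 pi f_b t + phi_cb) + s n_c(t)`
#' where `f_b` is the band's centre frequency, `phi_cb` i.i.d. uniform
#' carrier phases, and the envelope phase `eta_cb(t)` is a shared per-band
#' latent infraslow phase (frequency `envelope_freq` plus a slow common
#' drift) plus a per-channel wrapped Ornstein-Uhlenbeck offset whose
#' stationary law is von Mises(0, kappa). Coupling rules set kappa per
#' (channel set, band, condition); uncovered channels use `kappa_base`.
#'
#' @param fs sampling rate, Hz (default 500).
#' @param channel_labels ordered channel labels (default: the 60-channel
#'   montage).
#' @param bands named list of carrier bands (name -> `c(f_lo, f_hi)`); the
#'   carrier frequency is the band centre.
#' @param band_amplitudes amplitude `A_b` per band (recycled; default 1).
#' @param envelope_freq infraslow modulation frequency, Hz, in [0.05, 0.1].
#' @param modulation_depth modulation depth `m`, in [0, 1).
#' @param coupling list of [coupling_rule()]s (later rules win on overlap).
#' @param kappa_base concentration for channels not covered by any rule
#'   (default 1: weak global coupling).
#' @param noise_exponent 1/f^a power-spectrum slope of the additive noise.
#' @param noise_scale s.d. of the additive noise (0 disables it).
#' @param condition_schedule segment lengths in seconds, alternating
#'   conditions (default 6 x 30 s, about 90 s per condition).
#' @param first_condition condition of the first segment.
#' @param jitter_sd envelope-phase jitter, rad/sqrt(s); sets the offset
#'   diffusion rate (and with kappa the OU relaxation time 2/(kappa sd^2)).
#' @param latent_drift_sd common latent-phase drift, rad/sqrt(s).
#' @param seed default RNG seed used by [generate_recording()].
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(fs = 500,
                              channel_labels = analysis_channels(),
                              bands = carrier_bands(),
                              band_amplitudes = 1,
                              envelope_freq = 0.07,
                              modulation_depth = 0.5,
                              coupling = list(),
                              kappa_base = 1,
                              noise_exponent = 1,
                              noise_scale = 0.5,
                              condition_schedule = rep(30, 6),
                              first_condition = "eyes_closed",
                              jitter_sd = 0.2236,
                              latent_drift_sd = 0.05,
                              seed = 1L) {
  duration <- sum(condition_schedule)
  if (modulation_depth < 0 || modulation_depth >= 1)
    stop("modulation_depth must be in [0, 1)")
  if (envelope_freq <= 0) stop("envelope_freq must be positive")
  if (duration * envelope_freq < 3)
    stop("duration (", duration, " s) too short for envelope_freq ",
         envelope_freq, " Hz: fewer than 3 modulation cycles")
  if (any(condition_schedule <= 0)) stop("segment lengths must be positive")
  if (kappa_base < 0) stop("kappa_base must be >= 0")
  for (r in coupling)
    if (!inherits(r, "coupling_rule")) stop("'coupling' must hold coupling_rule objects")
  first_condition <- match.arg(first_condition, c("eyes_closed", "eyes_open"))
  band_amplitudes <- rep_len(band_amplitudes, length(bands))
  names(band_amplitudes) <- names(bands)
  structure(list(fs = fs, channel_labels = as.character(channel_labels),
                 bands = bands, band_amplitudes = band_amplitudes,
                 envelope_freq = envelope_freq,
                 modulation_depth = modulation_depth,
                 coupling = coupling, kappa_base = kappa_base,
                 noise_exponent = noise_exponent, noise_scale = noise_scale,
                 condition_schedule = condition_schedule,
                 first_condition = first_condition,
                 jitter_sd = jitter_sd, latent_drift_sd = latent_drift_sd,
                 duration = duration, seed = as.integer(seed)),
            class = "simulation_config")
}

schedule_intervals <- function(config) {
  ends <- cumsum(config$condition_schedule)
  starts <- c(0, ends[-length(ends)])
  conds <- rep(c(config$first_condition,
                 setdiff(c("eyes_closed", "eyes_open"),
                         config$first_condition)),
               length.out = length(ends))
  data.frame(start = starts, end = ends, condition = conds,
             stringsAsFactors = FALSE)
}

# channel-level kappa for one band: matrix channels x conditions
resolve_kappa <- function(config, band) {
  conds <- c("eyes_closed", "eyes_open")
  K <- matrix(config$kappa_base, length(config$channel_labels), 2L,
              dimnames = list(config$channel_labels, conds))
  regions <- standard_montage()$regions
  for (r in config$coupling) {
    if (r$band != band) next
    chans <- unique(c(unlist(regions[r$regions], use.names = FALSE),
                      r$channels))
    chans <- intersect(chans, config$channel_labels)
    cols <- if (is.null(r$condition)) conds else r$condition
    K[chans, cols] <- r$kappa
  }
  K
}

# 1/f^a noise by spectral shaping of white noise, unit variance
onef_noise <- function(n, fs, exponent) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) * fs / n
  scale <- c(0, f[-1L]^(-exponent / 2))
  y <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  y / stats::sd(y)
}

# wrapped-OU offset path on the simulation lattice; beta per step
ou_offset_path <- function(n, beta_step, sd_step, d0, eps) {
  d <- numeric(n)
  d[1L] <- d0
  if (all(beta_step == 0)) {
    # free random walk: vectorised
    d <- d0 + cumsum(c(0, eps[-1L] * sd_step))
  } else {
    for (j in 2:n)
      d[j] <- d[j - 1L] - beta_step[j - 1L] * sin(d[j - 1L]) + eps[j] * sd_step
  }
  d
}

#' Generate one synthetic recording
#'
#' Deterministic in (config, seed): the same pair always yields bit-identical
#' samples. The envelope-phase processes are simulated on a 10 Hz lattice
#' (the phases are infraslow) and linearly interpolated to the sampling
#' rate.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (default `config$seed`).
#' @return An `eeg_recording` with the schedule's condition intervals.
#' @export
generate_recording <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  fs <- config$fs
  n <- round(config$duration * fs)
  t <- (seq_len(n) - 1L) / fs
  nch <- length(config$channel_labels)
  fs_lat <- 10
  n_lat <- floor(config$duration * fs_lat) + 1L
  t_lat <- (seq_len(n_lat) - 1L) / fs_lat
  intervals <- schedule_intervals(config)
  # condition index per lattice step
  cond_lat <- character(n_lat)
  for (i in seq_len(nrow(intervals)))
    cond_lat[t_lat >= intervals$start[i] - 1e-9 &
               t_lat < intervals$end[i]] <- intervals$condition[i]
  cond_lat[!nzchar(cond_lat)] <- intervals$condition[nrow(intervals)]
  sd_step <- config$jitter_sd / sqrt(fs_lat)
  data <- matrix(0, nch, n)
  for (bd in names(config$bands)) {
    f_b <- band_center(config$bands[[bd]])
    K <- resolve_kappa(config, bd)
    # shared latent infraslow phase for this band
    eta0 <- stats::runif(1, -pi, pi) + 2 * pi * config$envelope_freq * t_lat +
      cumsum(c(0, stats::rnorm(n_lat - 1L, 0,
                               config$latent_drift_sd / sqrt(fs_lat))))
    carrier_cos <- cos(2 * pi * f_b * t)
    carrier_sin <- sin(2 * pi * f_b * t)
    for (c in seq_len(nch)) {
      kappa_t <- K[c, cond_lat]
      beta_step <- kappa_t * config$jitter_sd^2 / 2 / fs_lat
      d0 <- if (kappa_t[1L] > 0) 0 else stats::runif(1, -pi, pi)
      eps <- stats::rnorm(n_lat)
      phi <- stats::runif(1, -pi, pi)
      d <- ou_offset_path(n_lat, beta_step, sd_step, d0, eps)
      eta <- stats::approx(t_lat, eta0 + d, xout = t, rule = 2)$y
      amp <- config$band_amplitudes[[bd]] *
        (1 + config$modulation_depth * cos(eta))
      # cos(2 pi f t + phi) expanded so the per-band trig is hoisted
      data[c, ] <- data[c, ] +
        amp * (cos(phi) * carrier_cos - sin(phi) * carrier_sin)
    }
  }
  if (config$noise_scale > 0)
    for (c in seq_len(nch))
      data[c, ] <- data[c, ] + config$noise_scale *
        onef_noise(n, fs, config$noise_exponent)
  recording(data, fs, config$channel_labels, intervals = intervals,
            reference_note = sprintf("synthetic (seed %d)", seed))
}

# ---------------------------------------------------------------------------
# Cohorts

#' Cohort configuration for the synthetic generator
#'
#' @param n_per_group named counts for the groups Control, cMDD, pMDD, None.
#' @param base_config [simulation_config()] shared by every participant
#'   (including the control-group coupling rules).
#' @param effect_map named list (group -> list of [coupling_rule()]s) of
#'   group-specific coupling deficits; a rule matching a base rule's channel
#'   set, band and condition replaces it, otherwise it is appended.
#' @param bdi_ranges named list (group -> `c(lo, hi)`) of inclusive BDI
#'   sampling ranges; defaults respect the grouping thresholds (Control <= 7,
#'   depressive groups >= 13).
#' @param seed master seed; per-participant seeds derive deterministically
#'   from it.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(Control = 10, cMDD = 10,
                                          pMDD = 0, None = 0),
                          base_config = simulation_config(),
                          effect_map = list(),
                          bdi_ranges = list(Control = c(0, 7),
                                            cMDD = c(13, 40),
                                            pMDD = c(13, 40),
                                            None = c(13, 40)),
                          seed = 1L) {
  stopifnot(inherits(base_config, "simulation_config"))
  known <- c("Control", "cMDD", "pMDD", "None")
  bad <- setdiff(names(n_per_group), known)
  if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
  full <- stats::setNames(integer(4), known)
  full[names(n_per_group)] <- as.integer(n_per_group)
  for (g in names(effect_map))
    if (full[[g]] == 0L)
      warning("effect configured for empty group '", g, "'")
  structure(list(n_per_group = full, base_config = base_config,
                 effect_map = effect_map, bdi_ranges = bdi_ranges,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default cohort configuration with the canonical biomarker effects
#'
#' Controls carry strong infraslow envelope-phase coupling (kappa = 10, both
#' conditions) over the left frontal + left temporal regions in the theta
#' band and over the two occipital regions in the alpha band, on a weak
#' global baseline (kappa = 1). The cMDD group loses the fronto-temporal
#' theta coupling during eyes closed (kappa = 0), the pMDD group the
#' inter-occipital alpha coupling during eyes open (kappa = 0); outside the
#' deficit condition the affected channels re-couple within a few seconds,
#' so the group difference is condition-specific. Recordings are 4 x 90 s
#' alternating segments (360 s): condition blocks long relative to the
#' infraslow filter's temporal support keep planted deficits
#' condition-specific after filtering.
#'
#' @param n_per_group named group counts.
#' @param seed master seed.
#' @param ... overrides passed to [simulation_config()].
#' @return A `cohort_config`.
#' @export
default_cohort_config <- function(n_per_group = c(Control = 10, cMDD = 10,
                                                  pMDD = 0, None = 0),
                                  seed = 1L, ...) {
  base <- simulation_config(
    condition_schedule = rep(90, 4),
    coupling = list(
      coupling_rule("theta", 10, regions = c("left_frontal", "left_temporal")),
      # the occipital alpha source spans the midline: include POZ/OZ so the
      # surface Laplacian's local mixing does not dilute the coupled group
      coupling_rule("alpha", 10, regions = c("left_occipital", "right_occipital"),
                    channels = c("POZ", "OZ"))),
    ...)
  cohort_config(
    n_per_group = n_per_group, base_config = base,
    effect_map = list(
      cMDD = list(coupling_rule("theta", 0,
                                regions = c("left_frontal", "left_temporal"),
                                condition = "eyes_closed")),
      pMDD = list(coupling_rule("alpha", 0,
                                regions = c("left_occipital", "right_occipital"),
                                channels = c("POZ", "OZ"),
                                condition = "eyes_open"))),
    seed = seed)
}

rule_key <- function(r)
  paste(r$band, paste(sort(unique(c(r$regions, r$channels))), collapse = ","),
        if (is.null(r$condition)) "both" else r$condition, sep = "|")

# subject-level simulation config: base coupling with group effects applied
apply_effect <- function(base_config, rules) {
  if (!length(rules)) return(base_config)
  coupling <- base_config$coupling
  keys <- vapply(coupling, rule_key, character(1))
  for (r in rules) {
    i <- match(rule_key(r), keys)
    if (!is.na(i)) coupling[[i]] <- r
    else { coupling <- c(coupling, list(r)); keys <- c(keys, rule_key(r)) }
  }
  base_config$coupling <- coupling
  base_config
}

#' Participant table of a cohort (without generating signals)
#'
#' @param cohort a `cohort_config`.
#' @return data frame with `participant_id`, `group`, `clinical`, `bdi`,
#'   `seed` (the per-participant recording seed).
#' @export
cohort_participants <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cohort$seed)
  rows <- list()
  i <- 0L
  for (g in names(cohort$n_per_group)) {
    rng <- cohort$bdi_ranges[[g]]
    for (k in seq_len(cohort$n_per_group[[g]])) {
      i <- i + 1L
      rows[[i]] <- data.frame(
        participant_id = sprintf("sub-%03d", i),
        group = g,
        clinical = if (g == "Control") "not_interviewed" else g,
        bdi = sample(seq(rng[1], rng[2]), 1L),
        seed = (cohort$seed %% 100000L) * 10007L + 97L * i,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a recording for one cohort participant
#'
#' @param cohort a `cohort_config`.
#' @param participant one row of [cohort_participants()] (or its index).
#' @return An `eeg_recording`.
#' @export
generate_participant_recording <- function(cohort, participant) {
  if (is.numeric(participant))
    participant <- cohort_participants(cohort)[participant, ]
  cfg <- apply_effect(cohort$base_config,
                      cohort$effect_map[[participant$group]])
  generate_recording(cfg, seed = participant$seed)
}

#' Generate a whole synthetic cohort
#'
#' Materialises every participant's recording. Generation is a pure function
#' of the cohort configuration: per-participant seeds derive from the master
#' seed, and BDI scores are consistent with the group (Control <= 7,
#' depressive groups >= 13).
#'
#' @param cohort a `cohort_config`.
#' @return list with `participants` (data frame) and `recordings` (named
#'   list of `eeg_recording`s, one per participant).
#' @export
generate_cohort <- function(cohort) {
  participants <- cohort_participants(cohort)
  recordings <- lapply(seq_len(nrow(participants)), function(i)
    generate_participant_recording(cohort, participants[i, ]))
  names(recordings) <- participants$participant_id
  list(participants = participants, recordings = recordings)
}
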