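# Recording / montage containers and on-disk formats.

#' Construct a multi-channel recording
#'
#' A recording bundles a channels-by-samples signal matrix with its sampling
#' rate, channel labels and the eyes-closed/eyes-open condition intervals.
#' Units are microvolts for raw scalp potentials and current-source-density
#' units (microV/cm^2-like, unit-sphere convention) after the surface
#' Laplacian.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one unique label per row of `data`.
#' @param intervals data frame of condition intervals with columns `start`,
#'   `end` (seconds) and `condition` (`"eyes_closed"` or `"eyes_open"`), or
#'   `NULL` for none. Intervals must lie within the recording and must not
#'   overlap.
#' @param reference_note free-text provenance note (reference scheme,
#'   transformations applied).
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, fs, channel_labels, intervals = NULL,
                      reference_note = "") {
  data <- as.matrix(data)
  if (!is.numeric(data) || ncol(data) < 1L)
    stop("'data' must be a numeric channels x samples matrix with samples > 0")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop("need one channel label per data row (", nrow(data), " rows, ",
         length(channel_labels), " labels)")
  if (anyDuplicated(channel_labels))
    stop("duplicated channel labels: ",
         paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", "))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a positive scalar sampling rate in Hz")
  dur <- ncol(data) / fs
  intervals <- validate_intervals(intervals, dur)
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 intervals = intervals, reference_note = reference_note),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", format(rec_duration(x), digits = 4),
      " s)\n", sep = "")
  if (nrow(x$intervals) > 0L) {
    tot <- tapply(x$intervals$end - x$intervals$start, x$intervals$condition, sum)
    cat("  conditions:",
        paste(sprintf("%s %.4gs", names(tot), tot), collapse = ", "), "\n")
  } else cat("  conditions: none\n")
  if (nzchar(x$reference_note)) cat("  note:", x$reference_note, "\n")
  invisible(x)
}

rec_duration <- function(rec) ncol(rec$data) / rec$fs

validate_intervals <- function(intervals, duration) {
  if (is.null(intervals))
    return(data.frame(start = numeric(0), end = numeric(0),
                      condition = character(0)))
  intervals <- as.data.frame(intervals)
  stopifnot(all(c("start", "end", "condition") %in% names(intervals)))
  intervals <- intervals[, c("start", "end", "condition")]
  intervals$condition <- as.character(intervals$condition)
  bad <- setdiff(unique(intervals$condition), c("eyes_closed", "eyes_open"))
  if (length(bad))
    stop("unknown condition(s): ", paste(bad, collapse = ", "))
  if (any(intervals$start >= intervals$end))
    stop("intervals must satisfy start < end")
  if (any(intervals$start < -1e-9) || any(intervals$end > duration + 1e-9))
    stop("intervals must lie within [0, ", format(duration), "] s")
  o <- order(intervals$start)
  intervals <- intervals[o, , drop = FALSE]
  if (nrow(intervals) > 1L &&
      any(intervals$start[-1L] < intervals$end[-nrow(intervals)] - 1e-9))
    stop("condition intervals must not overlap")
  rownames(intervals) <- NULL
  intervals
}

# ---------------------------------------------------------------------------
# Montage

# Unit-sphere position: polar angle from the vertex, azimuth clockwise from
# the nose (+y); positive azimuth = right hemisphere, +z = vertex.
.pos <- function(polar_deg, az_deg) {
  p <- polar_deg * pi / 180; a <- az_deg * pi / 180
  c(x = sin(p) * sin(a), y = sin(p) * cos(a), z = cos(p))
}

# spherical linear interpolation between two unit vectors
.slerp <- function(p, q, f) {
  w <- acos(max(-1, min(1, sum(p * q))))
  (sin((1 - f) * w) * p + sin(f * w) * q) / sin(w)
}

build_1010_positions <- function() {
  pos <- list()
  # midline at 18-degree (10%) steps of the nasion-inion arc
  mid <- c(FPZ = 72, AFZ = 54, FZ = 36, FCZ = 18, CZ = 0)
  for (nm in names(mid)) pos[[nm]] <- .pos(mid[[nm]], 0)
  midb <- c(CPZ = 18, PZ = 36, POZ = 54, OZ = 72)
  for (nm in names(midb)) pos[[nm]] <- .pos(midb[[nm]], 180)
  # outer 10% ring (polar 72 deg), 18-degree azimuth steps
  ring <- c(FP1 = -18, FP2 = 18, AF7 = -36, AF8 = 36, F7 = -54, F8 = 54,
            FT7 = -72, FT8 = 72, T7 = -90, T8 = 90, TP7 = -108, TP8 = 108,
            P7 = -126, P8 = 126, PO7 = -144, PO8 = 144, O1 = -162, O2 = 162)
  for (nm in names(ring)) pos[[nm]] <- .pos(72, ring[[nm]])
  # intermediate electrodes on great-circle arcs midline -> outer ring
  arc <- function(from, to, at) .slerp(pos[[from]], pos[[to]], at)
  rows <- list(
    list("FZ",  "F7",  c(F1 = .25, F3 = .5, F5 = .75)),
    list("FZ",  "F8",  c(F2 = .25, F4 = .5, F6 = .75)),
    list("FCZ", "FT7", c(FC1 = .25, FC3 = .5, FC5 = .75)),
    list("FCZ", "FT8", c(FC2 = .25, FC4 = .5, FC6 = .75)),
    list("CZ",  "T7",  c(C1 = .25, C3 = .5, C5 = .75)),
    list("CZ",  "T8",  c(C2 = .25, C4 = .5, C6 = .75)),
    list("CPZ", "TP7", c(CP1 = .25, CP3 = .5, CP5 = .75)),
    list("CPZ", "TP8", c(CP2 = .25, CP4 = .5, CP6 = .75)),
    list("PZ",  "P7",  c(P1 = .25, P3 = .5, P5 = .75)),
    list("PZ",  "P8",  c(P2 = .25, P4 = .5, P6 = .75)),
    list("POZ", "PO7", c(PO3 = 1/3, PO5 = 2/3)),
    list("POZ", "PO8", c(PO4 = 1/3, PO6 = 2/3)),
    list("AFZ", "AF7", c(AF3 = .5)),
    list("AFZ", "AF8", c(AF4 = .5)))
  for (r in rows)
    for (nm in names(r[[3]])) pos[[nm]] <- arc(r[[1]], r[[2]], r[[3]][[nm]])
  do.call(rbind, pos)
}

#' The 60 channels retained for analysis
#'
#' The 64-channel cap minus the four channels outside the standard montage
#' (CB1, CB2, M1, M2).
#'
#' @return character vector of 60 channel labels.
#' @export
analysis_channels <- function() c(
  "FP1", "FPZ", "FP2", "AF3", "AF4",
  "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8",
  "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
  "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8",
  "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
  "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8",
  "O1", "OZ", "O2")

#' Standard 60-channel montage with the 8 scalp regions
#'
#' Positions are standard 10-10 locations on the unit sphere (nose along +y,
#' vertex at +z), built geometrically from the midline and outer-ring arcs.
#' The 8 regions (left/right frontal, temporal, parietal, occipital) contain
#' 9/9/3/3/7/7/4/4 channels.
#'
#' The conventional left-frontal listing repeats F8 (already a right-frontal
#' channel); by default F3 takes its place so that the two frontal regions
#' are symmetric and all regions pairwise disjoint. Set
#' `frontal_fix = FALSE` to keep the duplicated listing.
#'
#' @param frontal_fix logical; replace the spurious left-frontal F8 by F3
#'   (default `TRUE`).
#' @return An object of class `eeg_montage`: list with `positions` (matrix,
#'   channels x 3, unit rows) and `regions` (named list of channel vectors).
#' @export
standard_montage <- function(frontal_fix = TRUE) {
  positions <- build_1010_positions()
  positions <- positions[analysis_channels(), , drop = FALSE]
  lf <- if (frontal_fix) c("FP1", "AF3", "F7", "F5", "F3", "F1", "FC5", "FC3", "FC1")
        else c("FP1", "AF3", "F7", "F5", "F8", "F1", "FC5", "FC3", "FC1")
  regions <- list(
    left_frontal   = lf,
    right_frontal  = c("FP2", "AF4", "F2", "F4", "F6", "F8", "FC2", "FC4", "FC6"),
    left_temporal  = c("FT7", "T7", "TP7"),
    right_temporal = c("FT8", "T8", "TP8"),
    left_parietal  = c("CP5", "CP3", "CP1", "P7", "P5", "P3", "P1"),
    right_parietal = c("CP2", "CP4", "CP6", "P2", "P4", "P6", "P8"),
    left_occipital = c("PO7", "PO5", "PO3", "O1"),
    right_occipital = c("PO4", "PO6", "PO8", "O2"))
  montage(positions, regions)
}

#' Construct a montage
#'
#' @param positions numeric matrix with 3 columns (x, y, z) and channel labels
#'   as row names; rows are normalised to unit length.
#' @param regions named list mapping region names to channel-label vectors;
#'   every region channel must have a position.
#' @return An object of class `eeg_montage`.
#' @export
montage <- function(positions, regions = list()) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L || is.null(rownames(positions)))
    stop("'positions' must be a labelled n x 3 matrix")
  nrm <- sqrt(rowSums(positions^2))
  if (any(nrm == 0)) stop("zero-length position vector")
  positions <- positions / nrm
  for (rg in names(regions)) {
    missing <- setdiff(regions[[rg]], rownames(positions))
    if (length(missing))
      stop("region '", rg, "' references unknown channels: ",
           paste(missing, collapse = ", "))
  }
  structure(list(positions = positions, regions = regions),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", nrow(x$positions), " channels, ",
      length(x$regions), " regions\n", sep = "")
  for (rg in names(x$regions))
    cat(sprintf("  %-16s %s\n", rg, paste(x$regions[[rg]], collapse = ", ")))
  invisible(x)
}

#' All unordered cross-region channel pairs
#'
#' Enumerates every channel pair with one member in each region. For the
#' standard montage this gives e.g. 27 left-frontal/left-temporal pairs and
#' 16 left/right-occipital pairs.
#'
#' @param montage an `eeg_montage`.
#' @param region_a,region_b distinct region names present in the montage.
#' @return data frame with columns `channel_a`, `channel_b`, one row per
#'   unordered pair (deduplicated if the regions share channels).
#' @export
region_channel_pairs <- function(montage, region_a, region_b) {
  for (rg in c(region_a, region_b))
    if (!rg %in% names(montage$regions))
      stop("unknown region: '", rg, "'")
  if (region_a == region_b) stop("region_a and region_b must differ")
  a <- montage$regions[[region_a]]; b <- montage$regions[[region_b]]
  pr <- expand.grid(channel_a = a, channel_b = b, stringsAsFactors = FALSE)
  pr <- pr[pr$channel_a != pr$channel_b, , drop = FALSE]
  key <- ifelse(pr$channel_a < pr$channel_b,
                paste(pr$channel_a, pr$channel_b),
                paste(pr$channel_b, pr$channel_a))
  pr <- pr[!duplicated(key), , drop = FALSE]
  rownames(pr) <- NULL
  pr
}

#' All unordered channel pairs of a label set
#'
#' @param labels character vector of unique channel labels.
#' @return data frame with columns `channel_a`, `channel_b` (choose(n, 2) rows).
#' @export
all_channel_pairs <- function(labels) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicated channel in pair list")
  if (length(labels) < 2L) stop("need at least two channels")
  idx <- utils::combn(length(labels), 2L)
  data.frame(channel_a = labels[idx[1L, ]], channel_b = labels[idx[2L, ]],
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Participant grouping

#' Classify a participant from BDI score and clinical interview
#'
#' Beck Depression Inventory thresholds: a score of 7 or less defines the
#' control group; 13 or higher the depressive-symptoms group, subdivided by
#' the clinical interview into current MDD (cMDD), past MDD (pMDD) or neither
#' (None). Scores 8-12 are left unclassified (no such participants exist in
#' the motivating cohort).
#'
#' @param bdi non-negative integer BDI score(s).
#' @param clinical `"cMDD"`, `"pMDD"`, `"None"` or `"not_interviewed"`
#'   (recycled to the length of `bdi`).
#' @return character vector of group labels: `"Control"`,
#'   `"Depressive-cMDD"`, `"Depressive-pMDD"`, `"Depressive-None"` or
#'   `"Unclassified"`.
#' @export
classify_participant <- function(bdi, clinical = "not_interviewed") {
  if (any(bdi < 0) || any(bdi != round(bdi)))
    stop("'bdi' must be non-negative integer score(s)")
  clinical <- rep_len(as.character(clinical), length(bdi))
  bad <- setdiff(unique(clinical), c("cMDD", "pMDD", "None", "not_interviewed"))
  if (length(bad))
    stop("unknown clinical status: ", paste(bad, collapse = ", "))
  out <- character(length(bdi))
  out[bdi <= 7] <- "Control"
  mid <- bdi >= 8 & bdi <= 12
  out[mid] <- "Unclassified"
  dep <- bdi >= 13
  # not-interviewed depressive participants have no subgroup evidence
  out[dep] <- ifelse(clinical[dep] == "not_interviewed", "Depressive-None",
                     paste0("Depressive-", clinical[dep]))
  out
}

# ---------------------------------------------------------------------------
# Events / participants tables (BIDS-style TSV)

.condition_map <- c(
  EC = "eyes_closed", eyes_closed = "eyes_closed", closed = "eyes_closed",
  EO = "eyes_open", eyes_open = "eyes_open", open = "eyes_open")

#' Read a condition-interval events table
#'
#' Reads a BIDS-style `events.tsv` (columns `onset`, `duration`,
#' `trial_type`, seconds) and returns eyes-closed/eyes-open intervals.
#' Recognised trial types are `EC`/`eyes_closed`/`closed` and
#' `EO`/`eyes_open`/`open` (case-insensitive); unknown types are dropped with
#' a warning. Overlapping or adjacent intervals of the same condition are
#' merged; overlapping intervals of different conditions are an error.
#'
#' @param path path to a tab-separated events file.
#' @return data frame with columns `start`, `end`, `condition`.
#' @export
load_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("onset", "duration", "trial_type") %in% names(ev)))
    stop("events table needs columns onset, duration, trial_type")
  if (nrow(ev) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0),
                      condition = character(0)))
  cond <- .condition_map[match(tolower(ev$trial_type), tolower(names(.condition_map)))]
  names(cond) <- NULL
  unknown <- is.na(cond)
  if (any(unknown)) {
    warning("ignoring ", sum(unknown), " event(s) with unknown trial_type: ",
            paste(unique(ev$trial_type[unknown]), collapse = ", "))
    ev <- ev[!unknown, , drop = FALSE]; cond <- cond[!unknown]
  }
  if (nrow(ev) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0),
                      condition = character(0)))
  iv <- data.frame(start = ev$onset, end = ev$onset + ev$duration,
                   condition = as.character(cond), stringsAsFactors = FALSE)
  merge_condition_intervals(iv)
}

# Merge same-condition overlaps/adjacency; error on cross-condition overlap.
merge_condition_intervals <- function(iv) {
  iv <- iv[order(iv$start), , drop = FALSE]
  out <- iv[0, ]
  for (cd in unique(iv$condition)) {
    sub <- iv[iv$condition == cd, , drop = FALSE]
    st <- sub$start[1]; en <- sub$end[1]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] <= en + 1e-9) en <- max(en, sub$end[i])
      else { out <- rbind(out, data.frame(start = st, end = en, condition = cd)); st <- sub$start[i]; en <- sub$end[i] }
    }
    out <- rbind(out, data.frame(start = st, end = en, condition = cd))
  }
  out <- out[order(out$start), , drop = FALSE]
  if (nrow(out) > 1L) {
    ov <- out$start[-1L] < out$end[-nrow(out)] - 1e-9
    if (any(ov))
      stop("overlapping intervals with different conditions near t = ",
           format(out$start[-1L][ov][1]), " s")
  }
  rownames(out) <- NULL
  out
}

#' Write a condition-interval events table
#'
#' @param intervals data frame with `start`, `end`, `condition`.
#' @param path destination TSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(intervals, path) {
  ev <- data.frame(onset = intervals$start,
                   duration = intervals$end - intervals$start,
                   trial_type = intervals$condition)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a participants table
#'
#' `participants.tsv` has columns `participant_id`, `bdi`, `clinical` and
#' (on write) the derived `group`.
#'
#' @param path TSV path.
#' @return data frame with columns `participant_id`, `bdi`, `clinical`,
#'   `group`.
#' @export
read_participants <- function(path) {
  pt <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("participant_id", "bdi") %in% names(pt)))
    stop("participants table needs columns participant_id, bdi")
  if (is.null(pt$clinical)) pt$clinical <- "not_interviewed"
  pt$group <- classify_participant(pt$bdi, pt$clinical)
  pt
}

#' @rdname read_participants
#' @param participants data frame with at least `participant_id`, `bdi`,
#'   `clinical`.
#' @export
write_participants <- function(participants, path) {
  utils::write.table(participants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Recording on-disk format: <stem>_signal.tsv + <stem>_meta.json +
# <stem>_events.tsv (one recording per stem).

#' Save / load a recording in the internal tabular format
#'
#' The internal format is plain text: `<stem>_signal.tsv` holds the signal
#' (samples in rows, one column per channel, header = labels),
#' `<stem>_meta.json` the sampling rate and reference note, and
#' `<stem>_events.tsv` the condition intervals in BIDS events layout.
#'
#' @param rec an `eeg_recording`.
#' @param stem path stem (no extension) for the three files.
#' @return `save_recording` returns `stem` invisibly; `load_recording`
#'   returns an `eeg_recording`.
#' @export
save_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "eeg_recording"))
  sig <- as.data.frame(t(rec$data))
  names(sig) <- rec$channel_labels
  utils::write.table(sig, paste0(stem, "_signal.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(fs = rec$fs, reference_note = rec$reference_note,
               channel_labels = rec$channel_labels)
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  write_events(rec$intervals, paste0(stem, "_events.tsv"))
  invisible(stem)
}

#' @rdname save_recording
#' @param format `"internal"` (the tabular format above). `"edf"` is
#'   recognised but not supported in this build and raises an informative
#'   error.
#' @param montage optional `eeg_montage`; if supplied, the loaded recording
#'   must contain every montage channel (missing ones are an error listing
#'   the absentees).
#' @param drop_eog drop channels whose label contains "EOG" (with a message).
#' @export
load_recording <- function(stem, format = c("internal", "edf"),
                           montage = NULL, drop_eog = TRUE) {
  format <- match.arg(format)
  if (format == "edf")
    stop("EDF reading is not supported in this build; convert to the ",
         "internal tabular format (see ?save_recording)")
  sigf <- paste0(stem, "_signal.tsv")
  if (!file.exists(sigf)) stop("no such file: ", sigf)
  sig <- utils::read.delim(sigf, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  evf <- paste0(stem, "_events.tsv")
  intervals <- if (file.exists(evf)) load_events(evf) else NULL
  labels <- names(sig)
  if (drop_eog) {
    eog <- grepl("EOG", labels, ignore.case = TRUE)
    if (any(eog)) {
      message("dropping ", sum(eog), " EOG channel(s): ",
              paste(labels[eog], collapse = ", "))
      sig <- sig[, !eog, drop = FALSE]; labels <- labels[!eog]
    }
  }
  if (!is.null(montage)) {
    absent <- setdiff(rownames(montage$positions), labels)
    if (length(absent))
      stop("recording is missing montage channels: ",
           paste(absent, collapse = ", "))
  }
  recording(t(as.matrix(sig)), fs = meta$fs, channel_labels = labels,
            intervals = intervals,
            reference_note = if (is.null(meta$reference_note)) "" else meta$reference_note)
}
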