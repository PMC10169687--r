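# End-to-end orchestration: synthetic cohort (or files) -> M-psi table ->
# region-pair screen -> biomarker -> LOSO discrimination, with artifacts.

#' Pipeline configuration
#'
#' Validates and assembles everything [run_pipeline()] needs. In
#' `"synthetic"` mode a [cohort_config()] drives generation (its master seed
#' makes the run reproducible); in `"files"` mode recordings are loaded from
#' the internal tabular format.
#'
#' @param input `"synthetic"` or `"files"`.
#' @param cohort a `cohort_config` (synthetic mode).
#' @param recording_stems named character vector of path stems (files mode;
#'   names are participant ids).
#' @param participants participants data frame (files mode).
#' @param bands carrier bands to analyse.
#' @param env_bands envelope bands to analyse (the screen uses
#'   `screen_envelope_band`).
#' @param conditions conditions to analyse (must be non-empty).
#' @param contrasts list of length-2 character vectors (experimental,
#'   control), screened in order.
#' @param montage an `eeg_montage` (default [standard_montage()]).
#' @param fs_env decimated envelope rate, Hz.
#' @param trim_margin_s edge trim, seconds.
#' @param csd apply the surface Laplacian.
#' @param q FDR level.
#' @param fdr_family `"region_pair"` or `"global"`.
#' @param screen_envelope_band envelope band used by the screen.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = c("synthetic", "files"),
                            cohort = NULL, recording_stems = NULL,
                            participants = NULL,
                            bands = c("theta", "alpha"),
                            env_bands = "infraslow",
                            conditions = c("eyes_closed", "eyes_open"),
                            contrasts = list(c("cMDD", "Control")),
                            montage = standard_montage(),
                            fs_env = 10, trim_margin_s = 10, csd = TRUE,
                            q = 0.05, fdr_family = "region_pair",
                            screen_envelope_band = "infraslow") {
  input <- match.arg(input)
  if (!length(conditions))
    stop("'conditions' must name at least one condition")
  conditions <- match.arg(conditions, c("eyes_closed", "eyes_open"),
                          several.ok = TRUE)
  bands <- match.arg(bands, names(carrier_bands()), several.ok = TRUE)
  env_bands <- match.arg(env_bands, names(envelope_bands()), several.ok = TRUE)
  if (!screen_envelope_band %in% env_bands)
    stop("screen_envelope_band must be among env_bands")
  if (input == "synthetic") {
    if (!inherits(cohort, "cohort_config"))
      stop("synthetic mode needs a 'cohort' (cohort_config), including its seed")
  } else {
    if (is.null(recording_stems) || is.null(participants))
      stop("files mode needs 'recording_stems' and 'participants'")
  }
  for (ct in contrasts)
    if (length(ct) != 2L) stop("each contrast must have exactly 2 groups")
  structure(list(input = input, cohort = cohort,
                 recording_stems = recording_stems,
                 participants = participants, bands = bands,
                 env_bands = env_bands, conditions = conditions,
                 contrasts = contrasts, montage = montage, fs_env = fs_env,
                 trim_margin_s = trim_margin_s, csd = csd, q = q,
                 fdr_family = fdr_family,
                 screen_envelope_band = screen_envelope_band),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) obtain each participant's recording (generated or loaded),
#' (2) per participant: trim, surface Laplacian, envelope-band phases and
#' pairwise M-psi over every cross-region channel pair, (3) region-pair
#' screen per contrast, (4) biomarker selection, (5) leave-one-subject-out
#' discrimination on the biomarker channel pair. Recordings are processed
#' one at a time (a whole cohort is never held in memory). A stage failure
#' aborts with the stage name and participant id.
#'
#' @param config a [pipeline_config()].
#' @param out_dir if non-NULL, artifacts are written there: `mpsi.csv`,
#'   `screen_<exp>_vs_<ctl>.csv`, `biomarker_<...>.json`,
#'   `discrimination_<...>.json`, `participants.tsv`, `manifest.json`.
#' @param verbose print per-stage progress.
#' @return An object of class `psi_pipeline`: list with `participants`,
#'   `mpsi`, `screens`, `biomarkers`, `discriminations` (per contrast), and
#'   `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  mont <- config$montage
  # channel pairs in scope: every cross-region pair
  regs <- names(mont$regions)
  rp <- utils::combn(regs, 2L)
  pair_list <- lapply(seq_len(ncol(rp)), function(j)
    region_channel_pairs(mont, rp[1L, j], rp[2L, j]))
  pairs <- unique(do.call(rbind, pair_list))
  if (config$input == "synthetic") {
    participants <- cohort_participants(config$cohort)
  } else {
    participants <- config$participants
    if (is.null(participants$participant_id))
      participants$participant_id <- participants$id
  }
  mpsi_parts <- vector("list", nrow(participants))
  for (i in seq_len(nrow(participants))) {
    pid <- participants$participant_id[i]
    if (verbose) message("[mpsi] ", pid)
    rec <- tryCatch({
      if (config$input == "synthetic")
        generate_participant_recording(config$cohort, participants[i, ])
      else
        load_recording(config$recording_stems[[pid]], montage = mont)
    }, error = function(e)
      stop("stage 'input' failed for participant ", pid, ": ",
           conditionMessage(e), call. = FALSE))
    mpsi_parts[[i]] <- tryCatch(
      compute_mpsi(rec, mont, bands = config$bands,
                   env_bands = config$env_bands, fs_env = config$fs_env,
                   pairs = pairs, conditions = config$conditions,
                   trim_margin_s = config$trim_margin_s, csd = config$csd,
                   participant = pid),
      error = function(e)
        stop("stage 'mpsi' failed for participant ", pid, ": ",
             conditionMessage(e), call. = FALSE))
  }
  mpsi <- do.call(rbind, mpsi_parts)
  screens <- list(); biomarkers <- list(); discriminations <- list()
  for (ct in config$contrasts) {
    key <- paste(ct, collapse = "_vs_")
    if (verbose) message("[screen] ", key)
    scr <- region_pair_screen(mpsi, participants, mont, contrast = ct,
                              bands = config$bands,
                              conditions = config$conditions,
                              envelope_band = config$screen_envelope_band,
                              q = config$q, family = config$fdr_family)
    bm <- select_biomarker(scr)
    screens[[key]] <- scr
    biomarkers[[key]] <- bm
    if (isTRUE(bm$found)) {
      vals <- biomarker_values(mpsi, participants, bm)
      discriminations[[key]] <- loso_discriminate(vals$value, vals$group, ct)
    }
  }
  res <- structure(list(participants = participants, mpsi = mpsi,
                        screens = screens, biomarkers = biomarkers,
                        discriminations = discriminations, config = config),
                   class = "psi_pipeline")
  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  res
}

#' Per-subject biomarker values for a selected channel pair
#'
#' @param mpsi M-psi table.
#' @param participants participants data frame.
#' @param biomarker a `biomarker_selection` (found).
#' @return data frame with `participant_id`, `group`, `value`.
#' @export
biomarker_values <- function(mpsi, participants, biomarker) {
  stopifnot(isTRUE(biomarker$found))
  ch <- sort(biomarker$channel_pair)
  sub <- mpsi[pmin(mpsi$channel_a, mpsi$channel_b) == ch[1L] &
                pmax(mpsi$channel_a, mpsi$channel_b) == ch[2L] &
                mpsi$carrier_band == biomarker$carrier_band &
                mpsi$condition == biomarker$condition, , drop = FALSE]
  if (is.null(participants$participant_id))
    participants$participant_id <- participants$id
  grp <- stats::setNames(participants$group, participants$participant_id)
  data.frame(participant_id = sub$participant,
             group = as.character(grp[sub$participant]),
             value = sub$m_psi, stringsAsFactors = FALSE)
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_mpsi(res$mpsi, file.path(out_dir, "mpsi.csv"))
  write_participants(res$participants[, setdiff(names(res$participants), "seed")],
                     file.path(out_dir, "participants.tsv"))
  for (key in names(res$screens)) {
    utils::write.csv(res$screens[[key]]$cells,
                     file.path(out_dir, paste0("screen_", key, ".csv")),
                     row.names = FALSE, quote = FALSE)
    bm <- res$biomarkers[[key]]
    jsonlite::write_json(unclass(bm),
                         file.path(out_dir, paste0("biomarker_", key, ".json")),
                         auto_unbox = TRUE, digits = NA)
    ds <- res$discriminations[[key]]
    if (!is.null(ds))
      jsonlite::write_json(
        list(contrast = ds$contrast, accuracy = ds$accuracy,
             sensitivity = ds$sensitivity, specificity = ds$specificity,
             confusion = as.vector(ds$confusion),
             normalized_confusion = as.vector(normalized_confusion(ds))),
        file.path(out_dir, paste0("discrimination_", key, ".json")),
        auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    package = "eegpsi",
    version = as.character(utils::packageVersion("eegpsi")),
    input = res$config$input,
    seed = if (res$config$input == "synthetic") res$config$cohort$seed else NA,
    bands = res$config$bands, conditions = res$config$conditions,
    n_participants = nrow(res$participants),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.psi_pipeline <- function(x, ...) {
  cat("<psi_pipeline> ", nrow(x$participants), " participants (",
      paste(sprintf("%s: %d", names(table(x$participants$group)),
                    as.integer(table(x$participants$group))),
            collapse = ", "), ")\n", sep = "")
  cat("  M-psi rows: ", nrow(x$mpsi), "\n", sep = "")
  for (key in names(x$biomarkers)) {
    bm <- x$biomarkers[[key]]
    if (isTRUE(bm$found)) {
      cat("  ", key, ": ", bm$region_pair, " / ", bm$carrier_band, " / ",
          bm$condition, ", pair ", paste(bm$channel_pair, collapse = "-"),
          sep = "")
      ds <- x$discriminations[[key]]
      if (!is.null(ds)) cat(sprintf(", LOSO accuracy %.2f", ds$accuracy))
      cat("\n")
    } else cat("  ", key, ": no biomarker found\n", sep = "")
  }
  invisible(x)
}
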