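# Group comparison of M-psi per channel pair, FDR within region pairs,
# significant-pair counting and biomarker selection.

#' One-tailed Wilcoxon rank-sum test
#'
#' No distributional assumption is made on M-psi, so group comparisons use
#' the one-tailed Wilcoxon rank-sum test. The p-value is exact (full
#' enumeration distribution) when the smaller sample has at most 8
#' observations and there are no ties; otherwise the normal approximation
#' with tie and continuity corrections is used. If every value in both
#' samples is identical the test is degenerate and p = 0.5 is returned with
#' a warning.
#'
#' @param x,y numeric samples (non-empty).
#' @param direction `"less"` tests whether `x` is stochastically below `y`;
#'   `"greater"` the reverse.
#' @return the one-tailed p-value.
#' @export
ranksum_one_tailed <- function(x, y, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical in both samples; degenerate test, p = 0.5")
    return(0.5)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && min(length(x), length(y)) <= 8L
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = direction, exact = exact,
                       correct = TRUE)$p.value)
}

#' Benjamini-Hochberg FDR flags
#'
#' Step-up false discovery rate control within one test family: flags are
#' `TRUE` for every p-value at or below the largest `p_(k)` with
#' `p_(k) <= k * q / n`. Flags are monotone in the p-value ranks.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return logical vector of flags, same order as the input (empty input
#'   gives empty flags).
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  if (!length(pvalues)) return(logical(0))
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH") <= q
}

#' Region-pair screen for spatial-correlation disruption
#'
#' For each of the region pairs and each (carrier band, condition) cell,
#' compares M-psi of every cross-region channel pair between an experimental
#' and a control group with one-tailed rank-sum tests in both directions,
#' applies Benjamini-Hochberg FDR within the cell's channel-pair family (per
#' direction) and reports the significant-pair fractions.
#'
#' @param mpsi M-psi table as from [compute_mpsi()] (rows for all
#'   participants of both groups).
#' @param participants data frame with columns `participant_id` (or `id`)
#'   and `group`.
#' @param montage an `eeg_montage` providing the regions.
#' @param contrast length-2 character: (experimental group, control group);
#'   decreases are tested as experimental < control.
#' @param bands,conditions,envelope_band subset of cells to screen
#'   (default: all bands/conditions present in the table, envelope band
#'   `"infraslow"`).
#' @param q FDR level (default 0.05).
#' @param family FDR family: `"region_pair"` (default; one family per
#'   region pair x band x condition x direction) or `"global"` (one family
#'   per direction across the whole screen).
#' @return An object of class `psi_screen`: list with `cells` (one row per
#'   region pair x band x condition: pair counts, significant counts and
#'   fractions in both directions, minimum uncorrected p), `pairs` (per
#'   channel-pair p-values and FDR flags), `contrast`, `q`, `family`.
#' @export
region_pair_screen <- function(mpsi, participants, montage, contrast,
                               bands = NULL, conditions = NULL,
                               envelope_band = "infraslow", q = 0.05,
                               family = c("region_pair", "global")) {
  family <- match.arg(family)
  stopifnot(inherits(montage, "eeg_montage"), length(contrast) == 2L)
  if (is.null(participants$participant_id))
    participants$participant_id <- participants$id
  for (g in contrast) {
    n_g <- sum(participants$group == g)
    if (n_g < 2L)
      stop("group '", g, "' has ", n_g, " participant(s); need >= 2")
  }
  grp <- stats::setNames(participants$group, participants$participant_id)
  mpsi <- mpsi[mpsi$envelope_band == envelope_band &
                 grp[mpsi$participant] %in% contrast, , drop = FALSE]
  if (is.null(bands)) bands <- unique(mpsi$carrier_band)
  if (is.null(conditions)) conditions <- unique(mpsi$condition)
  regions <- names(montage$regions)
  rp <- utils::combn(regions, 2L)
  pair_rows <- list()
  for (j in seq_len(ncol(rp))) {
    ra <- rp[1L, j]; rb <- rp[2L, j]
    prs <- region_channel_pairs(montage, ra, rb)
    for (bd in bands) for (cd in conditions) {
      sub <- mpsi[mpsi$carrier_band == bd & mpsi$condition == cd, ,
                  drop = FALSE]
      # orientation-free pair key so table order does not matter
      key <- paste(pmin(sub$channel_a, sub$channel_b),
                   pmax(sub$channel_a, sub$channel_b))
      idx_by_key <- split(seq_len(nrow(sub)), key)
      p_lo <- p_hi <- numeric(nrow(prs))
      for (k in seq_len(nrow(prs))) {
        want <- paste(min(prs$channel_a[k], prs$channel_b[k]),
                      max(prs$channel_a[k], prs$channel_b[k]))
        rows <- sub[idx_by_key[[want]], , drop = FALSE]
        if (nrow(rows) == 0L)
          stop("M-psi missing for pair ", want, " (", bd, ", ", cd, ")")
        x <- rows$m_psi[grp[rows$participant] == contrast[1L]]
        y <- rows$m_psi[grp[rows$participant] == contrast[2L]]
        if (!length(x) || !length(y))
          stop("M-psi missing for a whole group at pair ", want)
        p_lo[k] <- ranksum_one_tailed(x, y, "less")
        p_hi[k] <- ranksum_one_tailed(x, y, "greater")
      }
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        region_pair = paste(ra, rb, sep = "|"),
        carrier_band = bd, condition = cd,
        channel_a = prs$channel_a, channel_b = prs$channel_b,
        p_lower = p_lo, p_higher = p_hi, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pair_rows)
  if (family == "region_pair") {
    fam <- interaction(pairs$region_pair, pairs$carrier_band,
                       pairs$condition, drop = TRUE)
    pairs$sig_lower <- stats::ave(pairs$p_lower, fam,
                                  FUN = function(p) fdr_bh(p, q)) > 0.5
    pairs$sig_higher <- stats::ave(pairs$p_higher, fam,
                                   FUN = function(p) fdr_bh(p, q)) > 0.5
  } else {
    pairs$sig_lower <- fdr_bh(pairs$p_lower, q)
    pairs$sig_higher <- fdr_bh(pairs$p_higher, q)
  }
  fam <- interaction(pairs$region_pair, pairs$carrier_band, pairs$condition,
                     drop = TRUE, lex.order = TRUE)
  cells <- do.call(rbind, lapply(split(pairs, fam), function(s) data.frame(
    region_pair = s$region_pair[1L], carrier_band = s$carrier_band[1L],
    condition = s$condition[1L], n_pairs = nrow(s),
    n_sig_lower = sum(s$sig_lower), frac_lower = mean(s$sig_lower),
    n_sig_higher = sum(s$sig_higher), frac_higher = mean(s$sig_higher),
    min_p_lower = min(s$p_lower), min_p_higher = min(s$p_higher),
    stringsAsFactors = FALSE)))
  rownames(cells) <- NULL
  structure(list(cells = cells, pairs = pairs, contrast = contrast, q = q,
                 family = family, envelope_band = envelope_band),
            class = "psi_screen")
}

#' @export
print.psi_screen <- function(x, ...) {
  cat("<psi_screen> ", x$contrast[1L], " vs ", x$contrast[2L], ", ",
      nrow(x$cells), " cells (", length(unique(x$cells$region_pair)),
      " region pairs), FDR q = ", x$q, " within ", x$family, "\n", sep = "")
  top <- x$cells[order(-x$cells$frac_lower, x$cells$min_p_lower), ]
  top <- utils::head(top[top$n_sig_lower > 0, , drop = FALSE], 5L)
  if (nrow(top)) {
    cat("  top cells by significant-decrease fraction:\n")
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %-35s %-6s %-12s %d/%d (%.1f%%)\n",
                  top$region_pair[i], top$carrier_band[i], top$condition[i],
                  top$n_sig_lower[i], top$n_pairs[i],
                  100 * top$frac_lower[i]))
  } else cat("  no significant decreases\n")
  invisible(x)
}

#' @export
summary.psi_screen <- function(object, ...) {
  object$cells[order(-object$cells$frac_lower, object$cells$min_p_lower), ]
}

#' Heatmap of significant-pair fractions across region pairs
#'
#' Displays the region x region matrix of significant-pair fractions for one
#' (band, condition, direction) cell of a screen.
#'
#' @param x a `psi_screen`.
#' @param band,condition cell to display.
#' @param direction `"lower"` or `"higher"`.
#' @param ... passed to [graphics::image()].
#' @return the fraction matrix, invisibly.
#' @export
plot.psi_screen <- function(x, band = x$cells$carrier_band[1L],
                            condition = x$cells$condition[1L],
                            direction = c("lower", "higher"), ...) {
  direction <- match.arg(direction)
  cells <- x$cells[x$cells$carrier_band == band &
                     x$cells$condition == condition, , drop = FALSE]
  regs <- unique(unlist(strsplit(cells$region_pair, "|", fixed = TRUE)))
  M <- matrix(NA_real_, length(regs), length(regs),
              dimnames = list(regs, regs))
  fr <- cells[[paste0("frac_", direction)]]
  for (i in seq_len(nrow(cells))) {
    ab <- strsplit(cells$region_pair[i], "|", fixed = TRUE)[[1L]]
    M[ab[1L], ab[2L]] <- M[ab[2L], ab[1L]] <- fr[i]
  }
  op <- graphics::par(mar = c(7, 7, 3, 1)); on.exit(graphics::par(op))
  graphics::image(seq_along(regs), seq_along(regs), M, axes = FALSE,
                  xlab = "", ylab = "",
                  main = paste0(x$contrast[1L], " vs ", x$contrast[2L], ": ",
                                band, ", ", condition, " (", direction, ")"),
                  ...)
  graphics::axis(1, seq_along(regs), regs, las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_along(regs), regs, las = 2, cex.axis = 0.8)
  invisible(M)
}

#' Select the biomarker cell and channel pair
#'
#' The winning cell is the (region pair, band, condition) with the largest
#' significant-pair fraction in the requested direction (ties broken by the
#' smaller minimum uncorrected p); the winning channel pair is the one with
#' the smallest uncorrected p inside that cell.
#'
#' @param screen a `psi_screen`.
#' @param direction `"lower"` (decreases, default) or `"higher"`.
#' @return An object of class `biomarker_selection`: list with `region_pair`,
#'   `carrier_band`, `condition`, `channel_pair`, `p_value`, `frac`,
#'   `direction`, `contrast`; or, when nothing is flagged anywhere, the same
#'   object with `found = FALSE`.
#' @export
select_biomarker <- function(screen, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  stopifnot(inherits(screen, "psi_screen"))
  cells <- screen$cells
  nsig <- cells[[paste0("n_sig_", direction)]]
  if (all(nsig == 0L))
    return(structure(list(found = FALSE, direction = direction,
                          contrast = screen$contrast),
                     class = "biomarker_selection"))
  frac <- cells[[paste0("frac_", direction)]]
  minp <- cells[[paste0("min_p_", direction)]]
  o <- order(-frac, minp)
  win <- cells[o[1L], ]
  sub <- screen$pairs[screen$pairs$region_pair == win$region_pair &
                        screen$pairs$carrier_band == win$carrier_band &
                        screen$pairs$condition == win$condition, , drop = FALSE]
  pv <- sub[[paste0("p_", direction)]]
  best <- sub[which.min(pv), ]
  structure(list(found = TRUE,
                 region_pair = win$region_pair,
                 carrier_band = win$carrier_band,
                 condition = win$condition,
                 channel_pair = c(best$channel_a, best$channel_b),
                 p_value = min(pv), frac = win[[paste0("frac_", direction)]],
                 direction = direction, contrast = screen$contrast),
            class = "biomarker_selection")
}

#' @export
print.biomarker_selection <- function(x, ...) {
  if (!isTRUE(x$found)) {
    cat("<biomarker_selection> no channel pair flagged (", x$contrast[1L],
        " vs ", x$contrast[2L], ")\n", sep = "")
    return(invisible(x))
  }
  cat("<biomarker_selection> ", x$contrast[1L], " vs ", x$contrast[2L],
      ": ", x$region_pair, ", ", x$carrier_band, ", ", x$condition,
      "\n  channel pair ", paste(x$channel_pair, collapse = "-"),
      " (p = ", format(x$p_value, digits = 3), ", cell fraction ",
      sprintf("%.1f%%", 100 * x$frac), ")\n", sep = "")
  invisible(x)
}
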