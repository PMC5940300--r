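# Threshold derivation and cell-cycle classification from per-cell marker
# tables: the Mcm2 x EdU four-state imaging classification and the
# Ki67 x DNA-bound-Mcm2 six-state flow classification, plus labeling
# indices and the stem-vs-TA licensing comparison.

#' Gating configuration
#'
#' @param mcm2_neg_quantile Quantile (in (0,1)) of DNA-bound Mcm2 among
#'   4N-gated cells used as the Mcm2-negative gate: G2 cells carry no bound
#'   MCM2-7, so their bound-Mcm2 signal is the measurement background, and
#'   a cell is licensed only if it exceeds essentially all of it.
#' @param dna_2n_window,dna_4n_window DNA-content windows (1 = 2N) for the
#'   2N and 4N gates.
#' @param s_late_dna_cut DNA content separating the S gate from the late
#'   S/G2/M gate.
#' @param edu_pos_quantile Quantile of EdU among definitively non-S cells
#'   (2N-gated, Mcm2-negative) anchoring the EdU positivity threshold.
#' @param edu_pos_margin Multiplier applied to that control quantile so the
#'   gate sits clearly above the negative distribution (EdU positives are
#'   orders of magnitude brighter than background).
#' @param ki67_low_fraction The Ki67-low threshold is this fraction of the
#'   median Ki67 of 4N-gated (actively cycling) cells.
#' @param total_low_fraction The Mcm2-expression threshold is this fraction
#'   of the median total Mcm2 of 4N-gated cells; below it a cell is
#'   Mcm2-nonexpressing (deep G0).
#' @return An object of class `gating_config`.
#' @export
gating_config <- function(mcm2_neg_quantile = 0.99,
                          dna_2n_window = c(0.8, 1.2),
                          dna_4n_window = c(1.8, 2.2),
                          s_late_dna_cut = 1.6,
                          edu_pos_quantile = 0.99,
                          edu_pos_margin = 3,
                          ki67_low_fraction = 0.5,
                          total_low_fraction = 0.25) {
  stopifnot(
    mcm2_neg_quantile > 0, mcm2_neg_quantile < 1,
    edu_pos_quantile > 0, edu_pos_quantile < 1,
    length(dna_2n_window) == 2L, length(dna_4n_window) == 2L,
    dna_2n_window[1] < dna_2n_window[2],
    dna_4n_window[1] < dna_4n_window[2],
    dna_2n_window[2] <= dna_4n_window[1],  # windows disjoint
    edu_pos_margin >= 1,
    ki67_low_fraction > 0, total_low_fraction > 0
  )
  structure(
    list(
      mcm2_neg_quantile = mcm2_neg_quantile,
      dna_2n_window = dna_2n_window,
      dna_4n_window = dna_4n_window,
      s_late_dna_cut = s_late_dna_cut,
      edu_pos_quantile = edu_pos_quantile,
      edu_pos_margin = edu_pos_margin,
      ki67_low_fraction = ki67_low_fraction,
      total_low_fraction = total_low_fraction
    ),
    class = "gating_config"
  )
}

#' Derive gating thresholds from control populations in the data
#'
#' Resolves the classification thresholds the way a flow operator would:
#' the Mcm2-negative gate from the bound-Mcm2 intensity of 4N (G2) cells,
#' which carry no chromatin-bound MCM2-7; the EdU gate from cells that are
#' certainly not in S phase (2N-gated and Mcm2-negative); and the Ki67-low
#' and Mcm2-expression thresholds as fractions of the 4N population's
#' medians.
#'
#' @param cells Cell table with `dna_content`, `bound_mcm2`, and (for the
#'   corresponding thresholds) `edu`, `ki67`, `total_mcm2` columns.
#' @param config A [gating_config()].
#' @return An object of class `gating_thresholds`: list with `mcm2_neg`,
#'   `edu_pos`, `ki67_low`, `total_low`, the DNA windows, and a
#'   `provenance` character vector describing how each value was derived.
#' @export
derive_thresholds <- function(cells, config = gating_config()) {
  stopifnot(inherits(config, "gating_config"))
  require_columns(cells, c("dna_content", "bound_mcm2"))
  w4 <- config$dna_4n_window
  g2 <- cells$dna_content >= w4[1] & cells$dna_content <= w4[2]
  if (!any(g2)) {
    stop("no cells in the 4N DNA window [", w4[1], ", ", w4[2],
         "]; supply thresholds explicitly or widen the window")
  }
  mcm2_neg <- stats::quantile(cells$bound_mcm2[g2],
                              config$mcm2_neg_quantile, names = FALSE)
  prov <- sprintf(
    "mcm2_neg = %.4g: %.2f quantile of bound_mcm2 among %d 4N-gated cells",
    mcm2_neg, config$mcm2_neg_quantile, sum(g2))

  w2 <- config$dna_2n_window
  edu_pos <- NA_real_
  if ("edu" %in% names(cells)) {
    ctrl <- cells$dna_content >= w2[1] & cells$dna_content <= w2[2] &
      cells$bound_mcm2 <= mcm2_neg
    if (any(ctrl)) {
      edu_pos <- config$edu_pos_margin *
        stats::quantile(cells$edu[ctrl], config$edu_pos_quantile,
                        names = FALSE)
      prov <- c(prov, sprintf(
        "edu_pos = %.4g: %g x %.2f quantile of edu among %d 2N Mcm2-negative cells",
        edu_pos, config$edu_pos_margin, config$edu_pos_quantile, sum(ctrl)))
    }
  }
  ki67_low <- NA_real_
  if ("ki67" %in% names(cells)) {
    ki67_low <- config$ki67_low_fraction *
      stats::median(cells$ki67[g2])
    prov <- c(prov, sprintf(
      "ki67_low = %.4g: %.2f x median ki67 of 4N-gated cells",
      ki67_low, config$ki67_low_fraction))
  }
  total_low <- NA_real_
  if ("total_mcm2" %in% names(cells)) {
    total_low <- config$total_low_fraction *
      stats::median(cells$total_mcm2[g2])
    prov <- c(prov, sprintf(
      "total_low = %.4g: %.2f x median total_mcm2 of 4N-gated cells",
      total_low, config$total_low_fraction))
  }
  structure(
    list(mcm2_neg = mcm2_neg, edu_pos = edu_pos, ki67_low = ki67_low,
         total_low = total_low,
         dna_2n_window = w2, dna_4n_window = w4,
         s_late_dna_cut = config$s_late_dna_cut,
         provenance = prov),
    class = "gating_thresholds"
  )
}

#' @export
print.gating_thresholds <- function(x, ...) {
  cat("Gating thresholds\n")
  for (p in x$provenance) cat(" ", p, "\n")
  cat(sprintf("  DNA windows: 2N [%g, %g], 4N [%g, %g]; S/late-S cut at %g\n",
              x$dna_2n_window[1], x$dna_2n_window[2],
              x$dna_4n_window[1], x$dna_4n_window[2], x$s_late_dna_cut))
  invisible(x)
}

require_columns <- function(cells, cols) {
  missing <- setdiff(cols, names(cells))
  if (length(missing)) {
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Four-state Mcm2 x EdU classification
#'
#' The imaging classification: every cell is assigned by a deterministic
#' 2x2 rule on DNA-bound Mcm2 and EdU positivity (ties at a threshold are
#' negative): (1) unlicensed, Mcm2- EdU- (a composite of G0, unlicensed G1
#' and G2); (2) licensed G1, Mcm2+ EdU-; (3) early/mid S, Mcm2+ EdU+;
#' (4) late S/G2, Mcm2- EdU+.
#'
#' @param cells Cell table with `bound_mcm2` and `edu` columns.
#' @param thresholds A `gating_thresholds` object (or list with `mcm2_neg`
#'   and `edu_pos`).
#' @return A data frame of phase calls: `cell_id` (if present), `called_group`
#'   (factor with levels `UNLICENSED`, `LICENSED_G1`, `S_EARLY_MID`,
#'   `LATE_S_G2`) and `gates_applied`.
#' @export
classify_mcm_edu <- function(cells, thresholds) {
  require_columns(cells, c("bound_mcm2", "edu"))
  mcm_pos <- cells$bound_mcm2 > thresholds$mcm2_neg
  edu_pos <- cells$edu > thresholds$edu_pos
  group <- ifelse(!mcm_pos & !edu_pos, "UNLICENSED",
           ifelse(mcm_pos & !edu_pos, "LICENSED_G1",
           ifelse(mcm_pos & edu_pos, "S_EARLY_MID", "LATE_S_G2")))
  out <- data.frame(
    called_group = factor(group, levels = c("UNLICENSED", "LICENSED_G1",
                                            "S_EARLY_MID", "LATE_S_G2")),
    gates_applied = sprintf("bound_mcm2>%.4g;edu>%.4g",
                            thresholds$mcm2_neg, thresholds$edu_pos),
    stringsAsFactors = FALSE
  )
  if ("cell_id" %in% names(cells)) out <- cbind(cell_id = cells$cell_id, out)
  out
}

six_state_levels <- function() {
  c("G0", "TRANSITION", "UNLICENSED_G1", "LICENSED_G1", "S", "LATE_S_G2M")
}

#' Map ground-truth phases onto the six flow-cytometry states
#'
#' The flow classification cannot separate late S from G2/M, so the truth
#' labels `S_EARLY_MID`, `LATE_S_G2` and `G2M` map to `S` and
#' `LATE_S_G2M`; the G0/G1 states map one to one.
#'
#' @param true_phase Factor or character vector of [phase_levels()] labels.
#' @return Factor with the six flow-state levels.
#' @export
map_phase_to_six <- function(true_phase) {
  m <- c(G0 = "G0", TRANSITION = "TRANSITION",
         UNLICENSED_G1 = "UNLICENSED_G1", LICENSED_G1 = "LICENSED_G1",
         S_EARLY_MID = "S", LATE_S_G2 = "LATE_S_G2M", G2M = "LATE_S_G2M")
  factor(unname(m[as.character(true_phase)]), levels = six_state_levels())
}

#' Six-state cell-cycle classification and population fractions
#'
#' Sequential gating on DNA content, EdU, Ki67 and Mcm2 states:
#' cells at or beyond the S/late-S DNA cut are late S/G2/M; remaining
#' EdU-positive cells are in S phase; among the remaining (2N) cells,
#' Ki67-low cells are G0 (total Mcm2 also low) or in the G0-to-G1
#' transition state (total Mcm2 maintained), and Ki67-high cells are
#' unlicensed or licensed G1 by the Mcm2-negative gate. When no EdU
#' channel is available (`use_edu = FALSE` or column absent) the S gate
#' falls back to DNA content between the 2N window and the late-S cut;
#' early-S cells still inside the 2N DNA window are then indistinguishable
#' from licensed G1.
#'
#' @param cells Cell table with `total_mcm2`, `bound_mcm2`, `ki67`,
#'   `dna_content` (and ideally `edu`).
#' @param thresholds A `gating_thresholds` object.
#' @param use_edu Use the EdU channel for the S gate when present.
#' @return List of class `flow_profile`: `calls` (factor per cell, six
#'   levels), `fractions` (named, sums to 1), `counts`, `n`.
#' @export
gate_flow_profile <- function(cells, thresholds, use_edu = TRUE) {
  require_columns(cells, c("total_mcm2", "bound_mcm2", "ki67",
                           "dna_content"))
  if (nrow(cells) == 0) stop("empty cell table")
  n <- nrow(cells)
  have_edu <- use_edu && "edu" %in% names(cells) &&
    !is.na(thresholds$edu_pos)
  call <- character(n)
  late <- cells$dna_content >= thresholds$s_late_dna_cut
  call[late] <- "LATE_S_G2M"
  if (have_edu) {
    s <- !late & cells$edu > thresholds$edu_pos
  } else {
    s <- !late & cells$dna_content > thresholds$dna_2n_window[2]
  }
  call[s] <- "S"
  rest <- !late & !s
  ki_low <- cells$ki67 <= thresholds$ki67_low
  tot_low <- cells$total_mcm2 <= thresholds$total_low
  call[rest & ki_low & tot_low] <- "G0"
  call[rest & ki_low & !tot_low] <- "TRANSITION"
  lic <- cells$bound_mcm2 > thresholds$mcm2_neg
  call[rest & !ki_low & !lic] <- "UNLICENSED_G1"
  call[rest & !ki_low & lic] <- "LICENSED_G1"
  calls <- factor(call, levels = six_state_levels())
  counts <- table(calls)
  structure(
    list(calls = calls, fractions = as.numeric(counts) / n,
         counts = as.integer(counts), n = n),
    class = "flow_profile"
  )
}

#' @export
print.flow_profile <- function(x, ...) {
  cat(sprintf("Six-state flow profile (%d cells)\n", x$n))
  df <- data.frame(state = six_state_levels(), count = x$counts,
                   fraction = round(x$fractions, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
#' @rdname gate_flow_profile
flow_fractions <- function(x) {
  stats::setNames(x$fractions, six_state_levels())
}

#' Labeling index for a marker channel
#'
#' Fraction of cells whose channel intensity exceeds a threshold, the
#' in-tissue analogue of a labeling index (e.g. the Mcm2 labeling index of
#' extracted vs unextracted crypts).
#'
#' @param cells Cell table.
#' @param channel Column name.
#' @param threshold Positivity threshold (strict inequality).
#' @return List with `index`, `n_positive`, `n_total`.
#' @export
labeling_index <- function(cells, channel, threshold) {
  require_columns(cells, channel)
  if (nrow(cells) == 0) stop("empty cell table")
  pos <- sum(cells[[channel]] > threshold)
  list(index = pos / nrow(cells), n_positive = pos, n_total = nrow(cells))
}

#' Licensing histogram of a cell population's DNA-bound Mcm2
#'
#' Builds the population analogue of the simulator's frequency
#' distribution: DNA-bound Mcm2 intensities of 2N-gated cells, scaled so
#' that full licensing (the `scale_quantile` of the licensed population)
#' is 100%, and distributed into `n_bins` bins. Feeding the result to
#' [detect_unlicensed_peak()] asks whether the population shows the
#' discrete unlicensed-G1 peak.
#'
#' @param cells Cell table with `dna_content` and `bound_mcm2`.
#' @param thresholds A `gating_thresholds` object (for the 2N window).
#' @param n_bins Number of bins (default 101).
#' @param scale_quantile Quantile of 2N bound-Mcm2 mapped to 100%.
#' @return A raw `licensing_histogram`.
#' @export
population_licensing_histogram <- function(cells, thresholds,
                                           n_bins = 101L,
                                           scale_quantile = 0.99) {
  require_columns(cells, c("dna_content", "bound_mcm2"))
  w2 <- thresholds$dna_2n_window
  g1 <- cells$dna_content >= w2[1] & cells$dna_content <= w2[2]
  # cycling, Mcm2-expressing G1 cells only: the unlicensed-vs-licensed
  # question is posed for Ki67+ cells that express Mcm2, not for G0 or
  # transition-state cells
  if ("ki67" %in% names(cells) && !is.na(thresholds$ki67_low)) {
    g1 <- g1 & cells$ki67 > thresholds$ki67_low
  }
  if ("total_mcm2" %in% names(cells) && !is.na(thresholds$total_low)) {
    g1 <- g1 & cells$total_mcm2 > thresholds$total_low
  }
  if (!any(g1)) stop("no cycling cells in the 2N DNA window")
  v <- cells$bound_mcm2[g1]
  top <- stats::quantile(v, scale_quantile, names = FALSE)
  lic <- pmin(1, v / top)
  idx <- floor(lic * (n_bins - 1) + 0.5) + 1L
  out <- new_licensing_histogram(tabulate(idx, nbins = n_bins), n_bins,
                                 "raw")
  # measured background floor on the normalised licensing scale: where
  # unlicensed cells sit (they read the flow background, not zero)
  low <- v[v <= thresholds$mcm2_neg]
  attr(out, "background") <- if (length(low)) {
    stats::median(low) / top
  } else {
    0.02
  }
  out
}

#' Stem vs TA DNA-bound Mcm2 at S entry
#'
#' Ratio of mean DNA-bound Mcm2 between stem-class and TA-class cells just
#' after S entry (ground-truth replicated fraction below `f_max`), the
#' licensing-factor comparison between Lgr5+ and Lgr5- cells.
#'
#' @param cells Cell table from [generate_population()] (needs
#'   `true_phase`, `cell_class`, `replicated_fraction`).
#' @param f_max Maximum replicated fraction defining "earliest S".
#' @return List with `ratio`, `mean_stem`, `mean_ta`, `n_stem`, `n_ta`.
#' @export
s_entry_licensing_ratio <- function(cells, f_max = 0.1) {
  require_columns(cells, c("true_phase", "cell_class", "bound_mcm2",
                           "replicated_fraction"))
  early <- !is.na(cells$replicated_fraction) &
    cells$replicated_fraction < f_max &
    cells$true_phase == "S_EARLY_MID"
  st <- early & cells$cell_class == "stem"
  ta <- early & cells$cell_class == "TA"
  if (!any(st) || !any(ta)) stop("no earliest-S stem or TA cells found")
  ms <- mean(cells$bound_mcm2[st])
  mt <- mean(cells$bound_mcm2[ta])
  list(ratio = ms / mt, mean_stem = ms, mean_ta = mt,
       n_stem = sum(st), n_ta = sum(ta))
}
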