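# Spatial analysis along the crypt-villus axis: distances to the crypt
# base, distance-binned phase composition, most-distal-positive statistics
# and zone comparisons.

#' Euclidean distance of cells to the crypt base
#'
#' @param points Numeric matrix or data frame of 3D coordinates (um), one
#'   row per cell.
#' @param reference Numeric vector of length 3: the base reference point.
#' @return Numeric vector of distances (um).
#' @examples
#' distance_to_base(rbind(c(3, 4, 0)), c(0, 0, 0))  # 5
#' @export
distance_to_base <- function(points, reference = c(0, 0, 0)) {
  points <- as.matrix(points)
  if (ncol(points) != length(reference)) {
    stop("points and reference have mismatched dimensions (",
         ncol(points), " vs ", length(reference), ")")
  }
  if (!all(is.finite(points)) || !all(is.finite(reference))) {
    stop("coordinates must be finite")
  }
  sqrt(colSums((t(points) - reference)^2))
}

#' Phase composition per distance bin along the crypt axis
#'
#' Bins cells into uniform half-open distance bins \[a, b) and reports the
#' fraction of each phase per bin. With a `crypt_id` column, per-crypt
#' fractions are computed first and averaged with equal weight per crypt
#' (with the between-crypt standard deviation reported); otherwise cells
#' are pooled.
#'
#' @param cells Cell table with `dist_to_base` and a phase column.
#' @param bin_width Bin width in um (> 0), default 20.
#' @param phase_col Column holding the phase label (default `called_phase`
#'   if present, else `true_phase`).
#' @return An object of class `crypt_profile`: data frame with `bin_start`,
#'   `bin_end`, `phase`, `fraction`, `n` (cells of that phase in the bin)
#'   and, for multi-crypt input, `sd_between_crypts`.
#' @export
profile_by_distance <- function(cells, bin_width = 20, phase_col = NULL) {
  require_columns(cells, "dist_to_base")
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("bin_width must be > 0")
  }
  if (is.null(phase_col)) {
    phase_col <- if ("called_phase" %in% names(cells)) "called_phase"
    else "true_phase"
  }
  require_columns(cells, phase_col)
  phase <- as.factor(cells[[phase_col]])
  bin <- floor(cells$dist_to_base / bin_width)  # half-open [a, b)
  n_bins <- max(bin) + 1L
  bins <- seq_len(n_bins) - 1L

  per_crypt <- function(ph, b) {
    tab <- table(factor(b, levels = bins), ph)
    tot <- rowSums(tab)
    frac <- sweep(tab, 1, pmax(tot, 1), "/")
    list(frac = frac, counts = tab, tot = tot)
  }
  if ("crypt_id" %in% names(cells)) {
    ids <- unique(cells$crypt_id)
    pcs <- lapply(ids, function(id) {
      sel <- cells$crypt_id == id
      per_crypt(phase[sel], bin[sel])
    })
    fr <- Reduce(`+`, lapply(pcs, `[[`, "frac")) / length(ids)
    counts <- Reduce(`+`, lapply(pcs, `[[`, "counts"))
    sds <- apply(
      simplify2array(lapply(pcs, function(p) as.matrix(p$frac))),
      c(1, 2), stats::sd)
  } else {
    pc <- per_crypt(phase, bin)
    fr <- pc$frac
    counts <- pc$counts
    sds <- NULL
  }
  out <- data.frame(
    bin_start = rep(bins * bin_width, ncol(fr)),
    bin_end = rep((bins + 1L) * bin_width, ncol(fr)),
    phase = rep(colnames(fr), each = n_bins),
    fraction = as.numeric(fr),
    n = as.integer(counts),
    stringsAsFactors = FALSE
  )
  if (!is.null(sds)) out$sd_between_crypts <- as.numeric(sds)
  structure(out, class = c("crypt_profile", "data.frame"),
            bin_width = bin_width, phase_col = phase_col)
}

#' Distance of the most distal marker-positive cell
#'
#' @param cells Cell table with `dist_to_base`.
#' @param channel Channel column name.
#' @param threshold Positivity threshold (strict).
#' @return List with `any_positive` (logical), `distance` (um; NA when no
#'   cell is positive) and `n_positive`.
#' @export
most_distal_positive <- function(cells, channel, threshold) {
  require_columns(cells, c("dist_to_base", channel))
  pos <- cells[[channel]] > threshold
  if (!any(pos)) {
    return(list(any_positive = FALSE, distance = NA_real_, n_positive = 0L))
  }
  list(any_positive = TRUE,
       distance = max(cells$dist_to_base[pos]),
       n_positive = sum(pos))
}

#' Phase composition per crypt zone
#'
#' Splits the crypt axis into zones (half-open \[a, b), default the
#' stem / early-TA / late-TA / differentiated boundaries at 40, 80 and
#' 120 um) and reports phase fractions per zone, optionally restricted to
#' a subset of cells (e.g. UEA-negative stem cells).
#'
#' @param cells Cell table with `dist_to_base` and a phase column.
#' @param zone_breaks Increasing numeric vector of zone boundaries,
#'   starting at 0; the last zone is open-ended.
#' @param subset Optional logical vector selecting the cells to analyse.
#' @param phase_col As in [profile_by_distance()].
#' @return Data frame with `zone_start`, `zone_end`, `phase`, `fraction`,
#'   `n`; empty zones are reported with `n = 0` and `fraction = NA`.
#' @export
zone_composition <- function(cells, zone_breaks = c(0, 40, 80, 120),
                             subset = NULL, phase_col = NULL) {
  require_columns(cells, "dist_to_base")
  if (is.unsorted(zone_breaks, strictly = TRUE) || zone_breaks[1] != 0) {
    stop("zone_breaks must be strictly increasing and start at 0")
  }
  if (!is.null(subset)) cells <- cells[subset, , drop = FALSE]
  if (is.null(phase_col)) {
    phase_col <- if ("called_phase" %in% names(cells)) "called_phase"
    else "true_phase"
  }
  require_columns(cells, phase_col)
  phase <- as.factor(cells[[phase_col]])
  breaks <- c(zone_breaks, Inf)
  zone <- cut(cells$dist_to_base, breaks = breaks, right = FALSE,
              labels = FALSE)
  tab <- table(factor(zone, levels = seq_along(zone_breaks)), phase)
  tot <- rowSums(tab)
  frac <- sweep(tab, 1, pmax(tot, 1), "/")
  frac[tot == 0, ] <- NA_real_
  data.frame(
    zone_start = rep(zone_breaks, ncol(tab)),
    zone_end = rep(c(zone_breaks[-1], Inf), ncol(tab)),
    phase = rep(colnames(tab), each = nrow(tab)),
    fraction = as.numeric(frac),
    n = as.integer(tab),
    stringsAsFactors = FALSE
  )
}
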