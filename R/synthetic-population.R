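# Seeded generator of per-cell marker tables emulating the measured
# structure of intestinal crypt epithelium: an asynchronous cell cycle in
# which most stem cells sit in an unlicensed G1 state, a transit-amplifying
# (TA) zone rich in S-phase cells, twofold higher DNA-bound Mcm2 at S entry
# in stem cells, H2B-GFP dilution by division, and quiescence-depth
# perturbation scenarios.

#' Cell-cycle phase labels used throughout the package
#'
#' Ordered from deepest quiescence to mitosis: deep G0; the transition
#' state between G0 and unlicensed G1 (Ki67 lost before Mcm2); unlicensed
#' G1 (2N DNA, abundant soluble Mcm2 but none bound); licensed G1 (MCM2-7
#' loaded, committed to S entry); early/mid S; late S/G2; G2/M.
#'
#' @export
phase_levels <- function() {
  c("G0", "TRANSITION", "UNLICENSED_G1", "LICENSED_G1",
    "S_EARLY_MID", "LATE_S_G2", "G2M")
}

population_scenarios <- c("homeostasis", "egfr_inhibited", "deep_g0",
                          "apc_mutant", "label_chase")

#' Configuration for the synthetic crypt population generator
#'
#' Builds a validated generator configuration. Calibration constants - the
#' per-zone cell-cycle composition of the cycling lineage, crypt geometry
#' and channel anchors - are read from a JSON calibration file; the package
#' default (`inst/extdata/default_population.json`) encodes a homeostatic
#' crypt in which the stem zone (< 40 um from the base) is dominated by
#' unlicensed-G1 cells, licensed-G1 cells peak at 40-60 um, and the TA zone
#' is rich in S-phase cells.
#'
#' @param n_cells Number of cells to generate.
#' @param scenario One of `"homeostasis"`, `"egfr_inhibited"`, `"deep_g0"`,
#'   `"apc_mutant"`, `"label_chase"`. Scenarios transform the homeostatic
#'   zone composition: EGFR inhibition parks cycling cells in unlicensed G1
#'   (and, from 4 days on, pushes them toward the G0-transition state with
#'   reduced Ki67 but maintained total Mcm2); `deep_g0` adds
#'   Mcm2-negative, Ki67-negative mass; `apc_mutant` removes the
#'   unlicensed-G1 state and lets cells enter S phase at sub-maximal
#'   licensing; `label_chase` adds an H2B-GFP pulse-chase with halving per
#'   division.
#' @param seed Integer seed; the generator is fully deterministic given
#'   config + seed.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise applied to intensity channels (DNA content uses
#'   `dna_noise_cv`). Set to 0 for noise-free ground truth.
#' @param dna_noise_cv CV for the DNA-content channel.
#' @param stem_license_factor Ratio of stem-cell to TA-cell DNA-bound Mcm2
#'   at S entry (default 2: stem cells license about twice as many
#'   origins).
#' @param egfr_days Days of EGFR inhibition for the `egfr_inhibited`
#'   scenario; at 4 or more days mass additionally shifts from unlicensed
#'   G1 into the transition state.
#' @param calibration Path to a JSON calibration file; defaults to the
#'   file shipped with the package.
#' @return An object of class `population_config`.
#' @examples
#' cfg <- population_config(n_cells = 500, seed = 42)
#' cells <- generate_population(cfg)
#' table(cells$true_phase)
#' @export
population_config <- function(n_cells = 10000L,
                              scenario = "homeostasis",
                              seed = 1L,
                              noise_cv = NULL,
                              dna_noise_cv = NULL,
                              stem_license_factor = NULL,
                              egfr_days = 1,
                              calibration = NULL) {
  scenario <- match.arg(scenario, population_scenarios)
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1) {
    stop("n_cells must be >= 1")
  }
  if (is.null(calibration)) {
    calibration <- system.file("extdata", "default_population.json",
                               package = "cryptlicensing", mustWork = TRUE)
  }
  cal <- jsonlite::read_json(calibration, simplifyVector = TRUE)
  zones <- as.data.frame(cal$zones)
  validate_zone_table(zones, cal$crypt_length_um)
  cfg <- list(
    n_cells = as.integer(n_cells),
    scenario = scenario,
    seed = as.integer(seed),
    egfr_days = egfr_days,
    zone_table = zones,
    crypt_length_um = cal$crypt_length_um,
    crypt_radius_um = cal$crypt_radius_um,
    stem_zone_max_um = cal$stem_zone_max_um,
    differentiated_zone_min_um = cal$differentiated_zone_min_um,
    noise_cv = if (is.null(noise_cv)) cal$noise_cv else noise_cv,
    dna_noise_cv = if (is.null(dna_noise_cv)) cal$dna_noise_cv else dna_noise_cv,
    stem_license_factor = if (is.null(stem_license_factor))
      cal$stem_license_factor else stem_license_factor,
    background_level = cal$background_level,
    stem_zone_classes = unlist(cal$stem_zone_classes),
    anchors = cal$channel_anchors,
    division_lambda = unlist(cal$division_lambda)
  )
  stopifnot(cfg$stem_license_factor >= 1, cfg$noise_cv >= 0,
            cfg$dna_noise_cv >= 0)
  structure(cfg, class = "population_config")
}

#' @export
print.population_config <- function(x, ...) {
  cat(sprintf("Synthetic crypt population config: %d cells, scenario '%s', seed %d\n",
              x$n_cells, x$scenario, x$seed))
  cat(sprintf("  crypt length %g um (stem zone < %g um), noise CV %g (DNA %g)\n",
              x$crypt_length_um, x$stem_zone_max_um, x$noise_cv, x$dna_noise_cv))
  cat(sprintf("  stem licensing factor %g\n", x$stem_license_factor))
  invisible(x)
}

validate_zone_table <- function(zones, crypt_length) {
  needed <- c("start", "end", phase_levels())
  missing <- setdiff(needed, names(zones))
  if (length(missing)) {
    stop("zone table is missing columns: ", paste(missing, collapse = ", "))
  }
  zones <- zones[order(zones$start), ]
  if (zones$start[1] != 0 ||
      any(abs(zones$start[-1] - zones$end[-nrow(zones)]) > 1e-9) ||
      abs(zones$end[nrow(zones)] - crypt_length) > 1e-9) {
    stop("zones must tile [0, crypt length] without gaps or overlaps")
  }
  sums <- rowSums(zones[, phase_levels()])
  if (any(abs(sums - 1) > 1e-6)) {
    stop("per-zone phase fractions must sum to 1 (zone starting at ",
         zones$start[which(abs(sums - 1) > 1e-6)[1]], " um does not)")
  }
  invisible(TRUE)
}

# Scenario transforms of the homeostatic zone composition. Each returns a
# zone table whose rows still sum to 1.
apply_scenario <- function(zones, scenario, egfr_days = 1) {
  ph <- phase_levels()
  z <- zones
  if (scenario %in% c("homeostasis", "label_chase")) return(z)
  if (scenario == "egfr_inhibited") {
    # replication and division block: cycling cells finish their cycle and
    # accumulate in unlicensed G1 with Ki67 and total Mcm2 maintained
    cycling <- c("LICENSED_G1", "S_EARLY_MID", "LATE_S_G2", "G2M")
    moved <- 0.7 * rowSums(z[, cycling])
    z[, cycling] <- z[, cycling] * 0.3
    z$UNLICENSED_G1 <- z$UNLICENSED_G1 + moved
    if (egfr_days >= 4) {
      # prolonged inhibition: intermediate G0, Ki67 falls, total Mcm2 kept
      shift <- 0.6 * z$UNLICENSED_G1
      z$UNLICENSED_G1 <- z$UNLICENSED_G1 - shift
      z$TRANSITION <- z$TRANSITION + shift
    }
  } else if (scenario == "deep_g0") {
    # quiescence deepens: Mcm2-negative, Ki67-negative mass appears
    z[, ph] <- z[, ph] * 0.65
    z$G0 <- z$G0 + 0.35
  } else if (scenario == "apc_mutant") {
    # restriction-point loss: cells license immediately on G1 entry and
    # progress into S phase after minimal licensing
    m <- z$UNLICENSED_G1 * 0.95
    z$UNLICENSED_G1 <- z$UNLICENSED_G1 * 0.05
    z$LICENSED_G1 <- z$LICENSED_G1 + 0.55 * m
    z$S_EARLY_MID <- z$S_EARLY_MID + 0.45 * m
  }
  z
}

#' Generate a synthetic crypt cell population
#'
#' Draws `n_cells` cells with ground-truth cell-cycle phase, cell class,
#' 3D crypt position and marker intensities. Noise-free channel rules
#' follow the licensing cell-cycle model: total Mcm2 is expressed in all
#' cycling states and lost only in deep G0; DNA-bound Mcm2 sits at the
#' flow background level in G0, the transition state, unlicensed G1, late
#' S and G2/M, rises toward its per-class maximum during licensed G1, and
#' declines linearly with replicated DNA fraction during S phase from its
#' S-entry value; stem-class cells enter S with `stem_license_factor`
#' times the TA S-entry level. Multiplicative lognormal noise (mean 1) is
#' applied last. The output is byte-identical for identical config + seed.
#'
#' @param config A [population_config()].
#' @return A data frame with one row per cell: `cell_id`, `true_phase`,
#'   `cell_class`, `x`, `y`, `z`, `dist_to_base`, `dna_content`
#'   (1 = 2N, 2 = 4N before noise), `total_mcm2`, `bound_mcm2`, `ki67`,
#'   `edu`, `lgr5`, `h2b_gfp`, `uea_positive`, `divisions_since_label`,
#'   and the ground-truth `replicated_fraction` (NA outside S phase).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  withr::with_seed(config$seed, generate_population_impl(config))
}

generate_population_impl <- function(config) {
  n <- config$n_cells
  ph <- phase_levels()
  zones <- apply_scenario(config$zone_table, config$scenario,
                          config$egfr_days)
  zones <- zones[order(zones$start), ]
  nz <- nrow(zones)

  # cells spread along the axis in proportion to zone width (uniform
  # density per um of crypt surface)
  zone_idx <- sample.int(nz, n, replace = TRUE,
                         prob = zones$end - zones$start)

  # cell class by zone: Paneth and label-retaining cells (LRCs) sit among
  # the stem cells at the base; TA above; differentiated past the TA zone
  in_stem <- zones$end[zone_idx] <= config$stem_zone_max_um
  in_diff <- zones$start[zone_idx] >= config$differentiated_zone_min_um
  cls <- ifelse(in_stem, NA_character_,
                ifelse(in_diff, "differentiated", "TA"))
  if (any(in_stem)) {
    scl <- config$stem_zone_classes
    cls[in_stem] <- sample(names(scl), sum(in_stem), replace = TRUE,
                           prob = scl)
  }

  # ground-truth phase: Paneth cells and LRCs are deeply quiescent; the
  # cycling lineage draws from its zone's composition
  phase <- character(n)
  forced_g0 <- cls %in% c("paneth", "LRC")
  phase[forced_g0] <- "G0"
  for (zi in seq_len(nz)) {
    sel <- which(zone_idx == zi & !forced_g0)
    if (length(sel)) {
      phase[sel] <- sample(ph, length(sel), replace = TRUE,
                           prob = as.numeric(zones[zi, ph]))
    }
  }

  cells <- data.frame(
    cell_id = sprintf("cell_%06d", seq_len(n)),
    true_phase = factor(phase, levels = ph),
    cell_class = cls,
    zone_idx = zone_idx,
    stringsAsFactors = FALSE
  )
  cells <- assign_positions(cells, config)

  a <- config$anchors
  b0 <- config$background_level
  s_late <- a$s_late_boundary

  # per-class DNA-bound Mcm2 at S entry (TA anchor = 1)
  entry_level <- ifelse(cells$cell_class %in% c("stem", "LRC"),
                        config$stem_license_factor, 1)
  # Apc-mutant cells lack the licensing checkpoint and enter S phase with
  # a random sub-maximal complement of licensed origins
  if (config$scenario == "apc_mutant") {
    entry_level <- entry_level * stats::runif(n, 0.2, 1)
  }
  sentry <- pmax(b0, b0 + (entry_level - b0))

  dna <- rep(1, n)
  bound <- rep(b0, n)
  total <- rep(a$total_high, n)
  ki67 <- rep(a$ki67_g1, n)
  edu <- rep(a$edu_negative, n)
  f <- rep(NA_real_, n)

  is_g0 <- phase == "G0"
  total[is_g0] <- a$total_negative
  bound[is_g0] <- a$total_negative
  ki67[is_g0] <- a$ki67_g0

  is_tr <- phase == "TRANSITION"
  ki67[is_tr] <- a$ki67_transition

  is_lic <- phase == "LICENSED_G1"
  if (any(is_lic)) {
    prog <- stats::runif(sum(is_lic), a$licensed_min_progress, 1)
    bound[is_lic] <- b0 + prog * (sentry[is_lic] - b0)
  }

  is_s <- phase == "S_EARLY_MID"
  if (any(is_s)) {
    fs <- stats::runif(sum(is_s), 0, s_late)
    f[is_s] <- fs
    dna[is_s] <- 1 + fs
    bound[is_s] <- b0 + (sentry[is_s] - b0) * (1 - fs / s_late)
    edu[is_s] <- a$edu_positive
    ki67[is_s] <- a$ki67_s
  }

  is_ls <- phase == "LATE_S_G2"
  if (any(is_ls)) {
    fl <- stats::runif(sum(is_ls), s_late, 1)
    f[is_ls] <- fl
    dna[is_ls] <- 1 + fl
    bound[is_ls] <- b0  # MCM2-7 displacement essentially complete
    edu[is_ls] <- a$edu_positive
    ki67[is_ls] <- a$ki67_s
  }

  is_g2m <- phase == "G2M"
  dna[is_g2m] <- 2
  ki67[is_g2m] <- a$ki67_g2m

  total <- pmax(total, bound)  # bound_mcm2 <= total_mcm2 before noise
  total[is_g0] <- a$total_negative

  lgr5 <- rep(a$lgr5_other, n)
  lgr5[cells$cell_class == "stem"] <- a$lgr5_stem
  lgr5[cells$cell_class == "LRC"] <- a$lgr5_lrc

  cells$dna_content <- dna
  cells$total_mcm2 <- total
  cells$bound_mcm2 <- bound
  cells$ki67 <- ki67
  cells$edu <- edu
  cells$lgr5 <- lgr5
  cells$uea_positive <- cells$cell_class == "paneth"
  cells$replicated_fraction <- f
  cells$h2b_gfp <- 0
  cells$divisions_since_label <- 0L

  if (config$scenario == "label_chase") {
    cells <- apply_label_chase(cells,
                               division_lambda = config$division_lambda,
                               initial = a$h2b_initial,
                               noise_cv = 0)  # channel noise applied below
  }

  noisy <- function(x, cv) {
    if (cv <= 0) return(x)
    sdlog <- sqrt(log(1 + cv^2))
    x * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  for (col in c("total_mcm2", "bound_mcm2", "ki67", "edu", "lgr5",
                "h2b_gfp")) {
    cells[[col]] <- noisy(cells[[col]], config$noise_cv)
  }
  cells$dna_content <- noisy(cells$dna_content, config$dna_noise_cv)
  cells$zone_idx <- NULL
  cells
}

#' Place cells on the crypt surface according to their zone
#'
#' The crypt is modelled as a cylinder of radius `crypt_radius_um` rising
#' from the base reference point at the origin. Each cell receives a
#' target distance drawn uniformly within its assigned zone's range; cells
#' whose distance is below the cylinder radius sit on the bottom rim. By
#' construction the Euclidean distance of every cell to the base equals
#' its target, so realised per-zone counts equal the assigned memberships
#' exactly.
#'
#' @param cells Data frame with a `zone_idx` column indexing rows of the
#'   config's (scenario-transformed) zone table.
#' @param config A [population_config()].
#' @return `cells` with `x`, `y`, `z` (um) and `dist_to_base` added.
#' @export
assign_positions <- function(cells, config) {
  stopifnot(inherits(config, "population_config"),
            "zone_idx" %in% names(cells))
  zones <- apply_scenario(config$zone_table, config$scenario,
                          config$egfr_days)
  zones <- zones[order(zones$start), ]
  validate_zone_table(zones, config$crypt_length_um)
  n <- nrow(cells)
  d <- stats::runif(n, zones$start[cells$zone_idx],
                    zones$end[cells$zone_idx])
  theta <- stats::runif(n, 0, 2 * pi)
  r <- config$crypt_radius_um
  on_wall <- d >= r
  rad <- ifelse(on_wall, r, d)
  cells$x <- rad * cos(theta)
  cells$y <- rad * sin(theta)
  cells$z <- ifelse(on_wall, sqrt(pmax(0, d^2 - r^2)), 0)
  cells$dist_to_base <- d
  cells
}

#' Dilute an H2B-GFP pulse label by cell division
#'
#' Sets the H2B-GFP channel to `initial * 0.5^divisions_since_label`:
#' chromatin-incorporated label halves at every division during the chase.
#' Paneth cells and label-retaining cells (LRCs) do not divide during the
#' chase and keep the full label; other classes draw their division count
#' from a Poisson distribution with a per-class mean.
#'
#' @param cells Cell table from [generate_population()] (any scenario).
#' @param division_lambda Named vector of Poisson means for divisions
#'   during the chase, by cell class; classes not named keep 0 divisions.
#' @param divisions Optional explicit nonnegative integer vector of
#'   divisions per cell, overriding the Poisson draw.
#' @param initial Label intensity at the start of the chase (> 0).
#' @param noise_cv CV of multiplicative lognormal noise applied to the
#'   diluted label (0 = none).
#' @return `cells` with `h2b_gfp` and `divisions_since_label` updated.
#' @export
apply_label_chase <- function(cells,
                              division_lambda = c(stem = 2, TA = 5,
                                                  differentiated = 5),
                              divisions = NULL,
                              initial = 1,
                              noise_cv = 0) {
  stopifnot(initial > 0)
  n <- nrow(cells)
  if (is.null(divisions)) {
    lambda <- rep(0, n)
    for (cl in names(division_lambda)) {
      lambda[cells$cell_class == cl] <- division_lambda[[cl]]
    }
    lambda[cells$cell_class %in% c("paneth", "LRC")] <- 0
    divisions <- stats::rpois(n, lambda)
  }
  if (any(divisions < 0)) stop("divisions must be nonnegative")
  cells$divisions_since_label <- as.integer(divisions)
  h2b <- initial * 0.5^cells$divisions_since_label
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    h2b <- h2b * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  cells$h2b_gfp <- h2b
  cells
}
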