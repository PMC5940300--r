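# CSV readers/writers for cell tables and licensing histograms, plus run
# manifests. CSV is the interchange format; column schemas are documented
# here and in the README.

cell_table_required_cols <- c("cell_id", "dist_to_base", "dna_content",
                              "total_mcm2", "bound_mcm2", "ki67", "edu")
cell_table_numeric_cols <- c("dist_to_base", "dna_content", "total_mcm2",
                             "bound_mcm2", "ki67", "edu", "lgr5",
                             "h2b_gfp", "x", "y", "z",
                             "replicated_fraction")

#' Read a per-cell marker table from CSV
#'
#' Validates the documented schema: required columns `cell_id`,
#' `dist_to_base`, `dna_content`, `total_mcm2`, `bound_mcm2`, `ki67`,
#' `edu`; optional columns (`true_phase`, `cell_class`, `x`, `y`, `z`,
#' `lgr5`, `h2b_gfp`, `uea_positive`, `divisions_since_label`,
#' `replicated_fraction`, `crypt_id`, ...) are preserved. Intensity
#' columns must be numeric; offending rows are reported by line number.
#'
#' @param path CSV file path.
#' @return The validated cell table (data frame); row count reported via
#'   message.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cell_table_required_cols, names(cells))
  if (length(missing)) {
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in intersect(cell_table_numeric_cols, names(cells))) {
    v <- cells[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "NA" & v != "")
      if (length(bad)) {
        stop("non-numeric value in column '", col, "' at data row(s) ",
             paste(utils::head(bad, 5), collapse = ", "),
             " (file line ", bad[1] + 1L, ")")
      }
      cells[[col]] <- num
    }
  }
  if ("true_phase" %in% names(cells)) {
    cells$true_phase <- factor(cells$true_phase, levels = phase_levels())
  }
  if ("uea_positive" %in% names(cells)) {
    cells$uea_positive <- as.logical(cells$uea_positive)
  }
  message(nrow(cells), " cells read from ", path)
  cells
}

#' Write a per-cell marker table to CSV
#'
#' @param cells Cell table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a licensing histogram as CSV
#'
#' Columns: `bin_center_percent`, `count`, `stage`. The round trip is
#' lossless to full double precision (counts are written with 17
#' significant digits).
#'
#' @param hist A `licensing_histogram`.
#' @param path CSV path.
#' @return `path` invisibly (write); a `licensing_histogram` (read).
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "licensing_histogram"))
  df <- data.frame(
    bin_center_percent = hist$bin_centers,
    count = format(hist$counts, digits = 17, scientific = TRUE,
                   trim = TRUE),
    stage = hist$stage
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_histogram
#' @export
read_histogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("bin_center_percent", "count", "stage")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("histogram file is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  stage <- unique(df$stage)
  if (length(stage) != 1L ||
      !stage %in% c("raw", "background_adjusted", "smoothed")) {
    stop("unrecognized histogram stage: ", paste(stage, collapse = ", "))
  }
  new_licensing_histogram(as.numeric(df$count), nrow(df), stage)
}

#' Write a run manifest
#'
#' Records the tool version, the full parameter set, input/output paths,
#' seeds and a timestamp as JSON, sufficient to re-run deterministic
#' stages bit-identically.
#'
#' @param path Output JSON path.
#' @param stage Pipeline stage name (e.g. "simulate", "generate").
#' @param params Named list of all parameters of the run.
#' @param inputs,outputs Character vectors of file paths.
#' @param seed Integer seed(s) used, if any.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, stage, params, inputs = character(),
                               outputs = character(), seed = NULL) {
  manifest <- list(
    tool = "cryptlicensing",
    version = as.character(utils::packageVersion("cryptlicensing")),
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params,
    inputs = inputs,
    outputs = outputs,
    seed = seed
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

#' Read a generator/fit configuration file (JSON or YAML)
#'
#' @param path File path ending in .json, .yaml or .yml.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    stop("unsupported config format: .", ext)
  }
}
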