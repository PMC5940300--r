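#' Parameters of the deterministic G1 licensing model
#'
#' Bundles and validates the knobs of the G1 origin-licensing simulator.
#' Time is measured in units of the minimum G1 period: a `rate` of 1 means a
#' cell becomes fully licensed in exactly the minimum G1 period, and an
#' `unlicensed_fraction` of 0.5 means licensing is paused for the first half
#' of that period after G1 entry.
#'
#' @param rate Positive number. Fraction of full licensing achieved per one
#'   minimum-G1 duration.
#' @param unlicensed_fraction Nonnegative number. Duration of the initial
#'   no-licensing pause, in minimum-G1 units.
#' @param checkpoint_threshold Number in (0, 1]. Licensing fraction a cell
#'   must reach before S entry is permitted. 1 is a robust licensing
#'   checkpoint; values below 1 model checkpoint loss (e.g. Apc-mutant
#'   epithelium, where cells enter S phase after minimal licensing).
#' @param n_steps Positive integer. Number of equal time steps the minimum
#'   G1 period is divided into.
#' @param background Number in [0, 1). Additive licensing offset modelling
#'   the background signal recorded by flow cytometry (0.05 = +5 percentage
#'   points).
#' @param push_fraction Number in [0, 1). Fraction of bin counts pushed to
#'   the neighbouring bin per smoothing pass, modelling measurement error.
#' @param n_bins Integer >= 2. Number of histogram bins from 0 (no
#'   licensing) to 100% (maximal licensing).
#'
#' @return An object of class `licensing_params` (a validated list).
#' @examples
#' p <- licensing_params(rate = 2, unlicensed_fraction = 0.25)
#' p
#' @export
licensing_params <- function(rate = 1,
                             unlicensed_fraction = 0,
                             checkpoint_threshold = 1,
                             n_steps = 10000L,
                             background = 0.05,
                             push_fraction = 0.8,
                             n_bins = 101L) {
  stopifnot(
    "rate must be a single positive number" =
      is.numeric(rate) && length(rate) == 1L && is.finite(rate) && rate > 0,
    "unlicensed_fraction must be a single nonnegative number" =
      is.numeric(unlicensed_fraction) && length(unlicensed_fraction) == 1L &&
        is.finite(unlicensed_fraction) && unlicensed_fraction >= 0,
    "checkpoint_threshold must be in (0, 1]" =
      is.numeric(checkpoint_threshold) && length(checkpoint_threshold) == 1L &&
        checkpoint_threshold > 0 && checkpoint_threshold <= 1,
    "n_steps must be a positive integer" =
      is.numeric(n_steps) && length(n_steps) == 1L && n_steps >= 1 &&
        n_steps == as.integer(n_steps),
    "background must be in [0, 1)" =
      is.numeric(background) && length(background) == 1L &&
        background >= 0 && background < 1,
    "push_fraction must be in [0, 1)" =
      is.numeric(push_fraction) && length(push_fraction) == 1L &&
        push_fraction >= 0 && push_fraction < 1,
    "n_bins must be an integer >= 2" =
      is.numeric(n_bins) && length(n_bins) == 1L && n_bins >= 2 &&
        n_bins == as.integer(n_bins)
  )
  structure(
    list(
      rate = as.numeric(rate),
      unlicensed_fraction = as.numeric(unlicensed_fraction),
      checkpoint_threshold = as.numeric(checkpoint_threshold),
      n_steps = as.integer(n_steps),
      background = as.numeric(background),
      push_fraction = as.numeric(push_fraction),
      n_bins = as.integer(n_bins)
    ),
    class = "licensing_params"
  )
}

#' @export
print.licensing_params <- function(x, ...) {
  cat("G1 licensing model parameters\n")
  cat(sprintf("  rate:                 %g (1 = fully licensed in one minimum G1)\n", x$rate))
  cat(sprintf("  unlicensed_fraction:  %g minimum-G1 units\n", x$unlicensed_fraction))
  cat(sprintf("  checkpoint_threshold: %g\n", x$checkpoint_threshold))
  cat(sprintf("  n_steps: %d   n_bins: %d\n", x$n_steps, x$n_bins))
  cat(sprintf("  background: %g   push_fraction: %g\n", x$background, x$push_fraction))
  cat(sprintf("  G1 exit time: %g minimum-G1 units\n", g1_exit_time(x)))
  invisible(x)
}

# Time of G1 exit in minimum-G1 units: a cell leaves G1 only once it is
# licensed to the checkpoint threshold AND the minimum G1 period has elapsed.
g1_exit_time <- function(params) {
  max(1, params$unlicensed_fraction +
        params$checkpoint_threshold / params$rate)
}
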