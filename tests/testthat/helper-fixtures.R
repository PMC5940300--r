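# Shared fixtures: small populations are generated once per test run.

small_population <- function(n = 4000, scenario = "homeostasis", seed = 101,
                             ...) {
  generate_population(population_config(n_cells = n, scenario = scenario,
                                        seed = seed, ...))
}

# Independent interval-based binning oracle: on the 0..(n_bins-1) scale,
# bin j (0-based) collects samples in [j - 0.5, j + 0.5), the top bin up
# to and including the maximum.
oracle_bin_counts <- function(samples, n_bins) {
  x <- samples * (n_bins - 1)
  vapply(seq_len(n_bins) - 1L, function(j) {
    if (j == n_bins - 1L) sum(x >= j - 0.5 & x <= j)
    else sum(x >= j - 0.5 & x < j + 0.5)
  }, numeric(1))
}

# Independent closed-form oracle for the sequential push smoothing: during
# the forward pass, mass pushed out of bin i reaches bin i+1 before that
# bin is visited, so a unit of mass starting at bin i ends the pass at bin
# k >= i with weight (1-p) p^(k-i), all residual mass piling into the top
# bin; the backward pass is the mirror image.
oracle_smooth <- function(counts, p) {
  n <- length(counts)
  pass_up <- function(x) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      if (i < n) {
        for (k in i:(n - 1)) out[k] <- out[k] + x[i] * (1 - p) * p^(k - i)
      }
      out[n] <- out[n] + x[i] * p^(n - i)
    }
    out
  }
  rev(pass_up(rev(pass_up(counts))))
}
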