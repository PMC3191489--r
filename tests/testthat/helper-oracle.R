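# Independent numerical oracle for the hypoexponential density: the d-fold
# convolution of exponential densities computed by nested adaptive
# Gauss-Kronrod quadrature (never via the closed form under test).
conv_exp_density <- function(x, mu) {
  stopifnot(length(x) == 1)
  if (x < 0) return(0)
  if (length(mu) == 1) return(stats::dexp(x, rate = 1 / mu))
  integrand <- function(u) {
    vapply(u, function(ui) conv_exp_density(x - ui, mu[-1]), numeric(1)) *
      stats::dexp(u, rate = 1 / mu[1])
  }
  pracma::quadgk(integrand, 0, x, tol = 1e-12)
}

# Build a small long-format trace tibble by hand.
make_trace <- function(counts, frame_interval = 60, start = 60,
                       division = rep(0L, length(counts)), cell_id = 1L) {
  tibble::tibble(
    cell_id = cell_id,
    frame_time_s = start + (seq_along(counts) - 1) * frame_interval,
    rna_count = as.integer(counts),
    division = as.integer(division)
  )
}
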