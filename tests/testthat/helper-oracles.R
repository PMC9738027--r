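# Independent numerical oracles used to freeze expected values.

# Composite Simpson quadrature of an arbitrary function (independent of
# the package's quadrature code paths).
oracle_simpson <- function(f, a, b, n = 4001L) {
  x <- seq(a, b, length.out = n)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  sum(w * f(x)) * (x[2] - x[1]) / 3
}

# Homogeneous NHPP log-likelihood with rate r on [0, L] given n sites.
oracle_homog_ll <- function(r, L, n) -r * L + n * log(r)

# All ways to split n items into two labelled non-empty groups.
oracle_bipartitions <- function(n) {
  out <- list()
  for (code in 1:(2^n - 2)) {
    out[[length(out) + 1]] <- as.integer(intToBits(code))[seq_len(n)] + 1L
  }
  out
}

# Quick homogeneous path of n uniform sites.
runif_path <- function(n, region = c(0, 10)) {
  sort(stats::runif(n, region[1], region[2]))
}

fast_fit <- function(n_freq = 4) {
  fit_control(n_freq = n_freq, n_restarts = 1, grid_n = 201)
}
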