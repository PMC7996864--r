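# shared fixtures, built in code at test time

# offsets that include the exact points +-1.0 and the GAG band samples,
# so formula-level checks avoid interpolation
dense_offsets <- function(step = 0.25) seq(-3, 3, by = step)

default_pool <- function(gag = 0.03) pool_model(gag_amplitude = gag)

# a noiseless phantom acquisition shared across expensive tests
noiseless_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_phantom(phantom_scene(), acquisition_spec(noise_sd = 0))
    }
    cache
  }
})

# independent brute-force grid search for the symmetry centre of a spectrum
grid_argmin_center <- function(spectrum, halfwidth = 0.4, step = 0.002) {
  grid <- seq(-halfwidth, halfwidth, by = step)
  costs <- vapply(grid, function(d) symmetry_cost(spectrum, d), numeric(1))
  grid[which.min(costs)]
}

# tie-corrected Kruskal-Wallis H computed from first principles (rank sums),
# independent of stats::kruskal.test
brute_force_kw_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tapply(r, g, length)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
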