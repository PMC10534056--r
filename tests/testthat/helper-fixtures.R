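# shared fixtures and independent oracles

NWK4 <- "((A:1,B:1):2,(C:2.5,D:2.5):0.5);"
tree4 <- function() read_newick(NWK4)

# dense grid-search maximiser of the logistic location-scale log-likelihood,
# independent of the package's optim-based fitter
grid_logistic_mle <- function(H, a_range, b_range, steps = 3L, pts = 121L) {
  ll <- function(a, b) sum(stats::dlogis(H, a, b, log = TRUE))
  for (s in seq_len(steps)) {
    as <- seq(a_range[1], a_range[2], length.out = pts)
    bs <- seq(b_range[1], b_range[2], length.out = pts)
    grid <- expand.grid(a = as, b = bs)
    vals <- mapply(ll, grid$a, grid$b)
    best <- grid[which.max(vals), ]
    da <- diff(a_range) / (pts - 1)
    db <- diff(b_range) / (pts - 1)
    a_range <- c(best$a - 2 * da, best$a + 2 * da)
    b_range <- c(max(best$b - 2 * db, 1e-8), best$b + 2 * db)
  }
  list(a = best$a, b = best$b)
}

# one randomly chosen depth per tree, so pooled values are i.i.d. across
# replicates and two-sample KS tests are valid
one_depth_per_tree <- function(draw, reps) {
  vapply(seq_len(reps), function(i) {
    d <- draw()
    d[sample.int(length(d), 1L)]
  }, numeric(1))
}

# forward-simulation oracle: depth draws from uniform n-samples of surviving
# birth-death populations, conditioned on N_T >= n
forward_depth_draws <- function(params, keep, max_pop = 1e4) {
  out <- numeric(keep)
  got <- 0L
  while (got < keep) {
    sim <- forward_simulate(params, max_pop = max_pop)
    if (sim$N_T >= params$n) {
      d <- forward_coal_depths(sim, n = params$n)$depths
      got <- got + 1L
      out[got] <- d[sample.int(length(d), 1L)]
    }
  }
  out
}
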