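test_that("approximate sampler reproduces the plug-in formula and moments", {
  p <- bd_params(lambda = 1, mu = 0, T = 20, n = 50)
  forced <- sample_coal_times_approx(p, W = 1, U = 0)
  expect_equal(forced$depths, rep(20 - log(50), 49))

  # marginal moments: E[H] = T - (log n + gamma)/r, Var[H] = (pi^2/2)/r^2
  set.seed(101)
  gamma_em <- -digamma(1)
  draws <- one_depth_per_tree(function() sample_coal_times_approx(p)$depths,
                              40000L)
  expect_equal(mean(draws), 20 - (log(50) + gamma_em), tolerance = 0.005)
  expect_equal(var(draws), pi^2 / 2, tolerance = 0.05)
})

test_that("approximate sampler spread scales as 1/r with matched seeds", {
  p1 <- bd_params(1.0, 0, T = 20, n = 30)
  p2 <- bd_params(2.0, 0, T = 20, n = 30)
  d1 <- sample_coal_times_approx(p1, seed = 5)$depths
  d2 <- sample_coal_times_approx(p2, seed = 5)$depths
  expect_equal(20 - d2, (20 - d1) / 2)
})

test_that("shared W induces one tree-level shift, logistic residuals i.i.d.", {
  # with U forced to 0 all depths in one tree are identical (the W shift);
  # across trees the shift is Exp(1)-distributed on the log scale
  p <- bd_params(1, 0, T = 30, n = 40)
  set.seed(8)
  shifts <- replicate(5000, {
    d <- sample_coal_times_approx(p, U = 0)$depths
    expect_equal(max(d) - min(d), 0)
    30 - d[1] - log(40)   # = log(1/W)
  })
  ks <- ks.test(exp(-shifts), "pexp")
  expect_gt(ks$p.value, 0.01)
})

test_that("exact sampler matches the forward-simulation oracle (KS)", {
  p <- bd_params(lambda = 1.5, mu = 0.5, T = 5, n = 5)
  set.seed(202)
  fw <- forward_depth_draws(p, keep = 500L)
  ex <- one_depth_per_tree(function() sample_coal_times_exact(p)$depths, 3000L)
  ks <- ks.test(ex, fw)
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(ex), mean(fw), tolerance = 0.1)
})

test_that("exact sampler depths lie strictly inside (0, T)", {
  set.seed(3)
  for (p in list(bd_params(1.5, 0.5, T = 5, n = 10),
                 bd_params(1, 0.5, T = 40, n = 100),
                 bd_params(0.6, 0.1, T = 40, n = 200),
                 bd_params(2, 0, T = 3, n = 25))) {
    for (i in 1:20) {
      d <- sample_coal_times_exact(p)$depths
      expect_length(d, p$n - 1L)
      expect_true(all(d > 0 & d < p$T))
    }
  }
})

test_that("exact sampler converges to the logistic approximation when n e^{-rT} is tiny", {
  p <- bd_params(1, 0.5, T = 40, n = 100)  # n exp(-rT) ~ 2e-7
  set.seed(404)
  ex <- one_depth_per_tree(function() sample_coal_times_exact(p)$depths, 3000L)
  ap <- one_depth_per_tree(function() sample_coal_times_approx(p)$depths, 3000L)
  ks <- ks.test(ex, ap)
  expect_gt(ks$p.value, 0.01)
})

test_that("exact sampler is scale equivariant with matched seeds", {
  # multiplying lambda, mu by c and dividing T by c rescales depths by 1/c
  p1 <- bd_params(1.2, 0.7, T = 24, n = 30)
  p2 <- bd_params(2.4, 1.4, T = 12, n = 30)
  d1 <- sample_coal_times_exact(p1, seed = 99)$depths
  d2 <- sample_coal_times_exact(p2, seed = 99)$depths
  expect_equal(d2, d1 / 2, tolerance = 1e-12)
})

test_that("CPP construction is the deterministic inverse of coalescence depths", {
  tr <- build_tree_cpp(coal_times(c(1, 2.5), T = 3))
  expect_true(check_ultrametric(tr)$pass)
  expect_equal(sort(branch_length_totals(tr)$internal_total), 1.5)
  expect_equal(sort(tr$edge.length[tr$edge[, 2] <= 3]), c(1, 1, 2.5))

  cherry <- build_tree_cpp(coal_times(1, T = 2))
  expect_equal(cherry$edge.length, c(1, 1))

  set.seed(11)
  for (i in 1:200) {
    H <- runif(sample(2:40, 1), 0.01, 10)
    got <- coalescence_depths(build_tree_cpp(coal_times(H)))
    expect_equal(sort(got$depths), sort(H))
  }
})

test_that("random merge preserves the depth multiset for every seed", {
  H <- c(1, 2.5)
  for (s in 1:10) {
    tr <- build_tree_random_merge(coal_times(H, T = 3), seed = s)
    expect_true(check_ultrametric(tr)$pass)
    expect_equal(sort(coalescence_depths(tr)$depths), H)
  }
})

test_that("random merge picks the first merging pair uniformly", {
  coal <- coal_times(c(1, 2), T = 3)
  set.seed(33)
  pair <- replicate(3000, {
    tr <- build_tree_random_merge(coal)
    d <- coalescence_depths(tr)
    # the cherry at depth 1 identifies the merged pair
    mrca12 <- ape::getMRCA(tr, c("t1", "t2"))
    h <- ape::node.depth.edgelength(tr)
    depth12 <- max(h[1:3]) - h[mrca12]
    mrca13 <- ape::getMRCA(tr, c("t1", "t3"))
    if (abs(depth12 - 1) < 1e-9) "12"
    else if (abs(max(h[1:3]) - h[mrca13] - 1) < 1e-9) "13" else "23"
  })
  freqs <- table(pair) / 3000
  expect_equal(length(freqs), 3L)
  expect_true(all(abs(freqs - 1 / 3) < 0.04))
})

test_that("CPP and random-merge trees are statistically equivalent", {
  p <- bd_params(1, 0.5, T = 40, n = 20)
  set.seed(55)
  int_cpp <- replicate(1200, {
    branch_length_totals(build_tree_cpp(sample_coal_times_exact(p)))$internal_total
  })
  int_rm <- replicate(1200, {
    branch_length_totals(build_tree_random_merge(sample_coal_times_exact(p)))$internal_total
  })
  expect_gt(ks.test(int_cpp, int_rm)$p.value, 0.01)
})

test_that("forward simulator matches analytic birth-death population laws", {
  set.seed(66)
  # pure birth: E[N_T] = e^T
  p <- bd_params(1, 0, T = 2, n = 2)
  NT <- replicate(3000, forward_simulate(p)$N_T)
  expect_equal(mean(NT), exp(2), tolerance = 0.06)

  # extinction probability by time t: mu (e^{rt} - 1) / (lambda e^{rt} - mu)
  p2 <- bd_params(1, 0.5, T = 10, n = 2)
  r <- 0.5
  p_ext <- 0.5 * (exp(r * 10) - 1) / (exp(r * 10) - 0.5)
  ext <- replicate(1500, forward_simulate(p2)$extinct)
  expect_equal(mean(ext), p_ext, tolerance = 0.04)
})

test_that("forward simulator caps runaway populations with a flag", {
  p <- bd_params(3, 0, T = 10, n = 2)
  sim <- forward_simulate(p, seed = 1, max_pop = 50)
  expect_true(sim$capped)
  expect_false(sim$extinct)
  expect_lte(sim$N_T, 50)
})

test_that("survivor tree reproduces the recorded genealogy", {
  p <- bd_params(1.5, 0.5, T = 4, n = 2)
  set.seed(12)
  repeat {
    sim <- forward_simulate(p)
    if (sim$N_T >= 3L) break
  }
  tr <- survivor_tree(sim)
  expect_true(check_ultrametric(tr)$pass)
  expect_equal(length(tr$tip.label), sim$N_T)
  # depths from the phylo agree with the chain-based computation
  full <- forward_coal_depths(sim, tips = sim$survivors)
  expect_equal(sort(coalescence_depths(tr)$depths), sort(full$depths))
})

test_that("mutation overlay is Poisson in edge length", {
  tr <- tree4()
  z <- overlay_mutations(tr, 0, seed = 1)
  expect_true(all(z$mutations == 0))
  expect_error(overlay_mutations(tr, -1), "nu")

  set.seed(77)
  totals <- replicate(4000, sum(overlay_mutations(tr, 2)$mutations))
  # total ~ Poisson(nu * total length) = Poisson(19)
  expect_equal(mean(totals), 19, tolerance = 0.02)
  expect_equal(var(totals), 19, tolerance = 0.08)
})

test_that("simulate_trees is reproducible and carries true metadata", {
  p <- bd_params(1, 0.5, T = 40, n = 25)
  a <- simulate_trees(p, reps = 5, seed = 123)
  b <- simulate_trees(p, reps = 5, seed = 123)
  expect_equal(lapply(a, write_newick), lapply(b, write_newick))
  for (t in a) {
    expect_equal(t$metadata$r, 0.5)
    expect_equal(t$metadata$n, 25L)
    expect_equal(t$metadata$T, 40)
  }
  rm_trees <- simulate_trees(p, reps = 3, sampler = "approx",
                             constructor = "random_merge", seed = 9,
                             condition_in_range = TRUE)
  for (t in rm_trees) expect_true(check_ultrametric(t)$pass)
})

test_that("internal branch length matches its asymptotic mean across trees", {
  p <- bd_params(1, 0.5, T = 40, n = 100)
  set.seed(88)
  trees <- simulate_trees(p, reps = 300)
  L <- vapply(trees, function(t) branch_length_totals(t)$internal_total,
              numeric(1))
  expect_equal(mean(L), 100 / 0.5, tolerance = 0.03)  # n/r = 200
})
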