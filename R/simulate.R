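#' Birth-death model parameters
#'
#' The clone is modelled as a supercritical linear birth-death process: each
#' cell divides symmetrically at rate `lambda` and dies or differentiates at
#' rate `mu`, so the net growth rate is `r = lambda - mu > 0` and the
#' expected clone size at time t is `exp(r t)`. Mutations accumulate along
#' lineages linearly in time at rate `nu`. A sample of `n` cells is drawn
#' uniformly from the clone at age `T`.
#'
#' @param lambda symmetric division rate (per unit time, > 0).
#' @param mu death/differentiation rate (per unit time, >= 0).
#' @param T clone age at sampling (time units, > 0).
#' @param n sample size (integer >= 2).
#' @param nu mutation rate per unit time (>= 0); only needed for mutation
#'   overlays and the shared-mutation estimator.
#' @return an object of class `"bd_params"` with fields `lambda`, `mu`,
#'   `r`, `T`, `n`, `nu`.
#' @export
#' @examples
#' p <- bd_params(lambda = 1, mu = 0.5, T = 40, n = 100)
#' p$r
bd_params <- function(lambda, mu, T, n, nu = 0) {
  stopifnot(is.numeric(lambda), lambda >= 0, is.numeric(mu), mu >= 0,
            is.numeric(T), T > 0, is.numeric(nu), nu >= 0)
  n <- as.integer(n)
  if (n < 2L) stop_data("sample size n must be >= 2")
  r <- lambda - mu
  if (r <= 0) stop_data("supercritical process required: lambda - mu must be > 0")
  structure(list(lambda = lambda, mu = mu, r = r, T = T, n = n, nu = nu),
            class = "bd_params")
}

#' @export
print.bd_params <- function(x, ...) {
  cat(sprintf("birth-death params: lambda = %g, mu = %g (r = %g), T = %g, n = %d, nu = %g\n",
              x$lambda, x$mu, x$r, x$T, x$n, x$nu))
  invisible(x)
}

#' Asymptotic (logistic) coalescence-time sampler
#'
#' Draws the n-1 coalescence depths from the large-T, large-n approximation
#' to the sample genealogy of a supercritical birth-death process:
#' \deqn{H_i = T - (1/r)(\log(1/W) + \log n + U_i)}
#' where `W ~ Exp(1)` is a single shared draw accounting for the randomness
#' of the initial growth, and the `U_i` are i.i.d. standard logistic. By
#' default the depths are *not* conditioned to lie in (0, T) -- the
#' unconditional law is the stated approximation, valid when `n exp(-rT)`
#' is small, where the conditioning is immaterial.
#'
#' @param params a [bd_params()] object (only `r`, `T`, `n` are used).
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param condition_in_range if `TRUE`, redraw the whole vector (preserving
#'   the shared-W dependence) until all depths lie in (0, T).
#' @param W,U optional forced values of the shared exponential draw and the
#'   logistic vector, for deterministic checks.
#' @param max_tries rejection cap for `condition_in_range`.
#' @return a [coal_times()] object; depths are in tip (coalescent point
#'   process) order.
#' @export
sample_coal_times_approx <- function(params, seed = NULL,
                                     condition_in_range = FALSE,
                                     W = NULL, U = NULL, max_tries = 1000L) {
  stopifnot(inherits(params, "bd_params"))
  r <- params$r; T <- params$T; n <- params$n
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      w <- if (is.null(W)) stats::rexp(1) else W
      u <- if (is.null(U)) stats::rlogis(n - 1L) else rep_len(U, n - 1L)
      depths <- T - (log(1 / w) + log(n) + u) / r
      if (!condition_in_range || all(depths > 0 & depths < T)) {
        return(coal_times(depths, T = T, n = n))
      }
    }
    stop_data("condition_in_range: no draw inside (0, T) after ",
              max_tries, " tries; is n * exp(-r T) large?")
  })
}

#' Exact coalescence-time sampler for a uniform birth-death sample
#'
#' Draws the n-1 coalescence depths of n cells sampled uniformly at random
#' at time `T` from a birth-death process started from one cell, conditional
#' on the population size being at least n at `T`. The construction uses the
#' coalescent point process (CPP) representation of the standing population:
#' conditioned on survival, the population genealogy is a CPP whose node
#' depths are i.i.d. with
#' \deqn{P(H \le t) = 1 - r / (\lambda e^{r t} - \mu),}
#' and the population size is the index of the first depth exceeding `T`
#' (geometric with success probability `q = r / (lambda e^{rT} - mu)`).
#' A uniform n-subsample's coalescence depths are the blockwise maxima of
#' the intervening population depths, which are drawn here in closed form
#' by inverse transform, so no part of the large population is ever
#' simulated explicitly.
#'
#' @inheritParams sample_coal_times_approx
#' @return a [coal_times()] object with all depths strictly inside (0, T),
#'   in tip (CPP) order.
#' @seealso [forward_simulate()] for the brute-force oracle this sampler is
#'   validated against.
#' @export
sample_coal_times_exact <- function(params, seed = NULL) {
  stopifnot(inherits(params, "bd_params"))
  lambda <- params$lambda; mu <- params$mu
  r <- params$r; T <- params$T; n <- params$n
  q <- r / (lambda * exp(r * T) - mu)  # P(population depth > T) = 1/W(T)
  with_seed(seed, {
    # population size N = n + Geom(q) (memorylessness gives the exact
    # conditioning on N_T >= n); inversion is stable for tiny q
    G <- floor(log(stats::runif(1)) / log1p(-q))
    N <- n + G
    pos <- sample_positions(N, n)
    m <- diff(pos)                    # depths pooled per sampled gap
    x <- log(stats::runif(n - 1L)) / m
    one_minus_F <- q - (1 - q) * expm1(x)  # 1 - F(T) U^{1/m}, stably
    depths <- log((r / one_minus_F + mu) / lambda) / r
    coal_times(depths, T = T, n = n)
  })
}

# n sorted distinct uniform positions from 1..N; N may exceed 2^31, in which
# case positions are drawn as floor(N*U)+1 with collision rejection (gap
# counts are then held as doubles, accurate to relative 1e-16, which is all
# the U^{1/m} inversion needs).
sample_positions <- function(N, n) {
  if (N < 2^31 - 1) {
    return(sort(sample.int(as.integer(N), n)))
  }
  repeat {
    pos <- sort(floor(N * stats::runif(n)) + 1)
    if (!anyDuplicated(pos)) return(pos)
  }
}

#' Build an ultrametric tree by the coalescent point process construction
#'
#' Deterministic construction: tips t1..tn are placed left to right and the
#' depth separating consecutive tips i and i+1 is `H_i`; equivalently, the
#' most recent common ancestor of tips i < j sits at depth
#' `max(H_i, ..., H_(j-1))`. Ties are resolved towards the leftmost maximum.
#'
#' @param coal a [coal_times()] object whose depths are in tip order.
#' @param stem if `TRUE`, attach a stem edge of length `T - max(depths)`
#'   above the MRCA (requires all depths < `T` and a known `T`).
#' @return an ultrametric `"phylo"` object with tips `t1..tn`.
#' @export
build_tree_cpp <- function(coal, stem = FALSE) {
  stopifnot(inherits(coal, "coal_times"))
  H <- coal$depths
  if (any(H <= 0)) {
    stop_data("non-positive coalescence depth(s); cannot build a tree ",
              "(for the approximate sampler consider condition_in_range = TRUE)")
  }
  if (stem) {
    if (is.na(coal$T)) stop_data("stem requested but T unknown")
    if (any(H >= coal$T)) stop_data("stem requested but some depth >= T")
  }
  build <- function(lo, hi, top) {
    if (lo == hi) {
      return(sprintf("t%d:%.15g", lo, top))
    }
    k <- lo - 1L + which.max(H[lo:(hi - 1L)])
    d <- H[k]
    sprintf("(%s,%s):%.15g", build(lo, k, d), build(k + 1L, hi, d), top - d)
  }
  n <- coal$n
  root_d <- max(H)
  k <- which.max(H)
  nwk <- sprintf("(%s,%s);", build(1L, k, root_d), build(k + 1L, n, root_d))
  tr <- read_newick(nwk)
  if (stem) tr$root.edge <- coal$T - root_d
  tr
}

#' Build an ultrametric tree by randomly merging lineages
#'
#' Processes the coalescence depths in increasing order (most recent first,
#' going backward in time) and at each depth merges a uniformly random pair
#' of the extant lineages. The depth multiset of the result always equals
#' the input; for i.i.d. CPP-distributed depths the resulting tree is
#' statistically equivalent to the [build_tree_cpp()] construction.
#'
#' @param coal a [coal_times()] object.
#' @param seed optional integer seed.
#' @return an ultrametric `"phylo"` object with tips `t1..tn`.
#' @export
build_tree_random_merge <- function(coal, seed = NULL) {
  stopifnot(inherits(coal, "coal_times"))
  H <- sort(coal$depths)
  if (any(H <= 0)) stop_data("non-positive coalescence depth(s)")
  n <- coal$n
  with_seed(seed, {
    frag <- sprintf("t%d", seq_len(n))
    fdep <- numeric(n)
    for (d in H) {
      k <- length(frag)
      ij <- sample.int(k, 2L)
      i <- ij[1L]; j <- ij[2L]
      merged <- sprintf("(%s:%.15g,%s:%.15g)",
                        frag[i], d - fdep[i], frag[j], d - fdep[j])
      frag <- c(frag[-c(i, j)], merged)
      fdep <- c(fdep[-c(i, j)], d)
    }
    read_newick(paste0(frag, ";"))
  })
}

#' Forward Gillespie simulation of the birth-death clone
#'
#' Exact continuous-time simulation of the full clonal population: each cell
#' independently divides at rate `lambda` and dies at rate `mu`; the
#' complete genealogy is recorded. This is the brute-force oracle used to
#' validate [sample_coal_times_exact()], which avoids simulating the (often
#' astronomically large) population.
#'
#' @param params a [bd_params()] object (`n` is ignored here).
#' @param seed optional integer seed.
#' @param max_pop population cap; if exceeded the simulation stops early and
#'   the result is flagged `capped` (not an error).
#' @return an object of class `"forward_sim"`: list with `records` (a
#'   data.frame of lineage segments: `id`, `parent`, `t_birth`, `t_end`,
#'   `fate` in died/divided/alive), `survivors` (ids alive at `T`), `N_T`,
#'   `extinct`, `capped`, and `params`.
#' @export
forward_simulate <- function(params, seed = NULL, max_pop = 1e5) {
  stopifnot(inherits(params, "bd_params"))
  lambda <- params$lambda; mu <- params$mu; T <- params$T
  if (lambda <= 0) stop_data("forward simulation needs lambda > 0")
  with_seed(seed, {
    cap <- 64L
    parent <- integer(cap); t_birth <- numeric(cap)
    t_end <- numeric(cap); fate <- integer(cap)  # 0 alive, 1 divided, 2 died
    n_rec <- 1L
    parent[1L] <- 0L; t_birth[1L] <- 0
    alive <- c(1L, integer(63L)); n_alive <- 1L
    t <- 0
    p_birth <- lambda / (lambda + mu)
    capped <- FALSE
    repeat {
      if (n_alive == 0L) break
      t <- t + stats::rexp(1L, n_alive * (lambda + mu))
      if (t >= T) break
      idx <- sample.int(n_alive, 1L)
      cell <- alive[idx]
      if (stats::runif(1L) < p_birth) {
        if (n_alive + 1L > max_pop) { capped <- TRUE; break }
        if (n_rec + 2L > cap) {  # grow record buffers
          cap <- cap * 2L
          length(parent) <- cap; length(t_birth) <- cap
          length(t_end) <- cap; length(fate) <- cap
        }
        c1 <- n_rec + 1L; c2 <- n_rec + 2L; n_rec <- n_rec + 2L
        parent[c(c1, c2)] <- cell
        t_birth[c(c1, c2)] <- t
        fate[cell] <- 1L; t_end[cell] <- t
        alive[idx] <- c1
        if (n_alive + 1L > length(alive)) length(alive) <- 2L * length(alive)
        n_alive <- n_alive + 1L
        alive[n_alive] <- c2
      } else {
        fate[cell] <- 2L; t_end[cell] <- t
        alive[idx] <- alive[n_alive]
        n_alive <- n_alive - 1L
      }
    }
    surv <- alive[seq_len(n_alive)]
    idx <- seq_len(n_rec)
    fate_v <- fate[idx]
    t_end_v <- t_end[idx]
    t_end_v[fate_v == 0L] <- T
    structure(
      list(records = data.frame(
             id = idx, parent = parent[idx], t_birth = t_birth[idx],
             t_end = t_end_v,
             fate = c("alive", "divided", "died")[fate_v + 1L]),
           survivors = surv, N_T = n_alive,
           extinct = n_alive == 0L && !capped, capped = capped,
           params = params),
      class = "forward_sim")
  })
}

#' @export
print.forward_sim <- function(x, ...) {
  cat(sprintf("forward birth-death simulation: N_T = %d at T = %g%s%s\n",
              x$N_T, x$params$T,
              if (x$extinct) " (extinct)" else "",
              if (x$capped) " (population cap hit)" else ""))
  invisible(x)
}

# ancestor chain (root -> cell) of a record id
ancestor_chain <- function(parent_vec, id) {
  chain <- id
  while (parent_vec[id] > 0L) {
    id <- parent_vec[id]
    chain <- c(id, chain)
  }
  chain
}

# pairwise coalescence depths (backward from T) of chosen survivor ids
split_depth_matrix <- function(sim, tips) {
  parent_vec <- sim$records$parent
  tb <- sim$records$t_birth
  T <- sim$params$T
  chains <- lapply(tips, function(id) ancestor_chain(parent_vec, id))
  k <- length(tips)
  D <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      a <- chains[[i]]; b <- chains[[j]]
      l <- seq_len(min(length(a), length(b)))
      first_diff <- which.max(a[l] != b[l])  # chains of distinct survivors always diverge
      D[i, j] <- D[j, i] <- T - tb[a[first_diff]]
    }
  }
  D
}

#' Coalescence times of a uniform sample from a forward simulation
#'
#' Samples `n` survivors uniformly without replacement from a
#' [forward_simulate()] result and returns the coalescence depths of the
#' induced genealogy (via single-linkage agglomeration of the pairwise
#' divergence depths, which is exact for ultrametric trees). Used as the
#' independent oracle for [sample_coal_times_exact()].
#'
#' @param sim a `"forward_sim"` object with `N_T >= n`.
#' @param n sample size; alternatively supply explicit `tips` (record ids).
#' @param tips optional survivor record ids to use instead of sampling.
#' @param seed optional integer seed for the tip draw.
#' @return a [coal_times()] object.
#' @export
forward_coal_depths <- function(sim, n = NULL, tips = NULL, seed = NULL) {
  stopifnot(inherits(sim, "forward_sim"))
  if (is.null(tips)) {
    stopifnot(!is.null(n))
    if (sim$N_T < n) stop_data("fewer than n survivors (N_T = ", sim$N_T, ")")
    tips <- with_seed(seed, sample(sim$survivors, n))
  } else {
    if (!all(tips %in% sim$survivors)) stop_data("tips must be survivor ids")
    n <- length(tips)
  }
  if (n < 2L) stop_data("need at least 2 tips")
  D <- split_depth_matrix(sim, tips)
  h <- stats::hclust(stats::as.dist(D), method = "single")
  coal_times(h$height, T = sim$params$T, n = n)
}

# newick from an hclust whose heights are node depths (ultrametric input)
newick_from_hclust <- function(hc, labels) {
  build <- function(k) {
    if (k < 0L) list(str = labels[-k], depth = 0) else {
      a <- build(hc$merge[k, 1L]); b <- build(hc$merge[k, 2L])
      d <- hc$height[k]
      list(str = sprintf("(%s:%.15g,%s:%.15g)",
                         a$str, d - a$depth, b$str, d - b$depth),
           depth = d)
    }
  }
  paste0(build(nrow(hc$merge))$str, ";")
}

#' Genealogy of all survivors of a forward simulation as a phylo tree
#'
#' @param sim a `"forward_sim"` object with at least 2 survivors.
#' @param max_tips guard against accidentally materialising an enormous
#'   tree (pairwise construction is quadratic in the number of survivors).
#' @return an ultrametric `"phylo"` object whose tip labels are the survivor
#'   record ids prefixed with `"c"`.
#' @export
survivor_tree <- function(sim, max_tips = 2000L) {
  stopifnot(inherits(sim, "forward_sim"))
  if (sim$N_T < 2L) stop_data("need at least 2 survivors")
  if (sim$N_T > max_tips) {
    stop_data("N_T = ", sim$N_T, " exceeds max_tips = ", max_tips)
  }
  tips <- sim$survivors
  D <- split_depth_matrix(sim, tips)
  hc <- stats::hclust(stats::as.dist(D), method = "single")
  read_newick(newick_from_hclust(hc, sprintf("c%d", tips)))
}

#' Overlay Poisson mutations on a tree
#'
#' Each edge receives an independent Poisson(`nu` x edge length) mutation
#' count, consistent with mutations accumulating linearly in time at rate
#' `nu`. Counts are stored in `tree$mutations`, aligned with the rows of
#' `tree$edge`; the rate is recorded in `tree$mutation_rate`.
#'
#' @param tree a `"phylo"` object.
#' @param nu mutation rate per unit time (>= 0).
#' @param seed optional integer seed.
#' @return the tree with `mutations` and `mutation_rate` fields added.
#' @export
overlay_mutations <- function(tree, nu, seed = NULL) {
  tree <- validate_tree(tree)
  if (!is.numeric(nu) || nu < 0) stop_data("nu must be >= 0")
  with_seed(seed, {
    tree$mutations <- stats::rpois(nrow(tree$edge), nu * tree$edge.length)
  })
  tree$mutation_rate <- nu
  tree
}

#' Simulate a batch of ultrametric trees
#'
#' Batch driver around the coalescence-time samplers and tree constructors.
#' Each returned tree carries a `metadata` list recording the generating
#' parameters, so downstream benchmarking can recover the truth.
#'
#' @param params a [bd_params()] object.
#' @param reps number of trees.
#' @param sampler `"exact"` ([sample_coal_times_exact()]) or `"approx"`
#'   ([sample_coal_times_approx()]).
#' @param constructor `"cpp"` ([build_tree_cpp()]) or `"random_merge"`
#'   ([build_tree_random_merge()]).
#' @param nu if non-`NULL`, overlay mutations at this rate on every tree.
#' @param seed optional integer seed; the whole batch is reproducible from it.
#' @param condition_in_range passed to the approximate sampler.
#' @return a list of `"phylo"` trees, each with `$metadata` (fields `r`,
#'   `lambda`, `mu`, `T`, `n`, `nu`, `sampler`, `constructor`, `index`).
#' @export
simulate_trees <- function(params, reps, sampler = c("exact", "approx"),
                           constructor = c("cpp", "random_merge"),
                           nu = NULL, seed = NULL,
                           condition_in_range = FALSE) {
  stopifnot(inherits(params, "bd_params"), reps >= 1L)
  sampler <- match.arg(sampler)
  constructor <- match.arg(constructor)
  with_seed(seed, {
    lapply(seq_len(reps), function(i) {
      coal <- switch(sampler,
        exact = sample_coal_times_exact(params),
        approx = sample_coal_times_approx(
          params, condition_in_range = condition_in_range))
      tr <- switch(constructor,
        cpp = build_tree_cpp(coal),
        random_merge = build_tree_random_merge(coal))
      if (!is.null(nu)) tr <- overlay_mutations(tr, nu)
      tr$metadata <- list(r = params$r, lambda = params$lambda,
                          mu = params$mu, T = params$T, n = params$n,
                          nu = if (is.null(nu)) params$nu else nu,
                          sampler = sampler, constructor = constructor,
                          index = i)
      tr
    })
  })
}
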