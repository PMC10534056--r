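estimate_one <- function(method, coal, tree, alpha, nu = NULL) {
  switch(method,
    ml = estimate_ml(coal, alpha = alpha),
    lengths = estimate_internal_lengths(tree, alpha = alpha),
    mutations = estimate_shared_mutations(tree, nu = nu, alpha = alpha),
    stop_data("unknown method: ", method))
}

#' Benchmark estimators over a grid of sample sizes and growth rates
#'
#' For every combination of `n_values` and `r_values`, simulates `reps`
#' exact-sampler ultrametric trees and applies the chosen estimators. For
#' each tree the birth rate is drawn from `lambda_sampler` (by default
#' uniform on `[r, 1 + r]`) and the death rate is `mu = lambda - r`, so the
#' net growth rate is exact by construction. Fully reproducible from
#' `seed`.
#'
#' @param n_values integer vector of sample sizes.
#' @param r_values numeric vector of true net growth rates.
#' @param reps trees per grid cell.
#' @param T clone age at sampling (default 40; because only the product
#'   `rT` matters for tree shape, fixing `T` loses no generality).
#' @param lambda_sampler function `(reps, r) -> lambda vector`; default
#'   `runif(reps, r, 1 + r)`.
#' @param methods estimators to run: subset of `"ml"`, `"lengths"`,
#'   `"mutations"`.
#' @param nu mutation rate (required when `"mutations"` is benchmarked;
#'   trees then receive a Poisson mutation overlay).
#' @param alpha CI level complement.
#' @param seed optional integer seed.
#' @return a long-format data.frame, one row per tree per method, with
#'   columns `n`, `r_true`, `lambda`, `mu`, `T`, `rep`, `method`, `r_hat`,
#'   `ci_low`, `ci_high`, `covered` (whether the CI contains the truth)
#'   and `ratio` (external/internal branch lengths).
#' @export
run_grid <- function(n_values, r_values, reps, T = 40,
                     lambda_sampler = function(reps, r) stats::runif(reps, r, 1 + r),
                     methods = c("ml", "lengths"), nu = NULL,
                     alpha = 0.05, seed = NULL) {
  stopifnot(reps >= 1L, length(n_values) >= 1L, length(r_values) >= 1L)
  methods <- match.arg(methods, c("ml", "lengths", "mutations"),
                       several.ok = TRUE)
  if ("mutations" %in% methods && is.null(nu)) {
    stop_data("the mutations method needs a mutation rate nu")
  }
  with_seed(seed, {
    out <- list()
    for (n in n_values) {
      for (r in r_values) {
        lambdas <- lambda_sampler(reps, r)
        if (any(lambdas < r)) stop_data("lambda_sampler returned lambda < r")
        for (i in seq_len(reps)) {
          p <- bd_params(lambda = lambdas[i], mu = lambdas[i] - r,
                         T = T, n = n)
          coal <- sample_coal_times_exact(p)
          tree <- build_tree_cpp(coal)
          if (!is.null(nu)) tree <- overlay_mutations(tree, nu)
          ratio <- branch_length_totals(tree)$ratio
          for (m in methods) {
            est <- estimate_one(m, coal, tree, alpha, nu)
            out[[length(out) + 1L]] <- data.frame(
              n = n, r_true = r, lambda = lambdas[i], mu = lambdas[i] - r,
              T = T, rep = i, method = m, r_hat = est$r_hat,
              ci_low = est$ci_low, ci_high = est$ci_high,
              covered = est$ci_low <= r & r <= est$ci_high,
              ratio = ratio)
          }
        }
      }
    }
    do.call(rbind, out)
  })
}

#' Summarise a benchmark table
#'
#' Per grid cell and method: root mean square error of `r_hat`, normalised
#' RMSE (RMSE divided by the true growth rate) and coverage (fraction of
#' runs whose confidence interval contains the truth).
#'
#' @param table a data.frame from [run_grid()] (or with the same columns).
#' @return a data.frame with one row per `(n, r_true, method)` and columns
#'   `rmse`, `nrmse`, `coverage`, `reps`.
#' @export
summarize_benchmark <- function(table) {
  if (is.null(table) || nrow(table) == 0L) stop_data("empty benchmark table")
  cells <- unique(table[, c("n", "r_true", "method")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- table$n == cells$n[i] & table$r_true == cells$r_true[i] &
      table$method == cells$method[i]
    sub <- table[sel, , drop = FALSE]
    rmse <- sqrt(mean((sub$r_hat - sub$r_true)^2))
    data.frame(n = cells$n[i], r_true = cells$r_true[i],
               method = cells$method[i], rmse = rmse,
               nrmse = rmse / cells$r_true[i],
               coverage = mean(sub$covered), reps = nrow(sub))
  })
  do.call(rbind, rows)
}

#' Coverage as a function of the external/internal ratio diagnostic
#'
#' Simulates trees with true growth rates drawn uniformly from `r_range`
#' (with `lambda ~ U(r, 1 + r)`, `mu = lambda - r`), estimates r with 95%
#' (or `1 - alpha`) confidence intervals, bins the trees by their
#' external/internal branch-length ratio, and reports per-bin CI coverage
#' plus aggregate error and coverage before and after applying the
#' star-shape cutoff (ratio >= `ratio_cutoff`).
#'
#' @param reps number of simulated trees (>= 100).
#' @param n,T sample size and clone age (defaults 50 and 40).
#' @param r_range range of the uniform law for the true growth rate.
#' @param ratio_cutoff star-shape cutoff (default 3).
#' @param bin_width width of the ratio bins (default 1).
#' @param methods estimators to track (default ML and internal lengths;
#'   per-bin coverage is reported for the first).
#' @param alpha CI level complement.
#' @param seed optional integer seed.
#' @return a list with `records` (per-tree table as in [run_grid()] plus
#'   `r_true` varying), `by_bin` (ratio bin, number of trees, ML coverage),
#'   `summary` (per method and filter `all` / `ratio_pass`: rmse, nrmse,
#'   coverage, n_trees), and `retained_fraction` (fraction of trees with
#'   ratio >= cutoff).
#' @export
ratio_coverage_analysis <- function(reps, n = 50L, T = 40,
                                    r_range = c(0.1, 1), ratio_cutoff = 3,
                                    bin_width = 1,
                                    methods = c("ml", "lengths"),
                                    alpha = 0.05, seed = NULL) {
  stopifnot(reps >= 100L)
  methods <- match.arg(methods, c("ml", "lengths"), several.ok = TRUE)
  with_seed(seed, {
    rs <- stats::runif(reps, r_range[1L], r_range[2L])
    lambdas <- rs + stats::runif(reps)
    out <- vector("list", reps * length(methods))
    k <- 0L
    for (i in seq_len(reps)) {
      p <- bd_params(lambda = lambdas[i], mu = lambdas[i] - rs[i],
                     T = T, n = n)
      coal <- sample_coal_times_exact(p)
      tree <- build_tree_cpp(coal)
      ratio <- branch_length_totals(tree)$ratio
      for (m in methods) {
        est <- estimate_one(m, coal, tree, alpha)
        k <- k + 1L
        out[[k]] <- data.frame(
          n = n, r_true = rs[i], lambda = lambdas[i], T = T, rep = i,
          method = m, r_hat = est$r_hat, ci_low = est$ci_low,
          ci_high = est$ci_high,
          covered = est$ci_low <= rs[i] & rs[i] <= est$ci_high,
          ratio = ratio)
      }
    }
    records <- do.call(rbind, out)
    first <- records[records$method == methods[1L], , drop = FALSE]
    bins <- floor(first$ratio / bin_width) * bin_width
    by_bin <- do.call(rbind, lapply(sort(unique(bins)), function(b) {
      sel <- bins == b
      data.frame(bin_low = b, bin_high = b + bin_width,
                 n_trees = sum(sel), coverage = mean(first$covered[sel]))
    }))
    summary <- do.call(rbind, lapply(methods, function(m) {
      sub <- records[records$method == m, , drop = FALSE]
      do.call(rbind, lapply(c("all", "ratio_pass"), function(f) {
        s <- if (f == "all") sub else sub[sub$ratio >= ratio_cutoff, , drop = FALSE]
        rmse <- sqrt(mean((s$r_hat - s$r_true)^2))
        data.frame(method = m, filter = f, rmse = rmse,
                   nrmse = sqrt(mean(((s$r_hat - s$r_true) / s$r_true)^2)),
                   coverage = mean(s$covered), n_trees = nrow(s))
      }))
    }))
    list(records = records, by_bin = by_bin, summary = summary,
         retained_fraction = mean(first$ratio >= ratio_cutoff))
  })
}
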