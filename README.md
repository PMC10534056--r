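# coalgrowth

Analytical estimation of the net growth rate of a clonal expansion from an
ultrametric time tree of sampled cells, or from shared mutation counts.

## The problem

Somatic clones — for example driver-mutant clones in blood — expand from a
single founder cell. Whole-genome single-cell sequencing lets us reconstruct
an ultrametric phylogeny of `n` cells sampled from one clone at a single
timepoint, with branch lengths in real time. The shape of that tree encodes
the clone's early growth dynamics: a fast-growing clone has a star-shaped
genealogy (all coalescences near the clone's origin), a slow one looks more
like Kingman's coalescent. `coalgrowth` turns this into a point estimate and
an analytical confidence interval for the net growth rate `r = λ − μ` of a
supercritical birth–death model of the clone (division rate λ, death or
differentiation rate μ), without MCMC or simulation at inference time.

## The model and estimators

For a birth–death clone sampled at age `T`, the `n − 1` coalescence depths
`H_i` (measured backward from the sampling time) are approximately

    H_i = a + b U_i,   b = 1/r,

with i.i.d. standard logistic `U_i` and a tree-level random shift in `a`
coming from the stochastic early growth. Three estimators are provided:

| method | estimator | 95% CI half-width (relative) |
|---|---|---|
| maximum likelihood | `r̂ = 1/b̂` (logistic MLE) | `c·z/√n`, `c = 3/√(3+π²) ≈ 0.836` |
| internal lengths | `r̂ = n/L_in` | `z/√n` |
| shared mutations | `r̂ = nν/M_in` | `(z/√n)·√(1 + n/M_in)` |

`L_in` is the total internal (non-pendant) branch length, asymptotically
Normal(n/r, n/r²); `M_in` is the number of mutations carried by more than
one but not all sampled cells, with mean `nν/r` when the per-lineage
mutation rate `ν` is known. The half-widths are provably ordered
ML < lengths < mutations. A star-shape diagnostic (external/internal branch
length ratio ≥ 3, sample size ≥ 10) flags trees outside the estimators'
domain of validity, which is governed by `n·e^{−rT}`.

The package also contains an exact sampler for the genealogy of a uniform
sample of size `n` from a birth–death process conditioned on `N_T ≥ n`
(via the coalescent point process representation, drawing blockwise maxima
in closed form), a brute-force Gillespie forward simulator used as the
correctness oracle for that sampler, site-frequency-spectrum utilities with
the neutral `1/k(k−1)` expectation, and benchmark drivers for estimator
RMSE and confidence-interval coverage.

## Worked example

```r
library(coalgrowth)

p  <- bd_params(lambda = 1, mu = 0.5, T = 40, n = 100)  # true r = 0.5
tr <- build_tree_cpp(sample_coal_times_exact(p, seed = 1))

estimate_ml(tr)
#> growth rate estimate (max_likelihood): r_hat = 0.4951, 95% CI [0.4139, 0.5762], n = 100

estimate_internal_lengths(tr)
#> growth rate estimate (internal_lengths): r_hat = 0.5048, 95% CI [0.4059, 0.6038], n = 100

diagnose(tr, r = 0.5, T = 40)
#> verdict: ok
#> n_tips: 100
#> ratio_ext_int: 14.83
#> n_exp_neg_rT: 2.061e-07
```

Both 95% intervals contain the true rate 0.5; the external/internal ratio
of 14.83 (≥ 3) and `n·e^{−rT} ≈ 2·10⁻⁷` confirm the star-shaped regime in
which the analytical intervals are calibrated. The clone's age at sampling
can be estimated with `clone_age(tr, 0.495)` (deepest coalescence plus
`1/r̂`).

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "coalgrowth.R", package = "coalgrowth")` with
subcommands `simulate | estimate | diagnose | sfs | bench`.

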