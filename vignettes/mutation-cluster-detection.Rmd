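---
title: "Detecting mutation clusters under a probe sampling design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mutation clusters under a probe sampling design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpcluster)
```

## The problem

Genotyping arrays observe the genome only at the fixed loci targeted by
their probes. When two samples are contrasted, a SNP genotype difference
can be detected only if it falls on a probe locus, so the observable data
are a subset `X` of the probe design `S` on each chromosome. The question
this package answers is whether the detected differences are spatially
clustered along the chromosome — a kataegis-like signature — or compatible
with spatial randomness, *conditional on the probe design*. Probe spacing
is strongly nonuniform (tight runs of sub-kilobase spacing next to
megabase-scale probe deserts), so any honest test must account for where
detection was possible at all.

Chromosomes are analyzed independently: each is a one-dimensional lattice
of integer base-pair positions carrying its own probe design.

## The statistics

For a sorted event set `X` bound to a design `S`, write
`N_A(x, d) = #{z in A : 0 < |z - x| <= d}` for the number of members of a
set `A` within distance `d` of `x`, never counting `x` itself. Five
statistic families are provided:

* **Mean detection ratio** `Rbar(d)`: the mean over events of
  `N_X(x, d) / N_S(x, d)` — locally, what fraction of the probes near an
  event also carry events. Events with no probe within `d` contribute no
  term (the exclusion count is reported); if every term is excluded the
  value is undefined and flagged.
* **Pooled detection ratio** `Rtilde(d)`:
  `sum_x N_X(x, d) / sum_x N_S(x, d)` — the same idea with numerators and
  denominators pooled first, which stabilizes sparse neighborhoods. This
  is the base of the package's recommended test.
* **`Dmin(n)`**: the smallest radius around any event containing `n`
  events (itself included). For `n = 2` it is the minimum adjacent gap.
  It is computed by a consecutive-window algorithm — for each run of `n`
  consecutive events the best center is the interior member minimizing
  the larger one-sided reach — which equals the brute-force definition
  because the `n` nearest events to any center are consecutive in sorted
  order.
* **`Nmax(d)`**: the largest `N_X(x, d)` over events.
* **Gap count `C(d)`**: the number of adjacent inter-event gaps *strictly*
  below `d` — the statistic behind rainfall plots. The strict inequality
  differs from the `<=` boundary used by the neighborhood counts; it is
  implemented exactly as defined and documented prominently, since at
  integer bp resolution `C(d)` and a `<=` variant differ on exact-tie
  grids.

Each family is used both at fixed arguments and as a curve `G(.)` over a
grid. The default grids are 20 distances `d = 5, 10, ..., 100 kb` and 7
cluster sizes `n = 2, ..., 8`; together with the Kolmogorov–Smirnov and
Cramér–von Mises functional forms of each family this enumerates 97
statistics (`enumerate_statistics()`).

Curve departures from a reference `G*` are summarized by the discretized
sup-norm distance `KS = max_i |G(y_i) - G*(y_i)|` and the trapezoid
discretization of the integrated squared difference,
`CvM = 1/2 * sum_i {[G-G*]^2(y_i) + [G-G*]^2(y_{i+1})} (y_{i+1} - y_i)`.
The trapezoid form is implemented verbatim rather than through a generic
quadrature, so reported values are exactly reproducible from the formula.

## Null model and Monte Carlo inference

Under the null, underlying mutations form a homogeneous Poisson process on
the integer sites of `[s_f, s_l]`; the detected set is its restriction to
probe loci. The calibration is operational: with target detected count
`eta` (normally the observed `|X|`), each site carries underlying Poisson
mean `eta / |S|`, i.e. a total underlying mean of
`eta * (s_l - s_f + 1) / |S|`.

Two distributionally identical simulators are provided. The literal
construction (`method = "multiset"`) draws the Poisson number of underlying
positions uniformly and intersects with `S`; the default
(`method = "thinned"`) uses the Poissonization identity — per-site hit
counts are independent Poisson — and simply includes each probe locus
independently with probability `1 - exp(-eta/|S|)`. The equivalence is
exact, and a property test compares the two generators' detected-count
distributions.

One subtlety: because multiple underlying hits on one locus collapse to a
single detected difference, the expected *distinct* detected count is
`|S| * (1 - exp(-eta/|S|))`, about 2% below `eta` at the package's default
scale (and negligible at array scale). `calibrate_null(adjust = TRUE)`
solves the collapse equation exactly for users who want
`E|detected| = eta`; the default keeps the linear rate–`eta` relationship.

`build_null_reference()` simulates `M` null replicates, averages the
replicate curves pointwise into `Ghat*` (undefined replicate points are
excluded pointwise, with counts recorded; a point undefined in more than
half the replicates is a hard error suggesting a coarser grid or larger
`eta`), and stores each replicate's KS/CvM distance to `Ghat*` along with
the per-argument replicate values — the empirical null distributions of
all 97 statistics. Observed samples are scored against this *same*
`Ghat*`, never a re-estimated one.

P-values use the add-one Monte Carlo estimator
`(1 + #{null >= obs}) / (1 + M)` (ties counted as extreme), whose smallest
achievable value is `1/(1+M)` and whose type-I error control is exact
under the simulated null. The rejection rule is `p <= alpha`; this matches
the empirical-critical-value rule up to a single Monte Carlo rank, and
guarantees that `alpha = 0` never rejects. The five fixed-argument
families are scored on their clustering-consistent one-sided tail — upper
for the ratios, `Nmax` and `C`, lower for `Dmin`. This direction is a
package choice (only the functional forms have a canonical direction);
it can be revisited by calling `mc_pvalue()` directly with the other tail.

The reference is estimated from the null replicates themselves, so each
replicate's distance to `Ghat*` is very slightly deflated (an `O(1/M)`
effect); at the default `M = 2000` this is far below the Monte Carlo
noise, and the type-I checks in the test suite confirm the nominal level.

## Clustered alternatives and power

The alternative is a Neyman–Scott process: `Poisson(mu_p)` unobserved
parents, each spawning `Poisson(mu_o)` offspring placed as truncated
normals (sd `sigma`, half-width `h = 3*sigma` by default) around the
parent, rounded half-away-from-zero to integer bp (the minimal bridge
between a continuous offspring law and integer genome coordinates);
detected events are the distinct offspring on probe loci. Three parent
domains are supported: `free` (anywhere in `[s_f - h, s_l + h]`, including
non-positive coordinates — such parents can still scatter offspring onto
the chromosome), `probe-anchored` (parents on probe loci, the most
detectable and hence highest-power configuration), and
`probe-neighborhood` (within `h_p` of a probe, default `h_p = sigma`).

Power studies need the alternative to match the null's expected detected
count. `calibrate_parent_mean()` does this by pilot Monte Carlo (default
1,000 pilot replicates): estimate the expected detected events per parent,
then set `mu_p = eta / r`. An analytic mode cross-checks the pilot on
small designs by summing, per candidate parent, the probability
`1 - exp(-mu_o * p_s)` that each probe site receives at least one
offspring, with `p_s` the truncated-normal mass rounding to the site.
Offspring of different parents can collide on a locus, which the analytic
mode ignores; at the calibrated scale this collision mass is negligible,
and the pilot (which includes it) is authoritative.

`estimate_power()` scores `M'` alternative replicates against the shared
null reference's empirical critical values; `run_factorial()` sweeps
variant × `mu_o` × `sigma` grids (defaults: `mu_o` in {375, 1125},
`sigma` in {0.5, 1, 2, ..., 10 kb}) and `optimal_arguments()` extracts the
best fixed argument per family and cell.

## The synthetic study scale

All shipped tests run on synthetic designs from `make_design()`. The
default spacing model draws iid lognormal inter-probe gaps
(`sdlog = 1.5`), scaled to the requested span. With the package's standard
study scale — 1,200 probes over 6 Mb, mean gap 5 kb, `eta = 50`,
`M = M' = 2000` — this reproduces the spacing heterogeneity that drives
the method: about 37% of gaps fall below 1 kb, comparable to real
genotyping arrays, alongside a heavy right tail. Two caveats about what
passing tests show: iid gaps understate the *run* structure of real
designs (real tight probes come in correlated runs, so the per-locus
near-neighbor fraction here is somewhat higher than on a real array), and
a miniature 6 Mb chromosome compresses the desert structure of a real
60 Mb chromosome. Deserts can be planted explicitly
(`spacing = "with-deserts"`), and every generator accepts the full array
scale when more fidelity is wanted — the statistics and inference code are
scale-free.

Monte Carlo sizes in the shipped tests (`M = M' = 2000`, 10^4 for the
two-sample discrimination check) are the package's desk-scale choice; all
power and size assertions carry binomial Monte Carlo tolerances, and
larger `M` is a single argument away.

## Numerical choices and degenerate inputs

* Distances and positions are integer bp held in doubles; neighbor counts
  use binary search (`findInterval`) with exact boundary handling at
  `|z - x| = d`.
* `Dmin(n)` with fewer than `n` events returns the chromosome span
  `s_l - s_f` as a finite, flagged "no cluster possible" sentinel, keeping
  functional forms computable (an infinite value would poison the CvM
  integral); callers can treat the flag specially.
* Undefined curve points are never imputed: an observed curve with an
  undefined point is an error naming the grid points, and null replicates
  contribute to `Ghat*` only where defined.
* Seeds: simulation entry points accept an optional seed and restore the
  caller's RNG state; unseeded calls draw from the session stream, so a
  single top-level `set.seed()` makes a whole analysis reproducible.
* Duplicate input positions collapse to sets with a message; BED input is
  converted to 1-based coordinates on read; binding events to a design is
  strict by default, with an explicit `drop` policy that reports the
  number of off-design events removed.

## Limitations

The test reports the *existence* of clustering per chromosome, not the
location of the clusters; a rejected chromosome still needs localization
by other means. Mutations between probe loci are invisible by design, so
power is conditional on clusters being detectable at all — a cluster
falling in a probe desert cannot be found. The null is homogeneous;
covariate-dependent mutation rates would need an inhomogeneous extension.
When many chromosomes or samples are tested, `adjust_pvalues()` provides
Bonferroni and Benjamini–Hochberg control.
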