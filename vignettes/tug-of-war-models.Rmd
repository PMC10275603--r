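---
title: "The tug-of-war Moran models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tug-of-war Moran models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tugwar)
```

## The model

`tugwar` simulates a constant-size population of `N` tumor cells in which
rare advantageous **driver** mutations compete against frequent, slightly
deleterious **passenger** mutations — a "tug of war" between selection for
drivers and the gradual load of passengers. A cell carrying `alpha` drivers
and `beta` passengers has multiplicative fitness

$$ f(\alpha, \beta) = (1+s)^{\alpha} (1-d)^{\beta}, $$

with `s >= 0` the driver advantage and `0 <= d < 1` the passenger
disadvantage per mutation. Multiplicativity encodes the absence of epistasis:
each additional mutation scales fitness by a constant factor.

The population evolves as a time-continuous Markov chain with two event
types, in the Moran "competitive replacement" frame:

* **Death–replacement**, at total rate $\Sigma_P = \sum_i f_i$ (the summed
  fitness of all `N` live cells). A dying cell `i` and a replacing cell `j`
  are drawn independently; the replacement is a copy of `j`. The two model
  variants differ *only* in how `i` is drawn:
    * **Model A** — `i` fitness-biased ($\Pr(i) = f_i / \Sigma_P$), `j`
      fitness-biased. Fitter cells both reach division faster *and* replace
      others preferentially. The expected fitness change per event is
      identically zero: drift alone neither raises nor lowers mean fitness.
    * **Model B** — `i` uniform on the `N` cells, `j` fitness-biased. The
      expected per-event change equals
      $\sum f^2 / \sum f - \bar f \ge 0$, with equality exactly when all
      cells share one fitness; drift is biased upward ("drift barrier"
      behaviour: deleterious load cannot accumulate freely).
* **Mutation**, at total rate $N\mu$. A uniformly chosen cell founds a new
  clone with one extra driver (probability `p`) or one extra passenger
  (probability `1 - p`).

The expected fitness effect of the mutation flow alone vanishes when
$sp = d(1-p)$; the package's worked configurations use the equilibrium
point `s = 0.1, d = 0.01, p = 0.0909`.

Bookkeeping follows the infinite-allele / infinite-site convention: every
mutation event creates a new clone, so clones form a rooted genealogy with
one mutation per edge, and the number of cells carrying a mutation is the
live-cell count of the corresponding clone's subtree. Cells are never stored
individually — with constant `N` and a 1:1 mutation-to-clone map, a multiset
over clones is lossless.

## Simulation engine

`sim_run()` is an event-driven (Gillespie) sampler. The two competing
exponential clocks are implemented as a single draw with total rate
$\Sigma_P + N\mu$ followed by a categorical choice of event type — the two
formulations give the same process, with less state. Choices worth noting:

* *Self-replacement is allowed*: dying and replacing cells are drawn
  independently, so `i = j` is a legal no-op event that still advances time.
* $\Sigma_P$ is maintained incrementally and recomputed exactly every
  10,000 events, bounding floating-point drift (the state invariant is
  checked at 1e-9 relative tolerance in the tests).
* The event loop is compiled (Rcpp) and draws from R's RNG, so a single
  `set.seed()` makes an entire run — genealogy, trajectory, snapshots —
  bit-reproducible. The pure-R `sim_step()` implements one transition of the
  identical chain and serves as the readable reference (the test suite
  checks its invariants against the compiled path).
* `max_events` (default 5e6) guards the `sp > d(1-p)` regime, where the
  total rate grows with mean fitness and runs can otherwise exhaust memory;
  hitting the cap raises a `tugwar_cap_error` carrying the partial result.
* The fitness trajectory is recorded on a fixed user grid (default
  `0, 1, ..., t_max`) by carrying the last state forward, keeping result
  sizes bounded independently of the event count.

Two initial conditions are provided. `init_homogeneous()` starts all `N`
cells at `(0, 0)`, fitness 1. `init_exponential_draw()` gives each cell
independent initial driver/passenger counts from exponential distributions
with parameters `10p` and `10(1-p)`, *rounded half-up*. We interpret the
parameters as the **means** (so `p = 0.5` seeds ~5 drivers and ~5 passengers
per cell, heterogeneity worth selecting on); a `rate` interpretation — under
which both means would be ≈ 0.1 and the population nearly homogeneous — is
available via a flag. Note that rounding shifts the mean for small scales:
the rounded draw has mean $\sum_{k\ge1} P(X \ge k - 1/2)$, which matters
below scale ≈ 1 and is what the tests assert.

## Site frequency spectra

`observed_sfs()` computes `S(k)`, the number of mutations carried by exactly
`k` of `n` cells, from carrier counts at the **final** simulation time;
extinct mutations are dropped, and fixed (truncal) mutations are excluded
unless requested, since only segregating sites are observable against the
ancestral background. Singletons are included by default — low-frequency
variants are often pruned from sequencing data as suspected artifacts, so a
`min_count` filter is provided rather than imposed.

`cumulative_tail()` evaluates $T(x)$, the spectrum mass at frequencies
$\ge x$ (weak inequality), as a step function on the observed frequencies;
normalized tails are inscribed in the unit square so curves from models with
different mutation totals can be overlaid. Semi-logarithmic axes resolve the
deep tail; log-log axes make power laws straight lines.

Under strict neutrality (`s = d = 0`) the tails of both models behave like a
power law. The package tests this on pooled Model A runs by a straight-line
fit of `log10 T` against `log10 x` over the **central frequency range
[0.03, 0.3]** — above the singleton/noise zone, below the sparse deep tail —
requiring R² > 0.95. Outside that range the constant-size logarithmic
correction visibly bends the curve; the choice of range is part of the test
design, fixed before use.

## Theoretical comparison spectra

* `gt_expected_sfs()` is the general coalescent form
  $ES_n(k) = \theta \sum_j j\,p_{nj}(k)\,E T_j$ with hypergeometric weights
  evaluated in log space. Supplying the constant-size
  $ET_j = 2N/(j(j-1))$ reproduces the classic $1/k$ spectrum exactly.
* `expected_coalescent_times()` estimates $ET_j$ for exponential growth by
  Monte-Carlo simulation of the time-inhomogeneous coalescent (closed forms
  are not generally available); `r = 0` returns the constant-size closed
  form.
* `durrett_sfs()` implements the large-population growth approximation
  $ES_n(k) = \theta n / (r k (k-1))$ plus the singleton asymptotic
  $\theta n \ln(rN)/r$. **Validity:** this is a small-frequency limit. The
  measured relative discrepancy against the coalescent form converges (in
  `N`) to roughly $0.27\,(k-1)/(n-1)$ — about 0.5% at `k = 2`, 26% at
  `k = n - 1` for `n = 20`. Agreement within 5% holds for `k/n < 0.2`,
  where essentially all of the spectrum's mass lives, and that is the range
  over which the two routes are cross-checked.
* `multiclone_sfs()` is the composite "binomial hump" spectrum of a tumor
  with `m` selective sweeps: each clone contributes a neutral
  $1/(k(k-1))$ tail weighted by its cell fraction, and each derived clone a
  binomial hump of mass $K_i$ (the mutations marking its founding lineage)
  centred at $P_i$. In hierarchy mode the fractions come from the branch
  times and growth rates, $K_i = \theta_{j_i}(t_i - t_{j_i})$ is kept
  real-valued (it is an expectation, not a count), and — since the relation
  between centroid and clone fraction is not spelled out for general
  hierarchies — we take $P_i$ to be the summed fraction of clone `i` *and
  its descendants*, i.e. the cells whose genomes actually carry the $K_i$
  marker mutations. Direct-parameter mode accepts $(A, K_i, P_i)$ as given.
* `power_law_tail()` provides the two-type birth–death comparison curve
  $c f^{-\alpha}$ with $\alpha = \lambda_0/\lambda_1$, with its analytic
  cumulative integral; it is a comparison curve only — no two-type
  simulation is attempted.

## Neutrality testing

Under the infinite allele model the alleles of a population are its live
clones, so a run yields an allele count `k` and singleton count `a_1`. The
Ewens sampling formula gives the neutral null: the allele-count distribution
$P(K=k) = |S_n^k|\theta^k / \theta^{(n)}$ uses unsigned Stirling numbers of
the first kind, computed by the standard recurrence carried in log-sum-exp
(exact against integer arithmetic up to `n = 18`, checked against frozen
big-integer values at `n = 20`). The scaled mutation rate is
$\theta = N\mu/\lambda$ with a fitness correction $\lambda$ accounting for
cell generation length; in the neutral scenarios tested here $\lambda = 1$,
and for non-neutral ensembles the natural choice is the ensemble mean of
final population-average fitness (the functions accept any fixed value).

Two procedures are applied to ensembles of runs:

* **Allele-count K-S.** The null is discrete, so the statistic is
  $D = \max_k |F_m(k) - F(k)|$ over the support — the empirical and null
  CDFs compared at the atoms. (Feeding discrete allele counts to a
  continuous-data K-S implementation inflates `D` by the largest atom mass,
  ≈ 0.1 here, and rejects even data drawn exactly from the null; the
  package therefore computes the discrete statistic directly.) The p-value
  uses the asymptotic Kolmogorov distribution, conservative on a discrete
  null; a parametric-bootstrap p-value recalibrated under the exact null is
  reported alongside.
* **Singleton Wilcoxon.** The semi-empirical null sample is the *un-rounded*
  conditional expectation $E(A_1 \mid k_i, n)$ evaluated at each run's
  observed `k`; the observed singleton counts are compared to it with a
  two-sample two-sided Wilcoxon rank-sum test, sensitive to central
  tendency rather than shape.

With `s = d = 0`, `mu = 0.1`, `N = 100`, ensembles of 200 runs fail to
reject both tests at the 5% level in the majority of replicates — mutation
without fitness effects is correctly seen as neutral — while fitness-biased
configurations are flagged.

## Variant tables and coverage-bias correction

`read_variants()` ingests per-site total/variant read counts from TSV
(canonical) or VCF (standard `AD` allelic depths only; multiallelic sites
split into one row per alternate allele). VAF = variant reads / total reads
is the empirical analogue of the SFS frequency `k/n`.

`histogram_equalize()` removes the coverage-depth bias between two samples
of the same individual by resampling: common-width total-read histograms,
per-bin target = the lower of the two counts, and uniform pruning without
replacement of the larger subset in each bin. The bin width is not dictated
by the method; the default is the Freedman–Diaconis width of the pooled
total-read counts (floored at one read), overridable. The procedure is
idempotent, never increases a bin, and leaves retained rows untouched.

`synthesize_paired_tables()` stands in for the controlled-access patient
data: given underlying frequency multisets it draws per-site depths from a
negative binomial (over-dispersed, as real capture data is) and variant
reads binomially. It emulates depth variation, binomial sampling noise, and
partial site sharing between a primary tumor and its metastasis; it does
**not** model tumor purity, copy-number alterations, FFPE damage, mapping
artifacts, or sequencing error, so tests passing on these tables speak to
the analysis stack, not to wet-lab robustness. Files shipped under
`inst/extdata/` are generated this way and carry `synthetic` in their names.

`compare_tails()` quantifies what tail figures show visually: the
sup-distance between `log10 T` curves on the common grid (plus an
area-between-curves tie-breaker), computed over points where both tails are
positive.

## Problem sizes in the test suite

The checks run at the study conditions with replicate counts chosen to keep
the full suite near a minute: 100-run ensembles for the Model A drift
martingale (`N = 100`, `t = 100`), 50 seeds per model for clone totals at
the mutational equilibrium, three ensembles of 200 runs (down from 1,000)
for the neutrality tests, and 20 runs per model (down from 100) for the
Model A/B tail separation at `N = 200`, `s = 0.5`, `d = 1e-4`, `Nmu = 6`,
`p = 0.01`. These sizes are the package's own trade-off between Monte-Carlo
error and runtime; all tolerances are expressed in standard errors measured
from the ensembles themselves.

## Known limitations

* Constant population size only: no growing (branching-process) variant of
  the tug-of-war is implemented; growth enters only through the theoretical
  comparison spectra.
* No spatial structure, cell age/cycle structure, diploidy, or
  recombination.
* The Ewens machinery assumes the infinite allele model and
  mutation–drift equilibrium; applying it far from equilibrium (short
  horizons, strong selection) is a test of those assumptions, not a bug in
  the data.
* Tail comparison assumes normalized tails on overlapping grids; it does
  not fit parameters (no likelihood or least-squares estimation of hump
  parameters is attempted).
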