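# tugwar

Stochastic simulation and spectrum analysis of the **tug-of-war** between
driver and passenger mutations in tumors, in a constant-population Moran
framework.

Tumor cell populations accumulate two kinds of point mutations: rare
**drivers** that raise a cell's fitness by a factor `1 + s`, and frequent,
mildly deleterious **passengers** that lower it by `1 - d`. A cell with
`α` drivers and `β` passengers has fitness

```
f(α, β) = (1 + s)^α (1 − d)^β .
```

The population of `N` cells evolves by death–replacement events (total rate
`Σ_P`, the summed fitness of all cells) and mutation events (total rate
`Nμ`; driver with probability `p`). Two variants differ only in how the
dying cell is chosen, and the difference is diagnostic of the mode of
selection:

* **Model A** — dying cell drawn ∝ fitness, replacing cell drawn ∝ fitness.
  The expected fitness change per drift event is exactly zero, so mean
  fitness follows the mutation balance alone (constant when
  `s p = d (1 − p)`).
* **Model B** — dying cell drawn uniformly, replacing cell drawn ∝ fitness.
  The expected change per event is `Σf²/Σf − mean(f) ≥ 0`: drift is biased
  toward fitness increase.

The package is aimed at researchers in cancer evolution / population
genetics who want to simulate these chains with full clone genealogies,
summarise populations and sequencing data as **site frequency spectra**
(SFS) and their cumulative tails `T(x) = ∫ₓ¹ S(ξ) dξ`, compare them against
theoretical expected spectra (Griffiths–Tavaré coalescent form, the
exponential-growth approximation `ES(k) = θn/(r k(k−1))`, a multiclone
binomial-hump model, and power-law curves `c·f^(−λ₀/λ₁)`), run Ewens
sampling formula **neutrality tests** (allele-count Kolmogorov–Smirnov and
singleton Wilcoxon), and correct coverage-depth bias between paired tumor
variant tables by total-count **histogram equalization**.

## Worked example

Simulate Model A at its mutational equilibrium (`s p = d (1 − p)`):

```r
library(tugwar)

params <- tugwar_params(N = 100, mu = 0.1, p = 0.0909, s = 0.1, d = 0.01,
                        t_max = 100)
set.seed(42)
run <- sim_run(params)
run
#> <tugwar_run> Model A, N = 100, t = 100: 1018 clones ever created, 10685 events
```

`Nμt = 1000` mutation events are expected, each founding one clone, so the
1,018 clones ever created (initial clone included) sit where the Poisson
argument puts them (mean ≈ 1001, sd ≈ 32). Of those, only 24 clones are
still alive at `t = 100` — drift keeps pruning the genealogy:

```r
glance(run)
#> # A tibble: 1 × 9
#>   model     N t_final clone_total clones_alive death_replacements ...
#> 1 A       100     100        1018           24               9668 ...
```

The observed spectrum and its normalized cumulative tail:

```r
sfs <- observed_sfs(run$final)       # 49 segregating mutations
tl  <- cumulative_tail(sfs_frequencies(sfs))
head(tail_table(tl), 3)
#> # A tibble: 3 × 3
#>       x     T log10_T
#> 1  0.01 1      0
#> 2  0.02 0.878 -0.0567
#> 3  0.03 0.755 -0.122
plot_tails(list(model_A = tl))       # semi-log tail plot
```

Under the infinite allele model the 24 live clones are 24 alleles; the
Ewens sampling formula with `θ = Nμ/λ = 10` expects `E[K] ≈ 24.4` — this
run is indistinguishable from neutral drift in allele counts, which is the
point of the neutrality-test module (`allele_count_test()`,
`singleton_test()`) when applied to ensembles of runs.

Paired variant tables (e.g. primary tumor and lymph-node metastasis) are
handled by the VAF module:

```r
a <- read_variants(system.file("extdata", "synthetic_primary.tsv",
                               package = "tugwar"))
b <- read_variants(system.file("extdata", "synthetic_lymphnode.tsv",
                               package = "tugwar"))
eq <- histogram_equalize(a, b)       # per-bin minimum rule, FD bin width
vafs <- lapply(eq[c("a", "b")],
               function(t) Filter(function(x) x > 0, vaf_frequencies(t)))
compare_tails(cumulative_tail(vafs$a),
              list(lymph_node = cumulative_tail(vafs$b)))
#> # A tibble: 1 × 4
#>   model      sup_distance area_between n_grid
#> 1 lymph_node        0.834       0.0992     74
```

A thin command-line front end over the same functions lives at
`inst/cli/tugwar.R` (subcommands `simulate`, `sfs`, `theory`, `neutrality`,
`equalize`, `compare`).

## Package layout

| File | Contents |
| --- | --- |
| `R/params.R`, `R/population.R` | parameters, clone-multiset populations, genealogy, carrier counts |
| `R/fitness.R` | fitness formula, exact expected-increment enumerations, sampling pmfs |
| `R/simulate.R`, `src/sim_core.cpp` | event-driven simulator (compiled core + pure-R reference step) |
| `R/spectra.R` | observed SFS, cumulative tails, VAF extraction, tail I/O |
| `R/theory.R` | coalescent, growth-approximation, multiclone-hump and power-law spectra |
| `R/neutrality.R` | log-space Stirling numbers, Ewens distributions, the two tests |
| `R/vaf.R` | variant-table I/O, histogram equalization, synthetic paired tables |
| `R/plots.R` | ggplot2 `autoplot()` / `plot_*()` methods |

The methods vignette (`vignettes/tug-of-war-models.Rmd`) documents the
models, the numerical choices, and the design decisions in detail.
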