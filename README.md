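# pathvar

Cell-to-cell variation in the expression of signaling proteins has two
opposing consequences. For a single cell transmitting an *analog* signal —
an output amplitude that tracks the input amplitude — expression noise is
purely harmful: it blurs the mapping from stimulus to response. For a
population of cells making a *binary* decision — divide or not, differentiate
or not — the same noise is what spreads activation thresholds across cells,
so that the **fraction** of activated cells can be dialed smoothly by the
stimulus instead of flipping all-or-none. `pathvar` implements a modeling and
statistics toolkit for quantifying this trade-off, together with the
single-cell measurement pipeline needed to estimate expression variation
(CV) and covariation (Pearson correlation of per-cell concentrations) from
targeted-proteomics and immunofluorescence data.

## The model and the two accuracy metrics

The core model is a five-step linear cascade: a fold-input `R` activates
`y1`, whose active form activates `y2`, down to the output `A* = y5*`. Each
of the ten activation/deactivation rates carries a per-cell lognormal factor
`eps_i = exp(z_i * CV)`, `z_i ~ N(0, 1)`, modeling expression variation of
the corresponding pathway component. With inactive pools held at 1 the fixed
point is exact:

    A* = R * (eps1 eps3 eps5 eps7 eps9) / (eps2 eps4 eps6 eps8 eps10)

so `log A* ~ Normal(log R, CV * sqrt(N))` for `N` independent components.

Two closed-form metrics summarize the trade-off:

- **fold-Input Detection Limit (fIDL)** — the smallest fold-input whose
  output distribution is distinguishable from the unstimulated one with 95%
  accuracy:

      fIDL = exp(2 * qnorm(0.95) * CV * sqrt(N)) = exp(alpha * CV * sqrt(N)),
      alpha ~ 3.3

- **apparent Hill coefficient (aHC)** — the steepness of the
  percent-activated dose-response of a thresholded (binary) version of the
  same cascade; the inverse measure of the controllable input range:

      aHC = beta / (CV * sqrt(N)),  beta ~ 1.4

Their product `log2(fIDL) * aHC = alpha * beta / ln 2` is a constant,
independent of CV and N: making analog transmission more accurate makes
binary population control proportionally coarser, and vice versa. With
`n_cov` perfectly covarying components the effective total CV becomes
`CV * sqrt(N - n_cov + n_cov^2)`, so covariation moves a pathway along the
same trade-off curve without changing any single protein's CV.

The package also includes a Sturm-type MAPK (Raf–MEK–ERK) cascade with
negative feedback and a bistable ERK phosphorylation cycle, which turns 15%
lognormal variation in MEK/ERK totals into bimodal terminal pERK, plus a
measurement-statistics module (median-of-reference correction factors,
per-batch CVs with bootstrap intervals, BH-adjusted pairwise correlations,
DNA-content gating, total-protein-mass normalization, FRET activity
scoring) and synthetic-data generators with known ground truth for all of
it.

## Worked example

```r
library(pathvar)

# analytic detection limits at 5, 10, 25% component CV (N = 10)
fidl_analytic(cv = c(0.05, 0.10, 0.25), n_components = 10)
#> [1]  1.682277  2.830057 13.473731

# the same limit estimated by simulating 100,000 cells
ns <- noise_spec(cv = 0.10, mode = "independent", seed = 1)
fidl_simulated(ns, n_cells = 1e5)
#> [1] 2.85065

# binary model: percent-activated dose-response and its Hill fit
spec <- binary_model_spec(noise_spec(0.10, "independent", seed = 1),
                          threshold = 10)
fit_hill(dose_response(spec))
#> hill_fit: h = 5.356, k_half = 9.998 (SSR 0.0004543, nls)

# the analog/binary co-dependency curve
tradeoff_curve(cv = c(0.05, 0.10, 0.40))
#>     cv n_components n_cov  cv_total      fidl log2_fidl      ahc  product
#> 1 0.05           10     0 0.1581139  1.682277 0.7504155 8.854377 6.644462
#> 2 0.10           10     0 0.3162278  2.830057 1.5008310 4.427189 6.644462
#> 3 0.40           10     0 1.2649111 64.147627 6.0033240 1.106797 6.644462
```

Reading the numbers: with 10% CV per component a cell can just distinguish a
2.8-fold input change (at 25% CV only a ~13-fold change), while the
population dose-response behaves like a Hill curve with coefficient ~5.4 —
steep, i.e. poor population-level control. The product column is the
invariant of the trade-off: ~6.6 whatever the CV.

Higher-level experiment bundles (each writing CSV/JSON plus a manifest) are
available through `run_experiment()`; see `list_experiments()`. A thin
command-line wrapper lives at `inst/cli/workbench.R`.

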