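---
title: "Methods: isotope-dilution estimation of N2 fixation in multi-harvest trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope-dilution estimation of N2 fixation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixntrace)
```

## The model

A ¹⁵N isotope-dilution trial feeds plants from three nitrogen pools:
labelled fertiliser (enrichment $E_{fert}$ atom % ¹⁵N excess), unlabelled
soil N, and atmospheric N₂ (natural abundance, zero excess). Tissue
enrichment is measured as atom % ¹⁵N abundance and corrected for the
natural background:

$$AE = \text{abundance} - 0.3663 .$$

A plant that derives part of its N from the atmosphere dilutes the label.
With a non-fixing reference plant grown under the same tracer supplying
the undiluted baseline, the atmospheric share is

$$\%Ndfa = 100\left(1 - \frac{AE_{fixing}}{AE_{reference}}\right),$$

and the amount fixed is $\%Ndfa/100 \times TN$ for the total N ($TN$) of
the same scope. For the whole plant top, the enrichment entering the
formula is the total-N-weighted atom excess over the above-ground parts:

$$WAE = \frac{\sum_i AE_i\,TN_i}{\sum_i TN_i},$$

a convex combination (always within the range of the part excesses,
invariant to rescaling all $TN_i$). Roots are weighed but never analysed
for N or ¹⁵N, so they enter whole-plant biomass only.

Assumptions inherited from the design: the reference treatment fixes no
N₂ but otherwise samples the fertiliser and soil pools like the test
plants (similar phenology and rooting); enrichment differences between
treatments reflect atmospheric dilution, not pool-sampling differences.
The fertiliser enrichment itself (4.72 atom % excess here) cancels out of
the estimator and is carried as metadata only.

## Parameters that matter

| parameter | unit | default | role |
|---|---|---|---|
| `natural_abundance` | atom % | 0.3663 | background subtracted from every measured abundance |
| `reference_treatment` | label | — | defines $AE_{reference}$ per part and harvest |
| `planting_density` | plants/ha | 53,333 | per-hectare extrapolation (mg/plant × density × 10⁻⁶ = kg/ha) |
| `fertilizer_enrichment` | atom % excess | 4.72 | metadata; never used by the estimator |
| `harvest_days` | days after planting | 50, 65 | rate denominators; the ear exists only from the last harvest |
| `alpha` | — | 0.05 | level of all letter displays |

## Two aggregation paths

`ndfa_pipeline()` offers `replicate_first` (default) and `mean_first`.

* **replicate_first** pairs each block's excess with the reference
  treatment's *mean* excess for that part and harvest, averages the
  per-block estimates and reports their SEM. This is the only path that
  yields per-cell standard errors, and is what a trial computing %Ndfa
  from raw replicates does.
* **mean_first** applies the estimator to the cell means. It carries no
  SEM but is the only path reproducible from published summary tables,
  so it drives the worked examples and the acceptance script
  (`ndfa_from_summary()`).

The two coincide exactly when blocks are identical (tested). They differ
slightly on real data because the mean of ratios is not the ratio of
means. A related consequence: a plant-top WAE recomputed from tabulated
*part means* does not generally equal a published plant-top WAE computed
per replicate — for the packaged trial's reference treatment the part
means give ≈1.21 against the tabulated 1.259. `ndfa_from_summary()`
therefore uses tabulated plant-top WAE rows verbatim when present
(`use_printed_top = TRUE`), and only falls back to recomputation when
they are absent.

Negative estimates (sample more enriched than reference) and
below-background excesses are reported with flags (`negative_ndfa`,
`below_background`), never silently clipped; `clip_negative = TRUE`
exists for reporting parity and adds a `clipped` flag.

## Inference

The trials this package serves report one-way ANOVA within each harvest
followed by Duncan's multiple range test, despite the blocked layout;
the default layout therefore omits the block factor, and a block-aware
two-way fit is available through `two_way_anova()`. DMRT critical ranges
are built from the studentized range quantile at Duncan's protection
level $\alpha_p = 1-(1-\alpha)^{p-1}$ for a stretch of $p$ ranked means:
$R_p = q(\alpha_p, p, df_e)\sqrt{MS_e/n}$. The implementation sweeps
stretches widest-first with the containment rule (a homogeneous stretch
declares all sub-stretches homogeneous untested) and assigns letters to
the maximal homogeneous intervals, so the largest mean always holds
letter "a". At $p = 2$ the protection level collapses and the decision
equals Fisher's LSD (tested against an independent all-pairs oracle).
Unbalanced group sizes are refused unless the caller opts into the
harmonic-mean approximation.

Between-harvest (uppercase) letters run the same test on the two harvest
groups within each treatment × part, each part fitted separately — error
terms are not pooled across parts, since part variances differ by an
order of magnitude. Multiple testing across response variables is *not*
corrected, matching field reporting practice for these tables; reports
note this.

Sink/source classification of between-harvest fluxes is gated on the
uppercase letters (a non-significant ΔN is `neutral` regardless of
sign); `raw = TRUE` disables the gate. When the three evidence streams
(ΔN, Δbiomass, Δexcess) disagree, classification follows ΔN only — the
other two deltas are reported alongside for the reader.

## The synthetic generator

`trial_scenario()`/`simulate_trial()` emulate the randomised
complete-block structure the estimators assume: 6 treatments × 4
blocks × 2 harvests × up to 6 above-ground parts. Biomass is lognormal
around its part × harvest mean (CV-parameterised, biological quantities
are positive) times a multiplicative lognormal block effect; N
concentration is lognormal; tissue excess follows the three-pool model

$$AE = f_{fert}\,E_{fert}\,(1 - Ndfa_{true}),$$

with only the fertiliser pool labelled; measured abundance adds the
natural background and Gaussian instrument noise (emission-spectrometer
behaviour) and is truncated just above zero. Default noise levels
(10 % biological CVs, 0.02 atom % instrument SD, 5 % block effects) sit
at the tabulated trial's SEM magnitudes. The fertiliser-derived fraction
$f_{fert}$ is a free scenario parameter because trials rarely report it;
the defaults (0.267 at day 50, 0.234 at day 65) are the values implied
by dividing the packaged reference treatment's plant-top WAE by the
4.72 atom % source. `reference_trial_scenario()` back-computes a full
scenario (cell means, CVs, per-cell true Ndfa) from the packaged summary
tables. Scenarios carry a mandatory seed; simulation is byte-identical
under the same seed and leaves the caller's RNG stream untouched.

What the generator does **not** emulate: plant growth dynamics and
soil-N cycling (pool fractions are fixed per harvest, not emergent),
spatial pot effects, reference-plant bias (the simulated reference
samples pools exactly like the test plants), and measurement drift.
Passing parameter-recovery tests therefore show the estimators invert
the assumed mixing model correctly at realistic noise — not that the
assumptions hold in any particular field trial.

## Numerical and design choices

* Reporting precision mirrors trial tables: %Ndfa and rates to one
  decimal, excess to three decimals, N to whole mg.
* All-constant ANOVA input is a defined degenerate path (F = 0, p = 1),
  not an error; zero-residual "perfect fit" warnings are muffled.
* `%N` concentration input is converted on load
  (`total_n = biomass × %N × 10`, g → mg); an absent ear before anthesis
  is structural (renders "N/A"), not missing data.
* The pipeline's report bundle is deterministic: identical input and
  configuration give byte-identical files; provenance records the input
  hash, configuration and package version (no timestamps).
* Test problem sizes were chosen for tight Monte-Carlo error at
  interactive runtimes: 200 blocks for the ±1-point Ndfa recovery check,
  2000 simulations for the null interaction-p uniformity check, 120
  four-block trials for the interval-coverage check, 500 random
  instances for the DMRT oracle comparison.

## Known limitations

* With four blocks, mean ± 2·SEM intervals cover the truth at ≈83 %,
  not 95 % (three degrees of freedom; the reference-mean pairing adds
  correlated noise). The recovery report states coverage rather than
  assuming nominal.
* `replicate_first` pairs blocks with the reference *mean*, so block
  effects common to sample and reference do not cancel within a block;
  with strong block effects the SEMs are conservative.
* Part-level %Ndfa assumes the reference's same part is a valid baseline
  for that part; parts with near-background reference excess would make
  the estimator unstable (guarded by the positive-reference error).
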