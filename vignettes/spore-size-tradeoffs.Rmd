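---
title: "Methods: offspring-size trade-offs and phylogenetic signal in AM fungi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: offspring-size trade-offs and phylogenetic signal in AM fungi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporetrade)
```

## The scientific problem

Arbuscular mycorrhizal (AM) fungi, subphylum Glomeromycotina, reproduce
through large asexual spores, and described species differ in spore size by
orders of magnitude. `sporetrade` treats the spore as the fungal *offspring*
and asks the two classic questions of reproductive ecology: does offspring
size trade off against offspring number, and how do both scale with parental
body size?

The trade-off model is the Smith–Fretwell budget partition

$$R = \frac{A}{W_0^{\,b}},$$

where $R$ is spore output (spores per g soil in a fixed time window), $A$ is
the total mass allocated to sporulation, $W_0$ is the mass of one spore, and
$b$ is the trade-off exponent. On log scales this is a line of slope $-b$:
$b = 1$ means a fixed budget split into few large or many small spores
(inverse proportionality); $0 < b < 1$ means large-spored species enlarge the
budget itself. Allometric scaling of total reproductive output with body size
$W_\alpha$ (total mycelium mass) is modelled as
$R\,W_0 = \sigma W_\alpha^{\beta}$.

## From taxonomic descriptions to spore sizes

Taxonomic descriptions report spore diameters as ranges: an inner range
holding most spores and an outer range with extremes. `spore_sizes()`
collapses the chosen range pair to one diameter per axis by its midpoint —
the only reading of "the mean of the two range values" that yields a single
diameter — and computes volumes as spheres for globose spores,
$V = (\pi/6)d^3$, or prolate spheroids for sub-globose spores with the short
axis duplicated, $V = (\pi/6)\,d_{long}d_{short}^2$. The inner range is the
default basis, being the more representative estimate; the outer basis is
retained for sensitivity, and records lacking an outer range fall back to the
inner one with a message. Dimorphic Ambisporaceae species carry two entries
(glomoid and acaulosporoid spore types); single-trait analyses select one
morph explicitly via `select_morph()`, and the pipeline runs the signal
analysis once per morph set.

Volume converts to mass with the only published joint volume/weight
measurement for an AM fungus: $1\ \mu m^3 = 3.64\times10^{-7}\ \mu g$.

Cross-taxa comparisons (`compare_taxa()`) summarize each group's quartiles
and orders of magnitude spanned, and report fold-differences as ratios of
*geometric* means: all analyses are on log scales, where the geometric mean
is the natural location; the arithmetic-mean ratio is reported alongside.

## Biomass conversions

Colonization assays give root ergosterol (µg/g root), soil hyphal length
(m/g soil) and spore density (spores/g soil). Conversions, bundled in
`conversion_constants()`:

* ergosterol → intraradical hyphal length via inversion of the linear
  calibration $E = 0.4L + 0.18$. Values below the 0.18 µg intercept would
  imply negative lengths and clamp to zero with a warning — colonization
  below the calibration floor is treated as none.
* hyphal length → dry mass assuming cylindrical hyphae of constant radius
  4 µm (mid-value of the 1–10 µm range reported for AM hyphae) and a dry
  density of 0.23 g/cm³; one meter is then 11.56 µg. The radius is fixed
  across species; sensitivity analyses can override it, and non-default
  constants are logged.
* body size $W_\alpha$ = root + soil hyphal length in common meters, as
  cylinder dry mass. Spore output is kept per g soil while the compartments
  are normalized per g of different substrates; slopes of the log-log fits
  are invariant to any common per-species rescaling, so the densities are
  used as published.

Replicates (5 per species × host) are averaged to species × host means
*before* conversion: each fitted point is one species growing with one host.
All conversions except the ergosterol clamp are linear, so aggregation and
conversion commute whenever ergosterol stays above the intercept; a
per-replicate mode is available.

## SMA regression and the slope test

Both axes of an allometric plot carry error, so the line of interest is the
standardized major axis: slope $\mathrm{sign}(r)\,s_y/s_x$, which ordinary
least squares attenuates by exactly $|r|$. Confidence intervals and the
correlation test use the standard $F$ statistic with $n-2$ df; the test of a
hypothesized slope $b_0$ correlates the residual axis $y - b_0x$ with the
fitted axis $y + b_0x$. The hypothesis $b_0 = 0$ is undefined for SMA (the
rotation degenerates) and is rejected with an error; slope-vs-zero questions
are answered by the correlation test. When the data lie on the hypothesized
line up to floating-point noise, the test correlation is set to zero and
$p = 1$ rather than letting rounding noise masquerade as signal.

Logs are base 10 throughout; slopes are base-invariant and intercepts are
reported in base-10 units. Tests are two-sided at a fixed 95% level and no
multiple-testing correction is applied. "Controlling for body size" is
implemented as ratio normalization — spores per meter of extraradical
mycelium, spores per µg of mycelium — with residual regression available as
an alternative; the three variants plus the allocation–size relationship are
fitted on the same species × host points. A variant whose derived axis is
degenerate (e.g. constant allocation in a noiseless construction) is skipped
with a message instead of aborting the others.

## Phylogenetic signal

Pagel's $\lambda$ multiplies the off-diagonal of the Brownian-motion tip
covariance while preserving tip-to-root variances. The fit profiles
$\lambda$ over $[0, \lambda_{max}]$ — $\lambda_{max}$ the largest value
keeping every terminal branch non-negative, so slightly above 1 on
ultrametric trees — with a 21-point grid scan followed by bounded
optimization (the profile can be rugged, with a narrow ridge just inside
$\lambda_{max}$ where the covariance nears singularity; the grid prevents
the optimizer from missing the global optimum, and endpoints are always
evaluated). Per candidate $\lambda$, the rate $\sigma^2$ and root state are
solved in closed form by GLS through a Cholesky factorization. The estimate
is invariant to affine trait transforms, hence to the log base. Trees need
not be ultrametric.

Significance comes from a likelihood-ratio test against $\lambda = 0$.
Because zero is a boundary, the default reference is the 50:50 mixture of a
point mass and $\chi^2_1$; plain $\chi^2_1$ is available. A caveat measured
by this package's own simulations (and echoed by the acceptance suite): on
200-tip ultrametric trees the boundary estimate occurs well over half the
time under the null, making the realized type-I error ≈ 0.01 at nominal
0.05. The test is *conservative* — it understates, never overstates,
evidence for signal — so strong reported signal survives the caveat, but the
mixture approximation should not be read as exactly calibrated at these tree
sizes.

Independent contrasts follow Felsenstein's pruning recursion on a fully
bifurcating tree; polytomies are resolved to zero-length bifurcations with a
logged count, and two zero-length sister branches (which would make a
contrast variance zero) are an error. Contrast correlations are forced
through the origin, as contrast signs are arbitrary, with $n_{contrasts}-1$
df. The PIC follow-up to the trade-off runs when the uncorrected correlation
is significant at $\alpha = 0.05$ and a tree is supplied, on host-averaged
species values.

## What the generator emulates

`simulate_allocation_experiment()` uses the Smith–Fretwell model
*generatively*: per species, $W_0$ and $A$ are lognormal (log10-scale
parameters), expected output is $A/W_0^{b}$, each host multiplies
sporulation by a lognormal effect, and each replicate applies independent
mean-1 lognormal noise to every measured quantity. Lognormals keep every
quantity positive and make the model exactly linear in logs, so noiseless
configurations recover slopes to machine precision. Body size is generated
with a configurable log-scale correlation to allocation and split into root
and soil compartments; the root compartment is re-expressed as ergosterol
through the *forward* calibration so that analysis must exercise the
inversion. Defaults mirror the analyzed greenhouse design — 14 species × 4
hosts × 5 replicates — with replicate CV 0.3 and host-effect SD 0.2 (log10),
typical magnitudes for greenhouse colonization assays; allocation spans
roughly an order of magnitude around 3 µg/g and spore masses center on
0.1 µg. One global seed fans out to named substreams so stages regenerate
independently.

What the generator does *not* emulate: measurement error structure specific
to ergosterol assays, host × species interactions beyond a multiplicative
host effect, non-lognormal heavy tails, or intraspecific spore-size
variability. Passing recovery tests therefore demonstrates correctness of
the estimators under the stated generative model, not robustness to every
failure mode of real colonization data.

`synthetic_reference_tables()` builds clearly-labelled *synthetic* stand-ins
for the published reference datasets used in cross-taxa comparisons: 294 AM
species with per-family counts and per-family log10 volume ranges following
the documented family structure (six dimorphic Ambisporaceae included), and
360 soil-ascomycete conidia species with realistic few-µm conidial
dimensions. They exercise parsing and comparison statistics offline; they
are not the published data, and per-species values are random within the
documented ranges.

## Numerical choices and degenerate inputs

* λ optimization: grid-then-`optimize` with tolerance 1e-8; the search range
  is capped at 10 on pathologically non-ultrametric trees.
* Cholesky failure (non-PD covariance) returns `-Inf` likelihood rather than
  an abort, so profiling skips infeasible λ.
* Diameter validation enforces `0 < low <= high` per range; sub-globose
  records must carry a short-axis inner range; species × morph must be
  unique. Swapped axes (short > long) are corrected by exchange rather than
  rejected, since antecedent descriptions occasionally list axes
  inconsistently.
* Zero variance in a fitted axis is an error for the primary axis (spore
  mass, body mass) and a logged skip for derived variants.
* Non-positive species × host points (e.g. zero spore counts) are excluded
  from log-scale fits with a message stating the count.

## Problem sizes

The bundled tests and the acceptance script run, by choice, at: 200-tip
trees with 200 simulated datasets per λ truth for signal recovery; 500
replicates for test-calibration rates; 100 random datasets for the SMA
brute-force cross-check; and the default 14 × 4 × 5 design for pipeline
runs. These sizes put Monte-Carlo error comfortably inside the asserted
tolerances while keeping a full run on one CPU within a few minutes.

## Known limitations

* Ergosterol is an imperfect biomass proxy for some AM fungi; the package
  inherits the calibration as published and offers no per-species radii.
* The λ LRT conservatism discussed above.
* Fold-difference comparisons on the synthetic reference tables validate the
  machinery, not the published species values.
* No mixed-effects or host-stratified models: points are pooled across hosts
  for the headline fits (per-host subsets can be fitted by filtering the
  allocation table before `tradeoff_analysis()`).
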