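---
title: "Models and methods behind galliso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind galliso}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(galliso)
```

`galliso` analyses compiled records of interspecific hybridization in
landfowl: which pairs have crossed, how their F1 offspring fared
(sterile, only males fertile, both sexes fertile), and how long ago the
parental lineages diverged. This vignette is the package's own account
of the models it fits, the choices made where the design was genuinely
open, and what its synthetic test bed does and does not establish.

## The data model

A *cross* is an unordered species pair with a categorical fertility
outcome and a divergence time in million years (MY). Pairs are
canonicalized alphabetically and subspecies are collapsed to the species
level, so a pair enters at most once; listing the same pair with
conflicting outcomes is treated as a data error rather than silently
resolved. The ordinal *isolation score* maps the outcome to 1 (sterile),
2 (male-only — the Haldane's Rule stage, since female birds are the
heterogametic ZW sex), 3 (both fertile). The summary statistics report a
dispersion interval for divergence, mean ± 1.96 sd. A source table may
label such an interval "CI"; for a quantity whose printed width spans
most of the data range that reading (a population interval, not a
standard-error interval) is the only consistent one, and the package
computes it explicitly as such.

## Logistic time courses

Both time courses are plain binomial-logit regressions on divergence
time, fitted by IRLS (convergence when the largest coefficient change
falls below 1e-8, at most 100 iterations). The Haldane regression uses
only crosses with some fertile offspring and models the male-only
indicator; the speciation regression uses all crosses and models the
sterile indicator. Each is summarized by the 50% *crossing point*
−β₀/β₁. The response coding is the "more isolated outcome = 1"
direction, so that probability rises with divergence; flipping the
coding negates both coefficients and leaves the crossing point
identical, which the tests assert, so nothing of substance rides on the
choice. A slope within 1e-12 of zero has no crossing and is an error
("flat time course"). Complete separation — possible in small compiled
datasets when outcome classes occupy disjoint divergence ranges — makes
the MLE diverge; it is detected as a standardized coefficient exceeding
50 and raised as an error rather than returning the meaningless
iteration limit.

## Predictors of the isolation score

Per-pair predictors are symmetric by construction: a habitat match
indicator (exact label equality after trimming and case-folding),
absolute clutch-size difference, and absolute differences in 11
morphological measurements. The difference matrix is centred and scaled
to unit variance before PCA because the variables mix millimetres and
grams; unscaled, mass dominates the first axis. Scaling is exposed as
`pca_scale` so both conventions can be compared. Mass is not
log-transformed before differencing. Zero-variance difference columns
are dropped with a warning (the loadings shrink accordingly); pairs with
incomplete traits are dropped and counted, not imputed.

The isolation model is Gaussian: `ri_score ~ divergence + clutch_diff +
pc1 + pc2 + habitat_match`. Treating an ordinal 1–3 response with a
linear model is deliberate — the downstream index arithmetically
averages residuals, which only makes sense on that scale, and the
Gaussian likelihood (at the ML variance RSS/n, with the variance counted
in k) gives AIC values on the conventional scale for model comparison.
Selection is bidirectional stepwise AIC starting from the full model,
stopping at a local minimum, with ties broken toward fewer terms and
then lexicographic term order, making the selected set invariant to
predictor column order. Candidates with zero variance (every pair
sharing a habitat, say) are removed before selection since they carry no
information and would make the design singular. McFadden's pseudo-R²,
1 − ℓ(fit)/ℓ(null), is reported against the intercept-only model using
the same Gaussian likelihoods.

## The reproductive-isolation and domestication indices

The species-level RI index is the mean residual of the score-on-
divergence regression over all crosses involving the species; each
cross's residual is attributed to both members. Because OLS residuals
with an intercept sum to zero, the record-weighted index sum vanishes —
a checked invariant. Positive values mean a species' crosses are more
fertile than divergence predicts.

The domestication index counts occurrences of each species' name
variants across a plain-text corpus. Matching is case-insensitive on
word boundaries (letter/non-letter transitions); hyphens become spaces
and a hyphen at a line break rejoins the wrapped word, since historical
OCR text wraps names freely. Variants are scanned longest-first (token
count, then length, ties lexicographically) and matched spans are
consumed, so "ocellated turkey" never also counts as "turkey". Each
variant must map to exactly one species; ambiguity is a load-time error.
Counts are occurrences, not documents containing. Scaling is min–max to
[0, 1] — both endpoints are attained, which suits an index meant to
span "never kept" to "ubiquitous" — with divide-by-max available
(`method = "maxdiv"`); post-scaling overrides (e.g. pinning the chicken
to 1) are clamped to [0, 1]. Counts are not normalized by corpus or
document size; raw totals are the index's basis.

## Phylogenetic layer

Under Brownian motion the trait covariance of two tips is their shared
root-to-MRCA branch length; for an ultrametric tree of height H this is
H − T_ij (T the divergence time). PGLS solves the GLS normal equations
through a Cholesky factorization of V = C(λ), reports the slope's F-test
against the intercept-only GLS fit (matching the F-statistic reporting
convention of comparative analyses), and defines R² as 1 − RSS/TSS in
the whitened space. λ defaults to 1 (pure Brownian) with `fixed_0` and
`ml` modes; the ML profile is optimized on [0, 1] with both endpoints
checked, since the optimum frequently sits on the boundary. Tips missing
from either index table are pruned with a message; the reported n is the
n actually used.

Phylogenetic signal offers both common statistics, neither privileged:
Pagel's λ by ML with a likelihood-ratio test against λ = 0, and
Blomberg's K with a seeded tip-permutation test using the add-one
convention p = (1 + #{K_perm ≥ K_obs}) / (n_perm + 1), which cannot
return zero and is bounded below by 1/(n_perm + 1).

## Bias diagnostics

The permutation null for a species with n records draws n residuals from
the full pool without replacement and averages them, 10,000 times by
default, with a two-sided p on |mean| — the question is whether any
species is more *or* less compatible than expected. The focal species'
own residuals stay in the pool by default (`exclude_focal` removes
them); with at most a handful of records per species against a pool of
over a hundred residuals the difference is immaterial, and inclusion is
the simpler exchangeability statement. The Bonferroni threshold is
computed as 0.05 divided by the number of species actually tested rather
than hard-coded, and is reported alongside each p-value. The second
diagnostic regresses the index on the record count and reports the slope
t-test and McFadden pseudo-R².

## The synthetic test bed

The generator's defaults are the study conditions: 77 species, 123
crosses, a pure-birth tree rescaled to 65 MY (the clade's age back to
the K–Pg boundary). Tree shape carries no claim here, so the simplest
ultrametric generator (Yule) suffices. Morphology evolves by Brownian
motion (σ² = 0.1 per MY from a common root), clutch size by Brownian
motion on the log scale (σ² = 0.005 around a root of 8 eggs, keeping
tips in the realistic 4–15 egg range), and habitat by a symmetric
3-state Markov jump process at 0.01 switches per MY, giving the
phylogenetic clustering that real habitat classes show. Pairs are
sampled with weight exp(−T/6), reflecting that recorded hybridizations
overwhelmingly involve close relatives; this reproduces the observed
mean divergence near 14 MY among hybridizing pairs. Uniform sampling is
available with `pair_weight_scale = Inf`.

Outcomes come from an ordered-logit model: latent
η = β₀ + β_T·T + β_C·|Δclutch| plus standard logistic noise, thresholded
at cutpoints c₁ < c₂. Defaults β₀ = 0, β_T = 0.15, β_C = 0.1, c₁ = 1.15,
c₂ = 2.9 place the latent male-only boundary near c₁/β_T ≈ 7.7 MY and
the sterile boundary near c₂/β_T ≈ 19.3 MY — the reported time course of
Haldane's Rule and speciation in this clade. The ordinal-by-construction
model makes the category probabilities monotone in divergence, which is
the framework the analysis assumes; with β_C = 0 the sterile indicator
is *exactly* logistic in T with slope β_T, which the parameter-recovery
test exploits. Corpus documents plant a known number of occurrences of
one variant per species among filler words, including a deliberately
overlapping name pair, so scanner recovery can be checked exactly.

A master seed drives per-stage substreams (seed + stage offset), so
adding a stage never perturbs earlier stages and a fixed configuration
is bit-identically reproducible, including every file the pipeline
writes.

What the generator does *not* emulate: real Galliformes trait values or
geography, correlated observation effort (domesticated species being
crossed more often and with more distant partners — precisely the bias
the diagnostics are for), misidentified or dubious records, and real
magazine prose (OCR noise beyond hyphenation/wrapping). Passing tests
establish that the machinery computes what it claims on data satisfying
the model's assumptions, not that those assumptions hold for any
particular compiled dataset.

## Problem sizes and numerical conventions

The test suite works at desk scale: grid-oracle logistic fixtures of
n ≤ 12, 1,000-replicate Monte-Carlo checks of the Brownian variance law,
200 replicates for E[K] ≈ 1, 2,000-cross runs for selection behaviour,
1,000-cross runs for parameter recovery, 500 simulated species-tests for
permutation-p uniformity, and exhaustive enumeration for permutation
pools of size ≤ 8. Stepwise AIC moves only on improvements larger than
1e-10 to keep tie-breaking exact across platforms; reports write floats
at 6 significant digits so reruns are byte-comparable.

## Known limitations

The ordinal score discards within-category variation (e.g. partial
fertility); the Gaussian treatment of a 3-point scale is a pragmatic
convention shared with the residual-averaging index rather than a
calibrated measurement model. Divergence times are taken as point
inputs with no uncertainty. The domestication index conflates captive
popularity with domestication proper and depends on lexicon
completeness. Single-predictor PGLS only — the analysis design has one
predictor — and no Ornstein–Uhlenbeck or other non-Brownian covariance
structures. Small-n species indices are noisy means with no shrinkage,
by design, since the permutation null accounts for their sample sizes.
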