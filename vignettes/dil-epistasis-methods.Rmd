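---
title: "Inferring epistasis among introgressions: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring epistasis among introgressions: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidil)
```

# The inference problem

A double-introgression line (DIL) carries two short donor-species
chromosomal segments, homozygous, in an otherwise isogenic recipient
background; its two parental introgression lines (ILs) each carry one of
them. If the two segments affect hybrid fertility independently, the
DIL's relative fitness should be predictable from its parents'. A
systematic departure from that prediction is epistasis between
conspecific introgressions, and its sign distinguishes antagonistic
interactions (the double hybrid is *less unfit* than predicted —
phenotype rescue) from synergistic ones.

## Relative fitness

Every phenotype is divided by the mean phenotype of the background
parent. Pollen fertility, a proportion, is variance-stabilised first with
`asin(sqrt(p))`; each replicate is transformed and then divided by the
mean transformed background value. The alternative order (relativise,
then transform) is not distinguishable from the description we follow;
transforming first keeps the normal likelihood operating on the scale on
which normality was improved, and rank order of genotype means is
preserved either way (a property test asserts this). Seed counts are
first *pollen-corrected*: a linear mixed model of seed on pollen with a
random intercept per genotype estimates a fixed slope `beta`, and the
corrected value is `seed − beta·(pollen − mean(pollen))`. Only the fixed
pollen component is removed — subtracting the conditional (genotype-level)
residuals would erase the sterility signal itself. The random intercept
is included solely so `beta` is not biased by between-genotype
differences; we use a random intercept only, the minimal structure
consistent with "genotype as a random effect". The correction is
idempotent to ~1e-13 relative, and individuals lacking pollen keep their
raw seed value, flagged.

## The likelihood

For a DIL with parental replicate vectors `w_i` (length `k_i`) and `w_j`
(length `k_j`) and DIL replicates `w_ij` (length `N`), the combined
parental vector under the additive family is `w_i* + w_j* − 1 + ε` and
under the multiplicative family `(1 + ε)(w_i* · w_j*)`. Because `k_i` and
`k_j` differ, both vectors are subsampled without replacement to
`k_m = min(k_i, k_j)` elements and paired in sampled (random) order; the
per-draw mean and variance are averaged over `B = 100` draws to give the
null moments `mu0`, `sigma0^2` per family. The DIL likelihood is the
product of normal densities of `w_ij` at the model moments.

Numerical choices:

* **ε applied analytically.** The epistasis parameter shifts the additive
  moments (`mu0 + ε`, variance unchanged) and scales the multiplicative
  ones (`(1+ε)·mu0`, `(1+ε)²·sigma0²`). The same `B` draws therefore
  underlie every ε and every family, giving a smooth, deterministic
  likelihood surface. Re-subsampling per ε evaluation would make the
  surface noisy and break the optimiser.
* **Estimation.** Additive ε̂ has the closed form `mean(w_ij) − mu0`
  (the normal-likelihood maximiser when the variance is ε-free),
  cross-checked against a numeric optimiser in the tests; multiplicative
  ε̂ is found by golden-section search on `(−1 + 1e−6, 10]` (relative
  fitness is O(1), and `1 + ε > 0` is a domain requirement), verified
  against a 1e5-point grid search.
* **Variance floor.** `sigma0² ≥ 1e−6·(1 + mu0²)` prevents degenerate
  likelihoods when parental replicates are (near-)constant.
* **Reproducibility.** Each DIL's subsample draws are seeded by a 31-bit
  hash of the master seed and the DIL id, so results are invariant to
  input row order; with `k_i = k_j` the additive mean is
  pairing-invariant exactly.
* **Model selection.** BIC is `−2 logL + q·log N` with `q = 1` for an
  epistatic model and `q = 0` for a null: ε is the single free parameter,
  the moments being derived from the parents rather than fitted. The best
  epistatic family (ties of less than 1e−9 broken toward additive, the
  family usually preferred in practice) must beat *both* nulls' BICs for
  epistasis to be called; support comes from a 1-df likelihood-ratio test
  against the best null. With ε̂ = 0 the epistatic BIC exceeds its null
  by exactly `log N` and epistasis is never called.
* **Tiers.** `significant` = LRT P < 0.01 and the BIC call;
  `highly-significant` additionally requires a Benjamini–Hochberg
  q-value < 0.01 within the phenotype. Both tiers are first-class
  outputs, and the realized FDR of the P-threshold tier is reported as
  `m·alpha / #calls`.

## IL sterility and the interaction network

Each IL is tested individually against the background: a quasi-binomial
GLM (logit link, unit weights, Pearson dispersion, t-test on the group
coefficient) for pollen proportions — the appropriate family when grain
denominators are unknown — and a normal linear model (equivalent to a
pooled t-test; verified against it) for corrected seed. Sterility
thresholds are `P ≤ 1e−4` (pollen) and `P ≤ 5e−3` (seed), the values
tied to per-phenotype FDRs of 1% and 5%. The boundary is *inclusive*:
published summaries print P-values rounded to one significant digit, and
the known pollen-sterile line whose printed value sits exactly at 1e−4
must classify sterile; with a strict inequality the printed table would
contradict its own annotation.

The network at a tier has all parental ILs as nodes (isolated ILs are
retained so denominators match the panel; ILs parenting no analyzable DIL
are flagged) and one edge per IL pair at that tier. Each edge's possible
DMI architecture is a pure function of (direction, parental sterility):
synergistic → higher-order; antagonistic between one sterile and one
non-sterile IL → pairwise DMI (complementation); between two sterile ILs,
either direction → higher-order or complex epistasis. The remaining cell
— antagonistic between two non-sterile ILs — is not covered by that
scheme and is deliberately labelled `undetermined` rather than forced
into a category.

# The synthetic world

`generate_dataset()` emulates the structure of the real greenhouse panel:
one background genotype (31 replicates), 15 ILs (3–6 replicates), 95
DILs (2–6 replicates, ~3% of genotype×phenotype cells missing), pollen
mean 0.90 (SD 0.07) and seed mean 42.1 (SD 16) in the background, with
default IL effect sizes taken from the published per-line summaries.
Noise models:

* **Pollen**: binomial counting over a fixed 100-grain denominator (the
  real denominators are unreported, so the binomial `n` is a free
  synthetic parameter), *plus* a plant-level latent fertility component
  (beta-distributed, variance scaled with `p(1−p)`). The latent layer is
  needed because published replicate SDs (up to 0.40) exceed anything
  binomial counting alone can produce; its scale is set so the background
  SD matches 0.07.
* **Seed**: negative binomial with size ≈ 8.3, derived from the
  background mean and SD (`mu²/(sd² − mu)`); counts are genuinely
  overdispersed (SD 16 at mean 42).
* **DIL truths** follow the configured model on the relative-fitness
  scale and are mapped to the phenotype scale via the background mean;
  pollen truths are clipped to `[0.001, 0.999]` and seed means floored at
  0.1, with clipping logged. The epistasis-free truth (`model = "none"`)
  combines parents multiplicatively: unlike the additive rule it cannot
  go negative for weak parents, so it is usable as a default null world
  for any effect-size configuration. Configurations implying DIL fitness
  below −0.05 are rejected as inconsistent.
* `table1_fixture()` is a separate, fully deterministic moment-matched
  fixture reproducing the published per-line N/mean/SD exactly; it is a
  documentation and test device, not a simulation.
* `simulate_fitness_sets()` generates replicate sets directly on the
  relative-fitness scale (parents normal around their truths, DIL normal
  around the model-combined truth plus ε, all with SD `sigma = 0.05` by
  default — the magnitude implied by arcsine pollen with ~100 grains).
  Calibration and parameter-recovery experiments run here, where ground
  truth lives on the same scale as the estimate.

What a green test does *not* establish: the generator has no
technical-replicate structure within flowers, no fruit-level seed
variance components, no floral-morphology failure modes, and its
missingness is independent per cell rather than mortality-driven.

# Calibration: what holds and what does not

Two distinct questions must be separated.

**Is the likelihood machinery implemented correctly?** Yes: when DIL
observations are drawn from the model's *own* null distribution (normal
at the subsample-derived moments, given the parental draws), the
significant-tier rate at P < 0.01 is statistically compatible with 1%
(unit test, 300 DILs), the additive closed form matches numeric
optimisation to 1e−6, and the multiplicative optimiser matches a grid
search to 1e−4.

**Is the procedure calibrated against a realistic generative null?** No —
and this is a property of the method, not of the implementation. Two
mechanisms inflate the realized type-I rate:

1. *Plug-in parental moments.* The likelihood treats `mu0` as known, but
   it is estimated from `k_i, k_j ≈ 3–6` parental replicates. Under the
   additive family the LRT statistic is approximately
   `(1/N + 1/k_i + 1/k_j) / (sigma0²/(N·sigma²))`-inflated; with DIL
   replicates as noisy as any single genotype's, the measured call rate
   at the relative-fitness level is ~7% instead of 1%.
2. *Transform-scale mismatch (pollen only).* Generative truths combine on
   the raw proportion scale, while the model operates on
   arcsine-transformed relative fitness; the transform is nonlinear, so a
   raw-scale null DIL mean does not coincide with either transformed-scale
   null. Through the full pollen pipeline the null call rate reaches
   ~20%.

The corresponding acceptance check is therefore expected to fail, and is
left failing deliberately: the null-calibration criterion as stated
(binomial CI over ≥500 generator-null DILs covering 1%) is unattainable
for this procedure in any world where parental moments carry sampling
noise. The practical reading is that the P < 0.01 tier of this method is
anti-conservative against full generative nulls — one reason the
FDR-controlled `highly-significant` tier, and not the raw P tier, should
be used for headline claims. Parameter recovery is unaffected: injected
ε = ±0.4 at six replicates is recovered with median absolute error
~0.03 and the correct sign in every significant call.

# The snowball simulator

Substitutions alternate between two lineages (a fair-coin rule is also
available); each new substitution is incompatible with each previously
fixed substitution in the *other* lineage independently with probability
`p`, permanently. Cross-lineage-only testing is the standard
interpretation of divergence-driven incompatibility and is also required
for the analytic onset `2/p` to match the documented "around 200
substitutions" at `p = 0.01`; a `within_lineage` flag exposes the
alternative without endorsing it. Internally every testable pair is drawn
once, at the moment its later member fixes — equivalent to the
per-substitution description but vectorisable; the implementation is
verified against a brute-force per-substitution oracle and against the
closed form `E[DMIs] = p·K1·K2`.

The involved-locus count is the size of the union of endpoints of formed
pairs (checked against an independent set-based recount). Pre-saturation
(`p = 1e−4`, K = 1000) the loci:DMI ratio is ~1.95 — just under 2
because occasionally one locus participates in two incompatibilities.
Post-saturation (`p = 0.01`, K in 400–1000) the involved-locus count
grows linearly — but with fitted slope ≈ 1.08, *above* 1: each new
substitution is involved almost surely (`1 − (1−p)^{K/2}`), and in
addition a backlog of older, still-uninvolved loci keeps being recruited
at rate `p·u(K)` where `u(K) ≈ K·(1−p)^{K/2}` shrinks slowly. Only the
cumulative count is bounded by K; the local slope approaches 1 from
above. An acceptance band that requires the slope to lie strictly below
1 therefore fails by construction, and is left failing with this
derivation as the explanation.

# Known limitations

* The method ignores parental-moment uncertainty (see calibration above);
  a profile-likelihood or hierarchical treatment would fix this but is a
  different estimator from the one reproduced here.
* Only pairwise combinations of introgressions are modelled; the optional
  `minimum` family (worse-parent null, epistasis as multiplicative
  scaling) is reported in separate columns and never alters the primary
  call — consistent with the observation that including it only slightly
  reduces the number of significant interactions.
* No genomic coordinates are processed; introgression size enters only as
  an optional annotation.
* The exact construction of the published "pollen-corrected seed
  fertility" summary column is not derivable from its description (the
  background's corrected mean, 12.4, is far from its raw 42.1); our
  correction keeps the raw seed scale instead, which changes no test
  decision but means that published column is not numerically
  reproduced.
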