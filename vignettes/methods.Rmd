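---
title: "Models and methods behind oculoevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oculoevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculoevo)
```

`oculoevo` reconstructs the joint evolution of retinal thickness and
retinal oxygen-supply mechanisms on time-calibrated phylogenies. This
vignette is the package's own account of the models it implements, the
choices that were genuinely open, and what its verification battery does
and does not demonstrate.

## Trees and the time axis

All functions operate on rooted `ape::phylo` trees with branch lengths in
Myr. Polytomies are accepted as hard multifurcations — composite trees
assembled from published time-calibrated phylogenies contain them, and
random resolution would inject arbitrary covariance structure.
Zero-length internal branches are retained; every algorithm tolerates
them. Node "age" means distance to the tips of an ultrametric tree
(Myr before present); non-ultrametric trees are allowed everywhere except
the Ornstein–Uhlenbeck covariance, which uses the stationary form and is
only well defined here on ultrametric trees.

`prune_to_taxa()` keeps the stem path between the original root and the
retained taxa's MRCA as the pruned tree's `root.edge`, so node ages and
root-to-tip depths keep the original time axis, while covariance
computations are taken relative to the new root — the standard
conditioning for comparative analyses of a subtree.

## Brownian motion: fitting and ancestral states

A continuous trait under BM with rate $\sigma^2$ (trait units² per Myr)
and root state $z_0$ has tip covariance $\sigma^2 C$, with $C_{ij}$ the
shared root-to-MRCA path length. `fit_bm()` computes the GLS mean
$\hat z_0$ and the ML rate $\hat\sigma^2 = r^\top C^{-1} r / n$. The ML
(1/n) convention is the default because ancestral point estimates are
invariant to the ML/REML choice; the REML (1/(n−1)) rate is exposed
alongside for users who want unbiased rate estimates.

`asr_ml()` returns, for every internal node, the conditional expectation
of the node state given the tips under the fitted model — the marginal ML
reconstruction. Three exact properties anchor the implementation and are
asserted in the tests: the root estimate equals $\hat z_0$; estimates are
linear in the data ($\mathrm{asr}(ax+b) = a\,\mathrm{asr}(x)+b$); and they
are invariant to rescaling all branch lengths. Node variances use the
plug-in $\hat\sigma^2$ and include the uncertainty from estimating the
root state, but not hyperparameter uncertainty in $\hat\sigma^2$ itself.

Missing tip values are handled per analysis: species without data for the
focal trait are pruned before fitting (complete cases), so different
traits legitimately use different $n$.

Layer reconstructions (`asr_layers()`) are run independently per layer.
Whether layer reconstructions should be constrained to sum to the
total-thickness reconstruction was an open design point; the package
reconstructs both and reports their discrepancy rather than hiding it.
When all layers and the total are measured on the same species the two
agree to numerical precision (GLS is linear), so any discrepancy is an
honest signal of differential missingness.

## PGLS and model choice

`pgls_fit()` is GLS with error covariance $V$ from either BM or the
stationary OU process
$V_{ij} = \frac{\sigma^2}{2\alpha} e^{-2\alpha(T - s_{ij})}
(1 - e^{-2\alpha s_{ij}})$, where $T$ is tree depth and $s_{ij}$ the MRCA
depth. The scale parameter is profiled analytically; for OU, $\alpha$ is
profiled by one-dimensional ML search on $\log\alpha \in [-10, 10]$
($\alpha$ in Myr⁻¹), tolerance 1e-8, started from three subintervals
because the profile likelihood can be bimodal near the BM boundary. Ties
in the subsequent model choice go to BM, the simpler model.

Structure choice uses small-sample Akaike weights: AICc
$= -2\ell + 2k + 2k(k+1)/(n-k-1)$, with $k$ counting coefficients plus
scale (plus $\alpha$ for OU). AICc is the default because comparative
sample sizes here are tens of species; plain AIC is available, and is
automatically substituted (with a flag) when $n \le k+1$ makes the
correction undefined. Coefficient standard errors use the $n-p$
denominator, matching `nlme::gls`; the test suite asserts exact agreement
of coefficients, SEs and log-likelihood with `nlme::gls` under
`ape::corBrownian`.

Body-mass correction (`phylo_residuals()`) follows the standard
residual-eye-mass construction: residuals of PGLS of log10(eye mass) on
log10(body mass). The V⁻¹-weighted residual mean is zero by the normal
equations; the raw residuals themselves need not average to zero.

## Simulation-based phylogenetic ANOVA

The observed statistic is the classical one-way F on species values. Its
null distribution is built by simulating the trait under BM on the fixed
tree and recomputing F. Two design points: the "generations" of the
simulation null are interpreted as the number of BM replicates (default
50,000, configurable; tests use 500 for runtime), and the null BM rate is
estimated from the observed trait ignoring groups — the standard
construction. Because F is invariant to location and scale, the p-value
$p = (1 + \#\{F_{sim} \ge F_{obs}\})/(1 + n_{sim})$ is exactly uniform
under the null by exchangeability; the acceptance battery verifies the
type-I error empirically at 60 tips. Zero within-group variance makes F
infinite; the function reports the minimal attainable p with a flag
rather than failing.

The ecotype comparison uses an ordinary one-way ANOVA with a
Student–Newman–Keuls posthoc at fixed $\alpha = 0.05$: ordered means are
compared over decreasing range spans with studentized-range critical
values, a non-significant range protects its sub-ranges, and homogeneous
subsets become letter codes. Unequal group sizes use the pairwise
harmonic mean (Tukey–Kramer style) and are flagged.

## Equal-rates Mk and stochastic mapping

The discrete vascular characters (CRM, intra-retinal, pre-retinal
capillaries; the three-state mammalian capillarization classes) evolve
under the equal-rates Mk model: one rate $q$ for every ordered state
pair, transition matrix $P(t) = \frac1k + (I - \frac1k)e^{-kqt}$ in
closed form. The likelihood is Felsenstein pruning with per-node
rescaling; species with no information enter as fully ambiguous tips
(all-ones partials) rather than being pruned, so the tree and node
numbering stay common across characters. The "equal root node prior" is
flat $1/k$; analyses may override it (the mammalian reconstruction uses
1:0:0 for anangiotic:merangiotic:holangiotic, reflecting the
all-vertebrate reconstruction's conclusion about the mammalian ancestor).
The single $q$ is fitted by bounded search on $\log q \in [-15, 5]$; a
character observed in only one state is reported at the lower bound with
a degeneracy flag instead of pretending precision.

Stochastic maps are drawn exactly: node states root-to-tip from the
conditional distributions over the pruning partials, then each branch
interior conditional on its endpoints by rejection sampling of forward
CTMC paths (with the first jump forced through a truncated exponential
when the endpoints differ). After 1000 rejections the sampler falls back
to uniformization with rate $\lambda = (k-1)q$ — a choice that makes the
uniformized jump chain's diagonal zero, so every auxiliary jump is a real
state change and no virtual-jump collapsing is needed. Rejection is exact
and fast in the common regimes; uniformization covers long branches with
unlikely endpoint pairs.

Summaries report both distributional transition counts (mean, median, 95%
interval of gains and losses over maps, per branch and total) and the
headline counts from the modal reconstruction — branches where the
posterior probability of "present" crosses 0.5 between parent and child,
with strict inequalities on both sides (exactly 0.5 does not cross).
Whether a published loss count refers to 0.5-crossing branches or to
expected counts over maps is genuinely ambiguous; emitting both makes the
distinction explicit.

## Trajectories

`build_trajectory()` evaluates reconstructions node-wise along a line of
descent; there is no interpolation along branches for continuous traits,
because reconstruction points exist only at nodes. The terminal record
carries the species' observed values where measured; traits without a
reconstruction at a node are emitted as missing, never interpolated.

## Ocular geometry and stereology

Eye volume assumes a spherical eye, $V = \frac43\pi r^3$. The retinal and
CRM volumes subtract sphere–sphere intersection ("lens") volumes; in the
lens regime
$V = \pi (r_1+r_2-d)^2 (d^2 + 2d(r_1+r_2) - 3(r_1-r_2)^2) / (12d)$, with
the containment and disjoint regimes handled explicitly and continuously.
The denominator placement (division by $12d$) is the only reading of the
semilunar decomposition that is dimensionally a volume and that agrees
with Monte-Carlo boolean integration, which the tests verify to 0.5%.
The CRM formula additionally assumes the two subtracted intersection
regions (with the eye sphere and with the optic-nerve sphere) are
disjoint; the oracle geometries respect this, and a negative resulting
volume raises an error flagging inconsistent geometry.

Maximal retinal thickness follows the measurement convention of taking
the maximum over the six angular positions (20°, 30°, 40° each side of
the optic nerve). Absolute layer thicknesses are the in vivo total times
the histological relative fractions, avoiding shrinkage bias.

Speckle-variance angiography (`quadratic_average()`) is the per-pixel
temporal RMS deviation from the temporal mean — zero iff the pixel is
constant, invariant to per-pixel additive constants. The Cavalieri
estimator is spacing × area-per-point × total hits; the test-line surface
estimator is $2IV/L$. Both are checked against phantoms: aligned cubes
(exact), spheres under random grid offsets (unbiasedness to 2%), and
isotropic line sets through spheres (5%).

The Root effect is computed by non-negative least squares unmixing of
each absorbance spectrum (480–700 nm at 0.2 nm) onto oxy/deoxy/met-Hb
basis spectra. Two open points were resolved as follows: metHb is
excluded from the functional pool, so saturation is
$S = \mathrm{oxy}/(\mathrm{oxy}+\mathrm{deoxy})$; and "percent
desaturation at pH 5.5 compared to 8.5" is read as the ratio form
$100\,(S_{8.5}-S_{5.5})/S_{8.5}$, with the absolute-difference form
available via `form = "difference"`. The result is clamped to [0, 100]:
whether a reversed (negative) Root effect is meaningful in this
convention is unstated, so the clamp is documented rather than silent.

## The synthetic-data generator

`synth_spec()` defaults define the study conditions the package is
verified under: a pure-birth ultrametric tree of 79 tips and 425 Myr
depth (the scale of the bony-fish radiation); maximal retinal thickness
evolving by BM from an ancestral 194 µm at rate 34 µm²/Myr (tip SD ≈ 120
µm, spanning the observed ~100–600 µm range) with a +100 µm shift where
the CRM is present (about a 30–50% increase on typical lineages); a Root
effect trait shifted +40 points by the CRM; log-scale pre-retinal
capillarization shifted −0.5 where the CRM is present (the observed
trade-off direction); binary characters under equal-rates Mk at
q = 0.003–0.008 Myr⁻¹ from an "absent" root (a handful of gains and
losses per character across the tree); and eye mass from
log10(eye) = 0.77·log10(body) − 2.64 plus a BM deviation with tip SD 0.1.
State-dependent evolution is implemented as mean shifts applied at the
character's transition points — a threshold-free approximation chosen
because the analyses verified against it (pAOV, PGLS) only require a
group-mean effect, not a particular joint model.

What the generator does *not* emulate: measurement error and intraspecific
variation, non-Brownian trait dynamics (trends, bounds, rate shifts),
correlated evolution between the discrete characters, phylogenetic signal
in missingness, and ultrasound physics in the speckle phantom (which is
plain heteroscedastic Gaussian noise). Passing tests therefore
demonstrate correctness of the estimators under their own assumptions,
not robustness to violations of them.

## Numerical choices and problem sizes

- GLS solves use Cholesky factorization; dense-matrix log-likelihood
  evaluation (`determinant` + `solve`) serves as the independent oracle.
- Optimizations: `optimize()` at tolerance 1e-8 (OU α, with three-segment
  multistart) and 1e-10 (Mk log q).
- Ultrametricity tolerance: relative 1e-6 on the spread of tip depths.
- Degenerate inputs are flagged, not hidden: all-equal traits
  (σ̂² = 0), single-state characters (q at the search bound), zero
  within-group variance (minimal p).
- Verification sizes: likelihood oracles on 100 random trees of ≤ 6 tips;
  geometry oracles on 50 random geometries at 2×10⁶ Monte-Carlo points;
  pAOV calibration over 500 trials (1500 in the acceptance script, for a
  tighter estimate of the same rate) of 500-replicate nulls on a 60-tip
  tree; BM rate recovery on 200 tips × 100 replicates; Mk rate recovery
  on 300 tips × 50 replicates at ~30 expected changes; stochastic-map
  convergence at 10,000 maps on 20 tips; sphericity on 10 voxel phantoms
  at 160³ resolution.

## Known limitations

- OU support is limited to the stationary covariance on ultrametric trees;
  non-stationary OU, early-burst and λ/κ/δ transforms are out of scope.
- Ancestral-state variances are plug-in; they understate uncertainty by
  ignoring the estimation of σ².
- The Mk machinery is equal-rates only; all-rates-different and
  correlated-evolution (Pagel) models are not provided.
- The morphometry functions compute estimators from supplied counts,
  radii and spectra; image segmentation and registration are upstream of
  this package.
- Each statistical test stands alone; no multiple-testing correction is
  applied across a battery of analyses.
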