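---
title: "Resource-ratio competition in flocs: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resource-ratio competition in flocs: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the competition model and its assumptions, the floc
diffusion model, the microhabitat construction, the community-profile
statistics, the synthetic-data generators, and the numerical and design
choices made where the problem left the design open.

## The consumer-resource model

Each ammonia-oxidizer taxon is described by six positive parameters
(`species_pool()`): maximum specific growth rate `mu_max` (1/d),
half-saturations `K_N` (mg N/L) and `K_O` (mg O2/L), loss rate `m`
(1/d), and consumption coefficients `c_N`, `c_O` (mg resource per mg
biomass formed). Growth on the two *essential* resources is Monod
kinetics combined by Liebig's minimum, not multiplicatively — the
standard formulation for essential resources, and the one that yields
right-angled zero-net-growth isoclines (ZNGIs) cornered at
$R^*_j = K_j m / (\mu_{max} - m)$. A taxon persists at a resource state
only if both concentrations strictly exceed its corner.

The chemostat realization (`chemostat_outcome()`) integrates

$$\dot R_j = D (S_j - R_j) - \textstyle\sum_i c_{ij}\,\mu_i(R)\,B_i,
  \qquad \dot B_i = (\mu_i(R) - D)\,B_i$$

with `deSolve::lsoda` from equal inocula of $10^{-3}$ mg/L. Steady
state is declared when every component's relative rate of change falls
below $10^{-8}$/d; species below the extinction threshold of $10^{-6}$
mg/L that are still declining are excluded from that criterion, since
their fate is sealed and their slow exponential decay would otherwise
postpone the verdict indefinitely. The default horizon is $10^4$ d;
non-convergence is reported, not hidden.

## Equilibrium classification at scale

The richness simulation evaluates competitive outcomes at millions of
supply points, which is far beyond what repeated ODE integration
supports. `equilibrium_survivors()` therefore implements the graphical
equilibrium theory directly, and `chemostat_outcome()` is retained as
the reference implementation against which the classifier is
cross-validated in the test-suite (randomized supply points, >= 95%
agreement required; in practice agreement is exact away from region
boundaries):

1. Taxa whose ZNGI corner is componentwise dominated by another's can
   never persist — any resident equilibrium of theirs is invadable — and
   are removed. The survivors form a trade-off front, ordered by
   $R^*_N$ ascending and $R^*_O$ descending.
2. A front taxon is the single winner wherever its resident equilibrium
   (walking the consumption vector down from the supply point to its
   ZNGI) is uninvadable by every other taxon.
3. Adjacent front taxa with crossing ZNGIs coexist where the supply
   point lies inside the cone spanned by their consumption vectors at
   the crossing, provided the pair is dynamically stable (each taxon
   consumes relatively more of the resource that limits it there).
   Unstable pairs produce founder control instead; both alternative
   residents then pass the single-winner test and both are reported,
   since either can occupy a patch. For species richness this is the
   ecologically correct accounting.

With two essential resources at most two taxa coexist at a point, so
richness above two requires spatial heterogeneity — which is exactly
what the microhabitat construction supplies.

## Floc diffusion and the size of a microhabitat

`solve_floc_profile()` solves the spherical steady diffusion-uptake
balance with saturable (Monod) volumetric uptake by damped Newton
iteration on a 201-node finite-difference grid (tolerance $10^{-9}$ on
the residual scaled by the Thiele-type modulus
$\Phi = q_{max} R^2 / (D_{eff} C_{bulk})$, with continuation in $\Phi$
for strongly diffusion-limited cases). Biomass density is folded into
`q_max`, which keeps the parameter count at what σ actually needs. The
zero-order (parabolic) and first-order (sinh) limits are exploited as
analytic oracles in the tests.

The "non-dimensional variation" σ of a profile is defined here as the
volume-weighted standard deviation of concentration divided by the bulk
concentration (`nondim_variation()`). This convention is dimensionless,
vanishes for flat profiles, and plugs directly into the bivariate
normal below. With the default uptake parameters (20 g O2/(L·d),
2 g N/(L·d) volumetric rates — ordinary activated-sludge respiration
when expressed per floc volume), a 100 µm floc at 3.6 mg O2/L bulk
gives σ = 0.014 for oxygen while ammonia is flat (σ ≈ 2·10⁻⁴), the
benchmark floc regime. The simulation default uses 200 µm flocs
(σ ≈ 0.056 at the same operating point): larger flocs mean stronger
internal gradients, hence wider microhabitats.

A microhabitat (`microhabitat()`) is the disk of radius 2.58 σ around a
mean supply point — 2.58 being the two-sided 99% normal quantile, so
the disk is the 0.99 contour in each axis of an independent circular
bivariate normal with common standard deviation σ. Supply points are
drawn from that truncated normal (not uniformly), because the contour
definition implies the normal law; negative coordinates are clipped to
zero, which cannot leave the disk when the centre is non-negative.
Because ammonia and oxygen are measured on different scales while the
construction assumes a *common* σ, both axes are first normalized by
their gradient maxima; this normalization is a documented package
convention.

## The richness sweep and its conventions

`richness_curve()` walks a linear supply gradient (`build_gradient()`),
places one microhabitat on each mean supply point, and repeats 50
independent richness draws of 100 supply points each per position.
Richness of one microhabitat is the *union* of survivor sets across its
points: different micro-patches crown different winners, which is the
RRT coexistence mechanism. Two ways of sizing σ are provided:

- `"diffusion"`: per axis, σ is the floc profile's non-dimensional
  variation at the local supply, converted to the normalized axis
  (multiplied by the normalized local supply); the common σ is the
  larger axis value — in practice always oxygen's.
- `"min_all_species"`: the smallest common σ such that some
  microhabitat on the gradient contains supply points inside every
  taxon's growth region (points above its ZNGI corner). The required
  disk radius per centre is the largest distance to a growth quadrant,
  available in closed form, so this is exact rather than sampled.
  "Growth region" rather than "winning region" is used deliberately:
  taxa dominated on both resources win nowhere, and the win-region
  reading would make the criterion unsatisfiable by construction.

Default study conditions: 23 taxa, dilution rate 0.2/d (a 5-day solids
retention time), gradient from (0.05, 0.025) to (6, 3) mg/L over 20
steps. The gradient is expressed in the model's supply units and spans
from below the weakest corner to about six times beyond the strongest,
because the humped curve lives where the gradient straddles the fan of
ZNGI crossings; a gradient placed at raw reactor feed concentrations
(tens to hundreds of mg N/L) would compress the entire fan into its
first step and resolve nothing. Replicates resample supply points with
a fixed species pool; resampling kinetic parameters instead would probe
parameter uncertainty, a different question, and is left to the caller
via `gen_species_pool()` seeds.

The synthetic pool (`gen_species_pool()`) draws kinetics log-uniformly:
`mu_max` in 0.9–1.1/d (a kinetically similar guild — congeneric AOB at
a common temperature — so competition is decided by affinities), `K_N`
in 0.5–4 mg N/L, `K_O` in 0.15–1.2 mg O2/L, with a Gaussian-copula
rank correlation of −0.9 between the two half-saturations. The strong
trade-off is what guarantees a non-degenerate competitive front: no
taxon is best at both resources. Consumption coefficients scale as the
square root of each half-saturation around ammonia-oxidizer
stoichiometry (7 mg N and 25 mg O2 per mg biomass, i.e. a yield near
0.14 on N and ~3.5 g O2 per g N oxidized); taxa thereby consume
relatively more of the resource they are worse at acquiring, which
makes every adjacent-pair equilibrium stable.

## Community-profile statistics

The Raup–Crick similarity (`raup_crick()`) keeps both observed richness
values fixed and redraws taxa uniformly without replacement from a
closed pool; the shared count under this null is hypergeometric, and
`raup_crick_exact()` provides that closed form
($P(X < s) + \tfrac12 P(X = s)$, a mid-P treatment of ties). The index
is *oriented* so that values above 0.95 mean significant similarity and
below 0.05 significant dissimilarity. The verbal definition of the
index in the fingerprinting literature (probability that randomized
similarity exceeds observed) points the opposite way from how its
thresholds are universally read; this package follows the reading on
which every interpretive statement depends: high value = similar. The
null pool defaults to the bands observed anywhere in the matrix
(closed-pool assumption, equal taxon weights) and can be overridden.
Pairwise values derive their Monte-Carlo seed from the unordered pair
of sample labels, so similarity matrices are symmetric and invariant to
sample reordering by construction.

Single-linkage clustering operates on distance 1 − S via
`stats::hclust`, with Newick export through `ape`. Moving-window
analysis computes consecutive-day similarities per reactor and flags
shifts (< 0.05) and stability (> 0.95). Chao1 is bias-corrected by
default ($S_{obs} + F_1(F_1-1)/(2(F_2+1))$, defined even when
doubletons are absent) with the classic form behind a flag for
comparison with older literature; ACE uses the standard rare/abundant
split at 10 with the coefficient-of-variation correction floored at
zero, falling back to Chao1 (with a warning) when every rare taxon is a
singleton and the coverage estimate collapses to zero. ACE standard
errors use the delta method over the rare frequency counts with
multinomial-type covariances; Chao1 uses the classical variance
formulas for whichever form is active. Rarefaction is the exact
hypergeometric expectation via `vegan::rarefy`, with a Monte-Carlo
subsampling oracle in the tests. Point estimates agree with
`vegan::estimateR` to numerical precision on non-degenerate inputs;
that agreement is asserted in the tests as an independent cross-check,
not used as the implementation.

## Water chemistry

Free ammonia and free nitrous acid follow the classical equilibrium
expressions with constants 6344 and −2300 K in the temperature terms
and mass conversions 17/14 (NH3 per N) and 46/14 (HNO2 per N). The
46/14 convention is documented because part of the older literature
uses 47/14 (the molar mass of HNO2); the difference is a 2% scale
factor on FNA. Validity ranges (0 < pH < 14, −5 < T < 60 °C) are
enforced.

## Synthetic fingerprint and clone-library generators

`gen_band_matrix()` emulates a 2 × 2 treatment design sampled on nine
days: all four reactors start from one common inoculum profile; before
day 28 profiles drift neutrally by richness-conserving band swaps
(15% of present bands per interval), and afterwards each reactor is
pulled toward a treatment-specific attractor (60% of bands reset per
interval, 5% noise). Attractors are disjointly biased subsets of a
36-band registry with richness 9/7/12/6 — the 5–12 band range typical
of such gels — so late samples cluster by reactor while early samples
cluster by time, and the within-treatment late-phase similarity exceeds
the between-treatment similarity by construction.

`gen_otu_counts()` draws 37–42 clones per library from a geometric
rank-abundance series, with ranks permuted per sample so different
libraries have different dominants. The geometric series is the
simplest skewed model that produces the singleton/doubleton tail the
nonparametric estimators feed on. The default parameter k = 0.3 yields
7–11 observed taxa per library from a 25-taxon pool with Chao1 above
observed richness in nearly every draw; steeper series (k = 0.5)
concentrate the clones so strongly that singletons become rare at this
depth and the estimators collapse onto the observed count.

## Numerical choices and degenerate inputs

- ODE: `lsoda` at rtol $10^{-10}$/atol $10^{-12}$, integrating in
  growing chunks with an early-exit steady-state test; washout
  ($D \ge \mu_{max}$) returns the supply point itself.
- Newton solver: step halving on the residual norm, non-negativity
  projection, continuation in $\Phi$ from $2^{-10}\Phi$ upward if the
  flat initial guess fails.
- Classifier tie-breaks: strict inequalities with $10^{-12}$ slack on
  invasion tests; points where no candidate equilibrium qualifies
  (measure-zero boundaries) are counted in an `unresolved` attribute
  and contribute no survivors.
- Saturated fingerprints (every taxon present in both profiles) carry
  no information; the null ties always and $S_{RC} = 0.5$ exactly —
  a documented edge, not an error.
- All generators are pure functions of spec + seed; `richness_curve()`
  derives one sub-seed per (position, replicate) from the master seed,
  so results are reproducible and position-wise independent.

## Problem sizes

The default test and analysis configuration — 20 gradient positions ×
50 replicates × 100 supply points per microhabitat, five seeds for the
robustness checks, Monte-Carlo null models at 999–9999 draws, and ODE
cross-validation at a few dozen supply points — was chosen so the whole
suite completes in a couple of minutes on a single core while keeping
every Monte-Carlo comparison inside three standard errors of its
closed form.

## What passing tests do and do not show

The synthetic generators reproduce the *statistical structure* the
analyses assume: a trade-off-structured kinetic guild, fingerprint
series with a common origin and treatment-specific attractors, and
skewed clone libraries at realistic depth. They do not emulate PCR or
gel artefacts, lane-calling error, chimeras, primer bias, heterotrophic
competition for oxygen, floc size distributions, or external
mass-transfer resistance. A humped curve here therefore demonstrates
that the mechanism — diffusion-generated microhabitats + R* competition
— produces the enrichment paradox under realistic AOB kinetics, not
that any particular reactor's diversity is quantitatively predicted.
Known further limitations: equilibrium community assembly (no
succession), fixed consumption vectors (classical RRT), and a
two-resource world with at most pairwise coexistence per micro-patch.
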