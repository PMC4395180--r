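---
title: "Models and methods behind haplogeo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind haplogeo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplogeo)
```

haplogeo analyses haploid, non-recombining sequence data — chloroplast DNA
in the motivating system, two sister *Allium* species of the Qinghai–Tibet
Plateau — through the complete chain from aligned sequences to a Bayesian
comparison of speciation scenarios. This vignette records the statistical
models, the estimator variants chosen where the literature offers several,
the numerical conventions, and the limits of what the bundled synthetic
data can show.

## Data model and haplotype identification

An alignment is a matrix over `A,C,G,T,N,-`; `N` is missing, `-` is a gap.
Indels are recoded by *simple indel coding*: every maximal gap run with
identical start and end coordinates across the sequences that carry it
becomes one binary presence/absence character, and sequences whose own gap
overlaps that span without matching it exactly are scored missing for the
character. This is the behaviour of the standard gap-recoding tools and
makes a multi-base deletion one mutational step, which matters for every
distance-based statistic downstream. Individuals with identical character
vectors — including identical missingness patterns; two vectors that differ
only in where they are missing are *not* merged — form a haplotype, labelled
in order of first appearance so outputs are reproducible under re-runs.

Inter-haplotype distances count differing characters with pairwise deletion
of missing values; indel characters count one step each. Whether indel
characters should enter distances at all is not settled usage; haplogeo
applies them uniformly, and `substitutions_only` flags reproduce the
nucleotide-only convention in the mismatch machinery.

## Diversity estimators

With $K$ populations, sample sizes $n_k$, haplotype frequencies $p_{ik}$,
and $\bar x_i = K^{-1}\sum_k p_{ik}$:

* within-population: $h_k = \frac{n_k}{n_k-1}\bigl(1-\sum_i p_{ik}^2\bigr)$,
  and $H_S = K^{-1}\sum_k h_k$ (the *unweighted* mean — weighting by $n_k$
  does not reproduce the behaviour of the standard permutation-test software
  on printed count tables);
* total: $H_T = 1-\sum_i \bar x_i^2 + K^{-1}\sum_i s_i^2$, where $s_i^2$ is
  the sample variance of $p_{ik}$ across populations. This is the unbiased
  analysis-of-variance form of the total-diversity estimator: the plug-in
  $1-\sum\bar x_i^2$ is biased down by the sampling variance of each
  $\bar x_i$, and $s_i^2/K$ estimates exactly that variance. The ordered
  statistics replace the 0/1 mismatch kernel with distances $\pi_{ij}$:
  $v_k = \frac{n_k}{n_k-1}\sum_{ij}\pi_{ij}p_{ik}p_{jk}$,
  $v_T = \sum_{ij}\pi_{ij}\bar x_i\bar x_j - K^{-1}\sum_{ij}\pi_{ij}\hat C_{ij}$
  with $\hat C$ the across-population frequency covariance matrix. Under
  unit distances these reduce *exactly* to the unordered statistics, which
  the test suite asserts.

Because the published tables this package is validated against do not state
the small-sample variant behind their $H_T$, a documented acceptance band of
±0.02 is attached to $H_T$ comparisons; the variant above lands inside it on
both species of the bundled fixture, and reproduces the monomorphic-species
value exactly. A related caveat: the source tables' narrative quotes a
pooled within-species diversity of 0.11 for the western species, which no
estimator variant we tried reproduces from the printed counts (pooling gives
0.17); the package asserts only the value (0.82) that the printed counts do
reproduce for the eastern species.

The contrast test permutes haplotype identities on the distance matrix,
recomputes $N_{ST}$, and reports $p=(1+\#\{N_{ST}^{perm}\ge
N_{ST}^{obs}\})/(n_{perm}+1)$ — the +1 convention avoids $p=0$ artifacts.
$N_{ST}>G_{ST}$ indicates that genetically similar haplotypes co-occur.
With few haplotypes the permutation group is small (24 relabellings for 4
haplotypes), which floors the attainable p-value; significance below 0.05
needs roughly 6 or more haplotypes.

## AMOVA, distances, Mantel

AMOVA decomposes squared inter-individual distances (individuals inherit
their haplotype's representative, so within-haplotype distance is zero —
haplotype-level AMOVA) into hierarchical variance components via expected
mean squares, with Φ fixation indices. P-values permute individuals among
populations (within groups for the two-level design) for Φ_ST/Φ_SC and
whole populations among groups for Φ_CT. Negative variance components are
reported as-is with a warning; a `floor_zero` flag controls whether Mantel
input Φ_ST values are floored at zero. Great-circle distances use the
haversine on a 6371-km sphere. Mantel tests correlate upper triangles, with
geographic distances optionally ln-transformed; zero and missing pairs are
dropped pairwise (the bundled coordinates contain two sites ~130 m apart,
so near-coincident populations keep their true small distance rather than a
patched zero). For ≤ 5 populations the permutation null is enumerated
exhaustively and the p-value is exact.

## Mismatch distributions and neutrality statistics

The expected mismatch under sudden demographic expansion follows the
closed form obtained by conditioning on whether a pair coalesces before the
expansion time τ (mutational units): the recent-epoch part is a geometric
mixture weighted by regularised incomplete gamma functions, the ancestral
part a Poisson(τ) convolution of the equilibrium geometric for θ₀. The
spatial model adds an infinite-island migration parameter M: lineages
sampled in one deme coalesce at rate 1/θ₁ while together and escape at rate
M/θ₁. Fitting minimises SSD over a coarse log-spaced grid followed by
`nlminb` refinement — deterministic, no RNG. Harpending's raggedness is the
sum of squared successive differences with the distribution padded by zero
classes on both sides (an isolated spike scores both its entering and
leaving step); published definitions differ, so `trailing = FALSE` drops
the final step. Bootstrap p-values refit the model on every simulated
replicate — the honest null, since SSD of a fitted curve is optimised.

Tajima's D uses the standard constants; D is reported as 0 with an
`undefined` flag when S = 0. Fu's F_S evaluates
$S' = P(K \ge k_{obs}\mid\theta=\pi)$ under the Ewens sampling formula with
unsigned Stirling numbers of the first kind computed in log space (exact to
n = 150 and beyond), and $F_S=\ln(S'/(1-S'))$. Neutrality p-values come
from constant-size coalescent simulation at θ = π̂: two-tailed via quantiles
for D, lower-tailed for F_S (expansion drives it negative).

## The coalescent simulator

The simulator is a standard piecewise-constant haploid coalescent (pair
rate $k(k-1)/(2N)$ per generation per population) with infinite-sites
mutation at rate μ·L per branch-year (default μ = 1.5 × 10⁻⁹/site/year,
L = 1448). Model A holds the western species at its current size N_AS,
squeezes it to N_aM between T_e and T_b ago, and merges both species into
an ancestor of size N_a at T. The size of the western lineage between T_b
and the split is not fixed by the scenario's published description; the
package uses N_AS (the minimal-parameter reading) and exposes
`N_west_pre` as an override. Model B keeps the western lineage at N_aM
from T_e back to the split: a persistently small progenitor population
that expanded instantaneously at T_e. Generation time defaults to one
year, making the generation scale of the scenario diagrams and the year
scale of the posterior tables coincide — the only self-consistent joint
reading. Infinite sites is justified by the data regime (17 variable
characters in ~1450 bp); a simulation whose mutation count exceeded L
would be rejected and redrawn (log-counted), though at realistic
parameters this does not occur.

Calibration checks: E[π] = θ for n = 2 and E[S] = θ·a₁ at n = 10 within 5%
(5 × 10⁴ and 10⁴ replicates — sizes chosen so Monte-Carlo error sits well
below the band), and a model A whose bottleneck equals the current size is
statistically indistinguishable (KS) from a clean split.

## ABC model choice

Fifteen summary statistics describe a two-species sample: per species the
number of haplotypes, polymorphic sites, private polymorphic sites, mean
pairwise differences, Tajima's D and Fu's F_S; plus the between-species
Φ_ST on pairwise differences, the mean between-species difference, and the
total polymorphic sites. Undefined D/F_S in monomorphic samples become the
sentinel 0 — applied identically to observed and simulated vectors, so
rejection treats them symmetrically and no selection bias enters (the
accompanying counts π = S = 0, k = 1 already encode the state).

Reference tables draw parameters from independent uniform priors (defaults:
N_a, N_AC ∈ [10³,10⁶]; N_AS ∈ [10²,10⁵]; N_aM ∈ [10,10⁴]; T ∈ [10⁴,2×10⁶];
T_b ∈ [10³,4×10⁴]; T_e ∈ [10³,T_b)); draws violating the scenario's time
ordering are rejected and redrawn. These bounds were chosen to contain the
plausible posterior region for plateau herbs with this mutation rate and
are fully overridable — they are declared defaults, not values inferred
from any particular dataset.

Each statistic is shifted strictly positive (1 − min), Box-Cox transformed
with a profile-likelihood λ, standardised, and reduced by PLS regression of
the parameters on the statistics (NIPALS, 11 components by default, fitted
on a 10⁴-row subsample). One transform is fitted on a pooled subsample of
both models' tables, with the six parameters common to both models as the
response: a per-model transform would put the two marginal densities in
different coordinate systems and make their ratio meaningless. Rejection
keeps the `n_retain` nearest simulations by Euclidean distance in component
space, ties broken by simulation index.

The regression adjustment is the ABC-GLM of Leuenberger & Wegmann: a
linear Gaussian model s = c + Cθ + ε fitted over the retained draws. The
parameters enter the linear model on the log scale — effective sizes and
times act multiplicatively on coalescent summary statistics, and a linear
fit on the raw scale badly underfits exactly where uniform priors place
their small values — and the uniform prior's Jacobian on the log scale is
an exp(linear) tilt that folds exactly into the Gaussian update as a mean
shift. The posterior is therefore a mean-shifted Gaussian truncated to the
(log) prior box, sampled by rejection with a weighted-uniform importance
fallback when the Gaussian barely intersects the box. The marginal density
of the observed statistics — the GLM likelihood integrated over the
uniform prior — is evaluated by completing the square: an analytic
constant times a truncated-Gaussian box probability, which the rejection
sampler estimates as its acceptance rate. (An earlier plain Monte Carlo
average over uniform prior draws was replaced: its heavy-tailed weights
systematically under-estimate the density of the higher-dimensional
model.) The Bayes factor is the ratio of marginal densities. Posterior
modes come from a weighted kernel density (Silverman bandwidth); intervals
are highest-posterior-density level sets — samples ranked by estimated
density and accumulated to 95% mass, the interval being that set's span,
with a warning when the set is disconnected. For unimodal posteriors this
equals the shortest interval containing the mass; on near-flat posteriors
(which weakly identified parameters produce) it trims both tails rather
than arbitrarily dropping one contiguous stretch. Singular residual
covariances and precision matrices receive a relative ridge of 10⁻⁸–10⁻¹⁰
of their mean diagonal. The time-ordering constraints among T_e, T_b and T
remove under 2% of the prior box's volume; the GLM treats the prior as
box-uniform, an approximation confined to weakly identified dimensions.

A candid note on identifiability: at the posterior-mode parameters the two
speciation models generate nearly indistinguishable data — the western
lineages reach their common ancestor long before the species split under
either scenario, so the scenarios differ only in the history of a single
surviving lineage, along which population size does not affect the
mutation process. Bayes factors on such data hover around 1 (the source
analysis itself reports a modest 2.33 on the real sequences), and model
recovery experiments at this parameter point behave accordingly.

Problem sizes: the package's calibration experiments use 2 × 10⁴
simulations per model with 1% retention and 20 pseudo-observed datasets —
a desk-scale budget chosen so the full suite runs comfortably on one core;
the machinery accepts the 3.5 × 10⁵/3500 production scale through the same
interfaces.

## The synthetic data, and what it does not show

The bundled fixture is the printed 19-population × 14-chlorotype count
table (86 + 64 individuals). `realize_alignment()` plants a deterministic
14 × 17 character design — 4 transitions, 6 transversions, 7 indels on a
two-clade topology, three shared steps separating the western pair — on a
seeded random 1448-bp backbone, and the result collapses back to the table
exactly. `study_like_dataset()` simulates at the posterior-mode parameters
of the bottleneck scenario and scatters individuals over pseudo-populations
with the fixture's sample sizes.

Limits worth stating. The speciation models are panmictic within species,
so simulated data carry no within-species population structure: the strong
among-population differentiation and the positive Tajima's D/F_S of the
real eastern species (refugial structure) are *not* reproduced by the
generator, and tests assert only the directional contrast (east more
diverse than west, west near-monomorphic). At the posterior-mode sizes the
eastern sample yields about seven haplotypes on average — the observed
twelve sits in that distribution's upper tail — so pattern checks use
fractions the simulator actually attains. Passing tests demonstrate
internal consistency of estimators and machinery on data with the study's
scale and structure, not agreement with the real sequences, which are not
bundled.

## Statistical parsimony limit

The network connection limit answers: up to how many observed differences
j (of `n_sites` characters) is "j differences = j mutations" credible at
95%? haplogeo models per-site hits as Poisson with the rate solved from the
Jukes-Cantor-corrected divergence at j differences, and computes the
probability that every differing site took exactly one hit and every
identical site none. The limit is the largest j keeping that probability
at or above 0.95 (≈12 steps at 1448 characters, growing with alignment
length). This is a direct implementation of the probability model behind
the classic statistical-parsimony software rather than a transcription of
its recursion; `conf = NULL` disables the cut entirely (pure
minimum-spanning network). Within a distance class every component-joining
edge is kept, so all tie-equal minimum-spanning alternatives appear.
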