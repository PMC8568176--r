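---
title: "Hierarchical Gaussian integration and the functional clustering ratio: model, estimation, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Gaussian integration and the functional clustering ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroFCR)
```

## The model and its assumptions

Parcel-level BOLD samples are modelled as i.i.d. realizations of a zero-mean
`N`-dimensional Gaussian with covariance $\Sigma$. Under this model the
entropy is $H = \tfrac12 \ln |\Sigma|$ up to an additive constant
$\tfrac{N}{2}(1+\ln 2\pi)$ that cancels in every quantity we report, because
block sizes always sum to the full dimension (this cancellation is verified
numerically in the test suite). For a partition of the parcels into $K$
systems, integration is the KL divergence between the joint distribution
and the product of the system marginals,

$$I[y_1,\dots,y_K] \;=\; \sum_{k=1}^{K} H(y_k) - H(y),$$

which is non-negative, zero exactly under independence, and invariant to
rescaling of individual parcels (so variance normalization of the series is
immaterial; the package exposes it as a flag anyway). With singleton units
this is the total integration $I_\mathrm{tot}$, and over systems it splits
exactly into

$$I_\mathrm{tot} = I_\mathrm{ws} + I_\mathrm{bs}, \qquad
  \mathrm{FCR} = I_\mathrm{ws}/I_\mathrm{bs},$$

the within-system term summing each system's internal integration and the
between-system term measuring the information shared across system blocks.
The identity is algebraic (block entropies cancel telescopically), so the
implementation treats any violation beyond $10^{-10}$ relative tolerance as
a bug, not noise. All logarithms are natural; units are nats.

Two modelling caveats matter for interpretation. First, temporal
autocorrelation violates the i.i.d. assumption and inflates integration
estimates; the generator therefore offers an AR(1) switch (default off,
matching the i.i.d. model) so users can probe the size of that bias.
Second, the Gaussian assumption makes integration a function of covariance
alone — higher-order dependence is invisible to it.

### Numerical choices

Log-determinants are computed from Cholesky factors
(`sum(log(diag(chol(S))))`), never from raw determinants, which underflow
long before `N = 400`. Positive definiteness is enforced with a relative
eigenvalue tolerance (smallest > $10^{-10}\times$ largest); failures are
hard errors reporting the offending eigenvalue, with an optional ridge
repair (`1e-6` × mean variance on the diagonal, logged) that is off by
default. FCR is undefined — an error, not infinity — when
$I_\mathrm{bs}$ is at tolerance, as happens for exactly block-diagonal
covariances. Singleton systems contribute zero within-integration rather
than erroring, keeping the decomposition exact for one-parcel assemblies.

## The hierarchy

Parcels nest strictly: cortex → 7 networks → 17 subnetworks → assemblies.
`hierarchical_integration()` decomposes the cortex over the 7 networks,
each network over its subnetworks (on the principal submatrix of its
parcels), and each subnetwork over its assemblies; nodes with fewer than
two children are skipped with a warning since a decomposition needs at
least two systems. The telescoping identity — singleton-unit cortex
integration equals the sum of all $I_\mathrm{bs}$ terms down the tree plus
the leaf-level internal integrations — is exact and is asserted to
$10^{-8}$ in the tests.

The assembly level is data-driven: within each 17-level system, baseline
(rested-state) correlations are thresholded at a two-sided $p<0.05$
(uncorrected t test for a Pearson correlation; non-significant entries set
to zero), converted to the dissimilarity $d = 1-r^2$, and clustered
agglomeratively with average linkage. The "maximised intraclass similarity"
objective could arguably be read as Ward-style; we treat $1-r^2$ as a plain
dissimilarity under average linkage and expose the linkage as an argument
rather than guessing. The tree is cut at the merge with the largest
increase in merge height (scanning successive height differences; ties take
the earlier merge, which yields the finer split), with a floor of two
clusters per system because downstream decompositions need two subsystems.
Degenerate all-equal dissimilarity structures split deterministically by
parcel order with a warning. Assembly labels are canonical (numbered by
first parcel appearance), making the output invariant to parcel input order
up to renaming. The number of clusters is data-dependent by construction
and is not a contract of the operation.

## Posterior inference on covariance matrices

The sampler uses a two-level conjugate hierarchy:

$$y_{i,t}\mid\Sigma_i \sim \mathcal N(0,\Sigma_i),\qquad
  \Sigma_i\mid\Psi \sim \mathrm{IW}(\nu,\Psi),\qquad
  \Psi \sim \mathrm{W}(\nu_0, S_0),$$

with closed-form Gibbs conditionals: the subject step combines the group
scale with the subject scatter, $\Sigma_i\mid\cdot \sim
\mathrm{IW}(\nu + T_i,\ \Psi + Y_i^\top Y_i)$, and the group step combines
the hyperprior with the summed subject precisions, $\Psi\mid\cdot \sim
\mathrm{W}(\nu_0 + n\nu,\ (S_0^{-1} + \sum_i \Sigma_i^{-1})^{-1})$. Each
retained sweep stores the group covariance on expectation scale,
$\Psi/(\nu-N-1)$. Defaults: 1,000 retained draws after 500 burn-in sweeps,
no thinning, subject degrees of freedom $\nu = N+32$ (the shrinkage dial:
larger values pull subject posteriors toward the group matrix, and the
prior keeps the posterior proper even when $T$ is modest relative to $N$,
so no ad-hoc ridge is needed inside the sampler).

The hyperprior is deliberately weak ($\nu_0 = N+2$) and is **centered on
the pooled sample covariance** (empirical Bayes). We initially centered it
on a scaled identity; that choice adds an identity-aligned term to the
group precision sum and provably shrinks posterior correlations toward
zero — at 8 subjects and a planted within-block correlation of 0.4 the
fixed point of the sweep sits near 0.35, a bias larger than the sampler's
Monte-Carlo error. Centering on the pooled covariance removes the
directional bias while keeping the same weak degrees of freedom; an
identity-centered prior remains available through `hyper_scale` for
sensitivity analyses, and reporting posterior FCR under two shrinkage
settings is the recommended robustness check.

Integration measures are computed on every retained draw, giving posterior
distributions whose frequency histograms approximate the posterior of each
measure; draws failing the positive-definiteness check are rejected and
counted, never silently dropped. Conditions are sampled in independent
chains and compared by draw index: `probability_of_difference()` is the
fraction of paired draws in which one condition strictly exceeds the other,
flagged significant above 0.95. With independent posteriors this estimates
$P(A>B\mid y)$; ties count against the difference (strict inequality).

## The synthetic cohort: what it emulates and what it does not

The generator mirrors the within-subject, multi-condition task-fMRI design
the methods target: per condition, a block-structured unit-variance
covariance (within-network correlation exceeding between-network
correlation), i.i.d. Gaussian rows, an additive global-signal component
shared equally by all parcels with condition-dependent amplitude,
HRF-convolved task responses, and behavioral change scores linearly coupled
to each subject's true FCR change with Gaussian noise (accuracy in percent;
reaction-time changes carry the opposite sign scaled to milliseconds).

Subject covariances are jittered around the condition covariance on the
correlation scale and projected to the nearest positive-definite
correlation matrix (keeping unit variances interpretable), with bounded
retries. The jitter has two components, both defaulting to sd 0.02 on the
correlation scale: a **trait** deviation shared across a subject's
conditions — functional-connectivity idiosyncrasies are stable traits in
test-retest studies, and a within-subject design shares them across
sessions — and an independent per-condition **state** deviation, which is
what gives the cohort a between-subject distribution of true FCR change for
the behavioral analyses. Defaults elsewhere follow the emulated design:
20 subjects, two-to-three conditions, several hundred volumes per session
(the source design concatenates about 26 minutes of task data; repetition
time and volume count are exposed as parameters rather than fixed, since
neither is pinned down), TR 2 s.

What the generator does *not* emulate: hemodynamic forward modelling beyond
HRF-convolved regressors, head motion, temporal autocorrelation (unless the
AR(1) switch is used), spatial autocorrelation on the cortical sheet, and
non-Gaussian tails. Passing recovery tests therefore demonstrates
correctness of the estimators under the model's own assumptions, not
robustness to every property of real BOLD data.

## Task regression and supporting statistics

Task regressors are an FIR basis (default span 16 s, one bin per TR)
convolved with a canonical double-gamma HRF (response peaking at 6 s,
undershoot at 16 s, amplitude ratio 6, kernel truncated at 32 s, 16-fold
oversampled grid); impulse events reproduce the HRF exactly, boxcar events
are dt-weighted. The regression always includes an intercept and a linear
trend — per-run demeaning at concatenation does not remove within-run
drift — and a rank-deficient design is an error naming the collinear
columns. Runs are demeaned per parcel before stacking (variance
normalization optional, default off: whether it preceded concatenation in
the emulated workflow is unstated, and integration is invariant to it
anyway). The global signal is the unweighted parcel mean; framewise
displacement uses the standard 50 mm head radius.

Edge-wise condition changes are paired two-sided t tests on Fisher-z
correlations with Benjamini–Hochberg control across all upper-triangle
edges. Behavioral change scores (second condition minus baseline) enter
task-wise standardized PCAs — standardization is enforced and documented
since accuracy (percent) and reaction time (ms) are not commensurable — and
the first component's sign is fixed to correlate positively with the mean
change. Brain–behavior associations are product–moment correlations;
covariate control (e.g. mean framewise displacement) residualizes both
variables and tests the partial correlation on $n-2-k$ degrees of freedom.
Subcortical regions are user-supplied series; no segmentation is performed,
and the region list is free (the emulated analyses vary between 6 and 8
regions).

The spin test compares two per-parcel maps under a null that preserves
spatial autocorrelation: 100 uniform random rotations of the spherical
centroids, mirrored across hemispheres, then a **greedy one-to-one** match
of rotated to original centroids, so every permuted map preserves the value
multiset exactly; plain nearest-neighbor lookup (which can duplicate
values) is available as `method = "replacement"` with duplication rates
logged. $p = (1 + \#\{|r_\mathrm{perm}| \ge |r_\mathrm{obs}|\})/(1 +
n_\mathrm{perm})$, so the smallest attainable p at 100 rotations is 1/101.

## Validation design and problem sizes

Every estimator is validated against an independent oracle or a planted
truth: closed-form bivariate and equicorrelated integration values
($\det = (1-r)^{N-1}(1+(N-1)r)$), eigenvalue-based entropy oracles,
decomposition additivity on random covariance/partition pairs, the
telescoping hierarchy identity, conjugate closed-form posterior means with
the group level clamped, planted-block assembly recovery, FDR null
control, and behavioral-coupling recovery where the generator's noise is
set from a pilot cohort so the per-task true correlation is about −0.7.
The behavioral-recovery scenario is designed by an explicit attenuation
analysis: per-subject FCR estimates carry measurement error of order
$(1-r^2)/\sqrt{T}$ on the correlation scale, which shrinks an estimated
brain–behavior correlation by the classical errors-in-variables factor
$\sigma_\mathrm{true}/\sqrt{\sigma_\mathrm{true}^2+\sigma_\mathrm{err}^2}$;
the validation cohort therefore uses the emulated study's session length
(800 volumes) and a subject state deviation (sd 0.05 on correlations) large
enough for true between-subject variation to dominate that error, the
regime the emulated study itself occupied. Posterior power and calibration
use a 20-parcel, two-system toy cortex with 20 subjects and 800 volumes — large enough for the posterior to
concentrate, small enough that the full replicate set (20 shifted plus 20
null cohorts, each with two 1,000-draw chains) runs on one core in
minutes. The pipeline orchestration is exercised end-to-end on an
8-parcel, 4-subject cohort and asserted byte-identical across reruns of
the same configuration and seed.

## Known limitations

Integration is a covariance functional: temporal or higher-order structure
is out of scope, as are time-resolved (dynamic) variants and
partial-correlation formulations. The Gibbs hierarchy is a documented
stand-in for an unpublished grouping model — conclusions should be checked
under at least two shrinkage settings. The elbow cut returns at least two
assemblies per system even when the data genuinely support one. And the
probability-of-difference pairs independent chains by draw index, which is
an estimator of $P(A>B)$ for independent posteriors, not a joint model of
paired subjects across conditions.
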