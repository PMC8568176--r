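# neuroFCR

Integration and segregation of cortical activity from parcellated BOLD time
series: hierarchical Gaussian functional integration, the functional
clustering ratio (FCR), and Bayesian posterior inference on covariance
matrices.

## The problem

Cognitive states — rested wakefulness, sleep deprivation, NREM sleep — shift
the balance between how much information cortical networks generate jointly
and how much they generate independently. Treating the parcel time series
`y = (y_1, …, y_N)` as i.i.d. samples of a zero-mean multivariate Gaussian
with covariance Σ, the **total integration** of the system over a partition
of parcels into K systems S₁…S_K is the mutual information

    I[y_1, …, y_K] = Σ_k H(y_k) − H(y),      H(y) = ½ ln |Σ|,

computed from covariance log-determinants (entropy constants cancel). Over
a partition into systems this decomposes exactly as

    I_tot = I_ws + I_bs,

the sum of each system's internal integration plus the integration between
system-level blocks, and the **functional clustering ratio**

    FCR = I_ws / I_bs

indexes functional segregation: a higher FCR means systems generate
proportionally more information internally. The package computes these
quantities at every node of a nested cortex → 7-network → 17-subnetwork →
assembly hierarchy, derives the assembly level by clustering baseline
connectivity, and infers posterior distributions of all measures with a
Gibbs sampler over group and subject covariance matrices, including the
posterior probability of a between-condition difference
`P(A|y) ≈ (1/S) #{FCR_B{s} > FCR_A{s}}` (significant above 0.95).

Supporting statistics mirror a complete task-fMRI workflow: FIR×HRF task
regression, run concatenation, edge-wise paired tests with
Benjamini–Hochberg control, amplitude/global-signal metrics, framewise
displacement, subcortical–cortical connectivity, behavioral change PCA with
brain–behavior (partial) correlations, and spin permutation tests for
cortical maps. A synthetic cohort generator with fully known ground truth
(block covariances, global signal, task responses, behaviorally coupled FCR
changes) backs every claim with a recoverable truth.

## Worked example

```r
library(neuroFCR)

# a 4-parcel system, two systems of two, equicorrelated at r = 0.3
R <- matrix(0.3, 4, 4); diag(R) <- 1
part <- partition(c("a", "a", "b", "b"))
decompose_integration(R, part)
#> integration: I_tot = 0.2141, I_ws = 0.0943, I_bs = 0.1198, FCR = 0.7874 (nats)
```

`I_tot = −½ ln((1−0.3)³(1+3·0.3)) ≈ 0.2141` nats of total interdependence;
0.0943 nats are generated within the two pairs (`−½ ln(1−0.3²)` each) and
0.1198 nats between them, so the system is slightly integration-dominant
(FCR < 1).

A self-contained synthetic study (two conditions differing in within-network
correlation, Gibbs posterior, probability of difference):

```r
hp <- hierarchical_partition(paste0("p", 1:20),
                             rep(c("A", "B"), each = 10),
                             rep(c("A1", "A2", "B1", "B2"), each = 5))
spec <- ground_truth_spec(20, hp,
                          within_r  = list(rested = 0.3, deprived = 0.5),
                          between_r = list(rested = 0.1, deprived = 0.1),
                          n_timepoints = 800, seed = 1)
cohort <- simulate_cohort(spec, n_subjects = 20)
part7 <- partition(hp$level7, hp$parcel_ids)
post <- lapply(c("rested", "deprived"), function(cn)
  posterior_measures(gibbs_sample_group_covariance(
    lapply(cohort$sessions, `[[`, cn), S = 1000, burn_in = 500, seed = 2),
    part7))
probability_of_difference(post[[2]]$FCR, post[[1]]$FCR)
#> [1] 1
#> attr(,"n_used")
#> [1] 1000
#> attr(,"n_dropped")
#> [1] 0
#> attr(,"significant")
#> [1] TRUE
```

The planted rise in within-network correlation (0.3 → 0.5) raises I_ws and
therefore the FCR; every posterior draw pair orders the conditions
correctly, so the posterior probability of an FCR increase is 1.

The full orchestration — task regression, assembly clustering, posterior
inference, edge statistics, behavioral coupling — is `run_pipeline()`; see
`vignette sources under vignettes/` for the methods account.

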