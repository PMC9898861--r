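---
title: "Network psychometrics for two-wave binary symptom panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network psychometrics for two-wave binary symptom panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

## The problem

Problem-gambling screens such as the 9-item Problem Gambling Severity Index
(PGSI) produce, in community samples, sparse binary data: each symptom is
endorsed by only a few percent of respondents.  The network-psychometric
view treats the symptoms not as exchangeable indicators of one latent
severity but as a system of mutually reinforcing states, and asks three
questions that this package operationalizes end to end:

1. *Cross-sectionally*, which symptoms co-occur beyond what their marginal
   rates imply, and which symptoms are most central to that web?
2. *Across waves*, does the cross-sectional network replicate — same edges,
   same weight ordering, same central nodes?
3. *Longitudinally*, which wave-1 symptoms predict which wave-2 symptoms,
   over and above every other symptom's wave-1 state?

## Models and estimators

### Cross-sectional: the Ising model via node-wise penalized regression

For binary symptoms $x \in \{0,1\}^p$ the Ising model puts

$$P(x) \propto \exp\Big(\sum_i \tau_i x_i + \sum_{i<j} W_{ij} x_i x_j\Big),$$

with node thresholds $\tau_i$ and pairwise couplings $W_{ij}$ on the
log-odds scale.  With $\{0,1\}$ coding the conditional of one node given
the rest is a logistic regression whose slopes *are* the couplings, so the
network can be estimated node by node: each node is regressed on the other
$p-1$ with an $\ell_1$ penalty,

$$\hat\beta(\lambda) = \arg\min_\beta \; -\ell(\beta) + \lambda\, n \|\beta\|_1,$$

along a 100-point log-spaced grid from $\lambda_{\max}$ (the smallest
penalty with an all-zero solution, computed from the null-model gradient)
down to $10^{-3}\lambda_{\max}$.  The per-node penalty is chosen by the
extended Bayesian information criterion

$$\mathrm{EBIC}_\gamma = -2\ell + k \log n + 2\gamma k \log(p-1),$$

with $\gamma = 0.25$ by default and ties broken toward the sparser model.
Edges are assembled under the AND rule: $\hat W_{ij}$ is the mean of the
two directed coefficients if *both* are nonzero, else zero (the OR rule is
available).  Predictors are deliberately not standardized, so couplings
stay on the interpretable log-odds scale.  Standardizing would also scale
each predictor's effective penalty by its standard deviation, which for
rare binary symptoms means *less* shrinkage exactly where the data are
thinnest; the unstandardized convention avoids that.

Numerical details: the path solutions are computed by coordinate descent
(glmnet) at convergence threshold $10^{-12}$, and the test suite checks
them coordinate-wise (tolerance $10^{-4}$) against an independent
proximal-gradient solver.  A node with fewer than two observations in
either response class cannot support a logistic fit; it is kept in the
network with zero edges and flagged, rather than aborting — with 2–8%
endorsement rates such nodes are a routine occurrence in resamples.

### Replicability: congruence and permutation invariance

Two estimated networks are compared by (i) the phi correlation of
edge presence/absence over the 36 unique pairs, (ii) Spearman rank
correlations of edge weights and of each centrality index, and (iii) a
permutation test of the maximum edge-weight difference
$M = \max_{i<j} |\hat W^{(1)}_{ij} - \hat W^{(2)}_{ij}|$ and the global
strength difference $S = |\sum_{i<j}|\hat W^{(1)}_{ij}| -
\sum_{i<j}|\hat W^{(2)}_{ij}||$.  The null distribution pools the two
samples and re-splits them into groups of the original sizes, re-running
the full estimator each time; p-values use $(r+1)/(B+1)$ smoothing.

The re-splitting null treats the groups as independent.  When the two
"groups" are two waves of the same people — as in a panel design — that
assumption is wrong in principle, and the package therefore also offers a
paired mode that swaps wave labels within person.  The independent
re-split remains the default because it is the established form of the
test; the paired variant is reported separately and never silently
substituted.

### Longitudinal: the cross-lagged panel network

Each wave-2 symptom is regressed on all nine wave-1 symptoms (its own
lagged value included) with LASSO logistic regression; the penalty is
chosen by ten-fold cross-validated binomial deviance with the
one-standard-error rule — the largest $\lambda$ whose mean deviance is
within one SE of the minimum — which favors the sparsest defensible
model.  The selected coefficients form a directed matrix $B$ whose
diagonal carries autoregressive effects; out-strength
$\sum_k |B_{jk}|$ and in-strength $\sum_j |B_{jk}|$ (self-loops excluded
by default) summarize which symptoms transmit and receive prediction.

Cross-validation folds are stratified on the outcome, balancing event
counts across folds to within one.  This is a deliberate departure from
plain random folds: with ~5% outcomes at $n = 335$, unstratified ten-fold
CV frequently produces folds without a single event, and the procedure
simply cannot run at the scale this estimator is meant for.  Here
predictors *are* standardized inside the penalized fit (coefficients are
returned on the original scale), matching the convention of the software
family this estimator comes from.

### Centrality

For undirected networks: strength $\sum_j |W_{ij}|$; closeness and
betweenness over shortest paths with edge length $1/|W_{ij}|$, the
standard transform for psychological networks (the data do not dictate
one; this choice is recorded in the output metadata).  Closeness comes in
two variants because the field's verbal definition ("sum of inverse
distances", i.e. harmonic) and its standard software (inverse of summed
distances) disagree: the default is `inverse_sum` to match the software
convention, restricted to each node's reachable component (sparse
low-prevalence networks are routinely disconnected, and this keeps the
index finite), with the component size reported; `harmonic` is a flag
away.  Standardized columns are z-scores with the $n-1$ SD across nodes.

### Stability and accuracy

Three bootstrap diagnostics, all person-level and deterministic under a
seed: percentile CIs for every edge from $B$ resamples with replacement;
difference tests that declare two edges (or two nodes' centralities)
different when the 95% percentile interval of their bootstrapped
difference excludes zero; and the case-dropping correlation-stability
(CS) coefficient — for each drop proportion $q$, $B$ subsamples *without*
replacement keep $(1-q)n$ persons, and CS is the largest $q$ at which at
least 95% of subset-to-full centrality correlations (Pearson by default)
reach 0.70.  CS $\ge 0.50$ is conventionally good, $\ge 0.25$ minimally
acceptable.  Degenerate resamples are kept under the estimator's
zero-edge policy and counted, not redrawn, to avoid biasing the bootstrap
distribution; undefined subset correlations count as failures.

## The synthetic-data generator

Because the motivating survey data cannot be redistributed, every
estimator is validated against a generator with known ground truth.
Wave 1 is drawn exactly from an Ising model (complete enumeration of the
$2^9$ states; single-chain Gibbs with burn-in 1000 and thinning 10 for
$p > 12$); wave 2 is drawn symptom-wise from
$\mathrm{Bernoulli}(\mathrm{logit}^{-1}(\alpha_k + \sum_j B_{jk} x^{w1}_j))$
— exactly the first-order process the CLPN estimator assumes.  Three
scenarios are built in:

- **`pgsi`** emulates a community gambling panel: nine symptoms,
  $n = 335$, thresholds solved by exact-enumeration calibration so each
  wave-1 marginal lands on a realistic 2–8% endorsement rate, ten
  positive couplings of 2.0 (2.5 for the strongest pair), and
  cross-lagged effects of 2.0 emanating from the "Tolerance" and "Health
  problems" nodes plus autoregression of 2.0.  Log-odds of 2 (odds ratio
  ≈ 7.4) is a strong-but-plausible link between co-occurring clinical
  symptoms, and effects of roughly this size are what a sparse
  1SE-selected model can plausibly have detected at this sample size.
- **`null`** has independent symptoms at 5% prevalence — the
  false-positive testbed.
- **`strong`** is a chain graph $W_{i,i+1} = 2$ with balanced marginals
  at $n = 2000$ — the recovery testbed.

What the generator does *not* emulate: ordinal response scales beyond
dichotomization, covariate-driven heterogeneity (age, sex), panel
attrition, and any dependence of wave 2 on more than the wave-1 symptom
vector.  Passing recovery tests therefore shows the estimators work under
their own assumptions at survey scale — not that real gambling data
satisfy those assumptions.

## Validation design and problem sizes

The test suite validates every layer against an independent oracle: exact
enumeration for the sampler, a proximal-gradient solver for the penalized
paths, exhaustive path enumeration (all simple paths, graphs up to six
nodes) for betweenness/closeness, and definitional recomputation for the
rank/phi statistics.  Simulation-based checks use these sizes, chosen to
keep the suite tractable on one CPU: 100 seeds for Ising null
calibration, 60 for CLPN null calibration and driver-rank recovery, 50
for chain recovery, 100 replications with 40 permutations for the type-I
error of the invariance test, and B = 120–200 for the CS checks.
Permutation- and bootstrap-heavy checks run the estimator with a
30-point penalty grid down to $10^{-2}\lambda_{\max}$, a coarsening that
leaves the EBIC selection essentially unchanged because the selected
penalties sit well above the grid floor.

## Known limitations

- The false-edge rate of the EBIC/AND estimator on null rare-symptom data
  at $n = 2000$ is about one edge per network, not zero; sparsistency is
  asymptotic and $\gamma = 0.25$ is a mild sparsity preference.
- The independent-groups permutation null applied to two waves of the
  same people ignores the within-person dependence (see the paired mode
  above).
- The CLPN is a between-person model: it does not separate within- from
  between-person variance and supports no causal reading.
- Paired effect sizes: the pooled-SD $d$ reported by `paired_t()` is
  $\bar d / \sqrt{(s_1^2 + s_2^2)/2}$ and is labelled as such; several
  incompatible "paired d" conventions circulate, so the raw ingredients
  (mean difference, both SDs, the dependent correlation) are always
  reported alongside.  `mcnemar_paired()` reports Cohen's
  $g = b/(b+c) - 1/2$ with the discordant counts rather than an
  ambiguous r-type effect size.
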