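---
title: "Network perturbation amplitude on two-layer causal networks"
author: "netpa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network perturbation amplitude on two-layer causal networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpa)
```

## The model

Curated causal network models of biological processes — for example, of
xenobiotic metabolism in airway epithelium — separate two layers. The
*functional* (backbone) layer contains nodes representing unmeasured
biological activities (the transcriptional activity of AHR, an oxidative
stress response, a phase II conjugation program), connected by signed
directed cause-and-effect edges: `increases` (+1) or `decreases` (−1). The
*transcriptional* (evidence) layer attaches measured genes to backbone
nodes, again with signs; a gene may be regulated by more than one backbone
node. The reasoning is backward: differential gene expression is treated as
the downstream consequence of changes in backbone activities, not as a
surrogate for them.

Given a contrast — per-gene log2 fold changes $\beta_g$ with estimated
variances — netpa infers a *differential backbone value* $f(b)$ for every
backbone node as the minimiser of the quadratic energy

$$
E(f) \;=\; \sum_{(x,y,s)\in E_{bb}} \big(f(x) - s\,f(y)\big)^2
\;+\; \sum_{(b,g,s)\in E_{ev}} \big(\beta_g - s\,f(b)\big)^2 ,
$$

the smoothest function on the signed backbone graph subject to the
transcriptional boundary. Stationarity yields a sparse symmetric
positive-definite linear system $K f = S\beta$, where $K$ is the backbone
block of the signed-graph Laplacian of the full two-layer graph and $S$
the signed evidence incidence; equivalently $f = M\beta$ with
$M = K^{-1}S$. The system is uniquely solvable exactly when every
connected component of the backbone graph is reached by at least one
measured evidence gene — this is what `validateNetwork()` diagnoses, and
what the fit re-checks after dropping edges of unmeasured genes.

The whole-network **perturbation amplitude** (NPA) is a Sobolev-type
(semi-)norm of the fitted profile on the signed backbone graph:

$$
\mathrm{NPA}(f) \;=\; \frac{1}{|E_{bb}|}\sum_{(x,y,s)\in E_{bb}}
\big(f(x)-s\,f(y)\big)^2 \;+\;
\alpha\,\frac{1}{|V_{bb}|}\sum_{v} f(v)^2 .
$$

With the default $\alpha = 0$ this is the pure Dirichlet semi-norm: zero
exactly when the fitted values are sign-consistent across every backbone
edge, and positive otherwise. Because $f$ is linear in $\beta$, the NPA is
a quadratic form $\beta^\top A \beta$ with $A = M^\top Q M$, which the
inference below exploits.

### Interpretation and statistics

* **Confidence interval.** Treating the estimated fold changes as
  $\beta \sim N(\hat\beta, \Sigma)$ with $\Sigma =
  \mathrm{diag}(\widehat{\mathrm{var}}\,\beta_g)$ (a central-limit
  approximation for per-gene contrast estimates), the variance of a
  quadratic form has the closed first/second-moment form
  $\mathrm{Var} = 4\hat\beta^\top A\Sigma A\hat\beta +
  2\,\mathrm{tr}\!\big((A\Sigma)^2\big)$. The reported interval is
  score $\pm z_{\mathrm{level}}\cdot$sd, truncated below at 0. A
  Monte-Carlo resampling route exists in the test suite purely as an
  oracle; the package itself uses the moment formula.
* **Evidence specificity (`*O`).** `permutationTestO()` shuffles the
  assignment of measured fold-change values to the network's gene labels,
  refits, rescores; the one-sided p-value is
  $(\#\{\mathrm{perm} \ge \mathrm{obs}\}+1)/(n+1)$, never zero.
* **Backbone contribution (`K*`).** `permutationTestK()` rewires the
  backbone layer — endpoints redrawn uniformly over distinct node pairs
  without self-loops or duplicates, signs redrawn independently at the
  observed negative-sign frequency — leaving the evidence layer untouched.
  Rewirings that strand a backbone component without evidence make the fit
  singular and are rejected and resampled; a backbone too small to admit
  more than one configuration yields a warning and $p = 1$.
* **Verdict.** The perturbation is *significant* when the CI lower bound
  exceeds 0, and *specific* when both permutation p-values are below the
  alpha level (default 0.05); `significanceCall()` encodes the three
  possible outcomes.
* **Profile comparison.** `compareProfiles()` reports Pearson r (t-based
  two-sided p), Spearman rho (average ranks; exact permutation p only for
  n ≤ 9), $R^2 = r^2$, and the least-squares regression of the second
  profile on the first with its F-test p. Backbone values are not
  independent draws, so these p-values are descriptive. The regression
  direction is fixed (B on A) and documented because scatter axes are
  otherwise a perennial source of confusion.
* **Negative control.** `negativeControlPermutation()` asks whether a
  backbone-level correlation between two contrasts could be produced by
  the dimension-reduction effect of the fit alone: gene labels are
  shuffled independently for each contrast, profiles refitted, and the
  two-sided p computed by the same counting rule. Pearson is the permuted
  statistic by default (Spearman is available via `statistic=`).

## Tunable parameters

| Parameter | Default | Units / scale | Why this default |
|---|---|---|---|
| `alphaRidge` | 0 | score units per squared node value | keeps the pure Dirichlet semi-norm; set > 0 only for networks without backbone edges or when node amplitude should count |
| `level` | 0.95 | probability | conventional CI level; the exact normal quantile is used, not a hard-coded 1.96 |
| `nPerm` (tests) | 500 (`*O`, `K*`), 1000 (negative control) | count | resolves p ≈ 0.002 at the counting rule's floor of 1/(n+1) |
| `alphaLevel` | 0.05 | probability | the conventional specificity cutoff for both companion tests |
| `seed` | required for every stochastic run | integer | all permutation and simulation results are bit-reproducible given (seed, nPerm) |

Sign conventions: relations `increases`/`directlyIncreases` map to +1 and
`decreases`/`directlyDecreases` to −1; anything else is an error, never a
guessed sign. Duplicate edges with consistent signs collapse with a
warning; conflicting signs are a hard error, since they would make the
energy ill-posed. Node identifiers are case-sensitive exact strings —
symbol mapping is the caller's concern. Genes in the contrast but absent
from the network are silently ignored (the network defines the scope);
network genes without a measurement drop their evidence edges with a
warning.

The contrast file's `var_log2fc` column holds **variances**, not standard
errors. `computeContrast()` is the simplest two-group case — pooled
equal-variance t contrast with Benjamini–Hochberg adjustment — because the
backbone fit consumes only (log2fc, variance); richer moderated models can
be substituted upstream by writing their output to the same contrast
format.

## What the simulator emulates — and what it does not

`generateNetwork()` draws a directed Erdős–Rényi backbone patched to
connectivity, signs Bernoulli at `negativeSignProb`, and attaches every
backbone node at least one gene (so generated networks are identifiable by
construction), with Poisson-distributed extra parents per gene.
`simulateContrast()` encodes the model's own generative assumption: a
gene's expected log2 fold change is the **mean** over its evidence edges of
sign × parent activity. The mean (not the sum) matches the least-squares
geometry of the fit, so noiseless recovery is exact. Replicate log2
intensities are baseline (drawn once per gene from $N(7,1)$, microarray
like) plus iid Gaussian noise; the defaults — triplicate groups,
`noiseSd = 0.1` on the log2 scale, 10 backbone nodes driving 200 genes,
truth drawn from $N(0,1)$ — mirror a small in-vitro exposure study design.

Passing tests on these simulations show that the solver, the variance
propagation, and the permutation machinery behave as claimed *under the
model's own assumptions*. They do not show robustness to what the
simulator omits: probe-level artifacts, batch/plate effects,
normalisation residue, correlated noise between genes, dose–response
kinetics, or miscurated network content.

A note on `K*` power that the simulator makes visible: the generator draws
the backbone wiring independently of the (iid Gaussian) truth vector, so
the observed configuration is essentially exchangeable with the rewired
null and `K*` p-values stay near-uniform no matter how strong the signal —
the test has no power against this generative process, by symmetry. `K*`
gains power exactly when the fitted profile is rougher on the true wiring
than on random rewirings, i.e. when wiring and perturbation are genuinely
coupled, as they are in curated models where both encode the same biology.
The test suite therefore exercises `K*` power on a truth vector
constructed to violate backbone sign-consistency edge by edge, and checks
calibration-style properties under the iid truth.

## Numerical choices

* Unit edge weights; each directed edge contributes one symmetric residual
  term. Direction is retained in the data model for provenance but does
  not weight the energy — the simplest reading of sign-aware smoothing.
* The backbone system is solved sparsely (Matrix package); node order is
  fixed lexicographically at parse time so results are independent of
  input row order.
* Per-node variances are $\mathrm{diag}(M\Sigma M^\top)$, computed as
  row sums of $M^2\,\mathrm{var}(\beta)$ without forming the full
  covariance.
* Permutation ties count as exceedances (`>=` with a 1e-12 slack), and the
  (k+1)/(n+1) rule keeps p-values strictly positive.
* Degenerate inputs are handled explicitly: all-equal fold changes make
  the `*O` null degenerate (warning, p = 1); a single-configuration
  backbone does the same for `K*`; zero backbone edges make the
  semi-norm degenerate and require `alphaRidge > 0`.
* Outputs are written atomically (temp file + rename) so interrupted runs
  never leave truncated results.

## Validation problem sizes

The shipped test suite validates, among others: exact agreement (≤ 1e−8)
between the sparse solver and an independent QR least-squares oracle on
100 random small networks; the moment-based CI against a $10^5$-resample
Monte-Carlo oracle and its empirical coverage over 500 simulated datasets;
type-I error of `*O` and of the negative control over 200 null replicates
at 200 permutations each; and parameter recovery across noise levels
(median over 20 seeds). These sizes were chosen to give stable empirical
rates on a single CPU; `scripts/acceptance.R` re-runs the same experiments
from scratch at any seed.

## Known limitations

* Correlation p-values between backbone profiles ignore the dependence
  induced by the shared network; treat them as descriptive.
* The CI is a first/second-moment normal approximation; for very small
  scores it is truncated at zero rather than being a bona fide one-sided
  interval.
* The fit weights all evidence terms equally; per-gene variance weighting
  is deliberately not applied (variances enter only the uncertainty
  propagation), keeping the estimator a pure graph smoother.
* No multi-network aggregation, leading-node decompositions, or pathway
  enrichment: one network, one contrast, one score.
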