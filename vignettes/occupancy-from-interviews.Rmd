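---
title: "Occupancy modelling from key-informant interviews: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy modelling from key-informant interviews}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occuInterview)
```

## The problem

In densely used agro-pastoral landscapes, conventional occupancy surveys
(sign transects, camera traps) are often infeasible: signs are erased by
traffic, cameras are stolen, and photographing people raises consent
problems. Key-informant interviews with pastoralists — who walk daily
grazing routes through the habitat — can substitute for repeat surveys: each
interview about a 5 × 5 km grid cell is treated as one survey replicate, and
reported sightings become detections.

Interview detections carry two error types. *False negatives* (the informant
simply never encountered the animal) are the standard occupancy-model
problem. *False positives* (misidentification, mislocation) are specific to
interview data and are handled in two stages: an identification flowchart
classifies every reported detection as certain (state 2) or uncertain
(state 1), and the analysis then either models the three states directly
(the false-positive model) or collapses uncertain detections to
non-detections and fits the standard binary model. The package implements
both; the binary route is the production path, because with rare uncertain
detections the three-state model is practically non-identifiable (see
below).

## Detection-state classification

`classifyDetection()` encodes the flowchart:

* **Certain (2)** — the informant identified the focal species *and* every
  look-alike in its paired photo set (tiger for leopard, jackal for wolf)
  without hints, and reported a sighting inside the focal grid within the
  past year.
* **Uncertain (1)** — a valid sighting, but identification needed a hint or
  stumbled on a look-alike.
* **FAILED** — the focal species was not identified even with a hint; the
  replicate is void *for that species only* and becomes a missing cell.
* **Non-detection (0)** — identification fine but no valid sighting.
  Sightings on the grid border or just outside are deliberately coded 0; the
  assignment of detections to cells is conservative, and no neighbouring-cell
  credit is given.

Species without a paired look-alike (hyena, sloth bear, blackbuck) have an
empty paired set, which is vacuously correct: certainty then depends only on
the hint and sighting-validity flags.

Interviews covering at least three of a grid's four sub-grids are
independent replicates; two-sub-grid interviews must be merged in
complementary pairs (`mergePaired()`). A merged pair keeps the longer
herding experience, and its per-species outcome is FAILED if *either*
respondent failed identification (both informants must pass the
identification criteria), otherwise the more certain of the two states.
Experience reported as a range enters as the midpoint.

## Likelihoods

For the binary layer $y_{ij} \in \{0, 1\}$ at site $i$, replicate $j$, with
$\psi_i = \mathrm{logit}^{-1}(x_i^\top\beta)$ and
$p_{ij} = \mathrm{logit}^{-1}(w_{ij}^\top\alpha)$,

$$L_i = \psi_i \prod_j p_{ij}^{y_{ij}} (1-p_{ij})^{1-y_{ij}}
      + (1-\psi_i)\,\mathbf{1}\{\textstyle\sum_j y_{ij} = 0\}.$$

Missing replicates (FAILED identifications, ragged interview counts of 1-7
per site) contribute a factor of one — they are skipped, never imputed. The
likelihood is invariant to replicate order within sites, so interview order
only affects display.

The three-state model adds the certainty probability $b$ and the
false-positive rate $p_{10}$: occupied sites emit state 2 with probability
$p_{11} b$, state 1 with $p_{11}(1-b)$; unoccupied sites emit state 1 with
$p_{10}$ and never state 2. Certain detections are therefore treated as
error-free, which is also why the binary collapse (2 becomes 1; 1 and 0
become 0) purges false positives at the cost of extra false negatives. The
parameterisation $(\psi, p_{11}, p_{10}, b)$ follows the multi-state
("type III") detection-state convention; $p_{10}$ and $b$ are scalar logits
while $\psi$ and $p_{11}$ take covariates.

Both negative log-likelihoods are tested against independent brute-force
oracles that marginalise the latent occupancy state by explicit enumeration;
agreement is at the $10^{-10}$ level over a thousand random instances.

## Fitting and numerical choices

`fitOccupancy()` minimises the negative log-likelihood with BFGS from ten
jittered starts (origin first; deterministic given `seed`), then applies up
to five Newton polish steps, because BFGS terminates on relative
log-likelihood change and can stop with a gradient well above zero when
covariates are badly scaled. Standard errors come from the inverse observed
information. A fit is declared converged only when the Hessian is
positive-definite and the max-norm of the finite-difference gradient is
below `gradTol = 1e-4`; gradients are computed by central differences with
step $10^{-6}\max(1, |\theta_k|)$, so demanding much less than `1e-4` on a
log-likelihood of order 100 would reject genuinely converged optima on
numerical noise. Non-convergence is a reported state, never an exception:
non-converged models are excluded from ladders, which mirrors how models
with convergence issues are dropped from candidate sets in practice.

Replicate-level detection covariates are z-scored over observed cells
(`standardizeDetCovariates()`), except 0/1 indicators such as
`grid_covered`, which keep their coding (0 = three sub-grids covered,
1 = all four).

## Covariates

Site covariates are land-cover areas in km² (monsoon *kharif* cropping,
irrigated double/triple cropping, open natural ecosystems), major-road
length in km, and livestock biomass in kg. ONE area counts pixels with
habitat probability **strictly** above 0.5. Village livestock is converted
to biomass with configurable body masses (defaults: cow 250, buffalo 350,
sheep 30, goat 25 kg — the sources for the original analysis cite
literature values without printing them, so the masses live in
configuration, not code) and apportioned to grids in proportion to village
area overlap, which conserves district totals exactly.

All covariates are z-scored with the sample (n−1) standard deviation — the
convention of the R modelling ecosystem — and the moments are computed over
*all* district grids, sampled and unsampled, so that a model fitted on the
sampled subset predicts to the full district on one scale. Pairs with
Pearson $|r| \ge 0.6$ (inclusive) may never co-occur in a model; inside the
global model the clash is resolved by an explicit priority order (menu order
by default), since no principled winner exists.

## Two-step selection and model averaging

Model selection is two-step: first the detection structure is selected with
occupancy held at the null, then occupancy structures are compared with the
best detection structure fixed. Each step fits the global additive model,
drops covariates whose SE is at least their $|\hat\beta|$ (a deliberately
blunt simplification rule; intercepts always stay), refits, estimates
overdispersion on the simplified global model, enumerates all remaining
subsets (null included, collinear pairs excluded), and ranks by QAICc:

$$\mathrm{QAICc} = -2\frac{\log L}{\hat c} + 2K + \frac{2K(K+1)}{n-K-1},$$

with $n$ the number of sites and $K$ the coefficient count **plus one**
slot for $\hat c$ — the convention that reproduces published QAICc tables
(a two-coefficient null model reports K = 3). $\hat c$ comes from a
parametric bootstrap of the detection-history Pearson chi-square: sites are
grouped into cohorts by replicate count, observed history counts are
compared with their expected values under the fit (a pooled cell absorbs
the never-observed histories), and the observed statistic is divided by the
mean of the statistic over `B` datasets simulated and refitted under the
fitted model. Values below 1 are floored at 1: underdispersion is not
credited, as only $\hat c > 1$ is the concern. The default is `B = 1000`;
desk-scale runs and the test suite use 30-100, which is noisy for $\hat c$
itself but has little leverage on which covariates are retained.

Models within $\Delta\mathrm{QAICc} \le 2$ (inclusive, so a tie at exactly
2.0 is retained) form the averaging set. Per-grid occupancy is the
weight-renormalised convex combination of the retained models' predictions
— renormalisation over the retained set is the standard reading of
averaging "across the models with $\Delta \le 2$". Grids with more than 3/4
of their area under water are excluded from the surface. The district
summary is the mean of per-grid averaged predictions over included grids;
its headline SE is the delta-method SE of that spatial mean (coefficient
covariance propagated through the average of inverse-logits, combined
across models with the usual between-model spread term). Because "SE of a
district-wide mean" is ambiguous between that quantity and the mean of
per-grid SEs, both are stored (`districtSE`, `meanOfSEs`).

## The synthetic district

`simulateLandscape()` and `simulateSurvey()` define the study conditions
the package is tested under: a 230-cell district with 119 cells sampled in
a checkerboard, 1-6 interviews per site (blackbuck-like settings allow 7),
occupancy near 0.5 and per-replicate detection near 0.3, certainty 0.9,
uncertain false positives at 0.02 per unoccupied replicate, and a 3%
identification-failure rate. Covariate fields are Gaussians truncated to
the 0-25 km² cell range with means chosen so truncation is mild, which is
why a requested cross-correlation is realised to within a few hundredths;
water fractions are mostly small with a 3% admixture of high-water cells so
the exclusion rule is exercised. False positives are always recorded as
uncertain — certain detections are error-free by construction, encoding the
premise of the classification protocol.

What the generator does *not* emulate: spatial autocorrelation in occupancy
(the model assumes site independence, so the tests cannot detect its
violation), informant-specific reporting biases beyond the experience
covariate, and any systematic misassignment of sightings across grid
borders. Passing the recovery and selection benchmarks therefore shows the
estimator and workflow are correct under the model's own assumptions, not
that the model is adequate for any particular field dataset.

## Benchmark problem sizes

The package's simulation benchmarks use sizes chosen to finish in minutes
on a laptop while leaving Monte-Carlo noise well inside the asserted
margins: parameter recovery runs 200 replicates of 500 sites × 5
replicates (bias on $\psi$ is asserted below 0.03, Wald 95% coverage within
[0.91, 0.98]); selection consistency runs 100 trials at 300 sites with unit
effects on one occupancy and one detection covariate and `B = 30` bootstrap
replicates; the likelihood oracles run on 1000 random small instances. The
goodness-of-fit self-consistency check asserts that *mean* raw $\hat c$
over trials lies near 1 — individual raw values spread widely at 119 sites
because the statistic is a ratio of a skewed chi-square to a bootstrap
mean — and that within-site correlated replicates push $\hat c$ above 1 in
at least 90% of trials.

## Known limitations

* Naive occupancy is reported with standard half-up rounding; two published
  values (10/118 printed as 0.09, 45/119 as 0.39) differ from that rounding
  by one hundredth and are documented rather than reproduced.
* The false-positive fitter is a diagnostic, not a production estimator:
  with sparse uncertain detections it sits on the $p_{10}$ boundary with
  inflated SEs — exactly the failure mode that motivates the binary
  collapse — and the package flags rather than "fixes" this.
* QAICc reconstruction from published tables is limited by the two-decimal
  rounding of the printed quasi-log-likelihoods and QAICc values
  (worst-case 0.015 discrepancy).
* No multi-season dynamics, spatial random effects, abundance-induced
  heterogeneity, or Bayesian fitting.

## A minimal run

```{r example, eval = FALSE}
cfg <- simConfig(seed = 42)
sv <- simulateSurvey(cfg, species = "hyena")
pc <- pipelineConfig(chat = "bootstrap", bootstrap_B = 100, seed = 1,
                     model_species = "hyena")
res <- runPipeline(sv$records, sv$landscape, pc)
res$hyena$naive
res$hyena$selection$psiLadder
res$hyena$surface
```
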