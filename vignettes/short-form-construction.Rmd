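---
title: "Short-form construction for ordinal scales: models, procedures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short-form construction for ordinal scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its statistical machinery: the
measurement model, each stage of the short-form workflow, the numerical
conventions behind them, and the design decisions that were genuinely open.
It states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The measurement model

Responses to item $j$ in categories $1,\dots,m$ follow the generalized
partial credit model (GPCM),

$$
P(X_j = c \mid \theta) =
\frac{\exp\!\big(\sum_{v<c} a_j(\theta - b_{jv})\big)}
     {\sum_{u=1}^{m}\exp\!\big(\sum_{v<u} a_j(\theta - b_{jv})\big)},
$$

with the cumulative term of the first category defined as zero. The
discrimination $a_j$ governs how sharply the category probabilities move
with the trait; the step difficulty $b_{jv}$ is the trait level at which
adjacent categories $v$ and $v{+}1$ are equally probable. The latent trait
is standard normal in the reference population; that fixed prior, together
with the $a(\theta - b)$ parameterization (one slope plus $m-1$ steps per
item), identifies the model.

The Fisher information of an item is $I_j(\theta) = a_j^2\,
\mathrm{Var}(C_j \mid \theta)$ with $C_j$ the 0-based category score; the
package verifies this closed form against a finite-difference oracle
($-E[\partial^2 \log P / \partial\theta^2]$, central differences,
$h = 10^{-4}$) in the suite. Test information is the exact sum of item
informations at every evaluated trait value.

### Estimation

The marginal likelihood integrates the trait over a fixed grid of 61
equally spaced nodes on $(-6, 6)$ with normal-density weights normalized to
one — stable, reproducible, and accurate to far beyond the EM stopping
tolerance for the trait range that matters. Estimation is EM: the E-step
posterior is a persons-by-nodes matrix; the M-step maximizes each item's
expected complete-data log-likelihood by BFGS with analytic gradients,
started at the current values, so the marginal likelihood never decreases
(asserted per iteration in the tests). Convergence is declared when the
largest parameter change drops below $10^{-4}$, with a 500-iteration cap
that flags rather than errors.

One numerical point deserves emphasis. The M-step is optimized in the
slope/intercept parameterization $a\,(c{-}1)\,\theta - d_c$ (with
$d_c = a B_{c-1}$, $B$ the partial sums of the steps), not in $(a, b)$.
The $(a, b)$ coordinates contain a ridge at $a = 0$: for an item whose true
slope has the opposite sign to its starting value, EM drives $a$ toward
zero while the steps diverge so that the products $a b_v$ keep matching the
marginal category frequencies, and the item jams in a spurious
zero-information solution. In the slope/intercept coordinates the slope
crosses zero freely and reverse-oriented items converge to their negative
slopes. Results are mapped back to $(a, b)$ for reporting.

Missing responses are skipped in the within-person likelihood product
(ignorable missingness); summed scale scores, by contrast, require complete
cases. Reverse-flagged items are recoded $x \mapsto m+1-x$ at ingest,
before any fitting. Categories never observed for an item are collapsed
out (with a warning) and the observed-category map is stored in the fitted
model, so scoring and likelihood evaluation remain consistent; parameter
comparisons against simulation truth use the same map.

Factor scores are expected a posteriori (EAP) posterior means on the same
quadrature grid. "Entire trait range" for integrated information means
$(-10, 10)$: beyond that, items of ordinary discrimination contribute
nothing material, and under this convention the published per-item
information column of the 21-item noise-sensitivity calibration sums to its
published full-range total within two-decimal rounding (the acceptance
suite performs that arithmetic).

## Unidimensionality screen

Polychoric correlations use the two-step estimator: thresholds from the
marginal normal quantiles, then one-dimensional maximum likelihood for the
latent correlation, with bivariate-normal rectangle probabilities computed
from the single-integral representation of the bivariate CDF evaluated by
32-node Gauss–Legendre quadrature. Degenerate pairs collapse unobserved
categories first and error informatively if a margin still has fewer than
two categories.

Factoring is minimum-residual (ULS): uniquenesses are optimized by
L-BFGS-B (started from squared-multiple-correlation communalities), the
loadings being the leading eigenstructure of the reduced matrix;
communalities reaching one are clamped with a Heywood warning. The
essential-unidimensionality gate requires the ratio of the first two
eigenvalues of the polychoric matrix to exceed 3 and the first factor to
explain at least 20% of variance. Three conventions here were open and are
fixed as follows: the variance-explained denominator is the number of items
(unit variances); the "20–40%" band that circulates as a rule of thumb is
operationalized as the single configurable threshold of 20%, its weakest
defensible reading; and the eigenvalue ratio uses the raw polychoric
eigenvalues, not communality-reduced ones — the commoner convention, though
the literature is not unanimous. Items with a negative first-factor loading
are removed before any IRT modeling: a negative loading on an otherwise
coherent scale marks an item keyed or functioning in the wrong direction.
KMO and Bartlett's sphericity test are reported alongside.

## DIF by the iterative Wald approach

Group DIF is assessed with a joint two-group GPCM: constrained (anchor)
items share parameters across groups, studied items get group-specific
parameters, the reference prior is fixed at N(0,1), and the focal group's
prior mean and variance are estimated — this is what separates true group
impact (a trait-distribution difference) from item-level DIF. With no
anchors the focal prior is unidentified (a location/scale shift of the
focal item parameters absorbs it), so the package then fixes it at N(0,1);
both mean and variance are freed by default whenever anchors exist.

Stage 1 (Wald-2) literally fits one constrained model per studied item,
with all other items as anchors — acceptable at desk scale for instruments
of this size — and flags items at $p < 0.05$. Anchors are then the five
unflagged items with the largest baseline discriminations (MaxA5, ties to
the lower index; the count is configurable). Stage 2 (Wald-1) frees all
non-anchor items in a single joint fit and removes those with $p < 0.05$.
The Wald statistic for an item is $d^\top V^{-1} d$ over the full
focal-minus-reference parameter difference ($1 + (m-1)$ degrees of
freedom), with $V$ from the inverse observed information, computed by
central finite differences of the analytic score (step $10^{-4}$) on the
joint fit. Raw p-values are the default — per-item testing at the nominal
level, as is standard in this procedure — with an optional
Benjamini–Hochberg adjustment that defaults off; the two stages run once,
with no loop-until-stable (an optional behavior deliberately not defaulted,
since repeated anchor re-selection reopens the anchor-contamination problem
the two-stage design exists to control).

The suite calibrates this test by simulation: a six-item design (five
anchors plus one studied item, discriminations uniform on (0.5, 1.5), six
categories, 500 persons per group, 31 quadrature nodes) chosen to make each
replicate cheap while keeping the anchor structure of the real procedure.
Across null replicates the rejection rate at the nominal 0.05 must land in
[0.02, 0.10] and the p-values must pass a Kolmogorov–Smirnov uniformity
check; under a 0.75 uniform threshold shift the rejection rate must exceed
0.5. Replicate counts (150 null, 40 power in the tests; 100 and 30 in the
acceptance script) trade Monte-Carlo resolution against runtime.

## Optimal test assembly

For a fixed length $L$, the objective is the summed item information at the
anchor trait levels $(-3, -1, 0, 1, 3)$ — information evaluated exactly at
those points, not integrated between them. The 0/1 selection problem is
solved by depth-first branch and bound with a sorted-prefix upper bound and
an exactness certificate; among equal-objective subsets the
lexicographically smallest index set is returned. For this pure
cardinality-constrained objective the optimum provably equals picking the
top-$L$ items by anchor-summed information, and the suite holds the search
to both that closed form and exhaustive enumeration on randomized
instances; the branch-and-bound machinery is what supports mandatory and
forbidden item sets and any later side constraints.

The minimal-length scan evaluates, per length, three retention constraints
on the training sample: subset alpha at least 95% of the full (non-DIF)
scale's alpha, and summed-score and EAP-score correlations with the full
scale of at least 0.9. During the scan, subset EAP scores use the full
model's parameters restricted to the subset — no refitting inside the
search loop, keeping it deterministic and fast — while the finally reported
short form is refitted on its own items, the convention a final report
would use. Both paths are exposed. If no length passes, a failure record
with the complete audit trail is returned rather than an exception.

## Evaluation conventions

Cronbach's alpha uses the variance decomposition on complete cases with a
Feldt F-interval; correlations use Fisher-z intervals. Convergent validity
is the plain Pearson correlation of the short-form summed score with each
covariate, without attenuation correction. The one-factor CFA treats the
ordinal items as continuous and fits the Pearson covariance matrix by
maximum likelihood (BFGS with analytic gradients on loadings and
log-uniquenesses); $\chi^2 = (n-1)F_{ML}$; RMSEA with its 90% interval
from the noncentral-$\chi^2$ inversion; SRMR over standardized residuals
including the diagonal; CFI against the independence baseline, with
$\mathrm{RMSEA} = 0$ and $\mathrm{CFI} = 1$ whenever $\chi^2 \le df$. An
ordinal (WLSMV-type) estimator is a defensible alternative the package
deliberately does not implement; with six well-used categories the
continuous-ML treatment is the conventional default, and the suite holds
the discrepancy minimum to base R's `factanal` and to independent
random-start optimization. Information retention is
$100 \cdot I_{subset}/I_{full}$, reported to one decimal, over both the
entire range and $(-3, 3)$.

## The synthetic-data generator

The generator emulates the study conditions under which such a scale is
shortened: two samples of roughly 569 and 500 adults; 21 six-category
items by default with discriminations uniform on (0.12, 1.7) — the span of
the published noise-sensitivity calibration; step difficulties as sorted
normal draws around a per-item location $\sim N(0,1)$ with spread 0.8,
giving well-behaved ordered Likert thresholds; a 37% focal group (a
roughly 63/37 female/male sample with males focal); optional uniform or
single-step threshold DIF and slope DIF per item; optional undeclared
reverse-oriented items (responses flipped, flags left unset — precisely
what the negative-loading screen must catch); and covariates jointly normal
with the trait at configured correlations (defaults +0.27 and −0.11,
typical of neuroticism and extraversion), rescaled and rounded to
NEO-FFI-like sum-score ranges. True traits and generating parameters are
retained in the output and in a truth sidecar file, clearly labelled.

What the generator does not emulate: survey-mode effects, nonresponse,
demographic strata, local dependence between items, multidimensionality
beyond the planted reversed items, and category-usage pathologies beyond
what the threshold draws produce. Passing tests therefore certify the
machinery — estimation, testing, selection — under clean GPCM data of
realistic size, not the behavior of any real population; published category
frequencies were never available to tune against, so the generator is
anchored only to the published discrimination span and covariate
correlations.

The end-to-end acceptance scenario uses a 12-item instrument: an 8-item
informative core, two weak fillers, one DIF item (uniform threshold shift
1.0) and one reverse-oriented item at slope 0.4 — large enough effects to
be unambiguous at $n = 569$. Twelve items rather than twenty-one keeps the
number of simultaneous Wald tests, and hence the chance that a single
nominal-level false positive spoils an "exactly the planted items" check,
commensurate with what that scenario is meant to demonstrate; the planted
reversed item is given a moderate slope for the same reason (a nearly flat
reversed item sits at the detection noise floor of any loading screen).
Problem sizes throughout the suite (replicate counts, quadrature nodes for
the multigroup fits, the nested-subsample recovery design) are the
package's own choices balancing Monte-Carlo resolution against desk-scale
runtimes.

## Seeds and determinism

Each generator configuration carries one integer seed; the true-model draw
and the response draw use the seed and seed+1, with draws in a fixed order,
so identical configurations are bit-reproducible. Experiment drivers derive
per-replicate seeds as base + replicate index. EM, quadrature, assembly and
CFA are deterministic given data and settings.

## Known limitations

- No multidimensional IRT, graded-response alternative, or MCMC
  estimation; the GPCM is the model, full stop.
- DIF is two-group only (the design question here was gender); no
  uniform/non-uniform decomposition of the detected DIF is attempted.
- The CFA estimator treats ordinal data as continuous (see above).
- The observed information comes from finite differences of the analytic
  score; severely under-identified configurations surface as singularity
  errors naming the parameter block rather than being regularized away.
- Assembly supports cardinality, mandatory and forbidden constraints only —
  no content balancing or enemy items, which the underlying search could
  accommodate but this workflow never needed.
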