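---
title: "Optimizing diagnostic criterion sets on chronicity and comorbidity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing diagnostic criterion sets on chronicity and comorbidity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critopt)
```

## The problem

Count-and-threshold diagnoses — endorse at least $T$ of $K$ symptom criteria
and you carry the disorder — are the workhorse of substance-use-disorder
nosology. The criterion sets behind them, however, were assembled by expert
panels, not derived empirically, and there is good evidence that some criteria
are mild, normative, or redundant. `critopt` implements an exhaustive,
validity-driven alternative for two-wave panel data: treat *every* pair
(criterion subset, threshold) as a candidate diagnostic rule, score each
candidate on external validity indicators, and let replicated optimization and
voting decide which criteria earn their place.

For $K$ criteria there are $2^K - 1$ nonempty subsets and
$K \cdot 2^{K-1}$ rules; for the 11 DSM-IV alcohol-use-disorder criteria that
is 2,047 subsets and 11,264 rules, which `enumerate_rules()` lists in a fixed
canonical order (subset size, lexicographic subset, threshold) so that every
run is reproducible.

## Validity metrics

Writing $AUD_w$ for the binary diagnosis a rule produces at wave $w$, each
valid rule receives three unweighted metrics:

* **Persistence** (chronicity): $P(AUD_2 \mid AUD_1)$, the fraction of Wave-1
  diagnoses that re-diagnose at Wave 2.
* **Axis I comorbidity**: the median over seven symptom disorders of the
  Jaccard agreement $J = a/(a+b+c)$ between $AUD_1$ and the disorder
  indicator, where $a, b, c, d$ count joint presence, first-only, second-only
  and joint absence. Jaccard ignores $d$, which is essential when prevalences
  are a few percent and joint absence dominates by design.
* **Axis II comorbidity**: $0.1\,C_A + 0.7\,C_B + 0.2\,C_C$, where $C_X$ is
  the median Jaccard against the personality disorders of cluster $X$. The
  weights encode the established ordering of cluster associations with
  alcohol disorders (dramatic/erratic cluster B strongest, then C, then A);
  they are configuration constants, not estimated quantities.

Medians over an even number of disorders (cluster B has four) are the mean of
the two middle order statistics. A rule that diagnoses nobody at Wave 1 has
undefined persistence and vacuous comorbidity; such rules are flagged invalid,
carry `NA` (never 0) for the three metrics, and are excluded from ranking —
they can never be selected, which we consider the only defensible policy for
clinically empty rules.

## Composite scoring

The three metrics live on different scales, so each is rank-transformed to a
normal score across the valid rules: ascending ranks with average ties, rank
percentile $r/(n_{valid}+1)$, then the standard-normal quantile. The
$r/(n+1)$ convention keeps the extreme quantiles finite; when every value is
identical the shared average rank sits at the 50th percentile and all scores
are 0 by construction. Each rule is then scored

$$S = \alpha_1 Z_{P(AUD_2|AUD_1)} + \alpha_2\,(0.5\,Z_{AxI} + 0.5\,Z_{AxII}),
\qquad \alpha_1 + \alpha_2 = 1,$$

with $\alpha_1$ swept from 0 to 1 in steps of .10 (11 grid points). The
equal .5/.5 split between the two comorbidity scores, like the cluster
weights, is fixed. The rule maximizing $S$ is the optimum at that $\alpha$;
exact ties (which arise whenever two rules induce identical diagnosis
vectors) are broken parsimony-first — fewer criteria, then lower threshold,
then lexicographic bitmask — since nothing in the data distinguishes the tied
rules and the smaller one is cheaper to administer.

## Guarding against capitalization on chance

An exhaustive search over 11,264 rules will happily overfit one sample, so
selection never rests on a single optimization:

1. **k-fold discovery** (`discover_solutions()`): the sample is split into
   $k = 5$ seeded folds of near-equal size and the full optimization runs
   independently in each fold at each grid point — 55 candidate solutions.
2. **Min-max cross-validation** (`cross_validate()`): consecutive grid points
   within a fold that share a winner are collapsed into one candidate row;
   each candidate is re-scored in every *other* fold, reading its composite
   percentile (lower = better) from that fold's full 11,264-rule score table
   at each $\alpha$ in the candidate's range and averaging. A rule invalid in
   an evaluation fold scores the worst possible percentile, 100. Each row is
   summarized by its worst (maximum) percentile and the least-worst row wins.
   Because the source study does not state which $\alpha$ generated its
   evaluation cells, the range-mean is our convention, documented here; the
   percentile is always computed against the full rule ranking of the
   evaluation fold.
3. **Consensus voting** (`consensus()`): each criterion's vote is the
   proportion of the 55 solutions containing it (duplicate winners within a
   fold count once per grid point, keeping the denominator at
   $k \times 11$). Criteria at or above the cutoff (default .60) are
   retained; the final threshold is a configured constant (default 2),
   honoring the warning against single-criterion diagnosis rather than being
   searched.

The two selectors answer different questions — min-max rewards a specific
rule's replicability, consensus nominates a criterion set no single fold may
have produced — and both are returned by `criterion_select()`, the package's
central fitting function.

## External validation

`validation_report()` compares two competing rules on held-out validators:
their Wave-1 diagnoses are cross-classified into Both / A-only / B-only /
neither, and three planned contrasts (A-only vs B-only, A-only vs Both,
B-only vs Both) are run on every validator. Comparisons are survey-weighted
Welch tests: weighted means, reliability-weight variances, effective sample
sizes $n_{\mathrm{eff}} = (\sum w)^2 / \sum w^2$, and Welch–Satterthwaite
degrees of freedom; with unit weights this reduces exactly to the ordinary
Welch two-sample $t$ test. Binary validators run through the same machinery
as differences of weighted proportions. We deliberately do not implement
design-based (Taylor-linearized or replicate-weight) variance estimation;
weighted Welch with effective sample sizes is a reasonable approximation for
point comparisons but understates design effects from clustering and
stratification, and this is a stated limitation. Planned comparisons are
reported unadjusted, with an optional Benjamini–Hochberg flag. Missingness in
validators is handled pairwise per comparison; the complete-case rule at
ingestion applies only to the optimization columns (criteria and comorbidity
indicators).

## The synthetic generator

Real two-wave survey panels of this kind are restricted-access, so
`generate_panels()` provides a structurally faithful stand-in used by every
test. Each subject carries a stable severity $\theta_1 \sim N(0,1)$ with
$\theta_2 = \rho\,\theta_1 + \sqrt{1-\rho^2}\,\varepsilon$ (default
$\rho = .75$, putting rule persistences in the .3–.5 range typical of
alcohol-disorder panels). Criterion $j$ at wave $w$ is endorsed with
probability $\mathrm{logit}^{-1}(a_j(\theta^{*}_w - b_j))$, where
$\theta^{*}$ is the stable severity for *informative* criteria and a
wave-specific transient factor for *noise* criteria — redrawn each wave, so
noise criteria specifically damage persistence and carry no comorbidity
signal, which is exactly the structure the optimizer is supposed to detect.
Discriminations default to 1.5 (informative) and 0.8 (noise); intercepts
$b_j$ are solved numerically so marginal endorsement rates hit their targets,
which default to the published Wave-1 endorsement percentages (8.9952% down
to 0.6643%) for $K = 11$. Comorbid disorders are thresholded liabilities
correlated with $\theta_1$ (loadings .50 for cluster B, .40 for Axis I, .35
for cluster C, .30 for cluster A; lifetime prevalences .005–.22 in the range
reported for these disorders in US epidemiological surveys). External scales
are linear in $\theta_2$ and scored to mean 50, SD 10 like short-form health
subscales (health indices load −3, consumption +4); binary validators are
Wave-2 liabilities. Weights default to a unit-mean gamma (shape 4), mimicking
survey-weight dispersion; an option shares the endorsement uniforms and
transient factor across waves ("comonotone"), making $\rho = 1$ reproduce
Wave 1 exactly — a useful degenerate limit for tests.

What the generator does *not* emulate: complex sampling design (clustering,
stratification, oversampling), item-level measurement error, non-logistic
item response shapes, and any dependence between weights and severity.
Passing tests on synthetic data therefore demonstrate that the machinery
recovers planted structure under a clean latent-trait model, not that any
particular criterion set is optimal for real populations.

## Numerical and design choices

* **Problem sizes.** The test-suite exercises the full 11-criterion lattice
  on fold sizes around 2,000 subjects and runs planted-recovery replicates at
  $N = 10{,}000$; exhaustive profiling of 11,264 rules at those sizes takes a
  few seconds because per-subset endorsement counts are shared across
  thresholds and all Jaccard counts per rule reduce to one matrix
  cross-product.
* **Brute-force oracles.** For $K \le 4$ the entire pipeline is re-derived in
  the tests by naive loops (explicit subset enumeration, hand-rolled medians
  and ranks) and must agree with the package exactly, at every $\alpha$.
* **Tie and degeneracy policy.** Exact $S$ ties break parsimony-first;
  all-tied metrics transform to $z = 0$; invalid rules are excluded before
  ranking; a fold in which no rule is valid is skipped with a warning rather
  than aborting discovery.
* **Percentile of a rule in a fold**: average rank of $-S$ among valid rules,
  divided by the number of valid rules, times 100, so the best rule in a
  fold of $n_v$ valid rules scores $100/n_v$, not 0.
* **Abstainer filtering** is a data-preparation concern: the ingestion schema
  does not force a past-year-drinker column, because panels differ in how
  abstention is recorded; users should subset before `read_panel()` if their
  design calls for it.
* **Lifetime aggregation of Axis II indicators** (e.g. combining waves for
  antisocial personality disorder) is likewise delegated to the input schema:
  the package consumes whatever binary indicator the analyst maps in.

## Known limitations

Weighted Welch is not design-based inference; votes come with no uncertainty
quantification; the consensus threshold is fixed rather than optimized; the
search is exhaustive by design and grows as $K \cdot 2^{K-1}$, so the guard
refuses $K > 24$; and graded (non-binary) severity outputs are out of scope —
the rule space is binary count-and-threshold by construction.
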