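---
title: "Methods: decision-tree scoring, Choquet aggregation and risk categorisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-tree scoring, Choquet aggregation and risk categorisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrewelfare)
```

## The assessment model

`fibrewelfare` scores the obligatory animal-welfare requirements of a
textile standard against the Five Domains framework. The framework's four
scored domains — nutrition, physical environment, health and behavioural
interactions — jointly determine the fifth, mental state, which is never
scored directly. Five production-species groups are recognised: alpacas,
goats, sheep, cattle and waterfowl. Waterfowl is modelled as one group
(ducks and geese share the same mutilation rules); the configuration
format leaves room for subtyping later.

An assessment of one standard runs in three stages.

**Stage 1 — decision trees.** Every provision is covered by ordered
yes/no single-measure questions ("Is the Body Condition Score of the
animals regularly monitored?"). Answers address what the standard
*obligates*, not what animals experience: a "yes" means the requirement is
present in the standard. A tree of depth $k$ is stored as an explicit
table of all $2^k$ answer paths to leaf scores in $[0, 100]$ — the
simplest representation to validate for completeness and to diff against a
published tree table. Question identifiers are stable slugs
(`ad_libitum_roughage`), decoupled from display text, so a translated or
re-worded questionnaire scores identically.

The mutilations provision follows its own rule set. Each species has a
fixed item list (alpaca: castration; goats/sheep/cattle: dehorning, tail
docking, castration, all graded by method and use of pain relief; sheep
additionally mulesing, and waterfowl live plucking, force feeding and any
form of flight restraint, all prohibition-only). Each item yields a
partial score; the **minimum** partial is retained; and if the standard
permits any mutilation outside the list, the provision scores 0 outright.

**Stage 2 — Choquet integral.** Within a domain, provision scores are
aggregated with respect to a capacity $\mu$: a set function on the
domain's provisions with $\mu(\emptyset) = 0$, $\mu(N) = 1$ and
monotonicity under inclusion. With scores sorted ascending and
$x_{(0)} = 0$,

$$C_\mu(x) = \sum_{i=1}^n \left(x_{(i)} - x_{(i-1)}\right)\,\mu(A_{(i)}),$$

where $A_{(i)}$ is the coalition of provisions scoring at least
$x_{(i)}$. This is the ascending-sort telescoping convention; the
equivalent Möbius form $\sum_B m(B) \min_{i \in B} x_i$ is implemented as
an interchange representation and used as the independent oracle in the
test suite. Ties in the sort are resolved by stable ordering; the
integral's value is invariant to the tie-break.

**Stage 3 — median and categorisation.** The final (mental-state) score
is the median of the four domain scores, defined as the arithmetic mean of
the two middle order statistics. This definition is the only one
consistent with the half-integer final scores in the packaged 17-standard
results (7.5, 14.5, 19.5, 21.5). The final score maps to one of five risk
bands (0–19 very poor, 20–39 poor, 40–59 acceptable, 60–79 good, 80–100
excellent). Domain scores shown in reports are categorised with the same
rule.

## Numerical choices

* **Rounding.** Intermediate scores are never rounded during aggregation;
  reports display one decimal place. Categorisation rounds half-up to the
  nearest integer before banding. The five integer bands are ambiguous
  for fractional scores on their own; half-up is anchored by the
  boundary case in the packaged results, where the final score 19.5 of
  standard 10 is categorised as "poor" (i.e. rounds to 20), not "very
  poor".
* **Capacity validation tolerance** is $10^{-9}$ absolute, for
  normalisation, monotonicity and oracle agreement. Capacities live on
  2–4 provisions, so all subset computations are exact dense
  enumerations; no tolerance-sensitive algebra is involved beyond float
  summation.
* **Degenerate inputs.** Trees must cover all $2^k$ paths (no default
  leaf); missing answers, unknown ids and out-of-range scores are errors
  naming the offender. Validators return findings rather than throwing,
  so a configuration review can list every defect at once.

## Defaults, and what is reference vs. illustrative

The shipped default framework is runnable end-to-end, but only part of it
is reference material:

* **Reference (exact):** the appropriate-feed decision tree (three
  measures: ad libitum roughage, appropriate feed quantity, BCS
  management; leaves 100/65/55/35/45/25/35/5), the per-species mutilation
  item lists, and the packaged results table for 17 anonymised standards.
* **Illustrative:** the remaining provisions carry placeholder monotone
  trees (two or three questions drawn from the indicator descriptions,
  leaves on the usual grid of fives), marked as such in the configuration
  file. The published species-specific question catalogue is not public,
  so only its structure (at least two single indicators per provision per
  species — enforced as a validation warning) is modelled.
* **Graded mutilation scores** default to prohibited = 100, allowed with
  anaesthesia and analgesia = 35, with partial pain relief = 17, without
  pain relief = 2. These reproduce the score vocabulary observed in the
  packaged results (0, 2, 17, 35, 100 in the mutilation column) but the
  elicited mapping itself is not public, so the mapping is ordinary,
  overridable configuration.
* **Capacities** are required configuration. The expert-elicited weights
  behind the published domain scores are not public, and back-computing
  them from the results table gives mutually inconsistent singleton
  values (consistent with the printed scores being rounded), so the
  package deliberately does not guess them: the published domain scores
  are **not** claimed reproducible from the defaults, while the median
  stage on top of them is exact. The default capacities are built by
  `capacity_from_ranking()` with interaction 0.3.

### The ranking construction

Where only an importance ranking of a domain's provisions is available,
`capacity_from_ranking(ranking, interaction)` builds a capacity with
rank-sum singleton weights ($n, n-1, \dots, 1$, normalised) and every
proper coalition shrunk below additivity:
$\mu(A) = (1 - \lambda) \sum_{i \in A} w_i$ for $A \neq N$. The single
parameter $\lambda \in [0, 1]$ interpolates between the additive capacity
($\lambda = 0$, Choquet = weighted mean) and the unanimity capacity
($\lambda = 1$, Choquet = min). Any $\lambda > 0$ makes every coalition
sub-additive, so the domain score sits below the weighted mean — the
intended behaviour that a strong provision cannot compensate for a weak
one. The default $\lambda = 0.3$ is a moderate setting chosen once for
the illustrative configuration; it is not an elicitation result.

## The synthetic generators

The `generator_config()` family produces random-but-valid frameworks,
trees, capacities and answer sets so that every stage and every property
is testable without external data. They emulate the *structure* of the
assessment: yes/no measures (two to four per tree), leaf scores on the
grid of fives in $[0, 100]$, monotone trees (built as base score plus
non-negative per-question increments, which guarantees that flipping any
answer from no to yes never lowers the leaf), and monotone capacities
(uniform draws propagated up the subset lattice by running maxima, then
renormalised — covering both sub- and super-additive coalitions). A fixed
seed reproduces outputs bit-exactly.

What they do **not** emulate: the empirical answer correlations of real
standards (real certifications answer question blocks consistently, not
independently per question), elicited leaf scores, or elicited
capacities. Passing the property suite therefore demonstrates the
correctness and monotonicity of the aggregation machinery on valid
inputs, not agreement with any particular elicitation.

## Test problem sizes

The test suite checks the Choquet stage against the independent
Möbius-sum oracle on 1000 random capacities across all three generation
schemes (with idempotence, boundedness, coordinate monotonicity,
comonotonic additivity and positive homogeneity at tolerance $10^{-9}$),
mutilation dominance on 300 randomised rule/answer draws, end-to-end
no-to-yes monotonicity on 100 random answer sets with every single-step
improvement applied (roughly 2,500 full assessments), and the 17-standard
median and categorisation regressions exactly. These sizes give each
randomised property thousands of distinct cases while keeping the default
suite fast.

## Known limitations

* The tool assesses the *risk* implied by a standard's obligatory
  requirements; it is not an on-farm welfare measurement protocol, and no
  animal-based measurements are modelled.
* Scores carry no uncertainty: a yes/no review has no sampling error
  model, and the package does not propagate elicitation uncertainty
  through the capacities.
* Only the feed tree and the mutilation rules are reference-exact;
  assessments under the default configuration are directionally
  meaningful but their absolute domain scores depend on illustrative
  trees and capacities.
* The five risk bands treat a 19.5 and a 39.4 alike ("poor"); the
  underlying continuous scores are retained in all outputs for users who
  need finer resolution.
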