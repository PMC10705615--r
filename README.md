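# fibrewelfare

An animal-welfare **risk assessment tool for fibre-producing farm animals**
— sheep, goats, cattle, alpacas and waterfowl — built on the Five Domains
welfare framework. It is aimed at auditors, certification-scheme owners and
animal-welfare scientists who want a single, reproducible welfare-risk score
for a textile standard (a certification scheme for wool, cashmere, mohair,
down, leather or alpaca fibre) from a yes/no review of the standard's
obligatory requirements.

## The scoring model

The assessment is a three-stage hierarchical aggregation:

1. **Single measures → provision score (decision trees).** Each of 12
   provisions (appropriate feed, appropriate water; environmental comfort,
   resting comfort, ease of movement; absence of injuries, absence of
   disease, mutilations, fitness; environmental enrichment, social
   behaviour, human–animal relationship) is covered by yes/no
   single-measure questions. An ordered decision tree maps every complete
   answer path to a leaf score in [0, 100]. The **mutilations** provision
   follows its own rules: one partial score per mutilation item
   (graded items scored by method and use of pain relief; prohibition-only
   items such as mulesing or live plucking score points only under complete
   prohibition), the *worst* partial is retained, and allowing any other
   mutilation (e.g. ear-notching) forces the provision to 0.

2. **Provisions → domain score (Choquet integral).** Within each of the
   four scored domains the provision scores x are aggregated by a discrete
   Choquet integral with respect to a capacity (fuzzy measure) μ:

       C_μ(x) = Σᵢ (x₍ᵢ₎ − x₍ᵢ₋₁₎) · μ(A₍ᵢ₎),   x₍₁₎ ≤ … ≤ x₍ₙ₎, x₍₀₎ = 0,

   where A₍ᵢ₎ is the coalition of provisions scoring at least x₍ᵢ₎. An
   additive μ gives a weighted mean; sub-additive coalitions drop the
   aggregate below the mean, so one bad provision cannot be compensated
   away.

3. **Domains → final score (median).** The fifth domain, mental state, is
   the interplay of the other four: the final score is the **median** of
   the four domain scores (mean of the two middle values), mapped to one
   of five risk bands: 0–19 very poor, 20–39 poor, 40–59 acceptable,
   60–79 good, 80–100 excellent (fractional scores rounded half-up, so
   19.5 falls in "poor").

The package ships the reference feed decision tree, the per-species
mutilation rules, and the full results table for 17 anonymised textile
standards as fixtures, plus generators for synthetic frameworks, capacities
and answer sets. Capacities and most provision trees in the default
configuration are clearly marked illustrative — the expert-elicited
weights behind the published domain scores are user-suppliable
configuration, not package constants.

## Worked example

```r
library(fibrewelfare)
fw  <- default_framework()
ans <- load_answers(system.file("extdata", "answers", "example_sheep.yaml",
                                package = "fibrewelfare"), fw)
assess_from_answers(ans, fw)
```

```
Welfare risk assessment: example-wool-standard [sheep]
  nutrition: 49.7 (Probability for acceptable animal welfare)
    appropriate_feed           45
    appropriate_water          65
  physical_environment: 77.2 (Probability for good animal welfare)
    environmental_comfort      65
    resting_comfort            65
    ease_of_movement           100
  health: 33.7 (Probability for poor animal welfare)
    absence_of_injuries        100
    absence_of_disease         35
    mutilations                17
    fitness                    35
  behavioural_interactions: 29.5 (Probability for poor animal welfare)
    environmental_enrichment   5
    social_behaviour           35
    human_animal_relationship  65
  final (mental state): 41.7 -> Probability for acceptable animal welfare
```

Reading it: the fictitious standard does not require ad libitum roughage
but does require feed-quantity and Body Condition Score management, so the
feed tree returns the 45 leaf; it allows castration with only partial pain
relief, so the worst mutilation partial (17) becomes the provision score
and drags the health domain to 33.7; the final score is the median of the
four domain scores, 41.7, just inside the acceptable-risk band.

The same pipeline is scriptable from a shell via the installed CLI
(`exec/fibrewelfare`): `assess`, `validate`, `fixtures table7`, `report`
and `simulate` subcommands. For example, the textual analogue of a
per-standard chart for fixture standard 10:

```sh
fibrewelfare report --table7 10
```

```
Standard 10
  nutrition                     31  Probability for poor animal welfare
  ...
  final (mental state)        19.5  Probability for poor animal welfare
```

## Configuration files

Frameworks, trees, capacities and answers are plain YAML/JSON; the schema
document ships at
`system.file("extdata", "schemas", "framework.schema.md", package = "fibrewelfare")`.
See `vignette` sources under `vignettes/` for the full account of the
model, its defaults and its limitations.
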