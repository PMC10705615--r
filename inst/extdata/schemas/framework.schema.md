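# Configuration file schemas

All input files are structured text, YAML or JSON, chosen by file
extension (`.yaml` / `.yml` / `.json`).

## Framework file

Top-level keys:

| key | required | content |
|---|---|---|
| `domains` | yes | mapping domain id → list of provision ids. Exactly the four scored domains `nutrition` (2 provisions), `physical_environment` (3), `health` (4), `behavioural_interactions` (3); every provision belongs to exactly one domain. |
| `questions` | no | mapping question id → display text. Scoring uses ids only; translated questionnaires score identically. |
| `trees` | yes | list of tree entries (below). Every (species, provision) pair must be covered. |
| `capacities` | yes | mapping domain id → capacity entry (below). |
| `bands` | no | list of `{lower, upper, label}` integer bands partitioning 0–100; defaults to the standard five-band legend. |
| `meta` | no | free-form. |

### Tree entry (decision tree)

```yaml
- provision: appropriate_feed        # provision id
  species: all                       # "all" or a list of species ids
  questions: [q1, q2, q3]            # ordered question ids, depth k >= 1
  leaves: {"yyy": 100, ..., "nnn": 5}  # all 2^k paths ("y"/"n" strings,
                                       # first question first) -> score in [0,100]
  monotone: true                     # optional; enforces that flipping any
                                     # answer no->yes never lowers the leaf
```

### Tree entry (mutilation rule)

```yaml
- provision: mutilations
  species: [sheep]
  type: mutilation_rule
  items: {dehorning: graded, mulesing: prohibition_only, ...}
  graded_scores:                     # optional; defaults shown
    prohibited: 100
    allowed_full_pain_relief: 35
    allowed_partial_pain_relief: 17
    allowed_no_pain_relief: 2
```

`graded` items are scored by method and use of pain relief via
`graded_scores`; `prohibition_only` items score the `prohibited` value if
prohibited and 0 if allowed. The worst item partial is retained, and
allowing any unlisted mutilation forces the provision to 0.

### Capacity entry

Either a ranking construction:

```yaml
nutrition:
  ranking: [appropriate_feed, appropriate_water]  # most -> least important
  interaction: 0.3                                # 0 = additive, 1 = min
```

or explicit subset measures (subset keys are ids joined by `+`):

```yaml
nutrition:
  ground_set: [appropriate_feed, appropriate_water]
  mu:
    appropriate_feed: 0.8
    appropriate_water: 0.2
    appropriate_feed+appropriate_water: 1
```

With `complete: additive`, only singletons are required and every other
subset is completed additively. Otherwise omitting a subset is an error.
A capacity must satisfy `mu(empty) = 0`, `mu(full) = 1` and monotonicity
under set inclusion (tolerance 1e-9).

## Answer file

```yaml
standard: "my-standard"        # standards are anonymised by number in the
species: sheep                 # packaged results; meta may attach names
answers:
  <provision id>:
    <question id>: yes/no      # one answer per question of that tree
mutilations:
  <item id>: <status>          # statuses as per the mutilation rule
  other_mutilations_allowed: yes/no
meta: {}                       # free-form
```

## Results

`write_results()` emits CSV in the published results-table column order
(standard, the 12 provision columns with each domain column following its
provisions, final score; integers printed without decimals, halves as
`.5`), or JSON adding per-domain and overall category labels.
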