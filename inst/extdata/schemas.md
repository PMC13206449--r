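# Artifact table schemas

All pipeline artifacts are tab-separated text with a one-line header.

## cohort.tsv (`write_cohort` / `read_cohort`)

| column          | type    | units | description                                   |
|-----------------|---------|-------|-----------------------------------------------|
| participant_id  | string  | -     | unique opaque id                              |
| sex             | F / M   | -     | female is the reference level everywhere      |
| age_months      | integer | months| age at acquisition                            |
| tiv             | number  | mm^3  | total intracranial volume, > 0                |
| tsa             | number  | mm^2  | total surface area (optional)                 |
| mct             | number  | mm    | mean cortical thickness (optional)            |
| tcv             | number  | mm^3  | total cerebral volume (optional)              |
| tiv_alt         | number  | mm^3  | second TIV source (optional)                  |

## measures.tsv (`write_measure_matrix` / `read_measure_matrix`)

First column `participant_id`; remaining columns are unit ids (regions,
vertices or voxels) holding the measure values (mm^3 | mm^2 | mm | unitless
Jacobian, depending on the metric). Missing entries are empty/NA.
A sibling `*_truth.tsv` carries the generator's ground truth per unit:
`unit`, `alpha`, `beta`, `age_slope`, `sex_effect`.

## design_*.tsv (`write_design` / `read_design`)

| column    | description                                                 |
|-----------|-------------------------------------------------------------|
| member_id | participant id in the subsample                             |
| male_id   | for paired designs: the male of the member's pair           |
| female_id | for paired designs: the female of the member's pair         |
| label     | matched / age_matched / not_matched / extreme               |
| tolerance | relative matching tolerance (paired designs)                |

## estimates_*.tsv (`write_estimates` / `read_estimates`)

Long format: `unit`, `term` ((Intercept), age, sexM, age:sexM, global),
`estimate` (standardized coefficient), `se`, `p`, `adj_r2`, `n`, `sample`,
`method`, `model` (eq1 | eq5).

## comparisons.tsv

One row per (comparison, term): `term`, `r`, `slope`, `t`, `p`, `p_fdr`,
`d`, `n_units`, `comparison` (e.g. `not_matched.pcp`, always against the
matched-sample raw-value gold standard).

## bias_maps.tsv

`unit`, `bias` (signed orthogonal distance of (gold, test) sex estimates
from the identity line, in standardized-estimate units), `comparison`.

## Unit coordinates (spin test)

`unit`, `x`, `y`, `z` (unit-sphere centroid), `hemisphere` (L/R).

## config (`write_config` / `read_config`)

`key: value` lines, one per `sim_config` field.
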