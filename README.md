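# jemkit

Psychosocial Job Exposure Matrices and an Occupational Job Strain Index
from ordinal survey microdata.

## The problem

National registers carry population-wide longitudinal data on employment
and health but almost nothing about working conditions. A **Job Exposure
Matrix (JEM)** bridges that gap: survey respondents' self-reported work
environment is aggregated by occupation, and the resulting occupation-level
exposure estimates are attached to every register individual with that
occupation code. `jemkit` implements this construction for *psychosocial*
exposures in the tradition of Karasek's Demand-Control model, for
epidemiologists and register researchers who need a documented, testable
pipeline from raw ordinal survey items to a mergeable occupation-level
strain index.

## The method

Given survey microdata with ten ordinal items — four psychological **demand**
items (quantitative demands, conflicting ways of doing things, insufficient
resources, contradictory requests) and six **control** / decision-latitude
items (decide how, decide pace, important decisions, use skills, develop
skills, monotonous work) — the pipeline is:

1. **Align** each item to an adverse-high orientation: protective items are
   reflected, x ↦ min + max − x.
2. **Individual median split.** For each item, the cut-off m is the median
   of the pooled aligned responses; respondent i is *exposed* iff
   x_i > m (strictly). E.g. with a median of 2 on a 1–5 frequency scale,
   responses 3, 4 and 5 classify as exposed.
3. **Share aggregation.** Within each (JEM group g, gender s) cell,
   share_g,s = 100 · #exposed / #non-missing per item. A share of 0 means
   no respondent in the cell is exposed; 100 means all are. Cells below a
   minimum size are suppressed to missing rather than conflated with 0.
4. **Occupation median split.** Per item, occupations are classified exposed
   iff their cell share strictly exceeds the median share across
   group-gender cells.
5. **Strain index.** demand index D = # exposed demand items (0–4); control
   adversity index C = # exposed control items (0–6). High demand ⇔ D >
   median(D); low control ⇔ C > median(C); the Karasek quadrants follow
   (high_strain = job strain, active, passive, low_strain).
6. **Linkage.** The exported one-row-per-(occupation code, gender) table is
   left-joined onto register data, optionally after a 4-digit occupational
   code crosswalk with explicit ambiguity policies.

A synthetic-data module generates surveys, registers, group maps and
crosswalk keys with *exact* known ground truth (the probability of
exceeding the cut-off is controlled by construction), so every stage of the
pipeline is verifiable.

## Worked example

```r
library(jemkit)
items <- default_item_set()                      # 10 items: 4 demand, 6 control
scenario <- simulation_scenario(n_codes = 12, n_groups = 8,
                                waves = c(2006L, 2009L), n_per_cell = 40,
                                seed = 42)
survey <- generate_survey(scenario, items)       # 2,560 respondents
cutoffs <- compute_cutoffs(survey, items)
cutoffs[cutoffs$item_id == "quantitative_demands", ]
#>   item_id              cutoff n_used
#> 1 quantitative_demands      2   1252
```

The pooled median for quantitative demands is 2, so only responses above 2
(weekly or more often) count as exposed. Building the matrix and the index:

```r
flags <- dichotomize(survey, cutoffs, items)
jem   <- build_jem(flags, survey_group_map(survey))
jem
#> <jem_matrix> 16 cells x 10 items (n_min = 10, 0 suppressed)
#>   jem_group_id gender share_quantitative_demands share_conflicting_ways ...
#> 1 G001         female                       20.3                   31.6
#> 2 G001         male                         16.9                   16.7
```

20.3 means: 20.3% of the women in JEM group G001 report adverse quantitative
demands. Classifying occupations and combining the dimensions:

```r
code_shares <- expand_to_codes(jem, survey_group_map(survey))
strain <- compute_strain(assign_occupation_exposure(code_shares, items), items)
table(strain$strain_quadrant)
#>      active high_strain  low_strain     passive
#>           3           3          12           6
```

Of the 24 (occupation, gender) cells, 3 are high-strain jobs: above-median
demands combined with below-median control. `export_strain_index()` writes
the combined JEM + index with a generated codebook; `merge_exposures()`
attaches it to register microdata with a full match report.

A command-line interface wraps the same functions:

```sh
exec/jemkit simulate --out fixtures --codes 20 --groups 10 --seed 5
exec/jemkit index --survey fixtures/survey.csv \
    --group-map fixtures/group_map.csv --out index.csv
exec/jemkit merge --index index.csv fixtures/register.csv merged.csv
```

## Scope

The package constructs and links exposure matrices; it deliberately does
not model health outcomes, survey weights, or wave trends, and it ships no
real survey data — the national survey microdata the method was designed
around is access-restricted, which is exactly why the synthetic generator
with known ground truth is part of the package.
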