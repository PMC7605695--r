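# triadscope

Triadic social-network analysis of classroom sociometric data, built for
studies of adolescent alcohol use: who spends time with whom, how those ties
organise into balanced (transitive) triads, and how the co-drinking network
relates to friendship and gender structure in rural versus urban schools.

## What it computes

Starting from a per-classroom ordinal contact matrix (directed ratings 1 =
"we never coincided" … 5 = "we are always together"), a roster with gender /
setting / AUDIT responses, and a binary co-drinking nomination network:

1. **Dichotomization** — three nested binary layers: minimum (rating ≥ 2),
   intermediate (≥ 3) and maximum (≥ 4) contact intensity.
2. **Triad census** — for each layer, counts of all C(n, 3) actor triples
   over the 16 Holland–Leinhardt MAN types (003 … 300), partitioned into
   transitive ({030T, 120D, 120U, 300}: triads satisfying "if X → Y and
   Y → Z then X → Z" non-vacuously) and intransitive (everything else),
   plus per-actor transitive-triad participation profiles.
3. **Composition layers** — the same-gender (homophilous) subnetwork, a
   gender-stratified census (FFF/FFM/FMM/MMM strata), and the consumption
   layer from drinking nominations.
4. **Aggregation** — per-classroom censuses summed into rural and urban
   setting totals.
5. **Inference** — AUDIT risk classification (total ≥ 8 by default),
   chi-square tests of risk against gender and setting, and per-classroom
   Pearson correlations of transitive-triad profiles between the
   consumption layer and the contact / gender layers, each with the exact
   power of the ρ = 0 test at the observed r.
6. **Synthetic data** — a generator producing classroom networks with
   reciprocity, gender homophily, triadic closure and risk-linked
   co-drinking nominations, so the entire chain is testable without any
   survey deposit.

## Worked example

```r
library(triadscope)

study  <- generate_study(generator_preset("survey_shaped", seed = 1))
report <- run_pipeline(pipeline_config(preset = "survey_shaped", seed = 1))
print(report)
#> <analysis_report> 10 classrooms (rural/urban), 195 actors
#>   rural / minimum: 459/3840 transitive triads
#>   rural / intermediate: 84/3840 transitive triads
#>   rural / maximum: 7/3840 transitive triads
#>   rural / gender_homophilous: 169/3840 transitive triads
#>   rural / consumption: 13/3840 transitive triads
#>   urban / minimum: 866/7843 transitive triads
#>   ...
#>   (2 warnings collected)
```

The `459/3840` line says that of the 3840 actor triples across the six
rural classrooms, 459 form transitive triads in the minimum-intensity
contact layer (11.95%, vs 11.04% urban in this simulation). The warnings
are classrooms whose sparse consumption layer has a zero-variance
transitive profile — reported, not silently dropped.

```r
triad_census(dichotomize(study$contact_matrices$rural_1, "minimum"))
#> <triad_census> 17 actors, 680 triads: 87 transitive (12.79%), 593 intransitive
#>   003:41  012:135  102:59  021D:41  021U:28  021C:57  111D:47  111U:75
#>   030T:38  030C:11  201:21  120D:23  120U:18  120C:39  210:39  300:8

report$risk$overall
#>   group  status   n      pct
#> 1   all no_risk 114 58.46154
#> 2   all at_risk  81 41.53846

print(report$risk$chi_square_setting)
#> X^2(1, N = 195) = 2.521, p = 0.1123

subset(report$correlations, classroom == "urban_1")
#>    classroom setting       target_layer  n         r    p_value     power
#> 13   urban_1   urban            minimum 24 0.2118081 0.32042576 0.1687982
#> 14   urban_1   urban gender_homophilous 24 0.4567714 0.02484454 0.6359902
```

The last table is one classroom's row of the correlation report: the
per-actor transitive-triad counts of the co-drinking layer correlate at
r = 0.46 with the same-gender contact layer (p = 0.025; the exact power of
the test at that r and n = 24 is 0.64).

`write_report(report, "out/")` writes `report.json`, the census,
correlation and risk CSV tables, and every derived network in UCINET DL and
edge-list form. A command-line wrapper with `simulate` and `analyze`
subcommands lives at `inst/cli/triadscope.R`.

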