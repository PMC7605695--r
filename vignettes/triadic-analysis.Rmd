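---
title: "Triadic analysis of classroom friendship and co-drinking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triadic analysis of classroom friendship and co-drinking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Adolescent alcohol use spreads through peer groups, and the smallest social
unit in which "group" structure can be seen is the triad: three classmates
and the directed ties among them. Balance theory predicts that friendship
triads drift toward *transitive* configurations — if X spends time with Y and
Y with Z, then X also with Z — and homophily predicts that ties concentrate
among actors with shared attributes such as gender. `triadscope` implements a
classroom-level analysis chain built on these two ideas: ordinal sociometric
ratings are dichotomized into binary contact networks at three intensity
levels, each layer gets a full triad census partitioned into transitive and
intransitive triads, censuses are aggregated by rural/urban school setting,
and the transitive structure of the co-drinking network is correlated with
the contact and gender-composition layers, with AUDIT-based risk
classification and chi-square tests on the actor side.

```{r, message = FALSE}
library(triadscope)
```

## Data model and conventions

Each classroom contributes a square ordinal **contact matrix** with entries
1 ("we never coincided") to 5 ("we are always together"). Rows are raters:
`values[i, j]` is actor *i*'s rating of *j*, so all derived networks are
directed and no symmetrization is applied anywhere in the default chain.
This convention has to be fixed somewhere, because triad type frequencies
change under transposition; the package states it in every reader and tests
the transposition symmetry explicitly (transposing swaps the `021D/021U`,
`111D/111U` and `120D/120U` counts and fixes the rest).

Missing ratings (an absent respondent) are an explicit `NA` sentinel. The
default policy recodes them as 1, i.e. "we never coincided" — conservative
in that it can only remove ties — with `drop_actor` available to remove
non-respondents entirely, and `keep`, under which a missing rating simply
never becomes a tie. Actor ids are whitespace-trimmed and matched
case-sensitively.

## Dichotomization

A tie exists at a level when the rating reaches that level's cut:

| layer        | no contact | contact      | cut |
|--------------|-----------|---------------|-----|
| minimum      | 1         | 2, 3, 4, 5    | ≥ 2 |
| intermediate | 1, 2      | 3, 4, 5       | ≥ 3 |
| maximum      | 1, 2, 3   | 4, 5          | ≥ 4 |

The cuts are configurable but validated to be monotone, so the nesting
property ties(maximum) ⊆ ties(intermediate) ⊆ ties(minimum) holds by
construction for any input. The minimum layer is the analytic default
throughout (a rating of 2 marks the *start* of a relationship), but censuses
of all three layers are always computed.

```{r}
vals <- matrix(c(1, 3, 1,
                 5, 1, 2,
                 1, 1, 1), 3, byrow = TRUE)
cm <- contact_matrix(vals, c("x", "y", "z"), classroom = "demo")
sapply(dichotomize_all(cm), function(net) sum(net$adjacency))
```

## The triad census and the transitive/intransitive partition

Every unordered triple of actors falls in exactly one of the 16
Holland–Leinhardt MAN classes (`003` … `300`; digits count Mutual,
Asymmetric, Null dyads, the letter disambiguates orientation).
Classification uses a precomputed 64-entry lookup over the six arc bits of a
triple — exact, not heuristic, since the lookup is built from the dyad-count
rules — and the test suite keeps an independent brute-force isomorphism
oracle (all 6 node permutations against canonical representatives) plus a
cross-check against `igraph::triad_census()`. Censuses are plain O(n³)
enumerations; with classrooms of at most a few dozen students
(C(35, 3) = 6545 triples) nothing faster is warranted, and the subquadratic
census algorithms are deliberately out of scope.

The partition follows the structural-balance reading: **transitive** types
are those containing at least one non-vacuously transitive ordered triple
and no intransitive one — `030T`, `120D`, `120U` and the complete triad
`300` — and everything else is reported as **intransitive**, including the
vacuous `003`/`012`/`102`. This binary labelling is what classroom tables in
this literature print (e.g. "Triad 102 (Intransitive)", "Triad 300
(Transitive)"); for sensitivity analysis `transitivity_scheme()` accepts an
explicit `vacuous` set, which turns the partition three-way without touching
the counts.

```{r}
full <- binary_network(1 - diag(4), letters[1:4], "demo", "minimum")
triad_census(full)
```

## Composition layers

The gender composition of a contact network is read here, by default, as
the *same-gender subnetwork*: keep tie i→j iff the two actors share a
gender. This is the homophily reading — the subnetwork carries exactly the
ties homophily can act on. An alternative reading, a census *stratified* by
the gender multiset of each triple (FFF/FFM/FMM/MMM) on the intact network,
is provided as `stratified_census()`; its per-stratum counts add back to the
unstratified census by construction, and the pipeline reports both, because
published per-composition counts could arise from either and the source
material does not disambiguate. Neither is claimed to be "the" original
computation.

The consumption layer is the directed co-drinking nomination network, kept
asymmetric. Flags exist to intersect it with the contact layer (a
nomination of a non-contact then drops) and to union-symmetrize; both are
off by default.

## Risk, association, correlation and power

AUDIT totals are the sum of the 10 item scores (items 1–8 in 0–4, items
9–10 in 0/2/4; total 0–40). The risk cut-off defaults to **total ≥ 8**, the
instrument's conventional screening threshold; because source studies do
not always state their cut, the threshold is a prominent configuration key
and every report names it. Chi-square tests of risk against gender and
setting use the Pearson statistic without continuity correction by default
(the common default in survey software), with Yates correction behind a
flag.

Cross-layer association is a Pearson correlation between vectors describing
the transitive structure of two layers on the same actors. The default
vector is the **node profile**: for each actor, the number of transitive
triads that contain them. This choice fits a design in which one
correlation is reported per classroom and its power varies with classroom
size; the 16-count census vector and the vectorized adjacency (`tie_level`,
a QAP-style comparison without the permutation test) are selectable
alternatives. Zero-variance vectors (e.g. an empty consumption network) are
reported as explicit warnings per classroom, never silently skipped.

The attached power is the probability of rejecting ρ = 0 at level α given
the observed r and n. The default method integrates the **exact sampling
density of the correlation coefficient** under a bivariate normal model
(Hotelling's form, with the Gaussian hypergeometric factor summed
directly); the Fisher z approximation (z = atanh r, SE = 1/√(n−3)) is
retained as `method = "fisher_z"`. The exact route is the default because
at the small classroom sizes this package targets the z approximation
visibly understates power for large |r| — at r = 0.8, n = 10 it gives 0.828
where the exact value is 0.869 (a Monte-Carlo check with 10⁵ simulated
samples gives 0.870) — and power columns in this literature are produced by
exact-distribution software. Boundary behaviour is pinned: power(0, n) = α
exactly, power is monotone in |r| and n, and |r| = 1 maps to power 1.

```{r}
c(exact = power_for_r(0.8, 10), fisher_z = power_for_r(0.8, 10, method = "fisher_z"))
```

## The synthetic classroom generator

Real sociometric deposits cannot ship with a package, so `generate_study()`
produces classrooms with the statistical structure the analysis assumes:

* **reciprocity** — a directed tie is more likely when the reverse tie
  already exists (`reciprocity_boost`, default +0.35 on the tie probability);
* **gender homophily** — same-gender pairs get `homophily_boost` (+0.10);
* **triadic closure** — repeated sweeps close each open two-path with
  `closure_prob` (0.15, 2 sweeps);
* **risk-linked co-drinking** — nominations occur on friendship ties with
  probability 0.60 when both actors are at risk, 0.08 otherwise;
* **consistent AUDIT items** — a target total is drawn on the correct side
  of the risk threshold and partitioned across items within their legal
  ranges (items 9–10 even-valued), so re-scoring the items always
  reproduces the drawn risk status.

The `survey_shaped` preset fixes the surveyed study's shape: 6 rural
classrooms totalling 100 students and 4 urban totalling 95 (195 actors,
54% female, rural risk prevalence 0.46 vs urban 0.41). Classroom sizes are
explicit vectors because those totals are not reachable from the generic
18–35 size range. Each classroom runs on its own pre-drawn sub-seed, so a
classroom's data are invariant to how many classrooms surround it. Baseline
tie probability (0.15), the intensity thresholds (0.5/0.8/0.95 on the
latent strength, so most ties are "sometimes together" and few are "always
together") and the mean-17 age distribution were chosen once as plausible
classroom values and are not calibrated to any dataset.

What the generator does **not** emulate: degree heterogeneity beyond what
the boosts induce (no popularity effects), age or classroom-subgroup
structure, negative ties, and any dependence between the friendship process
and AUDIT scores other than through the risk flag. Passing tests therefore
demonstrate correctness of the computations and the direction of the
designed effects — not that real classrooms look like these. Notably, sparse
co-drinking layers in small classrooms routinely yield zero-variance
transitive profiles; the pipeline reports these as per-classroom warnings,
which is the realistic outcome, not a failure.

```{r}
study <- generate_study(generator_preset("survey_shaped", seed = 1))
summarize_truth(study)$risk_by_setting
```

## The pipeline

`run_pipeline()` chains the stages — read or simulate, dichotomize, compose,
census, aggregate by setting, classify risk, test, correlate — and returns a
report whose every number traces to one operation's output; the setting
aggregates in the report are recomputed in the test suite from the
per-classroom censuses also present in the report. Reports carry a
provenance block (config hash, seed, package version) and contain no
timestamps, so a rerun with identical configuration is identical
byte-for-byte. `write_report()` emits `report.json`, the census/correlation
/risk CSVs, and every derived network in DL and edge-list form for audit in
UCINET or elsewhere. A thin command-line wrapper with `simulate` and
`analyze` subcommands ships in `inst/cli/triadscope.R`.

## Numerical and design notes

* Triad classification is exact integer arithmetic; the only floating-point
  computations are proportions, correlations and power. The power integrand
  is integrated with `stats::integrate()` at rel.tol 1e-9 after log-space
  assembly of the density constant, and the hypergeometric series is summed
  to a 1e-13 relative tail.
* Edge lists are sorted by (source, target) under C-locale radix order, so
  written files are deterministic across platforms.
* `p_value` for |r| = 1 is reported as 0 and power as 1 (degenerate but
  well-defined limits).
* Test problem sizes: oracle equivalence on all 64 labelled 3-node digraphs
  plus 50 random digraphs of up to 12 nodes; census identities on 200 random
  networks; generator effect-direction checks across 30 seeds with paired
  one-sided Wilcoxon tests on two-classroom studies of size 20. These sizes
  give the Wilcoxon trends p-values far below the 0.01 bar while keeping the
  whole suite fast.

## Limitations

* The Davis-style census here is the binary transitive/intransitive
  partition of the 16 MAN types; ranked-cluster permitted/forbidden typing
  is not implemented.
* No Holland–Leinhardt distributional tests (τ statistics, conditional
  uniform null models), no ERGM or multilevel modelling, and no
  multiple-testing correction across classroom correlations by default (a
  Benjamini–Hochberg column can be added downstream from the raw p-values
  the report carries).
* The UCINET DL reader supports the `fullmatrix` and `edgelist1` variants
  only; other variants are rejected with a clear message.
* Cross-sectional data: nothing here supports causal claims about whether
  transitivity drives drinking or vice versa.
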