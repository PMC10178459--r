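---
title: "Rule-based clonality calling from clonotype frequency tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based clonality calling from clonotype frequency tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonocall)
```

## The problem

B and T lymphocytes acquire a unique rearranged immunoglobulin or T-cell
receptor sequence during development. A lymphoproliferative lesion derived
from a single cell therefore shows one (or, with biallelic rearrangement,
two) over-represented V-J "clonotypes", while a reactive, polyclonal
population shows hundreds of distinct clonotypes each carrying a small
fraction of reads. Amplicon sequencing of the IGH framework regions
(FR1/FR2/FR3), IGK, TRG and TRB yields, per assay, a ranked clonotype
frequency table: sequence, read count, and percent of total reads. The
diagnostic question — *clonal* versus *no evidence of clonality* (NEC)
versus *invalid* — reduces to a small set of numeric rules over that table,
which is exactly what this package automates.

The hard part is not the obviously clonal or obviously polyclonal sample;
it is the middle ground. A sample with very few B or T cells has a
*restricted repertoire*: few clonotypes, each at artificially high percent
because the denominator is small, with none truly dominant. A rule that
asks only "is any clone above x% of reads?" calls every such sample clonal.
The decision-tree model implemented here guards against this by requiring a
*defined polyclonal background* before any percent threshold below the
bypass level may fire.

## The models

All five rule sets share three ingredients: a sample-acceptance read gate,
a dominant-clone percent criterion, and a polyclonal-background comparison.
They differ in every number and in how the background is defined.

| Model | Read gate | Dominant clone | Background definition |
|---|---|---|---|
| `roswell_park` | 20,000 | top-two sum ≥ 30% (B) / 50% (T) bypass; else ≥ 2.5% (FR), 5% (IGK, T) and ≥ 10× background | median of clones ranked 3–10 with percent ≤ 1% (FR) / 1.25% (IGK, T); at least 3 required, else undefined |
| `invivoscribe` | 20,000 | ≥ 2.5% and ≥ 10× background | the 3rd most frequent clone |
| `msk` | 30,000 | ≥ 2.5% / 10× (≥ 100k reads), ≥ 5% / 20× (< 100k) | the 3rd most frequent clone |
| `nollet_schumaker` | 1,000 | ≥ 4% and ≥ 4.5× background | first clone in the top 10 at ≤ half the clone above it |
| `ns_modified` | 20,000 | as `nollet_schumaker` | as `nollet_schumaker` |

The decision-tree (`roswell_park`) model is a strict step sequence; the
step that decides a call is recorded in the `fired_rule` field so every
result is auditable:

1. fewer than 20,000 total reads → `INVALID`;
2. top-two merged clones ≥ 30% (B assays) or ≥ 50% (T assays) → `CLONAL`
   irrespective of background — this is how samples with a very high clonal
   fraction (sometimes only 2–3 merged clonotypes in total) are caught;
3. fewer than 3 clones ranked 3–10 at or below the background ceiling →
   `NEC` (this is the restricted-repertoire guard); otherwise the
   background is the *median* percent of the qualifying clones;
4. top-two sum < 10× background → `NEC`;
5.–7. top-two sum ≥ 5% (IGK, TRG, TRB) or ≥ 2.5% (FR assays) → `CLONAL`,
   else `NEC`.

Case level: a lineage is clonal if *any* of its assays is clonal
(FR1/FR2/FR3/IGK for B; TRG/TRB for T); a lineage is invalid only if every
assay failed.

Where the tabulated summary of the rule sets and the step-list of the
implemented software disagree (the IGK bypass appears both as 30% and as
50%), the step list is implemented and the tabulated variant is reachable
through `model_config()` overrides, e.g.
`model_config("roswell_park", bypass_pct_b = 50)`.

The MSK model can emit `OLIGOCLONAL` (≥ 3 dominant clones above 100,000
reads) and the Nollet/Schumaker model `POLYCLONAL_MINOR` (neither clonal
nor strictly polyclonal). Neither source defines behaviour when its
background is undefined; for Nollet/Schumaker we emit `POLYCLONAL_MINOR`
with an undefined background whenever some clone exceeds 2% — a declared
choice, not an inference from data. Both categories count as valid
non-clonal results at case level.

### Numeric choices

Percent thresholds are compared on read counts (`count × 100` vs
`threshold × total`), not on the float quotient, so boundary cases like "a
clone at exactly 2.5%" are decided exactly; all thresholds are inclusive
("equal to or greater"), read gates fail on strict `<`. Ranks that do not
exist contribute zero percent; an empty table above the read gate is a
valid negative. Rank ties on read count are broken by merged-member count,
then lexicographically by sequence, so output is identical across
platforms.

## Merging

Sequencing and alignment errors scatter a clone's reads over near-identical
clonotypes. Before calling, each of the top 10 clones absorbs (in rank
order) any lower-ranked clone within the top 500 whose sequence is within
`max_mismatch` of its own; absorbed reads are summed into the absorber,
which keeps its own sequence, and an absorbed clone can never absorb.
The default mismatch budget is 2; the MSK dialect merges clones differing
by fewer than five nucleotides (`max_mismatch = 4`). Because "mismatch" is
not defined with respect to indels in any source, the default distance is
Levenshtein (`bounded_edit`) — junction-length variation between artifacts
is real — with a strict substitution-only Hamming mode
(`equal_length_hamming`) available. An `N` base never matches anything,
including another `N`: an ambiguous base is not evidence of identity. If
two top-10 clones are within range of each other the higher-ranked absorbs
the lower; this is deliberate — the same behaviour that collapses a
biclonal pair of similar sequences into one dominant clone.

## Run-level QC

Before any sample is called the run must pass three gates
(`evaluate_run()`): the fraction of bases at or above Q30 (default
threshold 0.75 — a configurable local acceptance choice, as no universal
value exists), a negative control in which no clone exceeds 1% of total
reads (inclusive boundary) and which carries at least the model's minimum
read count (a 50-read control trivially passing the percent rule says
nothing about contamination), and a positive control that the active model
calls clonal at its declared target. A failing run marks every sample of
the run invalid with the run-level reason in each report.

## The synthetic generator

`synthetic_spec()` / `generate_sample()` produce clonotype tables with
known truth. Background clone frequencies are a symmetric Dirichlet
(concentration 5 by default: visibly uneven but with no clone approaching
1%) scaled to the non-dominant mass; dominant clones sit at exact target
fractions; counts are one multinomial draw, so read sums are conserved
exactly and sampling noise is realistic at the margins the models test.
Satellite clones (a dominant sequence mutated at 1–2 positions, carrying
10% of that clone's mass) exercise the merge step from inside the merge
radius. Defaults per phenotype: polyclonal/monoclonal/biclonal use 500
background clones and 100,000 reads; `low_reads` uses 10,000 reads (below
every model's gate); `restricted` uses 8 clones and concentration 25. The
flatter restricted concentration is part of the phenotype's definition —
a restricted repertoire has *no dominant clone*, and at concentration 5 a
small Dirichlet occasionally concentrates over half the reads in two
clones, which is a (bi)clonal pattern, not a restricted one (the decision
tree correctly calls such tables clonal through its bypass step). At
concentration 25 the largest top-two share observed over 2,000 seeds is
39.8%, safely outside the bypass.

`generate_cohort()` jitters per-case parameters deterministically under a
master seed: the dominant fraction uniform over `dominant_range`
(default 0.30–0.60, chosen so the decision margin at every step dwarfs
multinomial noise; biclonal cases split it 60/40), background clone count
±10%, total reads ±20%. All randomness flows from explicit seeds;
regenerating with the same seed is bit-identical, and the generator
restores the caller's RNG state.

What the simulator does *not* emulate: real V(D)J sequence structure and
junction biology, PCR amplification bias, primer dropout, FFPE artifacts,
or the correlation between assays of one patient. Passing synthetic tests
therefore demonstrates that the rule logic is implemented correctly and
robust to sampling noise — not that any model's clinical accuracy
transfers to real specimens; the published validation numbers come from
clinical samples this package cannot regenerate, and only their metric
arithmetic is reproduced here.

## Evaluation

`build_confusion()` maps case calls against gold labels (clonal = positive)
with excluded cases skipped; invalid calls are a third outcome and are
omitted from the 2×2 unless `invalid_as_negative = TRUE`.
`compute_metrics()` reports sensitivity, specificity, PPV and NPV in
percent, rounded half-up to one decimal (matching how the published
accuracy tables are rounded; base `round()` is half-even), with undefined
metrics as `NA` rather than a silent 0 or 100.

## Problem sizes used in the checks

The bundled test-and-acceptance workloads are sized for a single CPU:
brute-force merge cross-checks on 1,000 fuzzed tables of up to 30 clones,
model-vs-oracle fuzzing at 200–1,000 tables per model, recovery cohorts of
20 + 20 cases × 2 targets at 100,000 reads, and 100-seed edge-case sweeps.
These sizes give every stochastic property a wide margin (the weakest,
the 20-case cohort, has per-case decision margins of several hundred
standard errors) while keeping a full run in minutes.

## Known limitations

* The accepted header-alias list for vendor tables is a best-effort
  reconstruction; no public schema exists for every software version.
* The positive-control pass criterion (control called clonal by the active
  model) is declared, not taken from a published numeric requirement.
* No `RESTRICTED_REPERTOIRE` output category exists: such samples are
  reported NEC via the undefined-background path, mirroring current
  practice; a distinct category would be the natural extension.
* Monoclonal-vs-biclonal subtyping and cross-timepoint sequence tracking
  (residual-disease monitoring) are out of scope.
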