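# clonocall

Automated, auditable clonality calling for NGS-based B- and T-cell receptor
rearrangement assays.

Molecular pathology labs assess lymphoid clonality by amplicon sequencing of
the IGH framework regions (FR1/FR2/FR3), IGK, TRG and TRB loci. The upstream
vendor software turns FASTQs into per-assay *clonotype frequency tables* —
ranked unique V-J sequences with read counts and percent of total reads.
Turning those tables into a diagnostic call (*clonal* / *no evidence of
clonality* / *invalid*) is traditionally a subjective read-out. `clonocall`
makes it a deterministic, fully audited computation, for molecular
pathologists and pipeline engineers who want reproducible sign-out.

## What it implements

The core is a decision-tree model with an explicitly defined polyclonal
background, alongside three previously published rule sets for comparison.
For an assay with total reads $N$ and merged clone percents
$p_1 \ge p_2 \ge \dots$, the decision tree is:

1. $N < 20{,}000$ → **INVALID**
2. $p_1 + p_2 \ge$ 30% (B assays) / 50% (T assays) → **CLONAL** (bypass)
3. background $B = \mathrm{median}\{p_r : 3 \le r \le 10,\ p_r \le c\}$
   with ceiling $c = 1\%$ (FR) or $1.25\%$ (IGK/TRG/TRB); fewer than 3
   qualifying clones → **NEC** (the restricted-repertoire guard)
4. $p_1 + p_2 < 10B$ → **NEC**
5. $p_1 + p_2 \ge$ 2.5% (FR) / 5% (IGK, T assays) → **CLONAL**, else **NEC**

A case is lineage-clonal if *any* assay of that lineage is clonal. The
comparator models (`invivoscribe` 2.5%/10× vs the rank-3 clone;
`msk` 2.5%/10× above 100k reads, 5%/20× below, with an OLIGOCLONAL
category; `nollet_schumaker` 4%/4.5× vs the first two-fold frequency drop,
plus a modified 20k-read variant) share the same interface. Around the
callers sit near-duplicate clonotype merging (top 10 absorb within the top
500 at ≤ 2 mismatches; the MSK dialect uses ≤ 4), run/control QC gating, a
diagnostic-accuracy evaluator, and a seedable Dirichlet–multinomial
simulator with known ground truth.

## Worked example

Simulate a biclonal TRG sample (two dominant clones at 25% and 20% with a
1–2-mismatch satellite each, over a 500-clone polyclonal background),
merge, and call:

```r
library(clonocall)
sp  <- synthetic_spec("biclonal", seed = 7, near_duplicate_rate = 1)
g   <- generate_sample(sp, "case042", "TRG")
tbl <- merge_top_clones(g$table, merge_policy())
call_clonality(tbl, model_config("roswell_park"))
#> <assay_call> case042 TRG [roswell_park] CLONAL (rule: step5)
#>   dominant %: 24.9, 20
#>   background %: 0.24
```

The satellites were absorbed (the top two records end with
`merged_member_count = 2`), the top-two sum 44.9% misses the 50% T-cell
bypass, the background is defined (median 0.24% over the qualifying clones
ranked 3–10), the 10× ratio and the 5% threshold hold, so step 5 calls the
sample clonal — and `fired_rule` records exactly that step.

Accuracy arithmetic against gold-standard labels:

```r
compute_metrics(list(tp = 17, tn = 8, fp = 2, fn = 1))
#> sensitivity 94.4%  specificity 80.0%  PPV 89.5%  NPV 88.9%
```

End-to-end runs — Q30/control gating, per-assay calling, case aggregation,
JSON reports — go through `run_pipeline()` or the thin CLI in
`inst/cli/clonocall.R` (`call`, `call-case`, `qc`, `simulate`, `evaluate`).

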