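---
title: "Methods: molecular diagnosis of familial hypercholesterolemia with fhdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular diagnosis of familial hypercholesterolemia with fhdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhdx)
library(dplyr)
```

`fhdx` models the diagnostic workup of familial hypercholesterolemia (FH)
cohorts: clinical scoring, rare-variant interpretation from targeted
sequencing panels of lipid-metabolism genes, exon-dosage analysis for
larger *LDLR* rearrangements, and cascade screening of relatives. This
vignette explains the models and procedures, the tunable parameters, the
synthetic-data generator, and the numerical and design choices — it is the
package's methods reference.

## The DLCN clinical score

The Dutch Lipid Clinic Network criteria fall into five groups: family
history, personal clinical history, physical examination, measured LDL-C,
and DNA evidence. `score_dlcn()` computes, per subject, each group's
subscore as the **maximum** of the points of the satisfied criteria in
that group — a subject with both tendon xanthomata (6) and premature arcus
cornealis (4) scores 6 in the physical group, not 10 — and the total as
the sum over the five groups. The within-group maximum is the standard
reading of the criteria; `fh_default_config(dlcn = list(aggregate =
"sum"))` switches to a sum for sensitivity analysis.

The point table (see `?fh_default_config`) ships as configuration data,
not code, because the criteria themselves are defined by external
consensus documents and groups occasionally use local variants: family
premature CVD 1, relative's LDL-C above the sex/age 95th percentile 1,
relative with xanthoma/arcus 2, child above the 95th percentile 2;
premature coronary disease 2, premature cerebral/peripheral disease 1;
tendon xanthomata 6, arcus before 45 years 4; LDL-C ≥ 8.5 mmol/L 8,
6.5–8.4 5, 5.0–6.4 3, 4.0–4.9 1; functional DNA mutation 8. An *untested*
DNA result contributes 0 so that pre- and post-genetic scores are both
computable — whether a cohort's reported bands included the DNA criterion
is often ambiguous, so both modes are supported and neither is asserted.

Totals are banded as unlikely (< 3), possible (3–5), probable (6–8) and
definite (> 8). `load_config()` rejects band configurations that overlap
or leave gaps, so `classify_band()` is a total function on the score
axis.

Two supporting calculations:

* `compute_friedewald_ldl()` estimates LDL-C as `TC − HDL-C − TG/2.2`
  (all mmol/L; 2.2 is the mmol/L form of the triglyceride divisor). The
  formula is unreliable at high triglycerides, so TG > 4.5 mmol/L is an
  error, and estimates above 4.5 mmol/L are *flagged* `direct_required`
  rather than rejected — software can recommend, but not perform, a
  direct measurement.
* `exceeds_95th_percentile()` compares LDL-C against a sex- and age-band
  95th-percentile table with a **strict** inequality: "exceeds the 95th
  percentile" reads naturally as strictly greater, so a tie does not
  score. The packaged table (`fh_default_p95_table()`) is synthetic and
  labelled non-clinical — real percentile tables are population-specific
  and must be supplied via configuration for clinical use.

## Rare-variant filtering

`apply_filter_cascade()` consumes an annotated variant table (one row per
variant and alt allele; multi-allelic sites must be split upstream) and
applies ordered steps:

1. **Rarity.** A record is removed when its maximum allele frequency
   across all `af_*` sources reaches `rare_af_threshold`. The maximum
   (a popmax-like statistic) is deliberately conservative against
   population-specific common alleles. A variant absent from every source
   is treated as frequency 0 — a never-observed allele must pass, since
   novel variants are the most interesting candidates. The default
   threshold 0.005 was chosen so that every clinically reported rare
   allele in the embedded reference spectrum (maximum printed MAF
   0.002244) passes while common polymorphisms (MAF ≥ 1%) fail; it is
   config-overridable.
2. **Clinical assertion.** Records asserted benign or likely benign are
   removed (`excluded_assertions`).
3. **Predictor consensus.** Survivors are tagged `damaging`,
   `benign_leaning` or `indeterminate` by `predictor_consensus()`. A
   record is damaging when the fraction of damaging calls among reporting
   tools reaches `predictor_damaging_fraction` (default 0.5) *and* at
   least one conservation tool places it at or above the
   `conservation_percentile_threshold` (default 0.7) within a reference
   score distribution. The percentile uses strict comparison with midrank
   ties (`conservation_percentile()`). Crucially, the consensus **never
   removes a record**: in-silico predictors are a supplementary signal,
   and the tag only feeds prioritization and the PP3/BP4 evidence codes.

The reference distribution for the conservation percentile is an explicit
argument (defaulting to the filtered table itself, i.e. a panel-wide
reference), because the appropriate comparison set — panel-wide or
genome-wide — is a study-level choice the package cannot make.

Every removed record is logged with its removing step; `tidy()` on the
report returns the audit trail and the per-step counts are weakly
decreasing by construction. `prioritize_candidates()` orders survivors
into review tiers: asserted pathogenic/likely-pathogenic first, then
records at positions carrying a described pathogenic allele (same
chromosome, position and reference allele — the alternate may differ,
which is exactly the situation where a new substitution at a known
disease residue deserves early review), then novel records with damaging
consensus, then the rest, stably by position.

## The ACMG/AMP evidence engine

`classify_acmg()` combines coded evidence items into the five classes.
The combining rules are shipped as a **data table**
(`acmg_rule_table()`), each row the minimum number of codes per strength
category for one rule; this makes the engine testable against an
independent enumeration oracle and lets users amend rules without
touching code. Classification depends only on the per-category counts; no
strength modulation (upgrading/downgrading of individual codes) is
supported — per-code strength is fixed by its category. If combinations
on both the pathogenic and the benign side fire, the result is uncertain
significance with rationale "conflicting"; if neither side fires,
"insufficient". PVS1 alone, with nothing else, is not classifiable under
the encoded combinations and yields uncertain significance.

`auto_evidence()` assigns only the mechanically computable codes:

* BA1 when the maximum observed frequency exceeds 0.05; PM2 when the
  variant is absent everywhere or below the ultra-rare threshold 1e-4
  (both overridable).
* PP3/BP4 from the predictor consensus.
* PS1 (same amino-acid change as a known pathogenic entry via a different
  nucleotide change) and PM5 (different missense at a residue with a
  known pathogenic missense), parsed from three-letter `p.` notation.
  The two are mutually exclusive at a residue — one observation must not
  be counted twice — and only the stronger applies.
* PVS1 only from an explicit `null_variant` flag on the record. The
  package auto-flags nothing here by position: splice variants outside
  the canonical ±1/2 dinucleotides (e.g. a +5 substitution that may still
  disrupt a donor site) require expert judgement, so the flag is the
  user's decision.

All other codes (functional data, segregation, de novo status, …) require
evidence the annotation table cannot contain and must be supplied
manually.

## MLPA dosage quotients

`normalize_run()` converts raw probe peak intensities into dosage
quotients in two stages: each probe peak is divided by the mean of the
*reference-probe* peaks within its sample (cancelling per-sample scale:
DNA input, PCR efficiency, injection), then by the median of those
intra-sample ratios across the *control* samples for that probe
(cancelling per-probe efficiency). The mean is used within samples,
matching common kit practice, and the median across controls for
robustness to one aberrant control. A DQ of 1 indicates two copies, ~0.5
a heterozygous deletion, ~1.5 a heterozygous duplication.

`call_exon_events()` applies thresholds — deletion below 0.7, duplication
above 1.3, homozygous deletion flagged below 0.25; all standard MLPA
practice and overridable — and merges adjacent non-normal probes in exon
order into single events, allowing single-probe events. Deletions are
named by `format_deletion_hgvs()` in the uncertain-breakpoint coding-DNA
style: deleting exons *a..b* with flanking cDNA ends *x* (end of exon
*a−1*) and *z* (end of exon *b*) gives
`c.(x+1_(x+1)-1)_(z+1_(z+1)-1)del`, i.e. breakpoints placed in the
flanking introns. The packaged `ldlr_exon_boundaries()` table is
deliberately partial (exons 1, 10, 14, 15 of NM_000527.4) — sufficient
for the two reference deletions (exons 2–10 and exon 15); complete
transcript tables are user-supplied configuration.

One documented ambiguity: ratio-chart figure captions sometimes quote a
"ratio of ~1.5" for a heterozygous deletion while simultaneously
describing deletion dots as falling *below* the lower reference curve.
The package follows the dosage arithmetic: a heterozygous deletion halves
the probe dose (DQ ≈ 0.5), and a reduced ratio is called a deletion.

## Cascade screening and cohort summaries

`propose_cascade()` builds testing waves: wave 1 holds the untested
first-degree relatives (parents, children, and siblings sharing at least
one recorded parent — half and full siblings are not distinguished, as
the pedigrees here are small) of the proband; each later wave holds the
untested first-degree relatives of individuals known positive in the
previous ring. Relatives already tested are not re-proposed, but a known
positive relative *does* seed the next wave — that is how a positive
sibling pulls the sibling's child into wave 2.

`simulate_transmission()` is plain Mendelian gene dropping: each parent
transmits each carried allele independently with probability 1/2, founders
have specified carrier states, a missing parent is a non-carrier. One
heterozygous parent gives a carrier probability of 1/2 per child, two give
3/4.

`summarize_cohort()` and `crosstab_dlcn_by_result()` produce the
detection-yield tables: subject-level yield, the per-gene split among
variant-positive probands (reported per gene and grouped LDLR / APOB /
other), the yield among children of probands, and per-DLCN-band
breakdowns. A subject is variant-positive when their genetic status is
positive; compound heterozygotes count **once** in all subject-level
denominators. Percentages are rounded **half-up to one decimal**
(`round_half_up()`), matching clinical reporting convention rather than
R's banker's rounding, and a zero denominator yields `NA` with an
explanatory flag — an undefined percentage must not masquerade as 0.

## Synthetic data and the reference fixture

`gen_cohort()` emulates the statistical structure of an FH referral
cohort. Defaults (`fh_sim_params()`): 60 probands, ~14 children in total
(Poisson, rate 14/60), proband molecular yield 26/60, 41% on
lipid-lowering therapy, 42% with tendon xanthomata. Lipids: total
cholesterol 8.6 ± 3.4 mmol/L and HDL-C 1.4 ± 0.4 mmol/L as truncated
normals with symmetric ±2.5 SD bounds — symmetric truncation preserves
the stated mean exactly (the SD shrinks by the truncation factor ≈ 0.95,
a documented trade-off for guaranteed positivity); triglycerides are
log-normal with the meanlog/sdlog solved from the arithmetic moments
1.8 ± 1.4 mmol/L, reflecting the right-skew of TG distributions. LDL-C is
derived by the Friedewald formula where valid, otherwise flagged as a
direct measurement. Carriers receive a +3 mmol/L total-cholesterol shift
(a generator-only assumption sized to make carrier status visible against
the phenotype-selected background; compound heterozygotes in the fixture
motivate the large upper tail). Because the shift is applied after
sampling, the Table-style lipid moments are recovered exactly only at
shift 0; the moment-recovery test therefore runs at shift 0 and a
separate test checks that the configured shift is visible under defaults.
Children's genotypes come from `simulate_transmission()` over the
generated pedigrees. All randomness flows from a single integer seed;
equal seeds give byte-identical outputs.

`gen_annotation_table()` embeds the 20-record reference variant spectrum
(`table2_variants()` — positions, alleles, allele frequencies and
clinical assertions as printed in the source material, with *synthetic*
`pred_*`/`cons_*` columns standing in for per-tool annotations, since the
annotation tools themselves are not run) plus common background variants
(AF 0.01–0.5) and rare benign/likely-benign decoys. By construction the
default filter cascade retains exactly the embedded spectrum: backgrounds
fail rarity, decoys fail rarity or assertion.

`build_paper_fixture()` is fully deterministic and encodes a cohort whose
*aggregate* counts equal the published ones: 80 subjects (60 probands, 14
children, 6 other first-degree relatives), bands 34/5/41, 26 positive
probands split 19/3/4 (LDLR/APOB/other), 12 of 14 children positive, the
definite band 26 LDLR + 3 APOB + 5 negative, and two compound-heterozygous
probands scoring DLCN 18. The published component counts (26 probands +
12 children + 1 other relative = 39) slightly exceed the published
subject-level yield (47.5% of 80 = 38); the fixture resolves this by
encoding 38 positives (the other relatives negative) so that all reported
percentages are simultaneously consistent. Per-subject lipid values are
synthetic (only aggregates were published) and are excluded from
acceptance checks.

## What the tests do and do not show

The test suite checks, among others: exact recovery of the published
aggregate percentages from the deterministic fixture; exact zero-noise
MLPA dosage algebra and the two reference deletion names; MLPA event-level
sensitivity and specificity ≥ 0.99 on 200 simulated samples with 30
heterozygous-deletion events under multiplicative log-normal noise
(sd 0.05) — heterozygous deletions sit ~5.7 noise SDs from the calling
threshold, duplications only ~2.4, so exact-span duplication recovery
under noise is *not* claimed at this bound; exhaustive agreement of the
evidence engine with an independently hand-coded decision procedure over
the bounded evidence grid (7 680 count vectors); filter-cascade closure
on generated tables; DLCN property suites (sum-of-group-maxima,
monotonicity, exhaustive band partition at 10⁴ random inputs); and
Mendelian carrier-fraction recovery within 3 standard errors at 10⁴
offspring.

What passing does **not** show: the generator reproduces marginal
distributions and Mendelian segregation, not linkage structure, assay
artefacts (incomplete digestion, probe cross-hybridization, GC effects),
population stratification of allele frequencies, or real per-tool
predictor behaviour — its `pred_*`/`cons_*` columns are synthetic.
Conclusions about real cohorts require real annotation sources, real
percentile tables, and laboratory validation of MLPA findings.

## Known limitations

* The 95th-percentile table and the predictor/conservation columns of the
  embedded spectrum are synthetic placeholders, clearly labelled.
* The evidence engine implements the category-count combining rules only:
  no gene-specific rule specifications and no Bayesian point-based
  reformulation.
* Splice-effect prediction is out of scope; splice variants outside the
  canonical dinucleotides must be null-flagged manually for PVS1.
* Pedigree handling targets small clinical families; the cascade planner
  does not model consanguinity loops beyond what acyclic parentage
  allows.
* Problem sizes in tests (10⁴ scoring inputs, 10⁴ offspring, 200 MLPA
  samples) were chosen as the smallest sizes at which the statistical
  bounds are sharp; they run in seconds.
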