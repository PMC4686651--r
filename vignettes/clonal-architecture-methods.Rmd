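---
title: "Models and methods for clonal-architecture inference in MDS-RS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for clonal-architecture inference in MDS-RS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonarch)
```

## The problem

Myelodysplastic syndromes with ring sideroblasts (MDS-RS) are typically
founded by a heterozygous `SF3B1` mutation arising in a rare
haematopoietic stem cell and propagated through the progenitor hierarchy
(MPP, GMP, MEP). Further lesions — `DNMT3A`, `JAK2`, `TET2` and others —
define subclones nested inside the founding clone, sometimes mutually
exclusive branches. The observable data are read counts: bulk allele
counts from sorted compartments, xenograft-derived human engrafted cells
(HEC) and long-term cultures (LTC); per-colony amplicon counts from
single-cell clonogenic assays; and germline SNP allele fractions for
loss-of-heterozygosity (LOH) scanning. This vignette documents the models
behind each stage, the tunable parameters, and the design decisions taken
where the procedure was genuinely open.

## Mutant allele burden and cellular prevalence

The mutant allele burden (MAB) of a variant is the fraction of reads at
its locus carrying the mutant allele, `alt / total`. Read counts are
modelled binomially, so `mab_from_counts()` attaches a Wilson score
interval (default level 95 %); the Wilson form is preferred over the Wald
interval because counts near the detection floor are small and skewed.

Replicates (independent PCR and sequencing experiments) are pooled by the
**unweighted mean of replicate MABs**, not by pooling reads: the replicate
is the unit of independent evidence, and averaging keeps a high-depth
replicate from dominating. Read-weighted pooling remains available via
`pool_mab(..., weight_by_reads = TRUE)`. With three or more replicates the
CI comes from the replicate spread (t interval); with fewer, from the
Wilson interval on pooled counts.

For a heterozygous mutation, the fraction of cells carrying it is twice
the MAB: `cellular_prevalence()` returns `min(2·MAB, 1)` and flags
over-unity values (2·MAB > 1), which indicate LOH or copy-number change
rather than a computational error. No copy-number-aware correction is
attempted beyond this flag.

The detection floor is `max(floor, min_alt_reads / coverage)` with
`floor = 0.01` calibrated at the 800× reference amplicon coverage: 1 % MAB
is the smallest burden reliably distinguishable from noise at that depth.
The floor is monotone non-increasing in coverage and binds from above at
high depth — deeper sequencing does not push the floor below 1 % because
the floor also absorbs non-counting noise (PCR and context errors).

## The somatic filter cascade

`filter_cascade()` applies four stages in order; a record passes iff no
rule fires, and every verdict lists the rules that fired.

1. **Read-level filters.** Mean alignment score < 10, mean base quality
   < 15, or fold strand bias > 10. *Fold strand bias* has no universal
   definition; here it is `max(fwd, rev) / max(1, min(fwd, rev))` over
   per-strand alt counts — simple, symmetric, and on the same scale as the
   "> 10" operating point. The clamp at 1 keeps single-strand signals
   finite.
2. **Somatic filters.** Two-sided Fisher's exact test of tumour alt/ref
   vs normal alt/ref (p < 0.01, computed by direct hypergeometric
   enumeration in `fisher_somatic_test()`); ≥ 3 supporting reads; normal
   alt fraction < 20 % for skin-paired normals or < 50 % for T-cell-paired
   normals; tumour burden > 5 %; population-known variants with allele
   frequency > 0.001 fail; genomic-duplicated-region records fail unless
   flagged as known mutations. All comparisons use exactly the printed
   strict/non-strict direction, so boundary values (p = 0.01, 2 reads,
   burden = 5 %, normal = 20 %) fail. The normal-contamination rule is
   exposed as two thresholds because the conventional phrasing of the rule
   mixes the skin and T-cell clauses; both are configurable in
   `filter_config()`.
3. **WGA artifact filters** (WGA-flagged records only). Whole-genome
   amplification of minute DNA inputs creates spurious variants enriched
   in homopolymer context and with positional bias. A record fails when a
   single-base run of ≥ 5 touches the variant from either flank (runs
   interrupted by the variant base are not joined), when the variant was
   seen in control WGA experiments, or when precomputed positional /
   read-length-distribution bias flags are set. The bias metrics are
   consumed as input flags, not recomputed: raw reads are out of scope and
   no formula for them is standard.
4. **HEC concordance** (xenograft records). A candidate mutation passes
   when detected in more than one HEC sample, or in an HEC experiment plus
   an LTC or primary CD34+ sample; with WGA-derived HEC data it may
   instead pass via WGA HEC + independent non-WGA HEC, repeat WGA samples
   of one engraftment, or WGA HEC + non-WGA support. For WGA-heavy series
   across three animals (`mds3_like = TRUE`), detection in ≥ 2 of the 3
   animals is additionally required.

Tightening any single threshold can only shrink the passed set
(monotonicity); verdicts depend only on the record and its evidence, not
on batch order. Both properties are tested.

## Colony genotyping and the clone tree

A colony grown from a single founder cell is genotyped per mutation:
**mutant** when strictly more than 30 % of reads carry the mutant allele,
**nocall** when depth is below `min_colony_depth`, **wildtype** otherwise.
The 30 % cut sits between the sequencing-error regime (≈ 0) and the
heterozygous expectation (50 %), so the per-entry miscall probability at
depth *d* is the binomial tail below 0.3·*d* — about 5.8 % at depth 20 and
negligible at amplicon depths. `min_colony_depth = 20` is this package's
own guard: the published rule gives no depth floor, but a 0/0 entry must
not be called wildtype. Mutant-colony percentages are rounded half-up to
integers, matching the reporting granularity of published screens, and
nocall entries leave the denominator.

Subclones are the distinct non-empty genotype signatures. Under the
infinite-sites assumption with a known wild-type ancestral state, the
matrix is compatible with a clone tree iff no mutation pair shows all
three patterns {10, 01, 11} across colonies (the directed three-gamete
test). `infer_clone_tree()` then orders signatures by strict set
containment: each clone's parent is its unique maximal observed proper
subset (uniqueness is guaranteed by compatibility and asserted), edge
labels are set differences, and containment-incomparable signatures become
sibling branches — e.g. `JAK2`-bearing and `DNMT3A`-bearing subclones
under a shared `SF3B1` founder. Unobserved intermediate clones are **not**
invented: an edge may gain several mutations, which is exactly what colony
data can support. Colonies containing any nocall are excluded from tree
inference by default because a nocall could flip a containment relation;
`nocall = "as_wildtype"` is available for sparse panels.

The founder set consists of mutations mutant in every mutant colony;
mutual exclusivity requires each mutation in ≥ 2 colonies (singletons are
too weak to declare a branch). The bulk-only hierarchy `mab_hierarchy()`
orders mutations by prevalence only when their CIs separate — a heuristic
mirror of burden-based ancestry arguments, deliberately not a formal test,
leaving similar burdens unordered.

## Clonal dynamics

`classify_mab_change()` partitions every (primary, follow-up) MAB pair
into five exhaustive categories. `not_detected` fires first (follow-up
below the 1 % floor, identified with "background noise"); then `same`
(absolute change ≤ 0.05 — an absolute tolerance, because burdens of 43 %
vs 46 % are biologically unchanged while a ratio rule would misread small
burdens); then fold = follow-up / max(primary, floor) with the ≥ 2-fold
classes taking the boundary and `changed_lt2fold` in between. Clamping the
primary at the floor keeps fold changes of emergent clones finite. The
published colour legend overlaps at exactly 2-fold and does not state
whether the < 2-fold class is directional; this 5-category scheme is a
documented interpretation, and its boundaries are config values. The
scheme is scale-consistent: shrinking both burdens by a common factor
never flips growth into shrinkage.

Shift significance uses the exact Fisher test on the two alt/ref count
pairs, or a two-tailed t-test when replicate MAB vectors are available.
`recapitulation_score()` reports the fraction of panel mutations with
identical categories in two comparisons (e.g. xenograft vs sequential
patient sample) plus a direction-only concordance, where `not_detected`
counts as a loss. `infer_acquisition_order()` ranks lesions by first
detection time, breaking same-time ties only where prevalence CIs
separate.

## LOH segmentation

Informative SNPs are population-known, non-somatic, outside duplicated
regions, at depth ≥ 20, and heterozygous in the paired normal (normal
fraction in [0.25, 0.75]). The selection keeps *known polymorphisms*: the
filter's purpose is an allele-balance scan, which only heterozygous
germline SNPs can power.

`detect_loh_segments()` slides a window of `w = 25` SNPs; a window is
shifted when its mean |fraction − 0.5| exceeds `δ = 0.15`, and runs of at
least `min_consecutive = 1` shifted windows form segments (one full
25-SNP window beyond δ is already strong evidence; the parameter exists
for stricter use). Because windows overlapping a deletion edge drag in
balanced flanking SNPs, segments are trimmed to SNPs whose own deviation
clears δ — on noise-free deletions this recovers boundaries exactly, and
the affected-fraction estimator `f = 2d/(0.5 + d)` then inverts the
forward model `d = f/(2(2 − f))` of a heterozygous deletion exactly. The
window/threshold design was chosen over an HMM or changepoint model for
transparency: all three parameters are visible, and the method's floor is
explicit — a deletion carried by 7 % of cells deviates by only ≈ 0.018,
far below δ, and is correctly not called (subclonal LOH at that level is
a targeted-assay question, not a WES-scan one). Coordinates are 1-based
inclusive; BED export converts to 0-based half-open.

## The simulator: what it emulates and what it does not

The generator produces the statistical structure the analysis assumes:

- a clone tree grown one mutation per edge (infinite sites), linear at
  branching probability 0;
- per-compartment clone fractions from gamma weights with multiplicative
  log-normal drift (drift 0 ⇒ identical compartments, emulating burdens
  maintained from HSCs to progenitors);
- bulk counts `Binomial(coverage, p)` with
  `p = m(1−e) + (1−m)e`, where `m` is half the summed fraction of clones
  carrying the mutation and `e` the symmetric per-read error rate;
- colony founders drawn i.i.d. from clone fractions (no plating bias —
  none is documented), all cells sharing the founder genotype;
- WGA artifacts: spurious records at a per-record rate (half with
  homopolymer flanks, a configurable fraction with bias flags) and allele
  dropout zeroing alt or ref reads.

Defaults are the study's conditions where stated — coverage 800, the
thresholds of `filter_config()` — and field-realistic choices where not:
per-base error 0.001 (Illumina substitution-error scale), WGA artifact
rate 0.02 and dropout 0.05 per record (single-cell WGA scale). The error
and WGA magnitudes are documented placeholders, not published values.

Ground-truth labels (true MAB, artifact and dropout flags, colony
founders) travel in a side-channel attribute that no analysis function
reads, preventing leakage. All randomness flows from one seed through
named per-stage streams, so identical seed and config give byte-identical
output at every stage, including partial pipelines.

What the simulator does **not** emulate: raw reads, alignment and capture
artifacts, indels, PCR duplicates, plating bias, doublet colonies,
copy-number changes coupled to point-mutation burdens, and correlated
(context-specific) sequencing error. Passing tests therefore demonstrate
correctness of the inference rules under the stated statistical model,
not robustness to every artifact of real libraries.

## Numerical choices and degenerate inputs

- `fisher_somatic_test()` enumerates the hypergeometric support directly
  and sums probabilities ≤ the observed one with a `1 + 1e-7` relative
  guard against floating-point ties; an all-zero table returns 1 with a
  warning.
- Percent rounding is half-up (`floor(100f + 0.5)`), not banker's.
- Zero evaluable colonies, empty compartment lists, zero totals, missing
  paired normals and missing flanks raise informative errors; batch
  processing records per-record errors in the verdict log instead of
  aborting.
- Validation problem sizes: the Fisher oracle check runs exhaustively
  over all 2×2 tables with both margins ≤ 14 plus 2,000 random tables
  with margins ≤ 50; the three-gamete oracle over 1,000 random matrices
  up to 12 × 6; parameter recovery over 1,000 seeded runs at 800×;
  round-trip tree recovery with 400–500 colonies so every clone is
  sampled with near certainty.

## Known limitations

- No probabilistic phylogeny: genotype calls are hard, and no likelihood
  over error rates is optimised. At amplicon depths the miscall rate is
  negligible; at low depth, nocall exclusion is the safety valve.
- The heterozygous doubling rule is the only prevalence model; CNV-aware
  correction is out of scope, flagged via over-unity prevalence.
- LOH segmentation does not distinguish deletion from copy-neutral LOH
  and has the stated subclonal floor.
- The colony-based tree sees only sampled clones: subclones below
  ~1/n_colonies frequency are invisible, with probability ≈ (1−f)^n
  quantified and tested.
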