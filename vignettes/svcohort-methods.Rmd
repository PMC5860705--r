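---
title: "Consensus SV calling and cohort analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus SV calling and cohort analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svcohort)
library(dplyr)
```

## The problem

Short-read resequencing of livestock cohorts yields structural variants
(SVs) — deletions, insertions, tandem duplications and inversions of
50 bp and more — from read-pair and split-read callers whose raw output
is noisy: breakpoints jitter by a few bases between programs, and each
program produces false positives the other does not. A widely used
remedy is *program intersection*: run two independent callers per
animal, keep only variants both report, then merge the per-animal
consensus calls across the cohort into a non-redundant population call
set restricted to variants seen in at least two individuals. svcohort
implements that design end to end for a cohort structured as breeds
nested in population groups (its defaults mirror a pig cohort of
Guizhou indigenous breeds compared with other Chinese and European
pigs), together with the downstream analyses such call sets feed:
group/breed-specific variant sets, PCA of the carrier matrix, gene
consequence classification, conserved-gene depletion testing,
SV-density hotspot scanning, and marker diversity statistics.

## Coordinates and the call model

All intervals are 0-based half-open, so `length = end - start` for
deletions, duplications and inversions; published per-variant tables
that satisfy exactly this identity round-trip unchanged (the
`gzp_candidate_svs()` reference table is the worked example: its
`GZsv12513` row gives 20311590 − 20311318 = 272 bp). Insertions are
stored as zero-width breakpoints (`start == end`) carrying the inserted
length explicitly, because read-pair callers report an insertion as a
point plus an estimated length, not a reference interval. Records
shorter than 50 bp — the conventional lower bound of the SV size
class — or with unknown type codes (translocations are deliberately
unsupported) are rejected at ingest and tallied per reason; nothing is
silently repaired. Chromosome names are normalized (leading `chr`
stripped, case folded) because cohort inputs mix sources.

## The merge rule

Two calls merge when they are on the same chromosome, of the same type,
and overlap by at least 25 bp. Two readings of "more than 25 bp" are
possible; the laxer `>= 25` is used and the threshold is a parameter
(`min_overlap`). No reciprocal-overlap fraction is imposed — the rule
is an absolute base-pair count, which is what SVmerge-style pipelines
apply. Because insertions are zero-width, the bp rule cannot bind them;
a 25 bp breakpoint-distance window (`ins_window`) substitutes,
preserving the spirit of the rule. Merging is *single linkage*: the
transitive closure of the pairwise relation, so chains of overlapping
calls collapse into one cluster even when the chain's ends do not
overlap each other. `cluster_calls()` computes this with a
chromosome/type-partitioned start-sorted sweep over a union–find
structure; the test suite proves it equal to brute-force all-pairs
closure on hundreds of random call sets and invariant to input order.

A merged record spans the union of its members (minimum start, maximum
end); the source design never states representative coordinates, and
the union is the deterministic, conservative choice. For insertion
clusters the smallest member breakpoint and largest member length are
kept.

Within a sample, raw calls are first filtered to `support >= 3`
read pairs and chromosome Y is excluded (sex-composition effect); the
support filter is applied per raw call, before merging, since the order
is not otherwise specified. A cluster becomes a consensus SV only if
every required caller contributes at least one member. Across samples,
the same rule merges consensus calls, and a cluster enters the
population call set only when its members come from `min_individuals`
(default 2) *distinct* animals — a sample contributing two calls to one
cluster counts once. Population SVs get zero-padded serial ids in
(chromosome, start) order, and per-SV breed/group membership is derived
from carriers through the sample sheet: a variant is "present in" a
breed when at least one carrier belongs to it, and breed-specific when
present in no other breed. Carrier absence means "not called"; no
re-genotyping of non-carriers is attempted, matching how such call sets
are reported.

## Cohort comparison

`build_presence_matrix()` produces the samples × SVs binary carrier
matrix. Venn partitions and specific sets are exact set algebra over
the per-label SV sets. PCA is the column-mean-centred singular value
decomposition of this binary matrix, without unit-variance scaling:
presence data are already on one scale, and scaling would blow up rare
variants. (Whether the original analyses used presence, genotypes or
dosages is not recorded anywhere; binary presence is the defensible
default for carrier-only call sets.) Variance explained is each squared
singular value over total variance, and each component's sign is fixed
by making its largest-magnitude loading positive so results are
reproducible across linear-algebra backends. A constant matrix returns
zero coordinates and zero variance rather than an error.

## Annotation

`classify_sv()` assigns each SV a consequence per overlapped gene with
precedence exonic (CDS overlap) > UTR > intronic; an SV overlapping no
gene but within `flank_bp` (default 5000, the usual regulatory-flank
default of consequence predictors — the source pipeline used such a
predictor but printed no window) is upstream or downstream by gene
strand; anything else is intergenic. Any single shared base pair counts
as gene overlap, since no minimum is stated anywhere. An SV touching
coding exon or UTR sequence is flagged loss-of-function; that
definition is reverse-engineered from the way published LoF counts
decompose into exon plus UTR variants. Per-SV summaries count each
variant once at its highest-precedence class, so class fractions
partition the call set.

The conserved-gene depletion test is a Pearson chi-square without
continuity correction on the 2×2 table of conservation status × SV
status, with the p-value from the df-1 chi-square distribution; on the
published marginals (437 conserved genes, 112 with SV; 25,880 genes,
7,881 with SV) it reproduces the printed χ² = 4.88, p = 0.027, which is
also the acceptance check. The SV–transcript association is a Spearman
rank correlation with average ranks for ties and a two-sided p-value
from the t approximation on n − 2 degrees of freedom. The published
ρ = 0.231 was computed on an unstated gene subset and is therefore not
a reproduction target; the operation is validated against the rank
formula instead.

### Hotspot scanning

No published criterion defines the reported X-chromosome hotspot, so
the package defines one and exposes every knob: tile each chromosome
with 1 Mb windows stepped by 0.5 Mb, count SV starts per window,
z-score each count against the genome-wide mean and standard deviation
of window counts, call windows with z ≥ 3 significant, and merge
overlapping significant windows into maximal hotspot intervals. One
known limitation is masking: when an enriched region occupies a large
fraction of the scanned genome it inflates the global mean and spread
and can hide itself. The validation therefore plants a 5 Mb, 10×
enrichment on a 100 Mb toy chromosome (5% of the genome), where the
scan recovers the full planted interval, and runs the null on the
40 Mb default genome at ~100 SVs per window, where false positives are
absent in almost all seeds; the suite requires a clean null in at
least 95% of 20 seeds, matching the normal tail at this window count.

## Diversity statistics

For a biallelic insertion/deletion marker scored as II/ID/DD counts,
allele frequencies come from gene counting, and per-locus statistics
use the classical definitions: homozygosity `Ho = Σp²`, expected
heterozygosity `He = 1 − Ho`, effective allele number `Ne = 1/Σp²`, and
Botstein's polymorphism information content
`PIC = 1 − Σp² − Σ_{i<j} 2p_i²p_j²`. The identities `Ho + He = 1`,
`PIC ≤ He` and `1 ≤ Ne ≤ k` are enforced as property tests over
thousands of random frequency vectors. Between-population genotype
comparisons use a Pearson chi-square on the 2×c genotype table,
dropping classes absent from both populations, with a Fisher exact
fallback on the DD-versus-rest collapse whenever an expected cell falls
below 5; the output records which path ran, since the original
significance claims name no test.

## The simulator

`sim_config()` freezes the study conditions every stochastic validation
runs under. The defaults emulate the cohort the pipeline targets:

* genome: three autosomes plus an X of 10 Mb each (40 Mb) — large
  enough that independent false positives essentially never collide,
  small enough for fast tests;
* 2,000 truth SVs weighted 84/8/7/1% DEL/INS/DUP/INV, with per-type
  length-bin weights matching the published call set's bins
  (log-uniform within bins); insertions draw 50–132 bp, the published
  insertion length range;
* three groups × two breeds × three samples; shared SVs carried with
  probability 0.3 per sample, 15% of SVs group-specific and 5%
  breed-specific (carried with probability 0.5 within their label) —
  chosen so specific sets are populated at test scale while shared
  variants dominate, as in real cohorts;
* two callers, each detecting a carrier's SV with probability 0.9,
  jittering both breakpoints independently by ±10 bp, adding 1 false
  positive per Mb per sample, and reporting support as 1 + Poisson(5).

Jitter is capped at ±10 bp by design: it keeps every ≥50 bp truth SV
mergeable between callers (worst-case shared span `L − 20 ≥ 25` bp
once `L ≥ 45`), so merge-rule correctness is testable separately from
breakpoint-sensitivity stress. False positives are caller-independent,
which is precisely the property the two-caller design exploits: the
validation measures their survival into the population call set and
expects zero.

Truth bookkeeping flows through the pipeline: simulated calls carry
their truth id, consensus and population records accumulate the ids of
their members, and `expected_recall()` turns the caller model into an
analytic yardstick — per caller, a carrier's call survives with
probability `detection × P(support ≥ 3) × P(jittered length ≥ 50)`
(the last term is exact, from the triangular distribution of the
difference of two uniform jitters); a sample succeeds when both callers
do; a truth SV is recoverable when at least two carriers succeed. The
measured count of truth SVs whose two-caller detections survive in two
or more samples is required to sit within three binomial standard
deviations of this expectation, and the merged call set must contain
every one of them. What the simulator does *not* model — read-level
noise, breakpoint-dependent caller biases, correlated false positives
from shared repeat structure, genotyping of non-carriers — bounds what
passing tests say about real data: they certify the merge/threshold
logic and the statistics, not caller behaviour on real reads.

Genotype tables are sampled under Hardy–Weinberg at configurable true
allele frequencies (defaults: 6 markers × 8 populations of 24–48
animals, 284 in total, the size of a typical PCR validation panel).
Toy gene models place non-overlapping genes with short exons on a
coarse grid so introns dominate genic space, 1–10 transcripts per gene,
and CDS plus flanking UTR pieces carved from the exon chain; they
round-trip through the package's GFF3 writer and reader.

## Numerical and interface choices

* Every generator derives its stream deterministically from one seed;
  reruns are byte-identical, which the pipeline tests assert on the
  written call-set files.
* Length bins are closed at their upper bounds (50–1000, 1001–10000,
  10001–100000 bp, plus an overflow bin), reproducing the published
  bin naming; boundaries are parameters.
* Covered length is reported both as the sum of SV lengths and as the
  union of reference intervals (insertions count in sums only). The
  two disagree in published totals (27.37 Mb quoted against ~27.78 Mb
  of summed bins), so neither is silently preferred.
* Writers emit a total order — chromosomes numerically, then X, then
  start, then id — so diffs are meaningful.
* The orchestration layer is an R function, `run_sv_pipeline()`, not a
  shell executable: the package's users drive it from R scripts, and a
  one-line `Rscript -e` wrapper covers shell use. It writes every
  stage's tables plus a JSON manifest whose stage counts reconcile
  (raw = kept + dropped at each filter).
* Validation problem sizes (2,000-SV cohorts of 18–20 samples, 10,000
  SVs for hotspot recovery, 100-seed clustering equivalence) were
  chosen to make binomial 3σ bands a few per cent wide while keeping
  the full suite in the low minutes on one core.

## Known limitations

Breed/group subset analyses recompute membership by carrier filtering
rather than re-merging the subset's raw calls; published per-breed
counts could have been produced either way. The consensus stage keeps
the union span, so a cluster's coordinates can be slightly wider than
any single caller's estimate. The hotspot scan's global z-score is not
robust to very large enriched fractions (see above). And the
acceptance-level reproductions are necessarily limited to quantities
recomputable from printed tables: cohort-level headline counts depend
on terabytes of raw reads and external caller binaries.
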