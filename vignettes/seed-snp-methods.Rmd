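---
title: "Methods: SNPs in miRNA seed regions — mapping, target overlap, and cluster enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNPs in miRNA seed regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirseedclust)
```

## The scientific question

A mature miRNA recognises its target mRNAs almost entirely through its
*seed*: nucleotides 2–8 from the 5′ end. A SNP inside the seed can therefore
rewire the miRNA's whole target spectrum at once. Two population-scale
observations structure the analysis implemented here:

1. **Clustering pattern.** miRNA genes often sit in genomic clusters
   (neighbouring precursors within 10 kb on the same strand), whose members
   tend to be co-expressed and to share targets. Are miRNAs that carry a
   seed SNP *enriched* in clusters, as functional complementarity within a
   cluster would predict?
2. **Functional effect.** How much of the target spectrum survives a seed
   SNP, and is the damage milder for clustered miRNAs?

`mirseedclust` implements the full pipeline: strand-aware mapping of SNPs
into seed coordinates, allele-dependent target prediction, a cosine-
similarity *percent overlap* between reference- and derived-allele target
sets, 10 kb single-linkage clustering, and the associated tests — plus a
synthetic-data generator with planted ground truth that exercises every
stage.

## Coordinate model and seed mapping

All in-memory coordinates are 1-based inclusive, the convention shared by
GFF3 and VCF; conversion to 0-based half-open happens only at BED export.
A single convention end to end eliminates off-by-one drift between the two
input formats.

The seed occupies mature positions 2–8. On the `+` strand the 5′ end is the
annotated `start`, so the seed interval is `[start + 1, start + 7]`; on the
`-` strand the 5′ end is the annotated `end`, giving `[end − 7, end − 1]`.
Both are exactly 7 bp. A SNP at genomic position *p* has seed offset
`p − start + 1` (`+`) or `end − p + 1` (`−`), counted 1..7 in the 5′→3′
direction of the miRNA.

VCF alleles always refer to the forward genomic strand, so for a minus-
strand miRNA each single-base allele is *complemented* (not reverse-
complemented — these are single bases) and `T` is rewritten `U` to obtain
the base in miRNA sense. A (SNP, seed) pair is kept only when the projected
REF base equals the annotated seed base at that offset; a mismatch signals
an annotation/genome-build inconsistency, and the pair is excluded with a
warning rather than silently "corrected" — substituting would fabricate a
seed supported by neither input.

SNPs are counted per distinct rsID per mature: a multiallelic SNP is one
SNP in count tables but yields one overlap result per ALT allele
downstream. A SNP overlapping the seeds of two matures is emitted once per
(SNP, mature) pair; both granularities are visible in the outputs. Rarity
follows the minor allele frequency with a *strict* threshold: rare iff
MAF < 0.05; a missing MAF gives `unknown`, which keeps the SNP in the
mapping but out of rare/common tabulations.

## Target prediction

The published analysis used an online seed-match predictor (with context
scoring) that cannot be embedded in a reproducible artifact. Because the
overlap statistic consumes only target *sets*, the package implements the
canonical seed-match site taxonomy directly, with no context scoring:

| site type | pattern on the UTR (5′→3′) | meaning |
|-----------|---------------------------|---------|
| 7mer-m8   | `M`                       | perfect match to mature 2–8 |
| 8mer      | `M` + `A`                 | 7mer-m8 plus A1 adenine |
| 7mer-A1   | `M[2..7]` + `A`           | match to mature 2–7 plus A1 |
| 6mer      | `M[2..7]`                 | match to mature 2–7 |

where `M` is the reverse complement of the 7 nt seed written as DNA. The A1
position is required to be a genomic `A` in the UTR, following the
canonical definition, not a pairing requirement. The default enabled set is
`{8mer, 7mer-m8, 7mer-A1}`; 6mer sites are off by default because
6mer-only sites are weak and would dominate set sizes, but the choice is a
single configurable argument. Overlapping matches of different types at one
locus collapse to the most specific type (8mer > 7mer-m8 > 7mer-A1 > 6mer);
membership of a gene in the target set needs only one enabled match
anywhere in its UTR. Matching is exact string search on the forward mRNA
strand, with overlapping occurrences of periodic patterns all counted.
Multiple UTR isoforms must be pre-collapsed to one sequence per gene id by
the caller; the package does not merge isoforms.

## Percent overlap (cosine similarity)

For reference target set *R* and derived target set *D*:

$$\text{percent overlap} = \frac{|R \cap D|}{\sqrt{|R|\,|D|}}$$

The square root damps seeds with abnormally many targets and bounds the
score in [0, 1]: 1 iff the sets are equal, 0 iff disjoint. A lower value
means a larger functional effect (more regulatory control lost and/or
gained). When either set is empty the score carries no information; it is
reported as an *undefined* sentinel and excluded from means, with the
undefined count reported alongside. Coding it as 0 would silently bias
aggregates downward. For multiallelic SNPs one value per ALT is computed;
per-SNP summaries use the mean across alleles (configurable to min/max).
Since it is not knowable whether a published average was taken over SNPs or
over SNP-alleles, both aggregations are emitted.

## Clustering

Precursors are grouped per (chromosome, strand) by single-linkage chaining:
sorted by start, a precursor joins the open chain when its edge-to-edge gap
to the chain so far (`max(0, start − max_prev_end − 1)`) is at most 10 kb,
boundary inclusive ("within 10 kb" read as ≤). Chains of ≥ 2 become
clusters. Decisions made where the source convention is not re-derivable:

* **Distance definition**: edge-to-edge gap, because "located within 10 kb"
  most naturally reads as inter-locus distance; a `distance_mode = "start"`
  switch provides start-to-start distances.
* **Single linkage** matches standard genomic-cluster practice: A–B ≤ 10 kb
  and B–C ≤ 10 kb puts A, C together even if A–C > 10 kb.
* Overlapping or nested precursors (gap 0) always co-cluster; a running
  maximum of interval ends makes chaining correct for nested loci.

Exact reproduction of the published 99-cluster/352-gene/634-mature table
from a specific annotation release is not claimed; clustering is always
recomputed from the supplied annotation.

## Inference

* **Cluster enrichment**: Pearson chi-square on the 2×2 table (with/without
  seed SNP × clustered/nonclustered) at mature-miRNA granularity, df = 1.
  The continuity correction is **off** by default: the published p-value on
  the printed counts (314/1226 vs 320/1587 → p = 6.06 × 10⁻⁴) is the
  *uncorrected* Pearson statistic, which the acceptance checks reproduce;
  Yates would give a larger p. The degenerate table in which every miRNA
  (or none) is clustered has identical group proportions by construction
  and is reported as statistic 0, p = 1.
* **Functional effect**: two-sided *pooled-variance* Student t-test between
  percent overlaps of clustered and nonclustered seed SNPs (the published
  method names Student's test); a Welch switch is provided. The comparison
  is run at both per-SNP and per-miRNA granularity, since the original
  grouping is not re-derivable.
* **Over-representation**: one-sided hypergeometric p per annotation set
  with Benjamini–Hochberg adjustment across sets; raw p-values are also
  emitted because published pathway tables report raw p < 0.01. This is a
  generic replacement for web-based miRNA set enrichment; no attempt is
  made to reproduce any specific pathway database.

## The synthetic-data generator

`simulate_seed_snp_data()` emits GFF3 + mature FASTA + VCF 4.2 + UTR FASTA
+ a GMT-like set file, all deterministic functions of one integer seed
(every random draw flows from it; file write order is fixed, so outputs are
byte-identical across runs). Defaults mirror the proportions of the real
annotation rather than its absolute size:

* 400 precursors on 3 chromosomes, two matures each (800 matures); 20% of
  precursors in planted clusters of 2–4 members — close to the ~19% of
  precursors / ~22% of matures clustered in the real annotation.
* Intra-cluster gaps 0.5–9.5 kb, inter-locus gaps 50–200 kb: every
  simulation exercises the 10 kb rule on both sides of the boundary.
* 350 seed SNPs (≈ 44% of matures carry one, matching the published 43.6%),
  placed at uniform seed offsets on both strands, with REF alleles derived
  from the mature sequence so the forward-strand VCF is consistent with the
  annotation; 97.5% rare (MAF ~ scaled Beta below 5%), 2% missing MAF, 5%
  multiallelic; 100 background SNPs outside all seeds.
* A planted clustered:nonclustered seed-SNP odds ratio of 2, realised by
  weighted sampling of the carrier mature.
* An *overlap cohort* of 20 clustered + 20 nonclustered biallelic seed
  SNPs receives planted UTR target sites: clustered SNPs draw
  (ref-only, der-only, common) counts from (1–3, 1–3, 4–8) — high overlap —
  and nonclustered from (3–6, 3–6, 0–2) — low overlap. Planted sites are
  injected as 7mer-m8 cores followed by a deliberate non-A base (so an
  offset-7 SNP, whose 7mer-A1 pattern is shared between its alleles, cannot
  acquire an unintended shared site), into background sequence that is
  rejection-sampled (bounded at 1000 attempts) until the UTR matches
  exactly its planted alleles and no other cohort allele. Cohort selection
  skips SNPs whose patterns collide with an already-selected SNP's
  patterns; among ~160 random 7-mers such collisions are expected about
  once per simulation and would make the screen unsatisfiable.

The cohort is deliberately a subset of the seed SNPs: screening every UTR
against the patterns of *all* ~350 SNPs would face an expected
accidental-match count far above one per UTR, making exact planting
infeasible — and the statistical comparison does not need it. Non-cohort
seeds may still hit UTRs by chance, which is realistic background noise;
planted-count exactness is defined, and verified, over the cohort. UTRs
are 150–300 nt over 600 genes, which keeps the expected number of
accidental cohort-pattern matches per UTR below ~3 and the rejection
sampler fast.

`verify_ground_truth()` closes the loop: it re-reads the emitted files
through the package's own readers and checks every ground-truth assertion
(tables round-trip, the computed cluster partition equals the planted one,
every planted SNP maps back to its mature and offset with the planted
rarity, cohort target sets equal the planted gene sets, the layout
straddles 10 kb). Any discrepancy is reported as a generator bug.

**What passing on synthetic data does not show.** The generator emulates
the *statistical structure* of the real analysis, not real data: mature
sequences are uniform random RNA (no sequence composition bias, no miRNA
families sharing seeds), UTRs are uniform random DNA (no composition or
length distributions of real 3′UTRs), there is no linkage disequilibrium,
no multi-locus rsIDs, and chromosome lengths are tiny. Passing tests
demonstrate correctness of the machinery and recoverability of planted
effects at the configured sizes — not that any particular biological
conclusion holds on a given annotation release.

## Numerical choices and degenerate inputs

* Test sizes: the end-to-end checks run one full simulation at the default
  scale (400 precursors / 350 SNPs / 600 UTRs), the clustering oracle
  comparison uses 500 random layouts of 4–12 precursors, the mapping oracle
  1000 SNPs × 100 seeds, the chi-square reference comparison 200 random
  tables (agreement to 1e-10 relative), and the null calibrations 1000
  (t-test) and 200 (chi-square) replicates, with acceptance bands of ±3
  binomial standard errors around the nominal 5% level.
* Degenerate statistics: identical constant samples give t = 0, p = 1;
  two degenerate samples with different means are an error; a zero marginal
  in the 2×2 is an error pointing at Fisher's exact test.
* Reader policy: invalid records are dropped with counted warnings, never
  silently coerced; errors that invalidate coordinates (sequence/interval
  length mismatch) are fatal.
* rsIDs appearing at multiple loci are all kept and flagged
  (`multi_mapped`), since discarding either placement would be arbitrary.

## Limitations

* The seed-match predictor is deliberately context-free; absolute target
  counts and genome-scale mean overlaps are not comparable with
  context-scored predictors, which is why the published genome-scale mean
  overlap (15.8%) is exercised as a formula property, not as a numeric
  target.
* Only single-nucleotide substitutions are considered; indels and
  structural variants are out of scope, as are SNPs elsewhere in the
  precursor.
* No liftover: annotation and VCF must share an assembly, and
  reference-mismatch warnings are the symptom when they do not.
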