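# mirseedclust

Analysis of single-nucleotide polymorphisms (SNPs) in human miRNA **seed
regions**: where they fall, how they redistribute among **miRNA genomic
clusters**, and how severely they rewire each miRNA's target spectrum.

A mature miRNA selects its targets through nucleotides 2–8 from its 5′ end
(the seed), so a single substitution there can simultaneously break old
target sites and create new ones. This package is for researchers in
regulatory genomics / population genetics who want to run that analysis on
standard inputs (miRBase-style GFF3, mature FASTA, VCF, 3′UTR FASTA) or to
study its statistical behaviour on simulated data with known ground truth.

## What it computes

1. **Seed mapping.** The genomic seed interval of every mature miRNA
   (strand-aware: `[start+1, start+7]` on `+`, `[end−7, end−1]` on `−`),
   intersected with SNPs; forward-strand VCF alleles are projected into
   miRNA sense (complemented on `−`, T→U), and each SNP gets a seed offset
   1–7 and a rare/common class (minor allele frequency < 5% = rare).
2. **Allele-dependent targets.** Canonical seed-match prediction (8mer,
   7mer-m8, 7mer-A1, optionally 6mer site types) of the target gene set of
   the reference seed and of each derived (ALT) seed against a 3′UTR
   collection.
3. **Percent overlap** (cosine similarity) between the two target sets:

   |R ∩ D| / √(|R|·|D|)  ∈ [0, 1]

   1 = identical target spectra, 0 = disjoint; lower overlap = larger
   functional effect of the SNP.
4. **Clustering.** Single-linkage grouping of precursors on the same
   chromosome and strand with inter-locus gaps ≤ 10 kb; matures inherit
   their precursor's cluster status.
5. **Inference.** Pearson chi-square on the 2×2 table (seed SNP ×
   clustered), pooled-variance two-sided t-test comparing percent overlaps
   of clustered vs nonclustered seed SNPs, and a hypergeometric
   over-representation test for miRNA annotation sets with
   Benjamini–Hochberg adjustment.
6. **Synthetic data.** `simulate_seed_snp_data()` generates a deterministic
   miniature genome (GFF3/FASTA/VCF/UTR FASTA/GMT) with planted clusters,
   planted seed SNPs at a chosen enrichment odds ratio, and planted
   target-site structure whose exact percent overlaps are known;
   `verify_ground_truth()` re-checks every assertion through the package's
   own readers.

## Worked example

```r
library(mirseedclust)

dir <- tempfile("sim")
simulate_seed_snp_data(simulation_config(seed = 1), dir)

cfg <- pipeline_config(
  gff          = file.path(dir, "mirna.gff3"),
  mature_fasta = file.path(dir, "mature.fa"),
  vcf          = file.path(dir, "snps.vcf"),
  utr_fasta    = file.path(dir, "utrs.fa"),
  mirna_sets   = file.path(dir, "mirna_sets.gmt"),
  out_dir      = file.path(dir, "run"))
report <- run_pipeline(cfg)
print(report)
```

The run prints one log line per stage and the report summary:

```
[annotation] 400 precursors, 800 matures, 450 SNVs (0 rejects)
[seed_mapping] 350 seed SNPs in 276 matures (0 reference mismatches)
[clustering] 29 clusters; clustered 30.4% (with SNP) vs 14.5% (without); p = 8.56e-08
[overlap] 350 defined / 0 undefined; mean = 0.143
[ora] 8 sets tested; top: planted_pathway (p = 1.43e-23)
mirseedclust run report (v0.1.0)
  precursors: 400  matures: 800  SNVs: 450
  seed SNPs: 350 in 276 matures
  clustered: 30.4% (with SNP) vs 14.5% (without), chi-square p = 8.56e-08
  mean percent overlap: 0.143 ( 350 defined )
```

Reading the numbers: of the 800 simulated matures, the ones carrying a
seed SNP are clustered far more often (30.4%) than the ones without
(14.5%) — the planted enrichment (odds ratio 2) is recovered with
p ≈ 8.6 × 10⁻⁸. The mean percent overlap of 0.143 mixes the planted
high-overlap clustered cohort with the low-overlap nonclustered cohort and
background noise; `report$overlap$t_test_per_snp` carries the clustered vs
nonclustered comparison (p ≈ 5 × 10⁻⁴ here), and the planted pathway set
ranks first in the over-representation table. Stage tables
(`seed_snps.tsv`, `clusters.tsv`, `overlaps.tsv`, `ora.tsv`, ...) and
`run_report.json` are written under `out_dir`.

On real data, replace the five paths with your annotation GFF3, mature
FASTA, dbSNP-style VCF and UTR FASTA.

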