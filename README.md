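# EnhancerFunnel

Differential enhancer calling and enhancer-driven oncogene prioritization
for paired tumor/normal cohorts.

Tumors can become addicted to regulatory DNA: clusters of newly active
enhancers drive lineage transcription factors and their target oncogenes.
`EnhancerFunnel` implements the epigenomic side of that analysis for
cohorts with matched tumor and adjacent-normal tissue profiled by
dual-histone-mark (H3K27ac + H3K4me1) ChIP-seq, and integrates it with
bulk expression, cell-type-specific chromatin accessibility, and
master-transcription-factor co-expression to nominate enhancer-driven
oncogene candidates. It is aimed at regulatory-genomics analysts who have
peak calls and count matrices in hand and want a tested, reproducible,
auditable pipeline rather than a pile of one-off scripts.

## What it computes

**Putative enhancers.** Per sample, H3K27ac peaks that overlap an H3K4me1
peak (≥ 1 bp) and lie at least 2.5 kb from every transcription start site.
Per group, the union of per-sample enhancer sets is merged and regions
reproducible in at least 2 samples are kept (`callSampleEnhancers()`,
`buildConsensus()`).

**Cancer-gained / cancer-depleted enhancers.** On the merged
tumor ∪ normal region universe, enhancer signal is RPKM
(reads · region-kb⁻¹ · million-mapped-reads⁻¹). Each region gets a paired
t-test on log₂(RPKM + 0.01) across patient pairs and Benjamini–Hochberg
correction over the universe. With `log2FC = log2(mean RPKM_T / mean
RPKM_N)` (pseudocounted),

- SOE (gained): `log2FC > 0.75` and `padj < 0.05`,
- CDE (depleted): `log2FC < −0.75` and `padj < 0.05`

(`callDifferentialEnhancers()`).

**Saturation.** Subsampling k of n patient pairs (25 seeded replicates per
k) and re-calling SOEs measures what fraction of full-cohort discoveries a
smaller cohort recovers (`saturationAnalysis()`).

**The candidate funnel.** Four ordered evidence layers
(`runFunnel()`):

1. SOEs overlapping cell-type-specific accessible (ATAC) peaks;
2. protein-coding genes with a TSS within 200 kb of a stage-1 locus;
3. genes upregulated in both bulk tumors (paired Wilcoxon signed-rank,
   BH, `log2FC > 1`, `padj < 0.05`) and the target single-cell cluster
   (rank-sum vs all other cells, Bonferroni);
4. genes whose expression correlates with **all** master TFs (TP63, SOX2,
   KLF5, GRHL2) across tumor samples (Pearson `r > 0.5`, BH-adjusted
   `p < 0.05` per TF).

Every stage records per-gene audit columns, so a rejected candidate shows
exactly which filter removed it.

**Synthetic cohorts.** `simulateCohort()` generates the full multi-omic
fixture with ground truth — paired negative-binomial counts with shared
patient effects and planted log₂ fold changes, stochastic per-sample peak
detection, a latent-factor expression model for the TF module, decoy genes
violating exactly one funnel criterion each — so the whole pipeline runs
and is verified with no external data.

## Worked example

```r
library(EnhancerFunnel)

co <- simulateCohort(simConfig(seed = 5))
co
#> SyntheticCohort: 18 pairs, 500 regions, 310 genes
#>   planted SOE: 50  CDE: 50

dir <- file.path(tempdir(), "demo")
writeFixtures(co, dir)                       # BEDs, TSVs, truth JSON

res <- runPipeline(readRunConfig(file.path(dir, "run.yaml")),  # or a list of paths
                   out_dir = file.path(tempdir(), "out"), seed = 7)
res$funnel
#> FunnelResult
#>   SOEs in:           50
#>   overlap loci:      28
#>   linked genes:      171
#>   dual-DE genes:     8
#>   candidates:        1
#>   -> g0001
```

Of 50 called SOEs, 28 overlap cluster-specific accessible peaks, 171
protein-coding genes lie within 200 kb of those loci, 8 survive both
expression filters, and exactly one — the planted oncogene `g0001` — is
co-expressed with all four master TFs. Per-region statistics:

```r
head(as.data.frame(res$differential), 3)
#>           region_id mean_rpkm_tumor mean_rpkm_normal      log2fc    stat         p       padj klass
#> univ_0001 univ_0001        7.620185         3.396060  1.16361420  9.2303  4.94e-08   2.82e-07   SOE
#> univ_0002 univ_0002        4.647248         8.734119 -0.90883528 -6.3353  7.46e-06   3.73e-05   CDE
#> univ_0003 univ_0003        9.682217         9.973247 -0.04268239 -0.2898  7.75e-01   9.54e-01    NS
```

The discovery curve saturates quickly — most SOEs are recoverable from a
handful of pairs:

```r
attr(saturationAnalysis(co@counts, co@design,
                        k_values = c(2L, 6L, 10L, 14L, 18L),
                        n_replicates = 25L, seed = 7), "summary")
#>    k   mean          sd n_replicates
#> 1  2 0.0008 0.004000000           25
#> 2  6 0.9520 0.023804761           25
#> 3 10 0.9880 0.010000000           25
#> 4 14 0.9944 0.009165151           25
#> 5 18 1.0000 0.000000000           25
```

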