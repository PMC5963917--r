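# splicelink

An R toolkit for analysing how an RNA-binding protein (RBP) shapes the
transcriptome, combining single-nucleotide crosslinking evidence (iCLIP)
with alternative-splicing and exon/junction-usage dynamics across a
cellular reprogramming time course (MEF → d3 → d6 → d9 → d12 → iPSC).
It is aimed at computational biologists who have per-nucleotide
crosslink counts, junction count tables and a differential-expression
table, and want the full chain from binding-site calling to integrative
overlap statistics — with seeded synthetic data and recorded ground
truth so every stage can be validated without external downloads.

## What it computes

**Crosslink site calling.** Unique-cDNA crosslink counts are tested per
co-transcribed region by randomisation: the observed events are
redistributed uniformly over the region's positions *n* times and, for
each count height *k*,

    FDR(k) = E_null[ #positions with count >= k ] / obs[ #positions with count >= k ]

monotonised to be non-increasing in *k*; sites with FDR < 0.05 are kept,
then filtered against a control library (count >= 2, absent from
control).

**Motif enrichment.** K-mers in the windows (−30,−5)(+5,+30) around each
site are presence-weighted (one unit per site); sites are re-shuffled
within their regions to form a null, and

    z(kmer) = (observed − mean_null) / sd_null.

A greedy aligner condenses the top k-mers into a PWM and IUPAC consensus.

**Splicing comparison.** Each event's inclusion fraction ψ is estimated
as the Beta(1,1) posterior mean (inc+1)/(inc+exc+2); conditions are
compared with a closed-form Bayes factor

    BF = B(a_i+1, a_e+1) B(b_i+1, b_e+1) / B(a_i+b_i+1, a_e+b_e+1)

and the standard filters (>=1 inclusion and exclusion read per sample,
>=10 reads in one sample, |ΔPSI| >= 0.2, BF >= 5, all bounds inclusive).

**Usage time course.** Flat exonic parts / junctions / introns are
tested for differential usage against their gene-rest counts with a
beta-binomial likelihood-ratio test (moment-estimated, floored
overdispersion), classified regulated / unregulated / untestable via
Benjamini–Hochberg FDR, and summarised as variance-stabilised log2
fold-change trajectories, cumulative (vs MEF) or sequential.

**Integration.** Regulated features with a binding site inside the
feature or within ±200 nt of a junction anchor are SARFs
(binding-associated regulated features); trajectories passing the
autocorrelation (>= 0.1) and max |log2FC| (0.5–8.5) filters are
clustered with seeded k-means++ (default k = 20); detained-intron and
DEG overlaps are reported as audited fractions with hypergeometric
enrichment p-values.

## Worked example

```r
library(splicelink)

cfg <- sim_config(seed = 1)              # the default synthetic world
res <- run_pipeline(cfg, n_rand = 100, n_shuffles = 20)

nrow(res$sites)                          # 20  significant crosslink sites
res$kmer_z$kmer[1]; res$kmer_z$z[1]      # "CUCUC", 16.6  (planted motif)
sum(res$psi$pass)                        # 44  significant AS events (iPSC vs MEF)
res$usage_cumulative$summary$n_regulated # 246 284 314 366 426
res$sarf_summary$sarf_fraction           # 0.74  SARFs in the 3 richest clusters
res$deg_stats$n_deg                      # 6   DEGs at FDR < 0.05, |log2FC| >= 1
```

All 20 planted sites are recovered (recall 1.00 at seed 1), the planted
pyrimidine-rich 5-mer is the top-ranked k-mer, the cumulative regulated
counts grow towards iPSC as planted, and the SARF fraction concentrated
in the top three clusters (0.74) against 0.54 of all kept features
reflects the planted cluster enrichment.

The same stages run from files via the CLI:

```sh
Rscript -e 'splicelink::splicelink_cli()' simulate --seed 1 --outdir sim/
Rscript -e 'splicelink::splicelink_cli()' callsites --xlinks sim/signal.bed \
    --genome sim/genome.fa --annotation sim/annotation.gtf --seed 1 --out sites.bed
```

## Layout

- `R/` — genome model, synthetic generators, crosslink calling, motif
  enrichment, PSI comparison, usage time course, integration, bench
  assays, IO, pipeline/CLI.
- `vignettes/splicelink-methods.Rmd` — the methods vignette: models,
  assumptions, parameter choices, what the synthetic world does and does
  not establish.
- `tests/testthat/` — unit, property and acceptance suites.
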