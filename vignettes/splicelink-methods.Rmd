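---
title: "splicelink: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{splicelink: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicelink)
```

splicelink chains five analyses around one biological question: where an
RNA-binding protein contacts the transcriptome, and how splicing and
exon/junction usage respond — in a knockout contrast and across a
reprogramming time course. This vignette explains each model, the
parameters that matter, what the synthetic world emulates, and the
choices we made where the design was genuinely open. Nothing stated
here as an empirical result is asserted anywhere but in the tests and
the acceptance script that compute it.

## Coordinates and strand

All internal coordinates are 0-based, half-open. BED is read and
written natively in that convention; GTF is converted from 1-based
closed on the way in and back on the way out. Anything directional —
offset windows, metagene coordinates, motif planting — is computed in
transcript orientation and mapped to the genome, mirrored on the minus
strand; no operation is strand-naive. Offset pairs such as (−30,−5) are
treated as closed integer intervals (26 positions): the notation is
ambiguous in the field, and the closed reading keeps both windows the
same length.

## Crosslink site calling

The unit of evidence is the unique cDNA: read records deduplicated on
(position, UMI), with the crosslink placed one nucleotide 5' of the
read start in transcript orientation (the reverse-transcriptase
truncation position). Significance is assessed per co-transcribed
region — the merged union of a gene's transcript spans — by
randomisation: the region's total event count is redistributed
uniformly over its positions (multinomial, collisions allowed, totals
preserved), `n_rand` times. For each observed count height $k$,

$$\mathrm{FDR}(k) = \frac{\mathbb{E}_{null}\,\#\{positions: count \ge k\}}
                        {\#\{observed\ positions: count \ge k\}},$$

capped at 1 and monotonised with a running minimum so that a taller
stack is never less significant than a shorter one. Retention uses
strict FDR < `alpha` (default 0.05). We deliberately call
single-nucleotide sites with no peak extension or low-count
regularisation: it is the simplest model consistent with a
per-position randomisation null, and it is exactly checkable — the
binomial marginal $L\,P(\mathrm{Bin}(N, 1/L) \ge k)$ and a
Stirling-number occupancy oracle validate the Monte-Carlo estimates on
small regions in the test suite.

Randomisation happens within whole co-transcribed regions, not within
segment types (exon vs intron); the finer stratification is defensible
but unstated in the protocols this follows, and whole-region shuffling
keeps the null model identical between the site caller and the k-mer
stage. Overlapping genes on opposite strands keep independent regions.

Downstream stages use the control-filtered site set (count ≥ 2 and no
control crosslink at the identical position) by default, mirroring how
binding maps are usually drawn; the unfiltered set stays available.
Site-set overlap comparisons default to a 3 nt tolerance — crosslink
positions jitter by a nucleotide or two between libraries — and the
tolerance is an explicit argument because published overlap figures
rarely state their matching rule.

## K-mer enrichment

Within the windows (−30,−5)(+5,+30) around each site, a k-mer present
at least once contributes weight 1.0 for that site — presence
weighting, our reading of "one occurrence … weighted by 1.0"; the two
windows form a union, so a k-mer occurring in both still contributes
one unit. Per-occurrence counting is available as `mode =
"occurrence"`. The null relocates sites uniformly within their
co-transcribed region and recomputes weights; $z = (obs -
\bar{w}_{null}) / sd_{null}$ per k-mer, with $sd = 0$ (degenerate
sequence) yielding $z = 0$ and a flag rather than an infinity. The
per-shuffle weight vectors (not pooled counts) define the null moments;
pooling would understate the shuffle-to-shuffle variance that the
z-score is supposed to capture.

The consensus builder is a deliberate stand-in for EM motif discovery:
greedy ungapped alignment of the top k-mers to the top-ranked seed at
the best-agreement offset (ties resolved toward offset 0; k-mers with
fewer than 2 agreeing positions stack at offset 0 with a warning),
weight-averaged into a PWM, and an IUPAC letter per column from the
smallest base set reaching a 2/3 majority. It condenses a ranked k-mer
list into a readable logo; it does not discover gapped or multi-modal
motifs.

## Splicing comparison

Inclusion/exclusion junction counts are modelled per event with a
Beta(1,1) prior: the reported PSI (PIR for intron retention) is the
posterior mean $(inc+1)/(inc+exc+2)$, the raw ratio is kept alongside,
and a zero-total event is flagged undefined rather than erroring. The
two-condition comparison is the closed-form Bayes factor of
"independent $\psi_a, \psi_b$" against "shared $\psi$", a ratio of Beta
functions — a defined replacement for isoform-aware samplers, justified
because the inputs are junction counts that are already
length-comparable. Replicates within a condition are summed before
comparison, matching the merged-control design the event filters came
from. The filters are applied verbatim and all bounds are inclusive
("at least", "minimum"): ≥1 inclusion and ≥1 exclusion read in each
sample, ≥10 reads in at least one sample, |ΔPSI| ≥ 0.2, BF ≥ 5; every
failed clause is named in the output.

One open question — whether multi-replicate designs should be compared
per replicate and intersected instead of summed — we resolved in favour
of summing: it matches the merged-control precedent, and the
intersection rule is a trivial wrapper the user can apply to the
per-replicate outputs.

## Usage time course

Flat features (disjoint exonic parts, junctions, introns, from TSL ≤ 1
transcript models) are tested for differential usage as
feature-vs-gene-rest proportions. The engine is a beta-binomial
likelihood-ratio test: intra-class correlation estimated from replicate
proportions by the method of moments (floored, default at 0 so that
clean binomial data degrade gracefully to a binomial LRT), condition
means fitted by maximum likelihood, statistic referred to
$\chi^2_1$. Benjamini–Hochberg across the testable features of one
contrast classifies regulated (FDR < 0.05) vs unregulated; a feature
with fewer than 5 reads (summed over replicates) in both contrasted
time points is untestable and leaves the BH denominator. The 5-read
floor is a config field: the original rule is stated only as "too few
reads".

Two caveats belong here rather than in a docstring. First, usage is
relative: when a gene's other features change, an objectively flat
feature's usage proportion changes too, so the regulated set contains
gene-coupled collateral calls — inherent to this class of test, not a
bug; trajectory filtering downstream works on the feature's own
fold-changes and is immune. Second, the fold-change "vst" is the
pseudocount transform $\log_2((x+c)/(y+c))$ with $c = 1$: the original
transform's parameters are not recoverable, and a unit pseudocount is
the standard variance-damping choice at these depths.

## Integration

A regulated feature is a SARF when a (control-filtered) binding site
lies inside it or within ±200 nt of either junction anchor; for
exonic parts and introns the anchors are the interval edges. Before
clustering, trajectories must have lag-1 Pearson autocorrelation ≥ 0.1
and maximum |log2FC| within [0.5, 8.5]; zero-variance trajectories are
dropped (their autocorrelation is undefined). Clustering is k-means
with k-means++ seeding, 10 restarts and a fixed seed (base `kmeans`
supplies the Lloyd iterations; the seeding layer is ours because base R
has no plus-plus initialisation), k = 20 by default. Cluster summaries
report the fraction of SARFs in the `top_n` SARF-richest clusters next
to the fraction of all features those clusters hold, with numerators
and denominators, so the enrichment is auditable. Detained-intron and
DEG overlaps are plain fractions with explicit denominators (empty
denominator ⇒ NA, never 0) plus one-sided hypergeometric enrichment
p-values; the hypergeometric is our choice — the fractions these
reproduce were published without a named test. "Flanking" for
DI-adjacent exons means sharing a boundary coordinate within the gene's
flat model.

## The synthetic world

The generators state one world and keep it: 30 multi-exon genes on two
chromosomes and both strands (every third gene carries an extra TSL-2
transcript so support-level filtering is exercised), a pyrimidine-rich
5-mer motif `CUCUC`, 20 planted crosslink sites at 50:1
signal-to-background over a 0.2 events/nt Poisson background, a 6-point
time course with 2 replicates, 6 planted trajectory shapes of which 3
(the upward-trending ones) are SARF-enriched at probability 0.8 vs 0.1,
a detained-intron fraction of 0.15, events at depth ~50 reads per
sample, and a DEG fraction of 0.3 at |log2FC| = 2. One master seed
feeds named substreams per generator, so any module can be regenerated
independently and the whole pipeline is byte-reproducible.

Two generator choices deserve their rationale. Crosslink counts are
Poisson around the configured rates: the simplest count model with
closed-form checks, which is exactly what the oracle tests need.
And the motif is written at transcript-orientation offsets +6..+10
from the planted site — inside the evaluated (+5,+30) window — because
the evaluated windows exclude ±4 nt around the crosslink; a
site-centred motif would be invisible to the k-mer stage by
construction. Biologically this encodes "the crosslink sits a few
nucleotides from the recognition element", which is what
truncation-based protocols actually observe.

What a green test does establish: the permutation FDR matches its
analytic null; planted sites, motifs, trajectory clusters, two-wave
change points and DEG labels are recovered at the stated rates; the
pipeline is deterministic. What it does not: performance on real
libraries with PCR artefacts, mappability gaps, overdispersed
biological replicates (the generator's replicates are Poisson), isoform
length biases, or annotation errors — none of which the generator
emulates. The headline numbers of the study this emulates depend on
those real datasets and are deliberately not targets.

## Numerical notes and limitations

- FDR ties: retention is strict (`fdr < alpha`), matching "FDR < 0.05".
- Bayes factors are computed in log space with `lbeta`; no
  integration error enters.
- The usage LRT clamps means to $[10^{-9}, 1-10^{-9}]$ and statistics
  at 0; untestable is decided before any optimisation.
- k-means determinism holds for a fixed seed and restart count; a tiny
  jitter ($10^{-9}$) on the seeded centres avoids degenerate duplicate
  centres on planted data.
- `region_density` resolves a site's class strand-aware with precedence
  CDS > 5'UTR > 3'UTR > ncRNA exon > intron > intergenic, and
  normalises by the class's total length pooled over both strands.
- MXE events are encoded as pairwise inclusion/exclusion counts; the
  multi-way formulation is out of scope, as is novel event discovery.
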