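---
title: "circSponge: models, parameters and design notes"
author: "circSponge maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circSponge: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ejaculated sperm carries a sparse, fragmented RNA payload in which circular
RNAs (circRNAs) are unusually stable, which makes them candidate noninvasive
markers of semen quality. circSponge implements a desk-scale version of the
analysis used to characterise the boar sperm circRNAome: discovery of
back-splice junctions (BSJs) from RNA-seq reads, assembly of a
multi-sample circRNA catalogue quantified in BSJ reads per million raw reads
(CPM) and classified by genomic co-location (CDS, 5'UTR, 3'UTR, intronic,
intergenic), inference of circRNA-miRNA sponge candidates by intersecting
negative partial-correlation edges with sequence-predicted miRNA target
sites, and a Pearson screen of circRNA abundance against fixed-effect
corrected sperm motility traits.

Every stage is exercised end to end on synthetic data with planted ground
truth, generated by the package itself, so the whole pipeline is testable
without any external download.

## BSJ detection

A BSJ read is one that crosses the head-to-tail splice: its left part maps
downstream of its right part on the same contig. The caller takes the
terminal `anchor_length` (default 20) nt of each read, finds their exact
occurrences in a k-mer index of the genome (both strands, resolved by
reverse-complement lookup), and considers every head-to-tail anchor pair.
Both anchors are then extended toward the read interior; the breakpoint `b`
that minimises mismatches (at most `max_extension_mismatches`, default 1)
defines the junction: the acceptor is the leftmost circle base, the donor
the rightmost. With `require_canonical_splice` (default on), only
breakpoints whose genomic flanks read `AG..[circle]..GT` (plus-strand
circles) or `AC..[circle]..CT` (the same signal seen from the minus strand)
are eligible; the matching pattern also assigns the circle strand. This
requirement doubles as the tie-break for junction microhomology: when
shifting the breakpoint by one base explains the read equally well, at most
one of the shifted positions carries a canonical signal. A read whose best
breakpoint remains tied is flagged ambiguous and contributes no support.

Three stringency filters follow, applied per sample to the aggregated
junctions:

* at least `min_unique_support` (default 2) supporting fragments whose
  anchors each have a single genomic hit;
* a junction-window quality of at least `min_junction_phred` (default 35),
  computed per supporting read as the mean base quality in the +/-10 nt
  window around the breakpoint, taking the minimum over reads. A bare
  Phred threshold does not by itself say what it is computed over; the
  windowed mean is this package's reading, and the window statistic is
  isolated so another interpretation can be substituted;
* a maximum genomic span (`max_circle_span`, default 1 Mb).

Junctions are then matched across samples at base-exact coordinates (the
extension rule makes breakpoints base-precise, so no fuzzy merge window is
used) and kept when present in at least `min_samples` samples, defaulting
to 75% of the cohort — 30 of the 40-sample design.

Design choices worth noting: the alignment backend is an exact k-mer index
rather than an external seed-and-extend aligner. At the genome sizes this
package targets the index is exact, deterministic and dependency-free;
mismatches are confined to the extension step. Support is counted per
fragment, so paired mates probing the same junction count once. Uniqueness
is read as "both anchors have exactly one genomic hit", the most
conservative reading of unique anchor support.

## Quantification and classification

CPM here is BSJ-spanning reads per million *raw sequenced* reads, not per
million mapped reads; the raw totals come from the read manifest. Mean and
SD CPM are computed over all catalogue samples, counting a sample where the
junction passed no filter as 0 — including undetected samples keeps the
statistic a property of the fixed cohort rather than of the detection
pattern.

Classification is by co-location: a circle span overlapping no gene is
intergenic; overlapping a gene but no exon is intronic; otherwise exonic,
sub-classified by the feature type (CDS, 3'UTR, 5'UTR) covering the largest
share of its exonic overlap, with ties broken CDS > 3'UTR > 5'UTR. The
host gene is the gene with the largest overlap, ties alphabetical. Exon
counts and spliced lengths use the host gene's annotated exons contained in
the span (the package's gene models carry one transcript per gene; with a
richer annotation this corresponds to using one designated transcript).
Hotspot genes are hosts of at least 5 distinct exonic circRNAs. Catalogue
comparison matches junctions within a per-boundary tolerance (default 0)
and is defined only for catalogues on the same assembly — coordinate
liftover is out of scope.

## The sponge network

Both abundance matrices are stabilised as `log2(x + 1)`; the pseudocount
keeps zero abundances finite while leaving the high-abundance scale
untouched.
All-pairs Pearson correlation is computed on the combined circRNA + miRNA
matrix and filtered by PCIT (partial correlation with information theory):
for every trio (x, y, z) the three first-order partials are formed, the
trio tolerance is the mean of the partial/direct ratios, and the x-y
association is eliminated when its magnitude falls below the
tolerance-scaled magnitudes of both other correlations for some z.
Numerical guards: correlations are clamped to |r| <= 1 - 1e-12, and ratio
terms with a numerically zero direct correlation are skipped from the
tolerance mean. With fewer than three features no trio exists and every
association is kept. PCIT runs on the full matrix, but only circRNA-miRNA
pairs are exported; circ-circ and miR-miR edges take part in the
elimination (as third features) without being reported.

The sequence side is a seed-anchored complementarity scan. A candidate site
requires a perfect Watson-Crick match to miRNA positions 2-7; the full
miRNA is then scored ungapped against the site with position weights (the
seed span 2-8 is up-weighted by `seed_scale` = 2), matches scoring +5, G:U
wobbles +1, mismatches -3, and sites at score >= `min_score` (default 55)
are reported. The scan is an approximation of the miRanda-style
complementarity alignment: it is gapless and omits miRanda's thermodynamic
(free-energy) filter, which is explicitly out of scope. Junction-spanning
sites are found by extending the linear circle representation by its own
first `miRNA length - 1` bases and wrapping pairing positions modulo the
circle length; reported positions are circle coordinates.

A final sponge edge must be PCIT-significant, negatively correlated, and
carry at least one predicted site — the intersection of the co-abundance
and sequence evidence. No post-PCIT correlation-magnitude cutoff is
applied beyond the sign requirement, and no multiple-testing correction is
involved at this stage.

## Phenotype association

Motility traits (motile %, VCL, VSL, VAP) are corrected by ordinary least
squares on dummy-coded farm (3 levels), age class (3) and season-year (9)
with first-level reference coding; the residuals are the corrected traits.
The abundance screen computes, per circRNA and trait, the Pearson
correlation of CPM (a `log2` option is available, but raw CPM is the default scale) with the corrected
trait and a two-sided p-value from the t transform with n - 2 degrees of
freedom; pairs at p < 0.05 are flagged with no multiple-testing correction by
default — an optional Benjamini-Hochberg flag is
provided but off by default, and the inflation risk of the uncorrected
screen should be kept in mind.

The age comparison splits boars at 24 months (configurable) or into the k
youngest vs k oldest (default k = 4 in extreme-groups mode) and applies
two-sided Wilcoxon rank-sum tests to the per-sample number of detected
circRNAs and the per-sample mean CPM — the per-sample abundance summary is
the mean over catalogue circRNAs, a choice this package makes explicit.
The exact distribution is used for small tie-free groups, the normal
approximation with tie correction otherwise.

## The synthetic-data generator

The generator emulates the study conditions the pipeline is designed for:
40 samples of 75 bp reads; a toy genome of 3 contigs x 100 kb carrying 30
gene models of 5-9 exons with canonical splice dinucleotides written at
every intron boundary, the outermost exons being UTR and internal exons
CDS; 20 exonic (14 CDS, 3 per UTR class) + 3 intronic + 3 intergenic
planted circles. Exonic circles re-use internal annotated exons so their
back-splice flanks are genuine splice signals; intronic and intergenic
circles get synthetic AG..GT flanks so they remain detectable under the
canonical-splice requirement (a relaxation flag exists). Expected BSJ read
counts are log-normal across circles (median 15) with log-normal per-sample
fluctuation, clamped at 5 reads — the well-supported regime the stringency
filters presume. Base qualities are constant Phred 37 with a per-sample
override for exercising the quality filter; sequencing errors are
substitution-only and off by default.

Sponged miRNAs couple as `log2 miRNA = mu - |effect| * sum(log2 circle
abundance) + noise`, with the coupling mean-centred so miRNA abundances
stay on scale. The noise sd is derived analytically from the configured
target correlation (default -0.7): `sd_noise = sd_signal * sqrt(1/r^2 - 1)`
with `sd_signal` computed from the configured per-sample log-abundance sd.
Each planted pair writes the reverse complement of miRNA positions 1-12
(seed plus 3'-supplementary pairing, as real sponge sites carry) into the
middle of the sponging circle's largest exon; sponging circles are drawn
from distinct host genes. Phenotypes are linear in the fixed effects and in
the log2 abundance of a configurable number of causal circles, with motile
% clipped to [0, 100] and ages spanning 9-54 months across three age
classes.

What the generator does *not* emulate: real sperm libraries are highly
fragmented, rRNA-depleted, and have abundance distributions never described
well enough to calibrate against; there is no positional coverage bias, no
adapter contamination, no indel errors, and linear gene expression is
uniform (only BSJ reads matter downstream). Passing the planted-truth tests
therefore demonstrates algorithmic correctness under the stated model, not
performance on real libraries.

## Numerical and interface choices

* Coordinates are 1-based inclusive GRanges throughout — the natural
  representation for an R/Bioconductor implementation — and the display
  format `contig:start..end` is 1-based inclusive. Junctions are stored as
  spans with start = acceptor (leftmost circle base) and end = donor.
* Determinism: every generator stage derives its own RNG stream from the
  master seed and restores the caller's RNG state, so outputs are
  byte-identical for a fixed configuration and independent of call order.
* Problem sizes in the test suite: the oracle-equivalence checks run on a
  2 x 25 kb genome with exhaustive splice-scan and naive O(n^3) PCIT
  references; the end-to-end recovery checks use the full 3 x 100 kb,
  40-sample design at 20,000 background reads per sample, and the
  linear-only control uses 10 samples — sizes chosen so a laptop reproduces
  them in minutes while every planted junction still has the support level
  the filters require.
* Degenerate inputs: zero-gene genomes fall back to contig-level background
  reads; empty candidate sets merge to empty catalogues; constant abundance
  rows are excluded from the correlation screen with a warning; zero or
  missing raw totals are errors naming the sample.

## Limitations

The caller requires exact terminal anchors, so reads with errors inside an
anchor are lost rather than rescued; multi-mapping anchor rescue and gapped
internal alignment are not attempted. The target scan has no energy model,
so its specificity rests on the strict seed plus the score threshold. The
association stage is a marginal screen — no kinship, repeated-measures or
mixed-model structure. Catalogue comparison cannot detect mixed assemblies;
that responsibility stays with the caller.
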