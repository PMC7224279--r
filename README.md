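# circSponge

Back-splice junction discovery, circRNA cataloguing, miRNA sponge-network
inference and motility association for sperm RNA-seq — with a built-in
synthetic-data generator carrying planted ground truth, so the entire
pipeline is testable end to end on a laptop with no downloads.

## The science

Circular RNAs (circRNAs) arise from back-splicing: a downstream splice
donor joins an upstream acceptor, producing a covalently closed transcript.
The only sequence evidence unique to a circRNA is a read spanning its
back-splice junction (BSJ) — a read whose left part aligns *downstream* of
its right part (head-to-tail). In sperm, circRNAs are attractive biomarker
candidates because they resist exonuclease degradation in an otherwise
fragmented RNA payload.

circSponge implements:

1. **BSJ detection** — terminal anchors (20 nt) of each read are matched
   exactly against a k-mer genome index; head-to-tail anchor pairs are
   extended toward the read interior (≤ 1 mismatch) and the best breakpoint
   defines the junction, required to carry the canonical splice flanks
   `AG..GT` (`AC..CT` for minus-strand circles, read on the plus strand).
   Stringency filters: ≥ 2 uniquely-anchored supporting fragments per
   sample, junction-window Phred ≥ 35, unambiguous breakpoint, and presence
   in ≥ 30 of 40 samples at base-exact coordinates.
2. **Cataloguing** — abundance as CPM = BSJ reads / raw reads × 10⁶;
   classification by genomic co-location (CDS, 5'UTR, 3'UTR, intronic,
   intergenic, largest-overlap rule); hotspot genes (≥ 5 circRNA isoforms);
   same-assembly catalogue comparison.
3. **Sponge network** — on log₂(x+1) abundances, all-pairs Pearson
   correlation filtered by PCIT: for each trio (x, y, z) the first-order
   partials r_xy·z = (r_xy − r_xz r_yz)/√((1−r_xz²)(1−r_yz²)) define a
   tolerance ε = mean(r_xy·z/r_xy, r_xz·y/r_xz, r_yz·x/r_yz), and the x–y
   edge is dropped when |r_xy| ≤ |ε r_xz| and |r_xy| ≤ |ε r_yz| for some z.
   In parallel, a seed-anchored complementarity scan (perfect Watson–Crick
   at miRNA positions 2–7, weighted ungapped score over the full miRNA,
   G:U wobbles allowed, junction-spanning sites via circular extension)
   predicts target sites. A final sponge edge must be PCIT-significant,
   **negatively** correlated, and carry ≥ 1 site.
4. **Motility association** — traits (motile %, VCL, VSL, VAP) are
   residualised on farm, age-class and season-year fixed effects by OLS;
   each circRNA's CPM is screened against the residuals by Pearson r with
   two-sided p from t = r√((n−2)/(1−r²)); age effects are tested by
   Wilcoxon rank-sum on per-sample circRNA count and mean abundance.

## Worked example

Simulate a compact 40-sample study (2 × 80 kb contigs, 8 planted circles,
3 planted sponge pairs), run detection, cataloguing, the sponge network and
the motility screen:

```r
library(circSponge)

cfg <- simConfig(seed = 1, n_samples = 40, n_contigs = 2,
                 contig_length = 80000, n_genes = 8,
                 n_circ = c(CDS = 4, `5UTR` = 1, `3UTR` = 1,
                            intronic = 1, intergenic = 1),
                 reads_per_sample = 2000, n_mirnas = 8, n_sponge_pairs = 3)
st <- simulateSpongeStudy(cfg, outDir = tempdir())

idx   <- buildGenomeIndex(st$genome, 20)
pars  <- detectionParams()
cands <- Map(function(f, s) filterCandidates(callSample(f, idx, pars, s), pars),
             st$manifest$fastq_1, st$manifest$sample_id)
names(cands) <- st$manifest$sample_id
mg     <- mergeSamples(cands, min_samples = 30)
rawTot <- setNames(st$manifest$total_reads, st$manifest$sample_id)
ctl    <- circCatalog(mg$junctions, mg$counts, rawTot, st$genome)
ctl
#> CircCatalog: 8 circRNA(s) x 40 sample(s)
#>   classes: 3UTR=1, 5UTR=1, CDS=4, intergenic=1, intronic=1
```

All 8 planted circles are recovered at base-exact coordinates and classified
correctly. The summary's top entries print display coordinates and CPM:

```r
summarizeCatalog(ctl, top_n = 3)$top[, c(1:5, 6)]
#>     circ_id       coordinates strand      class host_gene mean_cpm
#> 1 circ_0001   chr1:3796..4185      -        CDS   gene001    13701
#> 2 circ_0004 chr1:12959..13086      + intergenic      <NA>    12849
#> 3 circ_0002   chr1:3796..6440      -        CDS   gene001    11472
```

(CPM is large here only because the toy libraries have 2,000 reads.) The
sponge network intersects PCIT-negative co-abundance with predicted sites:

```r
exo  <- circClass(ctl) %in% c("CDS", "5UTR", "3UTR")
hits <- scanTargets(st$mirnaSeqs, circSequences(ctl, st$genome)[exo])
net  <- buildSpongeNetwork(circCpm(ctl)[exo, ],
                           normalizeCpm(st$mirnaCounts, rawTot), hits)
net
#> SpongeNetwork: 48 screened pair(s); 3 in final network
finalNetwork(net)[, c("circ_id", "mirna_id", "pearson_r", "n_sites")]
#>      circ_id mirna_id pearson_r n_sites
#> 6  circ_0001   miR-06    -0.567       1
#> 25 circ_0006   miR-01    -0.593       1
#> 34 circ_0007   miR-02    -0.459       1
```

Exactly the 3 planted sponge pairs survive: each shows the negative
co-abundance written in by the generator and the seed site planted in its
circle sequence. Finally, the motility screen on fixed-effect-corrected
traits:

```r
corr  <- correctPhenotypes(st$phenotypes)
assoc <- correlateAbundance(circCpm(ctl), corr)
head(assoc[order(assoc$p_value), ], 1)
#>     circ_id trait pearson_r p_value significant
#> 9 circ_0001   vcl     0.493 0.00123        TRUE
```

The top hit is one of the generator's causal circles (coefficient 2 per
log₂ abundance unit on VCL); at p < 0.05 with 104 circRNA–trait pairs a few
additional flags are expected by chance, since the screen is deliberately
uncorrected.

## Documentation

`vignettes/circSponge-methods.Rmd` describes the detection model and its
assumptions, every tunable parameter with its default and rationale, what
the synthetic data does and does not emulate, numerical guards, and known
limitations.
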