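# Generator: determinism, structural invariants of the toy genome, planted
# circle geometry, read construction, miRNA coupling and phenotypes.

test_that("generator output is byte-identical under a fixed seed", {
  cfg <- tinyConfig(seed = 42L)
  g1 <- generateGenome(cfg)
  g2 <- generateGenome(cfg)
  expect_identical(as.character(contigSeqs(g1)), as.character(contigSeqs(g2)))
  expect_identical(geneAnnotation(g1), geneAnnotation(g2))

  p1 <- plantCircRNAs(g1, cfg); p2 <- plantCircRNAs(g2, cfg)
  expect_identical(trueAbundance(p1$truths), trueAbundance(p2$truths))
  expect_identical(junctionKeys(junctions(p1$truths)),
                   junctionKeys(junctions(p2$truths)))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  small <- tinyConfig(seed = 42L, n_samples = 2L, reads_per_sample = 100L)
  gp <- plantCircRNAs(generateGenome(small), small)
  simulateReads(gp$genome, gp$truths, small, d1)
  simulateReads(gp$genome, gp$truths, small, d2)
  f1 <- sort(list.files(d1, "fastq$", full.names = TRUE))
  f2 <- sort(list.files(d2, "fastq$", full.names = TRUE))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("a zero-gene config yields contigs with empty annotation", {
  cfg <- simConfig(seed = 3L, n_genes = 0L, n_contigs = 2L,
                   contig_length = 5000L, n_circ = c(intergenic = 1L),
                   n_samples = 2L, reads_per_sample = 50L,
                   n_sponge_pairs = 0L)
  gp <- generateGenome(cfg)
  expect_length(geneAnnotation(gp), 0L)
  expect_length(contigSeqs(gp), 2L)
  # exonic circles on a gene-less genome are a placement error
  expect_error(plantCircRNAs(gp, simConfig(seed = 3L, n_genes = 0L,
                                           n_circ = c(CDS = 1L))),
               "no genes")
})

test_that("every annotated interval lies inside its contig and introns carry
           canonical splice dinucleotides on the gene strand", {
  st <- smallStudy()
  ann <- geneAnnotation(st$genome)
  contigs <- as.character(contigSeqs(st$genome))
  lens <- nchar(contigs)[match(as.character(GenomicRanges::seqnames(ann)),
                               names(contigs))]
  expect_true(all(GenomicRanges::start(ann) >= 1L))
  expect_true(all(GenomicRanges::end(ann) <= lens))

  ex <- ann[S4Vectors::mcols(ann)$feature == "exon"]
  for (g in unique(S4Vectors::mcols(ex)$gene_id)) {
    gex <- ex[S4Vectors::mcols(ex)$gene_id == g]
    o <- order(GenomicRanges::start(gex))
    gex <- gex[o]
    strand <- as.character(BiocGenerics::strand(gex))[1L]
    cs <- contigs[[as.character(GenomicRanges::seqnames(gex))[1L]]]
    # 5'->3' ordering of exon ranks matches the strand
    ranks <- S4Vectors::mcols(gex)$exon_rank
    expect_identical(ranks,
                     if (strand == "+") seq_along(ranks)
                     else rev(seq_along(ranks)))
    for (k in seq_len(length(gex) - 1L)) {
      i0 <- GenomicRanges::end(gex)[k] + 1L
      i1 <- GenomicRanges::start(gex)[k + 1L] - 1L
      first2 <- substr(cs, i0, i0 + 1L)
      last2 <- substr(cs, i1 - 1L, i1)
      if (strand == "+") {
        expect_identical(first2, "GT"); expect_identical(last2, "AG")
      } else {
        expect_identical(first2, "CT"); expect_identical(last2, "AC")
      }
    }
  }
})

test_that("planted circles honour the requested class counts and geometry", {
  st <- smallStudy()
  tr <- st$truths
  cls <- S4Vectors::mcols(junctions(tr))$true_class
  expect_identical(as.integer(table(factor(cls, names(st$cfg$n_circ)))),
                   unname(st$cfg$n_circ))
  # spliced length = sum of exon block widths
  bl <- exonBlocks(tr)
  expect_identical(S4Vectors::mcols(junctions(tr))$spliced_length,
                   vapply(seq_along(bl), function(i)
                     sum(IRanges::width(bl[[i]])), 0L))
  # every planted junction carries AG..GT (or AC..CT on '-') flanks
  contigs <- as.character(contigSeqs(st$genome))
  gr <- junctions(tr)
  for (i in seq_along(gr)) {
    cs <- contigs[[as.character(GenomicRanges::seqnames(gr))[i]]]
    A <- GenomicRanges::start(gr)[i]; E <- GenomicRanges::end(gr)[i]
    acc <- substr(cs, A - 2L, A - 1L)
    don <- substr(cs, E + 1L, E + 2L)
    if (as.character(BiocGenerics::strand(gr))[i] == "+") {
      expect_identical(acc, "AG"); expect_identical(don, "GT")
    } else {
      expect_identical(acc, "AC"); expect_identical(don, "CT")
    }
  }
})

test_that("BSJ reads reconstruct as circle suffix + prefix and the manifest
           counts FASTQ records exactly", {
  st <- smallStudy()
  circ <- as.character(circSequences(st$truths, st$genome))
  S <- circ[[1L]]
  r <- bsjRead(S, 30L, 75L)
  expect_identical(r, paste0(substr(S, nchar(S) - 29L, nchar(S)),
                             substr(S, 1L, 45L)))
  d <- withr::local_tempdir()
  cfg <- tinyConfig(seed = 13L, n_samples = 2L, reads_per_sample = 120L)
  pl <- plantCircRNAs(generateGenome(cfg), cfg)
  man <- simulateReads(pl$genome, pl$truths, cfg, d)
  for (s in seq_len(nrow(man))) {
    n_rec <- length(readLines(man$fastq_1[s])) / 4L
    expect_identical(as.integer(man$total_reads[s]), as.integer(n_rec))
  }
})

test_that("a circle with zero abundance emits no BSJ reads", {
  cfg <- tinyConfig(seed = 7L, n_samples = 1L, reads_per_sample = 50L,
                    abundance_floor = 0)
  pl <- plantCircRNAs(generateGenome(cfg), cfg)
  tr <- pl$truths
  tr@abundance[] <- 0
  d <- withr::local_tempdir()
  man <- simulateReads(pl$genome, tr, cfg, d)
  expect_identical(man$total_reads[1L], 50L)
})

test_that("planted sponge pairs put the seed complement into the circle and
           the coupling reaches r = -1 in the noise-free limit", {
  st <- smallStudy()
  sp <- spongePairs(st$truths)
  expect_gt(nrow(sp), 0L)
  circ <- as.character(circSequences(st$truths, st$genome))
  mir <- chartr("U", "T", as.character(st$mirnaSeqs))
  for (j in seq_len(nrow(sp))) {
    seedRc <- oracleRevcomp(substr(mir[[sp$mirna_id[j]]], 2L, 8L))
    expect_true(grepl(seedRc, circ[[sp$circ_id[j]]], fixed = TRUE))
  }
  # noise-free coupling: expected log2 profiles are exactly affine in the
  # summed circle log2 abundance
  cfg0 <- tinyConfig(seed = 19L, n_samples = 12L,
                     mirna_coupling_noise_sd = 0)
  pl <- plantCircRNAs(generateGenome(cfg0), cfg0)
  mi <- simulateMirnas(pl$genome, pl$truths, cfg0)
  sp0 <- spongePairs(mi$truths)
  x <- log2(trueAbundance(mi$truths)[sp0$circ_id[1L], ])
  y <- mi$profiles[sp0$mirna_id[1L], ]
  expect_equal(oraclePearson(x, y), -1, tolerance = 1e-12)
})

test_that("non-sponged miRNA vs circle correlations are null-calibrated", {
  cfg <- tinyConfig(seed = 23L, n_samples = 40L, n_sponge_pairs = 0L)
  pl <- plantCircRNAs(generateGenome(cfg), cfg)
  mi <- simulateMirnas(pl$genome, pl$truths, cfg)
  lam <- log2(trueAbundance(mi$truths))
  prof <- mi$profiles
  crit <- qt(0.975, df = 40L - 2L)
  rej <- 0L; tot <- 0L
  for (rep in seq_len(200L)) {
    i <- (rep %% nrow(lam)) + 1L
    j <- (rep %% nrow(prof)) + 1L
    # fresh independent noise replicate around the same design
    set.seed(1000L + rep)
    x <- lam[i, ] + rnorm(ncol(lam), 0, 0.3)
    y <- prof[j, sample(ncol(prof))]
    r <- oraclePearson(x, y)
    t <- abs(r) * sqrt((40 - 2) / (1 - r^2))
    rej <- rej + (t > crit); tot <- tot + 1L
  }
  # binomial 99% band around 5% of 200
  expect_gt(rej / tot, 0.05 - 2.576 * sqrt(0.05 * 0.95 / 200))
  expect_lt(rej / tot, 0.05 + 2.576 * sqrt(0.05 * 0.95 / 200))
})

test_that("phenotypes reduce to the intercept in the all-zero limit and the
           causal term is exactly affine; motile % is clipped", {
  cfg <- tinyConfig(seed = 29L, n_samples = 8L, fixed_effect_sd = 0,
                    trait_noise_sd = c(motile_pct = 0, vcl = 0, vsl = 0,
                                       vap = 0),
                    n_causal_circ = 0L)
  pl <- plantCircRNAs(generateGenome(cfg), cfg)
  ph <- simulatePhenotypes(pl$truths, cfg)
  for (tr in c("motile_pct", "vcl", "vsl", "vap"))
    expect_equal(ph[[tr]], rep(cfg$trait_intercepts[[tr]], 8L),
                 tolerance = 1e-12)

  cfg2 <- tinyConfig(seed = 29L, n_samples = 8L, fixed_effect_sd = 0,
                     trait_noise_sd = c(motile_pct = 0, vcl = 0, vsl = 0,
                                        vap = 0),
                     n_causal_circ = 1L, pheno_effect_size = 2)
  pl2 <- plantCircRNAs(generateGenome(cfg2), cfg2)
  ph2 <- simulatePhenotypes(pl2$truths, cfg2)
  eff <- phenoEffects(pl2$truths)
  y <- ph2[[eff$trait[1L]]]
  x <- log2(trueAbundance(pl2$truths)[eff$circ_id[1L], ])
  if (eff$trait[1L] == "motile_pct") {
    ok <- y < 100 & y > 0
    expect_gt(sum(ok), 2L)
    expect_equal(y[ok],
                 unname((cfg2$trait_intercepts[["motile_pct"]] + 2 * x)[ok]),
                 tolerance = 1e-9)
  } else {
    expect_equal(y, unname(cfg2$trait_intercepts[[eff$trait[1L]]] + 2 * x),
                 tolerance = 1e-9)
  }

  # clipping at 100
  cfg3 <- tinyConfig(seed = 31L, n_samples = 6L, fixed_effect_sd = 0,
                     trait_noise_sd = c(motile_pct = 0, vcl = 0, vsl = 0,
                                        vap = 0),
                     n_causal_circ = 0L,
                     trait_intercepts = c(motile_pct = 250, vcl = 43.7,
                                          vsl = 26.4, vap = 32.4))
  pl3 <- plantCircRNAs(generateGenome(cfg3), cfg3)
  ph3 <- simulatePhenotypes(pl3$truths, cfg3)
  expect_true(all(ph3$motile_pct == 100))
})
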