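# BSJ detection: k-mer index correctness, per-read junction calls against a
# brute-force splice-scan oracle, aggregation, filter semantics, and the
# multi-sample merge.

test_that("k-mer index lookups match direct enumeration", {
  gi <- buildGenomeIndex(Biostrings::DNAStringSet(c(chrA = "ACGTACGT")), 4L)
  h <- lookupKmer(gi, "ACGT")
  expect_identical(sort(h$pos[h$strand == "+"]), c(1L, 5L))
  # ACGT is its own reverse complement: the minus-strand hits coincide
  expect_identical(sort(h$pos[h$strand == "-"]), c(1L, 5L))
  expect_identical(nrow(lookupKmer(gi, "AAAA")), 0L)

  set.seed(5)
  contig <- paste(sample(c("A", "C", "G", "T"), 10000L, TRUE), collapse = "")
  idx <- buildGenomeIndex(Biostrings::DNAStringSet(c(c1 = contig)), 20L)
  for (q in seq_len(100L)) {
    p0 <- sample.int(9981L, 1L)
    kmer <- substr(contig, p0, p0 + 19L)
    got <- lookupKmer(idx, kmer)
    expect_identical(sort(got$pos[got$strand == "+"]),
                     sort(gregexprAll(kmer, contig)))
    expect_identical(sort(got$pos[got$strand == "-"]),
                     sort(gregexprAll(oracleRevcomp(kmer), contig)))
  }
  expect_error(buildGenomeIndex(
    Biostrings::DNAStringSet(c(cS = "ACGT")), 20L), "shortest contig")
})

test_that("reads from planted circles are detected at the exact coordinates
           and colinear reads are not", {
  st <- smallStudy()
  idx <- buildGenomeIndex(st$genome, 20L)
  p <- detectionParams()
  circ <- as.character(circSequences(st$truths, st$genome))
  gr <- junctions(st$truths)
  for (i in seq_along(gr)) {
    r <- bsjRead(circ[[i]], 33L, 75L)
    hit <- detectBsjRead(r, idx, p, strrep("F", 75L))
    expect_false(is.null(hit))
    expect_identical(hit$contig, as.character(GenomicRanges::seqnames(gr))[i])
    expect_identical(hit$strand, as.character(BiocGenerics::strand(gr))[i])
    expect_identical(hit$start, GenomicRanges::start(gr)[i])
    expect_identical(hit$end, GenomicRanges::end(gr)[i])
    expect_true(hit$anchors_unique)
    expect_equal(hit$junction_phred, 37)
  }
  # colinear fragments (either orientation) never produce a junction
  contigs <- as.character(contigSeqs(st$genome))
  set.seed(8)
  for (q in seq_len(25L)) {
    cs <- contigs[[sample(length(contigs), 1L)]]
    p0 <- sample.int(nchar(cs) - 80L, 1L)
    frag <- substr(cs, p0, p0 + 74L)
    if (q %% 2L == 0L) frag <- oracleRevcomp(frag)
    expect_null(detectBsjRead(frag, idx, p))
  }
})

test_that("microhomology at the junction makes the breakpoint ambiguous when
           no splice signal can arbitrate", {
  set.seed(99)
  left <- paste(sample(c("A", "C", "G", "T"), 150L, TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 150L, TRUE), collapse = "")
  # circle spans [A..E] = [11..110] on a 310-nt contig; base after the donor
  # equals the first circle base, so splitting at b or b+1 both match
  contig <- paste0(substr(left, 1L, 10L), substr(right, 1L, 100L),
                   substr(left, 11L, 150L))
  A <- 11L; E <- 110L
  first <- substr(contig, A, A)
  substr(contig, E + 1L, E + 1L) <- first
  S <- substr(contig, A, E)
  r <- bsjRead(S, 37L, 75L)
  idx <- buildGenomeIndex(Biostrings::DNAStringSet(c(cm = contig)), 20L)
  pOff <- detectionParams(require_canonical_splice = FALSE)
  hit <- detectBsjRead(r, idx, pOff)
  expect_true(isTRUE(hit$breakpoint_ambiguous))
  # ambiguous reads never reach the aggregate
  d <- withr::local_tempdir()
  f <- file.path(d, "amb.fastq")
  writeLines(c("@r1", r, "+", strrep("F", 75L)), f)
  expect_identical(nrow(callSample(f, idx, pOff, "s1")), 0L)
})

test_that("per-read calls agree with the exhaustive splice-scan oracle", {
  st <- smallStudy()
  idx <- buildGenomeIndex(st$genome, 20L)
  p <- detectionParams()
  contigs <- as.character(contigSeqs(st$genome))
  circ <- as.character(circSequences(st$truths, st$genome))
  set.seed(17)
  reads <- character(0)
  for (rep in seq_len(60L)) {
    ci <- sample(length(circ), 1L)
    reads <- c(reads, bsjRead(circ[[ci]], sample(20:55, 1L), 75L))
  }
  for (rep in seq_len(30L)) {   # colinear decoys
    cs <- contigs[[sample(length(contigs), 1L)]]
    p0 <- sample.int(nchar(cs) - 80L, 1L)
    reads <- c(reads, substr(cs, p0, p0 + 74L))
  }
  for (r in reads) {
    want <- oracleSpliceScan(r, contigs, 20L, requireSignal = TRUE)
    got <- detectBsjRead(r, idx, p)
    if (is.null(want)) {
      expect_true(is.null(got) || isTRUE(got$breakpoint_ambiguous))
    } else {
      expect_false(is.null(got))
      expect_identical(got[c("contig", "strand", "start", "end")],
                       want[c("contig", "strand", "start", "end")])
    }
  }
})

test_that("support aggregates per junction and per fragment", {
  st <- smallStudy()
  idx <- buildGenomeIndex(st$genome, 20L)
  p <- detectionParams()
  circ <- as.character(circSequences(st$truths, st$genome))
  d <- withr::local_tempdir()
  f <- file.path(d, "two.fastq")
  r1 <- bsjRead(circ[[1L]], 25L, 75L)
  r2 <- bsjRead(circ[[1L]], 40L, 75L)
  writeLines(c("@a", r1, "+", strrep("F", 75L),
               "@b", r2, "+", strrep("F", 75L)), f)
  cand <- callSample(f, idx, p, "s1")
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$support, 2L)
  expect_identical(cand$unique_support, 2L)

  # paired mates with the same fragment name count once
  f1 <- file.path(d, "p_1.fastq"); f2 <- file.path(d, "p_2.fastq")
  writeLines(c("@frag", r1, "+", strrep("F", 75L)), f1)
  writeLines(c("@frag", oracleRevcomp(r2), "+", strrep("F", 75L)), f2)
  cand2 <- callSample(c(f1, f2), idx, p, "s1")
  expect_identical(cand2$support, 1L)

  # empty FASTQ
  fe <- file.path(d, "empty.fastq"); file.create(fe)
  expect_identical(nrow(callSample(fe, idx, p, "s1")), 0L)
})

test_that("one simulated sample recovers nearly all well-supported circles", {
  cfg <- simConfig(seed = 37L, n_samples = 1L, n_genes = 20L,
                   n_circ = c(CDS = 12L, `5UTR` = 4L, `3UTR` = 4L),
                   reads_per_sample = 1000L, circ_meanlog = log(8),
                   n_sponge_pairs = 0L)
  pl <- plantCircRNAs(generateGenome(cfg), cfg)
  d <- withr::local_tempdir()
  man <- simulateReads(pl$genome, pl$truths, cfg, d)
  idx <- buildGenomeIndex(pl$genome, 20L)
  cand <- callSample(man$fastq_1[1L], idx, detectionParams(), "S01")
  got <- paste(cand$contig, cand$strand, cand$start, cand$end)
  want <- junctionKeys(junctions(pl$truths))
  expect_gte(sum(want %in% got), 19L)
  expect_identical(sum(!(got %in% want)), 0L)
})

test_that("filters implement the exact support/quality/ambiguity semantics
           and are monotone in their thresholds", {
  base <- data.frame(contig = "c1", strand = "+", start = 100L, end = 500L,
                     support = 5L, unique_support = 5L,
                     junction_phred = 37, splice_signal = "AG..GT",
                     breakpoint_ambiguous = FALSE, sample_id = "S01")
  p <- detectionParams()
  one <- base; one$unique_support <- 1L
  expect_identical(nrow(filterCandidates(one, p)), 0L)
  edge <- base; edge$unique_support <- 2L; edge$junction_phred <- 35
  expect_identical(nrow(filterCandidates(edge, p)), 1L)
  low <- base; low$unique_support <- 5L; low$junction_phred <- 34
  expect_identical(nrow(filterCandidates(low, p)), 0L)
  amb <- base; amb$breakpoint_ambiguous <- TRUE
  expect_identical(nrow(filterCandidates(amb, p)), 0L)
  wide <- base; wide$end <- base$start + 2000000L
  expect_identical(nrow(filterCandidates(wide, p)), 0L)

  set.seed(21)
  rand <- data.frame(contig = "c1", strand = "+",
                     start = seq(100L, 4100L, by = 200L), end = 0L,
                     support = sample(1:6, 21L, TRUE),
                     unique_support = 0L,
                     junction_phred = runif(21L, 30, 40),
                     splice_signal = "AG..GT",
                     breakpoint_ambiguous = FALSE, sample_id = "S01")
  rand$end <- rand$start + sample(200:900, 21L, TRUE)
  rand$unique_support <- pmin(rand$support, sample(1:6, 21L, TRUE))
  prev <- NULL
  for (ms in 0:6) {
    cur <- filterCandidates(rand, detectionParams(min_unique_support = ms))
    if (!is.null(prev)) expect_true(all(cur$start %in% prev$start))
    prev <- cur
  }
  prev <- NULL
  for (mq in c(30, 33, 35, 38, 41)) {
    cur <- filterCandidates(rand, detectionParams(min_junction_phred = mq))
    if (!is.null(prev)) expect_true(all(cur$start %in% prev$start))
    prev <- cur
  }
})

test_that("the multi-sample merge applies the presence threshold exactly", {
  mk <- function(junc, support = 3L) data.frame(
    contig = junc[1L], strand = junc[2L],
    start = as.integer(junc[3L]), end = as.integer(junc[4L]),
    support = support, unique_support = support,
    junction_phred = 37, splice_signal = "AG..GT",
    breakpoint_ambiguous = FALSE, sample_id = NA_character_)
  jA <- c("c1", "+", "100", "600")
  jB <- c("c1", "-", "2000", "2600")
  per <- lapply(seq_len(40L), function(s) {
    out <- mk(jA)[0, ]
    if (s <= 30L) out <- rbind(out, mk(jA, s))
    if (s <= 29L) out <- rbind(out, mk(jB))
    out
  })
  names(per) <- sprintf("S%02d", 1:40)
  mg <- mergeSamples(per, min_samples = 30L)
  expect_identical(length(mg$junctions), 1L)
  expect_identical(GenomicRanges::start(mg$junctions), 100L)
  # counts carry per-sample support, 0 where undetected
  expect_identical(unname(mg$counts[1L, "S05"]), 5L)
  expect_identical(unname(mg$counts[1L, "S31"]), 0L)

  # identical copies of one sample: merged set equals that sample's list
  copies <- per[rep(1L, 5L)]
  names(copies) <- paste0("T", 1:5)
  mg2 <- mergeSamples(copies, min_samples = 5L)
  expect_identical(length(mg2$junctions), 2L)

  noname <- per; names(noname) <- NULL
  expect_error(mergeSamples(noname), "named list")
})
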