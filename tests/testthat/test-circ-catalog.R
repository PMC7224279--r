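# Catalogue: CPM arithmetic, genomic classification, hotspot rule, summary
# and catalogue comparison.

test_that("CPM normalisation matches the direct formula", {
  expect_equal(normalizeCpm(matrix(10, 1, 1), 5e6)[1, 1], 2.0)
  expect_equal(normalizeCpm(matrix(0, 1, 1), 123)[1, 1], 0.0)
  set.seed(4)
  cnt <- matrix(rpois(100, 8), 20, 5,
                dimnames = list(NULL, paste0("S", 1:5)))
  tot <- setNames(runif(5, 1e4, 1e6), paste0("S", 1:5))
  expect_equal(normalizeCpm(cnt, tot), oracleCpm(cnt, tot),
               tolerance = 1e-12)
  expect_error(normalizeCpm(cnt, c(tot[-5], S5 = 0)), "S5")
  expect_error(normalizeCpm(cnt, tot[1:3]), "missing|length")
})

test_that("row sums recover integer counts from CPM", {
  st <- smallStudy()
  oc <- observedCircCounts(st$truths, st$cfg)
  cpm <- normalizeCpm(oc$counts, oc$raw_totals)
  back <- sweep(cpm, 2L, oc$raw_totals, "*") / 1e6
  expect_lt(max(abs(back - oc$counts)), 1e-9)
})

test_that("classification handles the canonical cases on a hand-built
           annotation", {
  ann <- miniAnnotation()
  # two CDS-only exons
  g1 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(100, 400),
                               strand = "+")
  c1 <- classifyCircRNAs(g1, ann)
  expect_identical(c1$class, "CDS")
  expect_identical(c1$host_gene, "gA")
  expect_identical(c1$n_exons, 2L)
  expect_identical(c1$spliced_length, 202L)
  # gene-free gap
  c2 <- classifyCircRNAs(GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(1000, 1200), strand = "+"), ann)
  expect_identical(c2$class, "intergenic")
  expect_true(is.na(c2$host_gene))
  expect_identical(c2$n_exons, 0L)
  # wholly inside the gA intron
  c3 <- classifyCircRNAs(GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(210, 290), strand = "+"), ann)
  expect_identical(c3$class, "intronic")
  expect_identical(c3$host_gene, "gA")
  expect_identical(c3$n_exons, 0L)
  # 3'UTR exon of gB
  c4 <- classifyCircRNAs(GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(600, 700), strand = "+"), ann)
  expect_identical(c4$class, "3UTR")
  expect_identical(c4$host_gene, "gB")
})

test_that("classification is deterministic under annotation permutation and
           agrees with the planted truth", {
  st <- smallStudy()
  ann <- geneAnnotation(st$genome)
  gr <- junctions(st$truths)
  c1 <- classifyCircRNAs(gr, ann)
  set.seed(12)
  c2 <- classifyCircRNAs(gr, ann[sample(length(ann))])
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_identical(c1$class, S4Vectors::mcols(gr)$true_class)
  expect_identical(c1$host_gene[c1$class != "intergenic"],
                   S4Vectors::mcols(gr)$host_gene[c1$class != "intergenic"])
  expect_identical(c1$n_exons[c1$class %in% c("CDS", "5UTR", "3UTR")],
                   S4Vectors::mcols(gr)$n_exons[
                     c1$class %in% c("CDS", "5UTR", "3UTR")])
})

test_that("hotspot flagging follows the >= 5 distinct-isoform rule", {
  mkCat <- function(nA, nB) {
    n <- nA + nB
    gr <- GenomicRanges::GRanges("c1",
                                 IRanges::IRanges(seq_len(n) * 1000L,
                                                  seq_len(n) * 1000L + 500L),
                                 strand = "+")
    counts <- matrix(5L, n, 2L, dimnames = list(NULL, c("S1", "S2")))
    ctl <- circCatalog(gr, counts, c(S1 = 1e5, S2 = 1e5),
                       GenomicRanges::GRanges())
    rd <- SummarizedExperiment::rowData(ctl)
    rd$class <- "CDS"
    rd$host_gene <- rep(c("geneA", "geneB"), c(nA, nB))
    rd$n_exons <- 1L
    SummarizedExperiment::rowData(ctl) <- rd
    ctl
  }
  hs <- detectHotspots(mkCat(8L, 4L))
  expect_identical(hs$n_isoforms[hs$gene_id == "geneA"], 8L)
  expect_true(hs$hotspot[hs$gene_id == "geneA"])
  expect_false(hs$hotspot[hs$gene_id == "geneB"])
  empty <- mkCat(1L, 1L)
  rd <- SummarizedExperiment::rowData(empty)
  rd$class <- "intergenic"; rd$host_gene <- NA_character_; rd$n_exons <- 0L
  SummarizedExperiment::rowData(empty) <- rd
  expect_identical(nrow(detectHotspots(empty)), 0L)
})

test_that("catalogue summary fractions and top-N ordering are exact", {
  gr <- GenomicRanges::GRanges("c1",
                               IRanges::IRanges(c(1, 2, 3, 4) * 1000L,
                                                c(1, 2, 3, 4) * 1000L + 300L),
                               strand = "+")
  counts <- matrix(c(5L, 50L, 20L, 20L), 4L, 1L,
                   dimnames = list(NULL, "S1"))
  ctl <- circCatalog(gr, counts, c(S1 = 1e6), GenomicRanges::GRanges())
  rd <- SummarizedExperiment::rowData(ctl)
  rd$class <- c("CDS", "CDS", "intronic", "intergenic")
  rd$host_gene <- c("g1", "g2", "g3", NA)
  rd$n_exons <- c(1L, 1L, 0L, 0L)
  SummarizedExperiment::rowData(ctl) <- rd
  s <- summarizeCatalog(ctl, top_n = 4L)
  expect_equal(sum(s$class_fractions), 1)
  expect_equal(unname(s$class_fractions[c("CDS", "intronic", "intergenic")]),
               c(0.5, 0.25, 0.25))
  expect_equal(unname(s$class_fractions[c("5UTR", "3UTR")]), c(0, 0))
  expect_equal(s$frac_exonic_short, 1.0)   # all exonic < 400 nt
  # oracle sort: decreasing mean CPM, coordinate tie-break
  rdf <- as.data.frame(SummarizedExperiment::rowData(ctl))
  o <- order(-rdf$mean_cpm, as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr))
  expect_identical(s$top$circ_id, rdf$circ_id[o])

  st <- smallStudy()
  oc <- observedCircCounts(st$truths, st$cfg)
  ctl2 <- circCatalog(junctions(st$truths), oc$counts, oc$raw_totals,
                      st$genome)
  s2 <- summarizeCatalog(ctl2, top_n = 5L)
  rdf2 <- as.data.frame(SummarizedExperiment::rowData(ctl2))
  gr2 <- SummarizedExperiment::rowRanges(ctl2)
  o2 <- order(-rdf2$mean_cpm, as.character(GenomicRanges::seqnames(gr2)),
              GenomicRanges::start(gr2), GenomicRanges::end(gr2))
  expect_identical(s2$top$circ_id, rdf2$circ_id[head(o2, 5L)])
})

test_that("catalogue comparison honours the boundary tolerance", {
  gr <- GenomicRanges::GRanges(c("c1", "c1", "c2"),
                               IRanges::IRanges(c(100, 900, 400),
                                                c(600, 1500, 800)),
                               strand = c("+", "-", "+"))
  same <- compareCatalogs(gr, gr)
  expect_equal(same$frac_a_in_b, 1.0)
  expect_equal(same$frac_b_in_a, 1.0)
  far <- GenomicRanges::shift(gr, 5000L)
  expect_equal(compareCatalogs(gr, far)$frac_a_in_b, 0.0)
  near <- GenomicRanges::shift(gr, 2L)
  expect_equal(compareCatalogs(gr, near, 5L)$frac_a_in_b, 1.0)
  expect_equal(compareCatalogs(gr, near, 5L)$frac_b_in_a, 1.0)
  expect_equal(compareCatalogs(gr, near, 0L)$frac_a_in_b, 0.0)
})

test_that("catalogue validity enforces the CPM identity and class rules", {
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(100, 600),
                               strand = "+")
  counts <- matrix(5L, 1, 1, dimnames = list(NULL, "S1"))
  ctl <- circCatalog(gr, counts, c(S1 = 1e5), GenomicRanges::GRanges())
  expect_true(methods::validObject(ctl))
  bad <- ctl
  SummarizedExperiment::assay(bad, "cpm")[1, 1] <- 999
  expect_error(methods::validObject(bad), "inconsistent")
  bad2 <- ctl
  rd <- SummarizedExperiment::rowData(bad2)
  rd$host_gene <- "gX"   # intergenic with a host gene
  SummarizedExperiment::rowData(bad2) <- rd
  expect_error(methods::validObject(bad2), "intergenic")
})
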