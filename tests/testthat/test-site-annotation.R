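test_that("region classification follows interval containment with half-open BED ends", {
  gene <- toyGene()
  # BED representation of exon 1 is [100, 200): genomic 101..200 inclusive.
  # Position 200 is the last exonic base; 201 is intronic.
  got <- classifyRegion(c(150L, 200L, 201L, 250L, 301L, 50L, 450L), gene,
                        toyRepeats())
  expect_equal(got$region,
               c("exon", "exon", "intron", "intron", "exon",
                 "intergenic", "intergenic"))
  expect_equal(got$ltr_overlap, c(TRUE, FALSE, FALSE, FALSE, FALSE,
                                  FALSE, FALSE))
})

test_that("LTR overlap is an orthogonal flag restricted to configured names", {
  gene <- toyGene()
  # 355 overlaps an AluY repeat: exonic but not LTR-derived by default
  got <- classifyRegion(c(120L, 355L), gene, toyRepeats())
  expect_equal(got$region, c("exon", "exon"))
  expect_equal(got$ltr_overlap, c(TRUE, FALSE))
  gotAlu <- classifyRegion(355L, gene, toyRepeats(), ltrNames = "AluY")
  expect_true(gotAlu$ltr_overlap)
})

test_that("sites on another chromosome are a contract error", {
  sites <- SNVSites("chr9", 150L, "A", "G", 1L, 10L)
  expect_error(classifyRegion(sites, toyGene()), "different chromosome")
})

test_that("region labels partition the gene span and counts are conserved", {
  gene <- toyGene()
  pos <- 50:450
  got <- classifyRegion(pos, gene, toyRepeats())
  expect_equal(nrow(got), length(pos))
  counts <- table(got$region)
  expect_equal(sum(counts), length(pos))
  expect_equal(unname(counts["exon"]), 200L)     # two 100-bp exons
  expect_equal(unname(counts["intron"]), 100L)   # 201..300
})

# -- coding effect --------------------------------------------------------

# A 9-bp CDS starting with codons CCT (Pro), CAT..: synth genome built so
# the classic Pro codon examples land at known positions.
codingFixture <- function(strand = "+") {
  seqChars <- rep("A", 60)
  cds <- c("C", "C", "T", "G", "G", "G", "A", "A", "A")  # Pro Gly Lys
  if (strand == "+") {
    seqChars[21:29] <- cds
  } else {
    # reverse-complement of the CDS placed so minus-strand reading gives it
    seqChars[21:29] <- rev(unname(c(A = "T", C = "G", G = "C",
                                    T = "A")[cds]))
  }
  genome <- Biostrings::DNAStringSet(paste(seqChars, collapse = ""))
  names(genome) <- "synth1"
  gene <- GeneModel("cacna2d3_like", "tx1", "synth1", 21L, 29L,
                    strand = strand, cdsStarts = 21L, cdsEnds = 29L,
                    biotype = "protein_coding")
  list(genome = genome, gene = gene)
}

test_that("coding effect distinguishes synonymous from nonsynonymous changes", {
  fx <- codingFixture("+")
  sites <- SNVSites("synth1", c(23L, 22L, 26L), ref = c("T", "C", "G"),
                    alt = c("A", "A", "T"), ac = 1L, an = 10L)
  got <- classifyCodingEffect(sites, fx$gene, fx$genome)
  # CCT->CCA Pro->Pro synonymous; CCT->CAT Pro->His nonsynonymous;
  # GGG->GGT Gly->Gly synonymous
  expect_equal(got[siteTable(sites)$pos == 23L], "synonymous")
  expect_equal(got[siteTable(sites)$pos == 22L], "nonsynonymous")
  expect_equal(got[siteTable(sites)$pos == 26L], "synonymous")
})

test_that("coding effect is strand invariant", {
  plus <- codingFixture("+")
  minus <- codingFixture("-")
  # plus: position 23 = codon pos 3 of codon 1 (T), alt A -> synonymous.
  # minus: the same transcript base sits at genomic 27 (9 - 3 + 21), with
  # genome base A (complement T) and alt T (complement A).
  gotPlus <- classifyCodingEffect(
    SNVSites("synth1", 23L, "T", "A", 1L, 10L), plus$gene, plus$genome)
  gotMinus <- classifyCodingEffect(
    SNVSites("synth1", 27L, "A", "T", 1L, 10L), minus$gene, minus$genome)
  expect_equal(gotPlus, gotMinus)
  # and a nonsynonymous one: plus pos 22 (codon pos 2) <-> minus pos 28
  gotPlus2 <- classifyCodingEffect(
    SNVSites("synth1", 22L, "C", "A", 1L, 10L), plus$gene, plus$genome)
  gotMinus2 <- classifyCodingEffect(
    SNVSites("synth1", 28L, "G", "T", 1L, 10L), minus$gene, minus$genome)
  expect_equal(gotPlus2, "nonsynonymous")
  expect_equal(gotPlus2, gotMinus2)
})

test_that("stop gains are nonsynonymous and lncRNA exons are noncoding", {
  fx <- codingFixture("+")
  # codon 3 spans genomic 27..29 = AAA (Lys); A->T at 27 gives the stop TAA
  stopGain <- classifyCodingEffect(
    SNVSites("synth1", 27L, "A", "T", 1L, 10L), fx$gene, fx$genome)
  expect_equal(stopGain, "nonsynonymous")

  lnc <- toyGene(biotype = "lncRNA")
  genome <- Biostrings::DNAStringSet(paste(rep("A", 500), collapse = ""))
  names(genome) <- "synth1"
  got <- classifyCodingEffect(SNVSites("synth1", c(150L, 250L), "A", "G",
                                       1L, 10L), lnc, genome)
  expect_equal(got, c("noncoding", "not_applicable"))
})

test_that("reference mismatches against the genome are errors naming the position", {
  fx <- codingFixture("+")
  sites <- SNVSites("synth1", 23L, "G", "A", 1L, 10L)  # genome has T
  expect_error(classifyCodingEffect(sites, fx$gene, fx$genome),
               "synth1:23")
})

test_that("RepeatMasker .out files parse to repeat intervals", {
  out <- tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query     position in query    matching repeat",
    "score   div. del. ins.  sequence  begin end (left)     repeat class/family",
    "",
    "  463   11.8  0.0  0.0  synth1     1001  1460 (8000) +  LTR7       LTR/ERVL  1 460 (0) 1",
    "  300   15.0  0.2  0.0  synth1     2000  2399 (7000) +  HERV-H-int LTR/ERVL  1 400 (0) 2"),
    out)
  gr <- readRepeatMasker(out)
  expect_equal(length(gr), 2L)
  expect_equal(S4Vectors::mcols(gr)$repeat_name, c("LTR7", "HERV-H-int"))
  expect_equal(GenomicRanges::start(gr), c(1001L, 2000L))
  expect_equal(GenomicRanges::end(gr), c(1460L, 2399L))
})
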