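test_that("parsimony ancestral calls follow the outgroup-concordance rule", {
  expect_equal(inferAncestralState("A", "G", "G"),
               "substitution_on_human_lineage")
  expect_equal(inferAncestralState("G", "G", "G"), "no_change")
  expect_equal(inferAncestralState("T", "G", "A"), "excluded")  # discordant
  expect_equal(inferAncestralState("-", "G", "G"), "excluded")  # human gap
  expect_equal(inferAncestralState("A", "-", "A"), "excluded")  # outgroup gap
  expect_equal(inferAncestralState("A", "N", "N"), "excluded")  # ambiguous
})

# Hand-built 14-column toy alignment. Human coordinates start at 101;
# exon = 101..106, intron = 107..114 (single-exon toy gene for counting).
#   col:        1    2    3    4    5    6    7    8    9   10   11   12   13   14
#   human:      A    C    G    T    A    C    G    T    A    C    G    T    A    C
#   chimp:      A    G    G    T    A    C    G    T    C    C    -    T    A    T
#   bonobo:     A    G    G    T    A    C    G    T    T    C    -    T    A    T
# col 2: concordant difference in exon (SNS exon)
# col 9: discordant outgroups -> excluded
# col 11: outgroup gap -> excluded
# col 14: concordant difference in intron (SNS intron)
toyAlignment <- function() {
  TrioAlignment(human = "ACGTACGTACGTAC",
                chimp = "AGGTACGTCC-TAT",
                bonobo = "AGGTACGTTC-TAT",
                chrom = "synth1", humanStart = 101L)
}

toyAlnGene <- function() {
  GeneModel("toy_div", "toy_div_tx", "synth1", 101L, 106L,
            strand = "+", biotype = "lncRNA")
}

test_that("divergence and polymorphism counting on a hand-counted fixture", {
  aln <- toyAlignment()
  gene <- toyAlnGene()
  strata <- classifyRegion(101:114, gene)
  strata$region[strata$region == "intergenic"] <- "intron"  # toy: rest intronic
  noPoly <- SNVSites(character(0), integer(0), character(0), character(0),
                     integer(0), integer(0), sampleChromosomes = 100L)
  counts <- countDivergence(aln, noPoly, strata)
  df <- divergenceTable(counts)
  expect_equal(df$sns[df$stratum == "exon"], 1)    # col 2
  expect_equal(df$sns[df$stratum == "intron"], 1)  # col 14
  expect_equal(counts@excludedColumns, 2L)         # cols 9 and 11
  expect_equal(df$sites[df$stratum == "exon"], 6)
  expect_equal(df$sites[df$stratum == "intron"], 6)
})

test_that("identical sequences yield zero substitutions", {
  aln <- TrioAlignment("ACGTAC", "ACGTAC", "ACGTAC", humanStart = 101L)
  strata <- classifyRegion(101:106, toyAlnGene())
  noPoly <- SNVSites(character(0), integer(0), character(0), character(0),
                     integer(0), integer(0), sampleChromosomes = 100L)
  df <- divergenceTable(countDivergence(aln, noPoly, strata))
  expect_equal(sum(df$sns), 0)
})

test_that("polymorphism takes precedence over apparent divergence", {
  aln <- toyAlignment()
  gene <- toyAlnGene()
  strata <- classifyRegion(101:114, gene)
  strata$region[strata$region == "intergenic"] <- "intron"
  # column 2 (human pos 102) differs from the ancestor AND is polymorphic:
  # it must count as SNV only
  poly <- SNVSites("synth1", c(102L, 104L), c("C", "T"), c("G", "A"),
                   ac = c(5L, 1L), an = 100L)
  counts <- countDivergence(aln, poly, strata)
  df <- divergenceTable(counts)
  expect_equal(df$sns[df$stratum == "exon"], 0)
  expect_equal(df$snv[df$stratum == "exon"], 2)
  # invariant: snv + sns never exceeds sites in any stratum
  expect_true(all(df$snv + df$sns <= df$sites))
})

test_that("Fisher ratio tests match enumeration and worked examples", {
  counts <- DivergenceCounts(c("exon", "intron"), sns = c(2, 4),
                             snv = c(10, 20), sites = c(100, 100))
  res <- divergenceRatioTest(counts)
  expect_equal(testRatio(res), 0.5)
  expect_equal(testPValue(res),
               enumFisherP(rbind(c(2, 98), c(4, 96))), tolerance = 1e-9)

  fix <- fixationRateContrast(counts)
  expect_equal(testRatio(fix), 1.0)   # 2/10 vs 4/20: proportional
  expect_equal(testPValue(fix), 1.0)

  counts2 <- DivergenceCounts(c("exon", "intron"), sns = c(1, 10),
                              snv = c(10, 10), sites = c(50, 50))
  fix2 <- fixationRateContrast(counts2)
  expect_equal(testRatio(fix2), 0.1)
  expect_equal(testPValue(fix2),
               enumFisherP(rbind(c(1, 10), c(10, 10))), tolerance = 1e-9)
})

test_that("two-sided Fisher equals the enumeration oracle on random tables", {
  # symmetric doubling case first: p = 2 * (P0 + P1 + P2) by symmetry
  symP <- fixationRateContrast(DivergenceCounts(
    c("exon", "intron"), sns = c(2, 8), snv = c(8, 2), sites = c(10, 10)))
  expect_equal(testPValue(symP), 4252 / 184756, tolerance = 1e-9)
  expect_equal(testPValue(symP), 0.023, tolerance = 1e-3)

  set.seed(77)
  for (i in 1:100) {
    repeat {
      tab <- matrix(rpois(4, sample(5:40, 1)), 2)
      if (sum(tab) <= 200 && all(rowSums(tab) > 0) && all(tab[, 2] > 0)) break
    }
    counts <- DivergenceCounts(c("exon", "intron"), sns = tab[, 1],
                               snv = tab[, 2], sites = rowSums(tab) + 5)
    expect_equal(testPValue(fixationRateContrast(counts)), enumFisherP(tab),
                 tolerance = 1e-9, label = paste(tab, collapse = ","))
  }
})

test_that("degenerate denominators flag the ratio but keep the p-value", {
  counts <- DivergenceCounts(c("exon", "intron"), sns = c(3, 0),
                             snv = c(10, 10), sites = c(50, 50))
  res <- divergenceRatioTest(counts)
  expect_true(is.na(testRatio(res)))
  expect_true(length(res@flags) > 0)
  expect_false(is.na(testPValue(res)))
  expect_error(divergenceRatioTest(DivergenceCounts(
    c("exon", "intron"), sns = c(0, 0), snv = c(1, 1), sites = c(0, 10))),
    "sites > 0")
})

test_that("neutral simulation keeps both ratio statistics near one at ~5% rejection", {
  # count-level neutral replicates: exon and intron identical processes
  set.seed(88)
  nRep <- 200L
  LExon <- 20000; LIntron <- 40000
  theta <- 0.003; Tdiv <- 0.006
  H <- harmonicNumber(1999L)
  divP <- fixP <- divRatio <- fixRatio <- numeric(nRep)
  for (r in seq_len(nRep)) {
    snsE <- rbinom(1, LExon, Tdiv); snsI <- rbinom(1, LIntron, Tdiv)
    snvE <- rpois(1, theta * LExon * H); snvI <- rpois(1, theta * LIntron * H)
    counts <- DivergenceCounts(c("exon", "intron"), sns = c(snsE, snsI),
                               snv = c(snvE, snvI),
                               sites = c(LExon, LIntron))
    dr <- divergenceRatioTest(counts); fr <- fixationRateContrast(counts)
    divP[r] <- testPValue(dr); fixP[r] <- testPValue(fr)
    divRatio[r] <- testRatio(dr); fixRatio[r] <- testRatio(fr)
  }
  expect_equal(mean(divRatio), 1, tolerance = 0.05)
  expect_equal(mean(fixRatio), 1, tolerance = 0.08)
  expect_lt(mean(divP < 0.05), 0.10)   # Fisher is conservative: <= alpha
  expect_gt(mean(divP < 0.05), 0.005)
  expect_lt(mean(fixP < 0.05), 0.10)
  expect_gt(mean(fixP < 0.05), 0.005)
})

test_that("purifying selection drives the fixation-rate ratio below one, monotonically", {
  gammas <- c(0, -2, -5, -10)
  meanRatio <- vapply(seq_along(gammas), function(gi) {
    set.seed(90 + gi)
    u <- relativeFixationRate(gammas[gi])
    reps <- vapply(1:40, function(r) {
      snsE <- rbinom(1, 20000, 0.006 * u); snsI <- rbinom(1, 40000, 0.006)
      snvE <- rpois(1, 450); snvI <- rpois(1, 900)
      (snsE / snvE) / (snsI / snvI)
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_true(all(diff(meanRatio) < 0))
  expect_lt(meanRatio[2], 0.45)   # u(-2) ~ 0.313
  expect_lt(meanRatio[3], 0.08)   # u(-5) ~ 0.034
  expect_lt(meanRatio[4], 0.01)   # u(-10) ~ 4.5e-4
})

test_that("end-to-end: simulated alignment plus sites recover the selection signal", {
  # neutral locus: ratios near 1, tests non-significant in most seeds
  neutralP <- SimParams(seed = 101, theta = 0.02, nChrom = 400L, m = 300L,
                        Tdiv = 0.01, LExon = 6000L, LIntron = 12000L,
                        LReference = 500L)
  ds <- simulateDataset(neutralP)
  strata <- classifyRegion(ds$alignment@humanPos[
    !is.na(ds$alignment@humanPos)], ds$gene, ds$repeats)
  counts <- countDivergence(ds$alignment, ds$sites, strata)
  df <- divergenceTable(counts)
  expect_true(all(df$snv + df$sns <= df$sites))
  res <- divergenceRatioTest(counts)
  expect_gt(testRatio(res), 0.6)
  expect_lt(testRatio(res), 1.5)

  # strongly selected exons: both ratios clearly below one
  selP <- SimParams(seed = 102, theta = 0.02, nChrom = 400L, m = 300L,
                    Tdiv = 0.01, LExon = 6000L, LIntron = 12000L,
                    LReference = 500L, fracSelected = 1, gamma = -10)
  ds2 <- simulateDataset(selP)
  strata2 <- classifyRegion(ds2$alignment@humanPos[
    !is.na(ds2$alignment@humanPos)], ds2$gene, ds2$repeats)
  counts2 <- countDivergence(ds2$alignment, ds2$sites, strata2)
  expect_lt(testRatio(divergenceRatioTest(counts2)), 0.3)
  expect_lt(testRatio(fixationRateContrast(counts2)), 0.3)
  expect_true(isSignificant(divergenceRatioTest(counts2)))
})

test_that("trio alignments read from FASTA preserve the coordinate map", {
  path <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(Biostrings::BStringSet(
    c(human = "AC-GT", chimpanzee = "ACCGT", bonobo = "ACCGT")), path)
  aln <- readTrioAlignment(path, chrom = "chr3", humanStart = 50L)
  expect_equal(humanPositions(aln), c(50L, 51L, NA, 52L, 53L))
  bad <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(Biostrings::BStringSet(
    c(a = "AC", b = "AC")), bad)
  expect_error(readTrioAlignment(bad), "3 records")
})
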