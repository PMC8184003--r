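test_that("projection matches exhaustive subsample enumeration on small cases", {
  # every (ac, an <= 12, m <= an): expectation over all C(an, m) subsamples
  for (an in 3:12) {
    for (ac in 1:(an - 1)) {
      for (m in seq(2, an, by = 2)) {
        expect_equal(projectSite(ac, an, m), enumProjection(ac, an, m),
                     tolerance = 1e-12,
                     label = sprintf("ac=%d an=%d m=%d", ac, an, m))
      }
    }
  }
})

test_that("projection has unit mass and preserves the allele frequency", {
  cases <- data.frame(ac = c(2, 1, 7, 150, 3), an = c(4, 100, 20, 3000, 10),
                      m = c(2, 50, 11, 2000, 10))
  for (i in seq_len(nrow(cases))) {
    v <- projectSite(cases$ac[i], cases$an[i], cases$m[i])
    expect_equal(sum(v), 1, tolerance = 1e-12)
    expect_equal(sum((seq_along(v) - 1) * v),
                 cases$m[i] * cases$ac[i] / cases$an[i],
                 tolerance = 1e-9 * cases$m[i])
  }
  # identity projection: m = an is a point mass at ac
  v <- projectSite(3, 10, 10)
  expect_equal(v[4], 1)
  expect_equal(sum(v), 1)
})

test_that("worked projection examples hold exactly", {
  expect_equal(projectSite(2, 4, 2), c(1 / 6, 2 / 3, 1 / 6))
  # closed form C(1,1) C(99,49) / C(100,50) for the singleton bin
  v <- projectSite(1, 100, 50)
  expect_equal(v[2], 0.5, tolerance = 1e-12)
  expect_equal(v[1], 0.5, tolerance = 1e-12)
})

test_that("buildSFS accumulates projections and books monomorphic mass", {
  s2 <- SNVSites("synth1", c(10L, 20L), c("A", "C"), c("G", "T"),
                 ac = 1L, an = 100L)
  sfs <- buildSFS(s2, m = 100L)
  expect_equal(sfs@bins[1], 2)        # identity projection
  expect_equal(sum(sfs@bins), 2)
  expect_equal(sfs@droppedMass, 0)

  s1 <- SNVSites("synth1", 10L, "A", "G", ac = 2L, an = 4L)
  sfs1 <- buildSFS(s1, m = 2L)
  expect_equal(sfs1@bins, 2 / 3)
  expect_equal(sfs1@droppedMass, 1 / 3)
  expect_equal(sum(sfs1@bins) + sfs1@droppedMass, sfs1@nSitesUsed)
})

test_that("sites with an below the projection target are excluded and counted", {
  s <- SNVSites("synth1", c(10L, 20L, 30L), "A", "G",
                ac = c(1L, 2L, 3L), an = c(80L, 120L, 150L))
  sfs <- buildSFS(s, m = 100L)
  expect_equal(sfs@nSitesUsed, 2)
  expect_equal(sfs@nExcludedLowAN, 1L)
})

test_that("expected projection agrees with a seeded subsampling oracle", {
  set.seed(9)
  n <- 25L
  ref <- sample(c("A", "C", "G", "T"), n, TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  an <- sample(40:60, n, TRUE)
  sites <- SNVSites("synth1", sort(sample.int(10000L, n)), ref, alt,
                    ac = pmin(sample.int(30L, n, TRUE), an - 1L), an = an)
  m <- 40L
  expected <- buildSFS(sites, m = m)
  # oracle: average spectrum over many random m-subsamples per site
  tab <- siteTable(sites)
  acc <- numeric(m + 1)
  for (i in seq_len(nrow(tab))) {
    acc <- acc + sampleProjectionOracle(tab$ac[i], tab$an[i], m,
                                        nDraws = 4000L)
  }
  expect_equal(expected@bins, acc[2:m], tolerance = 0.06)
  # and the package's own sampled mode agrees too
  sampled <- buildSFS(sites, m = m, method = "sampled", seed = 11)
  expect_equal(sum(sampled@bins) + sampled@droppedMass, nrow(tab))
})

test_that("singleton fraction handles degenerate and plain spectra", {
  mk <- function(bins, m) new("SiteFreqSpectrum", m = as.integer(m),
                              bins = bins, nSitesUsed = sum(bins),
                              droppedMass = 0, nExcludedLowAN = 0L)
  expect_equal(singletonFraction(mk(c(5, 0, 0), 4))$fraction, 1)
  expect_equal(singletonFraction(mk(c(0, 7), 3))$fraction, 0)
  expect_equal(singletonFraction(mk(c(3, 1, 2), 4))$fraction, 0.5)
  expect_warning(sf <- singletonFraction(mk(c(0, 0), 3)), "undefined")
  expect_true(is.na(sf$fraction))
})

test_that("neutral simulation reproduces the harmonic-number singleton fraction", {
  # theta * L * H(n-1) ~ 4,400 segregating sites; projection from n = 1,100
  # chromosomes to m = 1,000. Neutral expectation: 1 / H(m - 1).
  params <- SimParams(seed = 21, theta = 0.02, LExon = 2500L,
                      LIntron = 5900L, LReference = 40000L,
                      nChrom = 1100L, m = 1000L, missingRate = 0.01)
  sites <- samplePolymorphism(params)
  sfs <- buildSFS(sites, m = 1000L)
  neutral <- 1 / harmonicNumber(999L)
  got <- singletonFraction(sfs)$fraction
  expect_equal(got, neutral, tolerance = 0.05)
})

test_that("chi-squared singleton contrast matches the hand formula", {
  mkCounts <- function(s, o) list(singleton_mass = s, total_mass = s + o)
  res <- singletonChi2Test(mkCounts(10, 90), mkCounts(20, 80))
  expect_equal(res@statistic, chi2Hand(rbind(c(10, 90), c(20, 80))),
               tolerance = 1e-12)
  expect_equal(res@statistic, 3.92, tolerance = 0.01)
  expect_equal(res@pValue,
               pchisq(res@statistic, df = 1, lower.tail = FALSE))

  homog <- singletonChi2Test(mkCounts(10, 90), mkCounts(30, 270))
  expect_equal(homog@statistic, 0)
  expect_equal(homog@pValue, 1)

  set.seed(31)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 40) + 1, 2)
    got <- singletonChi2Test(mkCounts(tab[1, 1], tab[1, 2]),
                             mkCounts(tab[2, 1], tab[2, 2]))
    expect_equal(got@statistic, chi2Hand(tab), tolerance = 1e-9)
  }
})

test_that("low expected cells are flagged but still tested", {
  mkCounts <- function(s, o) list(singleton_mass = s, total_mass = s + o)
  expect_warning(res <- singletonChi2Test(mkCounts(1, 1), mkCounts(0, 200)),
                 "expected cell")
  expect_true(length(res@flags) > 0)
  expect_false(is.na(res@pValue))
  expect_error(singletonChi2Test(mkCounts(0, 0), mkCounts(5, 5)),
               "total counts")
})

test_that("singleton chi-squared test is calibrated under neutrality", {
  # 2,000 replicates of a neutral target vs an independent neutral
  # reference, both drawn from near-identity projections so counts keep
  # multinomial variance; rejection at alpha = 0.05 should be ~5%
  set.seed(41)
  m <- 100L
  nT <- 250L; nR <- 2500L
  p0 <- 1 / harmonicNumber(m - 1L)
  rej <- logical(2000)
  for (r in seq_len(2000)) {
    tgt <- list(singleton_mass = rbinom(1, nT, p0), total_mass = nT)
    ref <- list(singleton_mass = rbinom(1, nR, p0), total_mass = nR)
    rej[r] <- suppressWarnings(isSignificant(singletonChi2Test(tgt, ref)))
  }
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.075)
})

test_that("purifying selection elevates the singleton fraction monotonically", {
  m <- 400L
  fracAt <- function(gamma, seed) {
    params <- SimParams(seed = seed, theta = 0.02, nChrom = 500L, m = m,
                        fracSelected = 1, gamma = gamma,
                        LReference = 1000L, LIntron = 1000L,
                        LExon = 20000L, missingRate = 0)
    sites <- samplePolymorphism(params)
    gene <- lncsel:::.simLayout(params)$gene
    strata <- classifyRegion(sites, gene)
    exonic <- siteRanges(sites)[strata$region == "exon"]
    sf <- singletonFraction(buildSFS(
      new("SNVSites", sites = exonic, sampleChromosomes = 500L), m = m))
    sf$fraction
  }
  fracs <- vapply(c(0, -2, -5, -10), fracAt, numeric(1), seed = 51)
  neutral <- 1 / harmonicNumber(m - 1L)
  expect_equal(fracs[1], neutral, tolerance = 0.06)
  expect_true(all(diff(fracs) > 0))      # monotone in |gamma|
  expect_gt(fracs[4], 1.5 * neutral)     # strong selection, strong excess
})

test_that("the lncRNA singleton screen enforces the 50-SNV floor and flags selection", {
  set.seed(61)
  m <- 200L
  # reference: large neutral pool
  refParams <- SimParams(seed = 62, theta = 0.05, nChrom = 220L, m = m,
                         LReference = 30000L, LExon = 100L, LIntron = 100L,
                         missingRate = 0)
  refSites <- samplePolymorphism(refParams)
  refRegion <- lncsel:::.simLayout(refParams)$reference
  reference <- new("SNVSites",
                   sites = siteRanges(refSites)[IRanges::overlapsAny(
                     siteRanges(refSites), refRegion)],
                   sampleChromosomes = 220L)

  mkGene <- function(seed, gamma, L) {
    params <- SimParams(seed = seed, theta = 0.05, nChrom = 220L, m = m,
                        fracSelected = 1, gamma = gamma, LExon = L,
                        LIntron = 100L, LReference = 100L, missingRate = 0)
    sites <- samplePolymorphism(params)
    gene <- lncsel:::.simLayout(params)$gene
    strata <- classifyRegion(sites, gene)
    new("SNVSites", sites = siteRanges(sites)[strata$region == "exon"],
        sampleChromosomes = 220L)
  }
  genes <- list(
    tiny = mkGene(70, 0, 150L),            # << 50 SNVs -> excluded
    neutral1 = mkGene(71, 0, 2000L),
    neutral2 = mkGene(72, 0, 2000L),
    selected = mkGene(73, -10, 2500L)
  )
  expect_lt(buildSFS(genes$tiny, m = m)@nSitesUsed, 50)
  screen <- lncrnaSingletonScreen(
    genes, reference,
    conservationClass = c(tiny = "other", neutral1 = "other",
                          neutral2 = "other", selected = "conserved"),
    minSNVs = 50L, m = m)
  expect_false("tiny" %in% screen$gene_id)
  expect_true(all(c("neutral1", "neutral2", "selected") %in% screen$gene_id))
  sel <- screen[screen$gene_id == "selected", ]
  neu <- screen[screen$gene_id != "selected", ]
  expect_true(sel$significant)
  expect_gt(sel$singleton_fraction, max(neu$singleton_fraction))
  expect_true(all(screen$p_bh >= screen$p))
  expect_error(lncrnaSingletonScreen(genes, SNVSites(
    character(0), integer(0), character(0), character(0), integer(0),
    integer(0))), "empty")
})
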