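#' Parameters for the synthetic locus generator
#'
#' Bundles the population-genetic and bookkeeping parameters of the
#' Poisson-random-field generator. Defaults reproduce the study conditions
#' of a gnomAD-scale analysis of an ESRG-like locus: a population sample of
#' 2 x 15,708 = 31,416 chromosomes projected down to 30,000; per-site
#' Watterson theta of 0.004 (matching the genome-wide segregating-site
#' density of deep human whole-genome panels rather than pairwise diversity);
#' human-lineage divergence of 0.008 substitutions per site to the
#' chimpanzee-bonobo ancestor; an exon/intron structure of 2,500 exonic and
#' 5,900 intronic bases with the first 60% of exon 1 LTR-derived, mirroring
#' the HERV-H geometry of ESRG.
#'
#' @slot theta Per-site population-scaled mutation rate.
#' @slot gamma Scaled selection coefficient of selected sites (0 neutral,
#'   negative deleterious).
#' @slot LExon,LIntron,LReference Stratum lengths (bp); the reference region
#'   is the synonymous-like neutral comparator.
#' @slot nChrom Population sample size in chromosomes.
#' @slot m Projection target in chromosomes.
#' @slot Tdiv Expected neutral substitutions per site on the human lineage.
#' @slot fracSelected Fraction of exonic sites under selection.
#' @slot discordance Chimpanzee-bonobo discordance rate (exercises the
#'   parsimony exclusion path).
#' @slot gapRate Outgroup gap-column rate.
#' @slot gridSize Inverse-CDF grid resolution for frequency sampling.
#' @slot missingRate Per-individual genotype missingness (makes `an` vary
#'   below `nChrom`, exercising the projection).
#' @slot fracLowCoverage Fraction of positions emitted with failing coverage.
#' @slot fracFailFilter Fraction of sites emitted with `FILTER = FAIL`.
#' @slot nScreenGenes,screenExonLength Extra single-exon neutral lncRNA genes
#'   for the singleton screen.
#' @slot alnPad Alignment padding around the gene span (bp).
#' @slot consHighAbove,consLowAbove Mass above score 0.9 for the
#'   conservation-score modes of selected and neutral sites.
#' @slot nGenesExpr,nPerGroup,dispersion,focalLfc Count-matrix settings:
#'   genes, samples per species x cell-type cell, NB dispersion, and the
#'   interaction log2 fold change spiked into the focal gene.
#' @slot seed Integer seed; all outputs are deterministic given it.
#' @export
setClass("SimParams",
  slots = c(theta = "numeric", gamma = "numeric", LExon = "integer",
            LIntron = "integer", LReference = "integer", nChrom = "integer",
            m = "integer", Tdiv = "numeric", fracSelected = "numeric",
            discordance = "numeric", gapRate = "numeric",
            gridSize = "integer", missingRate = "numeric",
            fracLowCoverage = "numeric", fracFailFilter = "numeric",
            nScreenGenes = "integer", screenExonLength = "integer",
            alnPad = "integer", consHighAbove = "numeric",
            consLowAbove = "numeric", nGenesExpr = "integer",
            nPerGroup = "integer", dispersion = "numeric",
            focalLfc = "numeric", seed = "integer")
)

setValidity("SimParams", function(object) {
  if (object@theta <= 0) return("theta must be positive")
  if (!is.finite(object@gamma)) return("gamma must be finite")
  if (object@LExon <= 0 || object@LIntron <= 0 || object@LReference <= 0) {
    return("stratum lengths must be positive")
  }
  if (object@fracSelected < 0 || object@fracSelected > 1) {
    return("fracSelected must lie in [0, 1]")
  }
  if (object@m > object@nChrom) return("m must not exceed nChrom")
  if (object@dispersion <= 0) return("dispersion must be positive")
  if (object@Tdiv < 0 || object@Tdiv > 1) return("Tdiv must lie in [0, 1]")
  TRUE
})

#' @rdname SimParams-class
#' @param ... Named values overriding the defaults listed above.
#' @return A validated `SimParams` object.
#' @examples
#' SimParams(seed = 1, gamma = -5, fracSelected = 1)
#' @export
SimParams <- function(...) {
  defaults <- list(theta = 0.004, gamma = 0, LExon = 2500L, LIntron = 5900L,
                   LReference = 20000L, nChrom = 31416L, m = 30000L,
                   Tdiv = 0.008, fracSelected = 0, discordance = 0.002,
                   gapRate = 0.001, gridSize = 10000L, missingRate = 0.02,
                   fracLowCoverage = 0, fracFailFilter = 0,
                   nScreenGenes = 0L, screenExonLength = 1500L,
                   alnPad = 500L, consHighAbove = 1, consLowAbove = 0,
                   nGenesExpr = 1500L, nPerGroup = 4L, dispersion = 0.1,
                   focalLfc = 4, seed = 1L)
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown SimParams field(s): ", paste(unknown, collapse = ", "))
  }
  vals <- utils::modifyList(defaults, override)
  for (f in c("LExon", "LIntron", "LReference", "nChrom", "m", "gridSize",
              "nScreenGenes", "screenExonLength", "alnPad", "nGenesExpr",
              "nPerGroup", "seed")) {
    vals[[f]] <- as.integer(vals[[f]])
  }
  do.call(new, c(list("SimParams"), vals))
}

setMethod("show", "SimParams", function(object) {
  cat(sprintf(
    "SimParams: theta=%g, gamma=%g (%.0f%% of exon selected), n=%d -> m=%d, T=%g, seed=%d\n",
    object@theta, object@gamma, 100 * object@fracSelected, object@nChrom,
    object@m, object@Tdiv, object@seed))
})

.simSeed <- function(params, offset) (params@seed %% 2000000000L) + offset

#' Stationary allele-frequency density under selection
#'
#' The Wright stationary density of a derived allele at population frequency
#' q: proportional to `1/q` for neutral sites and to
#' `(1 - exp(-gamma * (1 - q))) / ((1 - exp(-gamma)) * q * (1 - q))` for
#' sites with scaled selection coefficient `gamma`. Negative `gamma` piles
#' mass onto low frequencies. The density is non-integrable at q = 0 (for
#' any gamma), so sampling uses a truncated, normalized version — see
#' [frequencyGrid()].
#'
#' @param q Frequencies in (0, 1).
#' @param gamma Scaled selection coefficient.
#' @return Unnormalized density values.
#' @export
stationaryDensity <- function(q, gamma) {
  stopifnot(all(q > 0 & q < 1))
  if (gamma == 0) return(1 / q)
  if (gamma < -500) {
    # asymptotic form: (1 - e^{-g(1-q)})/(1 - e^{-g}) -> e^{g q} for g -> -Inf
    return(exp(gamma * q) / (q * (1 - q)))
  }
  num <- -expm1(-gamma * (1 - q))
  den <- -expm1(-gamma)
  (num / den) / (q * (1 - q))
}

#' Truncated inverse-CDF sampling grid for allele frequencies
#'
#' Discretizes the stationary density on a log-spaced grid over
#' `[1/(100 * nChrom), 1 - 1/(2 * nChrom)]`. The log spacing is essential:
#' singletons in a sample of ~30,000 chromosomes arise from population
#' frequencies around 1e-5, far below the resolution of a uniform grid of
#' practical size. The truncation removes the non-integrable 1/q spike;
#' the mass lost below the cutoff corresponds to alleles almost never seen
#' even once in the sample (relative singleton-bin loss about
#' `nChrom * qmin` = 1%).
#'
#' @param gamma Scaled selection coefficient.
#' @param nChrom Population sample size in chromosomes.
#' @param gridSize Number of grid points (default 10,000).
#' @return List with `q` (grid midpoints), `w` (normalized probabilities)
#'   and `normalizer` (the quadrature mass of the unnormalized density over
#'   the truncated support).
#' @export
frequencyGrid <- function(gamma, nChrom, gridSize = 10000L) {
  qmin <- 1 / (100 * nChrom)
  qmax <- 1 - 1 / (2 * nChrom)
  bounds <- exp(seq(log(qmin), log(qmax), length.out = gridSize + 1L))
  q <- sqrt(bounds[-1] * bounds[-(gridSize + 1L)])   # geometric midpoints
  w <- stationaryDensity(q, gamma) * diff(bounds)
  total <- sum(w)
  list(q = q, w = w / total, normalizer = total)
}

.sampleFrequencies <- function(n, grid) {
  if (n == 0L) return(numeric(0))
  grid$q[sample.int(length(grid$q), n, replace = TRUE, prob = grid$w)]
}

#' Relative fixation rate under selection
#'
#' `u(gamma) = gamma / (1 - exp(-gamma))`, the fixation probability of a new
#' mutation with scaled selection coefficient `gamma` relative to a neutral
#' one (`u(0) = 1` by the analytic limit). Purifying selection suppresses
#' fixation: `u(-5)` is about 0.034.
#'
#' @param gamma Scaled selection coefficient (vectorized).
#' @return Relative fixation rate.
#' @export
relativeFixationRate <- function(gamma) {
  ifelse(gamma == 0, 1, gamma / (-expm1(-gamma)))
}

# ---------------------------------------------------------------------------
# locus layout on the synthetic contig "synth1"

.simLayout <- function(params) {
  chrom <- "synth1"
  flank <- 1000L
  e1 <- as.integer(floor(params@LExon * 0.5))
  e2 <- params@LExon - e1
  geneStart <- flank + 1L
  exon1 <- c(geneStart, geneStart + e1 - 1L)
  intron <- c(exon1[2] + 1L, exon1[2] + params@LIntron)
  exon2 <- c(intron[2] + 1L, intron[2] + e2)
  ltrEnd <- exon1[1] + as.integer(floor(e1 * 0.6)) - 1L
  refStart <- exon2[2] + 501L
  refEnd <- refStart + params@LReference - 1L
  cursor <- refEnd + 501L
  screenGenes <- NULL
  if (params@nScreenGenes > 0L) {
    starts <- cursor + (seq_len(params@nScreenGenes) - 1L) *
      (params@screenExonLength + 200L)
    screenGenes <- GRanges(chrom,
                           IRanges(starts, width = params@screenExonLength))
    S4Vectors::mcols(screenGenes)$gene_id <-
      sprintf("screen_lnc_%03d", seq_len(params@nScreenGenes))
    cursor <- max(GenomicRanges::end(screenGenes)) + 1L
  }
  contigLength <- cursor + 1000L

  gene <- GeneModel("ESRG_like", "ESRG_like_tx", chrom,
                    exonStarts = c(exon1[1], exon2[1]),
                    exonEnds = c(exon1[2], exon2[2]),
                    strand = "+", biotype = "lncRNA")
  repeats <- GRanges(chrom, IRanges(exon1[1], ltrEnd))
  S4Vectors::mcols(repeats) <- S4Vectors::DataFrame(
    repeat_name = "LTR7", repeat_class = "LTR/ERV1")

  exonPos <- c(seq(exon1[1], exon1[2]), seq(exon2[1], exon2[2]))
  set.seed(.simSeed(params, 0L))
  nSel <- round(params@fracSelected * length(exonPos))
  selectedPos <- if (nSel > 0) sort(sample(exonPos, nSel)) else integer(0)

  list(chrom = chrom, gene = gene, repeats = repeats,
       exonPos = exonPos, intronPos = seq(intron[1], intron[2]),
       referencePos = seq(refStart, refEnd),
       reference = GRanges(chrom, IRanges(refStart, refEnd)),
       screenGenes = screenGenes, selectedPos = selectedPos,
       contigLength = contigLength,
       alnStart = max(1L, geneStart - params@alnPad),
       alnEnd = exon2[2] + params@alnPad)
}

# segregating sites for one stratum; infinite-sites: positions sampled
# without replacement
.sampleStratumSites <- function(positions, gamma, params, grid = NULL) {
  H <- harmonicNumber(params@nChrom - 1L)
  nSeg <- stats::rpois(1L, params@theta * length(positions) * H)
  nSeg <- min(nSeg, length(positions))
  if (nSeg == 0L) {
    return(data.frame(pos = integer(0), ac = integer(0), an = integer(0)))
  }
  if (is.null(grid)) grid <- frequencyGrid(gamma, params@nChrom,
                                           params@gridSize)
  pos <- sort(positions[sample.int(length(positions), nSeg)])
  nIndiv <- params@nChrom %/% 2L
  an <- params@nChrom -
    2L * stats::rbinom(nSeg, nIndiv, params@missingRate)
  q <- .sampleFrequencies(nSeg, grid)
  ac <- stats::rbinom(nSeg, an, q)
  bad <- which(ac <= 0L | ac >= an)
  while (length(bad) > 0L) {   # condition on segregating in the sample
    q[bad] <- .sampleFrequencies(length(bad), grid)
    ac[bad] <- stats::rbinom(length(bad), an[bad], q[bad])
    bad <- bad[ac[bad] <= 0L | ac[bad] >= an[bad]]
  }
  data.frame(pos = pos, ac = as.integer(ac), an = as.integer(an))
}

#' Draw population polymorphism for the synthetic locus
#'
#' Poisson-random-field sampling: per stratum, the number of segregating
#' sites is Poisson with the neutral expectation `theta * L * H(n - 1)`;
#' each site's population frequency is drawn from the stationary density
#' (neutral for intronic, reference and screen-gene sites; `gamma`-selected
#' for the selected fraction of exonic sites), and its sample allele count
#' from a Binomial over the site's called chromosomes, conditioned on being
#' polymorphic in the sample. Deterministic given the seed.
#'
#' @param params A [SimParams-class] object.
#' @param humanSeq Optional `DNAString` of the synthetic human contig, used
#'   to make VCF reference bases agree with the genome FASTA.
#' @return An [SNVSites-class] over all strata of the contig.
#' @export
samplePolymorphism <- function(params, humanSeq = NULL) {
  stopifnot(is(params, "SimParams"))
  layout <- .simLayout(params)
  set.seed(.simSeed(params, 1L))

  neutralGrid <- frequencyGrid(0, params@nChrom, params@gridSize)
  selGrid <- if (params@gamma != 0) {
    frequencyGrid(params@gamma, params@nChrom, params@gridSize)
  } else neutralGrid

  neutralExon <- setdiff(layout$exonPos, layout$selectedPos)
  parts <- list(
    .sampleStratumSites(layout$selectedPos, params@gamma, params, selGrid),
    .sampleStratumSites(neutralExon, 0, params, neutralGrid),
    .sampleStratumSites(layout$intronPos, 0, params, neutralGrid),
    .sampleStratumSites(layout$referencePos, 0, params, neutralGrid)
  )
  if (!is.null(layout$screenGenes)) {
    for (i in seq_along(layout$screenGenes)) {
      gpos <- seq(GenomicRanges::start(layout$screenGenes)[i],
                  GenomicRanges::end(layout$screenGenes)[i])
      parts[[length(parts) + 1L]] <-
        .sampleStratumSites(gpos, 0, params, neutralGrid)
    }
  }
  tab <- do.call(rbind, parts)
  if (nrow(tab) == 0L) {
    return(SNVSites(character(0), integer(0), character(0), character(0),
                    integer(0), integer(0),
                    sampleChromosomes = params@nChrom))
  }
  tab <- tab[order(tab$pos), , drop = FALSE]
  ref <- if (!is.null(humanSeq)) {
    strsplit(as.character(humanSeq), "")[[1]][tab$pos]
  } else sample(BASES, nrow(tab), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1))
  pass <- stats::runif(nrow(tab)) >= params@fracFailFilter
  SNVSites(layout$chrom, tab$pos, ref, alt, tab$ac, tab$an,
           filter_pass = pass, sampleChromosomes = params@nChrom)
}

#' Draw human-lineage divergence and emit the trio alignment
#'
#' Builds an ancestral sequence for the contig, places human-lineage
#' substitutions independently per site with probability `Tdiv` (scaled by
#' the relative fixation rate `u(gamma)` at selected sites), and sets
#' chimpanzee = bonobo = ancestor apart from a configurable discordance rate
#' and outgroup gap columns that exercise the parsimony exclusion path.
#'
#' @param params A [SimParams-class] object.
#' @return List with `alignment` (a [TrioAlignment-class] over the gene span
#'   plus padding), `humanSeq` (`DNAString` for the whole contig) and
#'   `substitutionPos` (true human-lineage substitution positions).
#' @export
sampleDivergence <- function(params) {
  stopifnot(is(params, "SimParams"))
  layout <- .simLayout(params)
  pSel <- params@Tdiv * relativeFixationRate(params@gamma)
  if (pSel > 1) {
    stop("Tdiv * u(gamma) exceeds 1: substitution probability overflow")
  }
  set.seed(.simSeed(params, 2L))
  L <- layout$contigLength
  anc <- sample(BASES, L, replace = TRUE)
  pSub <- rep(params@Tdiv, L)
  pSub[layout$selectedPos] <- pSel
  isSub <- stats::runif(L) < pSub
  human <- anc
  human[isSub] <- vapply(anc[isSub],
                         function(b) sample(setdiff(BASES, b), 1L),
                         character(1))
  span <- layout$alnStart:layout$alnEnd
  chimp <- bonobo <- anc[span]
  disc <- stats::runif(length(span)) < params@discordance
  chimp[disc] <- vapply(chimp[disc],
                        function(b) sample(setdiff(BASES, b), 1L),
                        character(1))
  gap <- stats::runif(length(span)) < params@gapRate
  chimp[gap] <- "-"
  bonobo[gap] <- "-"
  aln <- TrioAlignment(paste(human[span], collapse = ""),
                       paste(chimp, collapse = ""),
                       paste(bonobo, collapse = ""),
                       chrom = layout$chrom, humanStart = layout$alnStart)
  list(alignment = aln,
       humanSeq = Biostrings::DNAString(paste(human, collapse = "")),
       substitutionPos = which(isSub))
}

#' Draw the base-wise conservation-score track
#'
#' Selected sites receive scores from a high mode (mass above 0.9 set by
#' `consHighAbove`), neutral sites from a low mode (below 0.9 except for
#' `consLowAbove`), over the gene span, the neutral reference region and any
#' screen genes.
#'
#' @param params A [SimParams-class] object.
#' @return Per-base `GRanges` with a `score` column in [0, 1].
#' @export
sampleConservationTrack <- function(params) {
  stopifnot(is(params, "SimParams"))
  layout <- .simLayout(params)
  set.seed(.simSeed(params, 3L))
  pos <- c(layout$exonPos, layout$intronPos, layout$referencePos)
  if (!is.null(layout$screenGenes)) {
    pos <- c(pos, unlist(lapply(seq_along(layout$screenGenes), function(i) {
      seq(GenomicRanges::start(layout$screenGenes)[i],
          GenomicRanges::end(layout$screenGenes)[i])
    })))
  }
  pos <- sort(pos)
  sel <- pos %in% layout$selectedPos
  mode <- ifelse(sel, "high", "low")
  score <- numeric(length(pos))
  # scores are rounded to 4 digits for compact files; draws from the
  # above-0.9 component are kept strictly above the threshold afterwards
  highDraw <- function(n) pmax(round(stats::runif(n, 0.9, 1), 4), 0.9001)
  nHigh <- sum(sel)
  if (nHigh > 0) {
    above <- stats::runif(nHigh) < params@consHighAbove
    score[sel] <- ifelse(above, highDraw(nHigh),
                         round(stats::runif(nHigh, 0, 0.9), 4))
  }
  nLow <- sum(!sel)
  if (nLow > 0) {
    above <- stats::runif(nLow) < params@consLowAbove
    score[!sel] <- ifelse(above, highDraw(nLow),
                          round(stats::runif(nLow, 0, 0.6), 4))
  }
  gr <- GRanges(layout$chrom, IRanges(pos, width = 1L))
  S4Vectors::mcols(gr)$score <- score
  gr
}

#' Simulate a two-species, two-cell-type count matrix
#'
#' Negative-binomial counts with log-linear means over species, cell type
#' and spiked species-by-cell-type interaction effects, log-normal library
#' size factors, and a common dispersion. Null genes carry random species
#' and cell-type main effects but no interaction.
#'
#' @param nGenes Number of genes.
#' @param nPerGroup Samples per species x cell-type cell (>= 1; the
#'   downstream interaction model needs >= 2).
#' @param interactionLfcSpikes Named numeric vector: interaction log2 fold
#'   changes to spike into specific genes (names may be gene names or, when
#'   unnamed, the first `length()` genes are spiked).
#' @param dispersion NB dispersion (1/size), > 0.
#' @param seed Integer seed.
#' @param focalGene Optional gene renamed `focal_lnc` and given both the
#'   first spike and a high human-iPSC expression (an ESRG-like profile).
#' @return List with `counts` (integer matrix) and `metadata` (`data.frame`
#'   with sample, species, cell_type).
#' @export
sampleCountMatrix <- function(nGenes = 1500L, nPerGroup = 4L,
                              interactionLfcSpikes = numeric(0),
                              dispersion = 0.1, seed = 1L,
                              focalGene = FALSE) {
  stopifnot(nGenes >= 1L, nPerGroup >= 1L)
  if (dispersion <= 0) stop("dispersion must be positive")
  set.seed(seed %% 2000000000L)
  genes <- sprintf("gene_%05d", seq_len(nGenes))
  species <- rep(c("chimpanzee", "human"), each = 2L * nPerGroup)
  cellType <- rep(rep(c("iPSC", "iPSC_CM"), each = nPerGroup), times = 2L)
  samples <- sprintf("%s_%s_%d", substr(species, 1, 3),
                     sub("iPSC_CM", "CM", cellType),
                     rep(seq_len(nPerGroup), times = 4L))
  metadata <- data.frame(sample = samples, species = species,
                         cell_type = cellType, stringsAsFactors = FALSE)

  baseMean <- 2^stats::rnorm(nGenes, mean = log2(60), sd = 1.7)
  speciesLfc <- stats::rnorm(nGenes, 0, 0.4)   # main effects, no interaction
  cellLfc <- stats::rnorm(nGenes, 0, 0.4)
  interLfc <- numeric(nGenes)
  spikes <- interactionLfcSpikes
  if (length(spikes) > 0) {
    idx <- if (!is.null(names(spikes))) match(names(spikes), genes)
      else seq_along(spikes)
    if (anyNA(idx)) stop("spike names not found among genes")
    interLfc[idx] <- spikes
  }
  if (isTRUE(focalGene)) {
    # ESRG-like profile: modest baseline (below the median in chimpanzee
    # iPSCs), upregulated in the stem-cell state, with the spiked
    # human-by-iPSC interaction carrying the species-specific activation
    genes[1] <- "focal_lnc"
    baseMean[1] <- stats::quantile(baseMean, 0.20)
    speciesLfc[1] <- 0
    cellLfc[1] <- 1
  }
  isHuman <- metadata$species == "human"
  isIPSC <- metadata$cell_type == "iPSC"
  sizeFactor <- 2^stats::rnorm(nrow(metadata), 0, 0.2)
  mu <- outer(baseMean, sizeFactor) *
    2^(outer(speciesLfc, as.numeric(isHuman)) +
       outer(cellLfc, as.numeric(isIPSC)) +
       outer(interLfc, as.numeric(isHuman & isIPSC)))
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = nGenes, dimnames = list(genes, samples))
  list(counts = counts, metadata = metadata)
}

#' Generate a complete synthetic dataset
#'
#' Composes the polymorphism, divergence, conservation and expression
#' samplers into one coordinate-consistent dataset on the contig `synth1`,
#' together with the gene model, LTR repeat track, coverage table and
#' neutral reference region. Fully deterministic given the seed in
#' `params`.
#'
#' @param params A [SimParams-class] object.
#' @return Named list: `params`, `gene`, `repeats`, `sites`, `coverage`,
#'   `alignment`, `humanSeq`, `scores`, `counts`, `metadata`,
#'   `referenceRegion`, `screenGenes`, `layout`.
#' @export
simulateDataset <- function(params) {
  stopifnot(is(params, "SimParams"))
  layout <- .simLayout(params)
  div <- sampleDivergence(params)
  sites <- samplePolymorphism(params, humanSeq = div$humanSeq)
  scores <- sampleConservationTrack(params)

  covPos <- sort(c(layout$exonPos, layout$intronPos, layout$referencePos,
                   if (!is.null(layout$screenGenes))
                     unlist(lapply(seq_along(layout$screenGenes), function(i) {
                       seq(GenomicRanges::start(layout$screenGenes)[i],
                           GenomicRanges::end(layout$screenGenes)[i])
                     }))))
  set.seed(.simSeed(params, 5L))
  lowCov <- stats::runif(length(covPos)) < params@fracLowCoverage
  coverage <- data.frame(chrom = layout$chrom, pos = covPos,
                         frac_over_15x = ifelse(lowCov, 0.90, 1.00),
                         stringsAsFactors = FALSE)

  expr <- sampleCountMatrix(
    nGenes = params@nGenesExpr, nPerGroup = params@nPerGroup,
    interactionLfcSpikes = stats::setNames(params@focalLfc, "gene_00001"),
    dispersion = params@dispersion, seed = .simSeed(params, 4L),
    focalGene = TRUE)

  list(params = params, gene = layout$gene, repeats = layout$repeats,
       sites = sites, coverage = coverage, alignment = div$alignment,
       humanSeq = div$humanSeq, scores = scores, counts = expr$counts,
       metadata = expr$metadata, referenceRegion = layout$reference,
       screenGenes = layout$screenGenes, layout = layout)
}
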