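#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

BASES <- c("A", "C", "G", "T")

#' Population SNV sites with allele counts
#'
#' A set of bi-allelic single-nucleotide variants, each carrying the
#' alternate-allele count (`ac`), the number of called chromosomes (`an`) and
#' a quality-filter flag, anchored on genomic coordinates. This is the central
#' polymorphism container: downstream site-frequency spectra and
#' polymorphism/divergence contrasts all consume it.
#'
#' @slot sites A [GenomicRanges::GRanges] of width-1 positions with metadata
#'   columns `ref`, `alt` (single bases), `ac`, `an` (integers) and
#'   `filter_pass` (logical).
#' @slot sampleChromosomes Nominal maximum `an`, i.e. twice the number of
#'   sequenced individuals (e.g. 2 x 15,708 = 31,416 for a gnomAD-scale
#'   population sample).
#'
#' @seealso [SNVSites()] for construction, [readSNVs()] to read from VCF.
#' @export
setClass("SNVSites",
  slots = c(sites = "GRanges", sampleChromosomes = "integer")
)

setValidity("SNVSites", function(object) {
  gr <- object@sites
  need <- c("ref", "alt", "ac", "an", "filter_pass")
  missing <- setdiff(need, colnames(mcols(gr)))
  if (length(missing) > 0) {
    return(paste("missing metadata columns:", paste(missing, collapse = ", ")))
  }
  if (length(gr) == 0L) return(TRUE)
  if (any(width(gr) != 1L)) return("all sites must have width 1")
  m <- mcols(gr)
  if (!all(m$ref %in% BASES) || !all(m$alt %in% BASES)) {
    return("ref and alt must each be one of A, C, G, T")
  }
  if (any(m$ref == m$alt)) return("ref must differ from alt")
  if (any(m$ac < 0L) || any(m$ac > m$an)) return("need 0 <= ac <= an")
  if (any(m$an <= 0L)) return("an must be positive")
  key <- paste(as.character(seqnames(gr)), start(gr))
  if (anyDuplicated(key)) return("positions must be unique per chromosome")
  if (is.unsorted(order(as.character(seqnames(gr)), start(gr)))) {
    return("sites must be sorted by (chrom, pos)")
  }
  TRUE
})

#' Construct an SNVSites object
#'
#' @param chrom Chromosome names.
#' @param pos 1-based genomic positions (VCF convention).
#' @param ref,alt Single reference/alternate bases.
#' @param ac Alternate-allele counts.
#' @param an Numbers of called chromosomes.
#' @param filter_pass Logical quality-filter flags (default all `TRUE`).
#' @param sampleChromosomes Nominal maximum `an`; defaults to `max(an)`.
#' @return An [SNVSites-class] object, sorted by (chrom, pos).
#' @examples
#' SNVSites("synth1", c(101, 205), ref = c("A", "C"), alt = c("G", "T"),
#'          ac = c(1, 12), an = c(31000, 31416))
#' @export
SNVSites <- function(chrom, pos, ref, alt, ac, an,
                     filter_pass = TRUE, sampleChromosomes = NULL) {
  n <- length(pos)
  gr <- GRanges(rep_len(chrom, n), IRanges(pos, width = 1L))
  mcols(gr) <- DataFrame(
    ref = rep_len(as.character(ref), n),
    alt = rep_len(as.character(alt), n),
    ac = as.integer(rep_len(ac, n)),
    an = as.integer(rep_len(an, n)),
    filter_pass = rep_len(as.logical(filter_pass), n)
  )
  gr <- gr[order(as.character(seqnames(gr)), start(gr))]
  if (is.null(sampleChromosomes)) {
    sampleChromosomes <- if (n > 0) max(mcols(gr)$an) else 0L
  }
  new("SNVSites", sites = gr, sampleChromosomes = as.integer(sampleChromosomes))
}

#' @describeIn SNVSites Number of sites.
#' @param x,object An `SNVSites` object.
#' @export
setMethod("length", "SNVSites", function(x) length(x@sites))

#' Accessors for SNVSites
#'
#' `siteRanges()` returns the underlying `GRanges`; `siteTable()` a plain
#' `data.frame` with columns chrom, pos, ref, alt, ac, an, filter_pass;
#' `sampleChromosomes()` the nominal maximum `an`.
#'
#' @param x An [SNVSites-class] object.
#' @return See description.
#' @export
siteRanges <- function(x) {
  stopifnot(is(x, "SNVSites"))
  x@sites
}

#' @rdname siteRanges
#' @export
siteTable <- function(x) {
  stopifnot(is(x, "SNVSites"))
  gr <- x@sites
  data.frame(
    chrom = as.character(seqnames(gr)), pos = start(gr),
    ref = mcols(gr)$ref, alt = mcols(gr)$alt,
    ac = mcols(gr)$ac, an = mcols(gr)$an,
    filter_pass = mcols(gr)$filter_pass,
    stringsAsFactors = FALSE
  )
}

#' @rdname siteRanges
#' @export
sampleChromosomes <- function(x) {
  stopifnot(is(x, "SNVSites"))
  x@sampleChromosomes
}

setMethod("show", "SNVSites", function(object) {
  cat("SNVSites with", length(object), "bi-allelic SNVs;",
      "nominal sample of", object@sampleChromosomes, "chromosomes\n")
  if (length(object) > 0) {
    tab <- utils::head(siteTable(object), 4)
    print(tab, row.names = FALSE)
    if (length(object) > 4) cat("...\n")
  }
})

#' Gene model for one analysis transcript
#'
#' Exon (and optional CDS) structure of a single transcript. The analysis
#' transcript is explicit configuration rather than an automatic "canonical"
#' pick: selection statistics at a locus like ESRG are reported for one
#' stated isoform.
#'
#' @slot geneId,transcriptId Identifiers.
#' @slot txStrand `"+"` or `"-"`.
#' @slot exons `GRanges` of exon intervals (1-based, inclusive; sorted,
#'   non-overlapping).
#' @slot cds `GRanges` of coding intervals, possibly empty; subset of exons.
#' @slot biotype One of `"lncRNA"`, `"protein_coding"`, `"other"`.
#' @export
setClass("GeneModel",
  slots = c(geneId = "character", transcriptId = "character",
            txStrand = "character", exons = "GRanges", cds = "GRanges",
            biotype = "character")
)

setValidity("GeneModel", function(object) {
  if (!object@txStrand %in% c("+", "-")) return("txStrand must be '+' or '-'")
  if (!object@biotype %in% c("lncRNA", "protein_coding", "other")) {
    return("biotype must be lncRNA, protein_coding or other")
  }
  ex <- object@exons
  if (length(ex) == 0L) return("gene model needs at least one exon")
  if (is.unsorted(start(ex))) return("exons must be sorted by start")
  if (length(ex) > 1L && any(start(ex)[-1] <= end(ex)[-length(ex)])) {
    return("exons must be non-overlapping")
  }
  cds <- object@cds
  if (length(cds) > 0L) {
    cov <- sum(IRanges::width(IRanges::intersect(IRanges::ranges(cds),
                                                 IRanges::ranges(ex))))
    if (cov != sum(width(cds))) return("cds must lie within exons")
  }
  TRUE
})

#' Construct a GeneModel
#'
#' @param geneId,transcriptId Identifiers.
#' @param chrom Chromosome name.
#' @param exonStarts,exonEnds 1-based inclusive exon coordinates.
#' @param strand `"+"` or `"-"`.
#' @param cdsStarts,cdsEnds Optional coding intervals (1-based inclusive).
#' @param biotype `"lncRNA"` (default), `"protein_coding"` or `"other"`.
#' @return A [GeneModel-class] object.
#' @export
GeneModel <- function(geneId, transcriptId, chrom, exonStarts, exonEnds,
                      strand = "+", cdsStarts = integer(0),
                      cdsEnds = integer(0), biotype = "lncRNA") {
  ord <- order(exonStarts)
  exons <- GRanges(chrom, IRanges(exonStarts[ord], exonEnds[ord]))
  cds <- if (length(cdsStarts) > 0) {
    ordc <- order(cdsStarts)
    GRanges(chrom, IRanges(cdsStarts[ordc], cdsEnds[ordc]))
  } else GRanges()
  new("GeneModel", geneId = geneId, transcriptId = transcriptId,
      txStrand = strand, exons = exons, cds = cds, biotype = biotype)
}

#' @rdname GeneModel
#' @param x A `GeneModel`.
#' @export
geneExons <- function(x) {
  stopifnot(is(x, "GeneModel"))
  x@exons
}

#' @rdname GeneModel
#' @export
geneCds <- function(x) {
  stopifnot(is(x, "GeneModel"))
  x@cds
}

#' @rdname GeneModel
#' @export
geneSpan <- function(x) {
  stopifnot(is(x, "GeneModel"))
  range(x@exons)
}

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel", object@geneId, "/", object@transcriptId,
      sprintf("(%s, %s): %d exon(s), %d CDS segment(s)\n",
              object@biotype, object@txStrand, length(object@exons),
              length(object@cds)))
})

#' Downsampled site-frequency spectrum
#'
#' Expected counts of derived (alternate) alleles at frequencies 1..m-1 in a
#' projected sample of `m` chromosomes. Bins are fractional because each site
#' contributes its hypergeometric expectation rather than one random
#' subsample. Mass projected to frequency 0 or m (sites that look
#' monomorphic in the smaller sample) is kept aside in `droppedMass`, so that
#' `sum(bins) + droppedMass == nSitesUsed` per site.
#'
#' @slot m Projected sample size in chromosomes (e.g. 30,000).
#' @slot bins Numeric vector of length `m - 1`, entry j = expected number of
#'   sites at derived-allele count j.
#' @slot nSitesUsed Number of polymorphic sites that contributed.
#' @slot droppedMass Expected mass projected to j = 0 or j = m.
#' @slot nExcludedLowAN Sites skipped because `an < m` (cannot project up).
#' @export
setClass("SiteFreqSpectrum",
  slots = c(m = "integer", bins = "numeric", nSitesUsed = "numeric",
            droppedMass = "numeric", nExcludedLowAN = "integer")
)

setValidity("SiteFreqSpectrum", function(object) {
  if (length(object@bins) != object@m - 1L) {
    return("bins must have length m - 1")
  }
  if (any(object@bins < -1e-12)) return("bins must be non-negative")
  tot <- sum(object@bins) + object@droppedMass
  if (abs(tot - object@nSitesUsed) > 1e-9 * max(1, object@nSitesUsed)) {
    return("sum(bins) + droppedMass must equal nSitesUsed")
  }
  TRUE
})

#' @rdname SiteFreqSpectrum-class
#' @param x A `SiteFreqSpectrum`.
#' @export
sfsBins <- function(x) {
  stopifnot(is(x, "SiteFreqSpectrum"))
  x@bins
}

#' @rdname SiteFreqSpectrum-class
#' @export
sfsM <- function(x) {
  stopifnot(is(x, "SiteFreqSpectrum"))
  x@m
}

#' @rdname SiteFreqSpectrum-class
#' @export
sfsSitesUsed <- function(x) {
  stopifnot(is(x, "SiteFreqSpectrum"))
  x@nSitesUsed
}

setMethod("show", "SiteFreqSpectrum", function(object) {
  cat(sprintf(
    "SiteFreqSpectrum: m = %d, %s segregating sites used (%d excluded an < m)\n",
    object@m, format(object@nSitesUsed), object@nExcludedLowAN))
  if (sum(object@bins) > 0) {
    cat(sprintf("  singleton fraction = %.4f; dropped monomorphic mass = %.3f\n",
                object@bins[1] / sum(object@bins), object@droppedMass))
  }
})

#' Result of a selection contrast test
#'
#' Wraps a 2x2 contingency table, the headline ratio statistic (when the test
#' has one), the test statistic and p-value, and a significance call at the
#' chosen alpha. Produced by [singletonChi2Test()], [divergenceRatioTest()]
#' and [fixationRateContrast()].
#'
#' @slot testName Short test label.
#' @slot table 2x2 count matrix.
#' @slot statistic Test statistic (chi-squared value, or `NA` for Fisher).
#' @slot ratio Headline ratio (e.g. d_exon/d_intron); `NA` when undefined.
#' @slot pValue Two-sided p-value in [0, 1].
#' @slot alpha Significance level used for the call.
#' @slot significant Logical call, `pValue < alpha`.
#' @slot flags Character vector of warnings (e.g. low expected counts,
#'   undefined ratio denominators).
#' @export
setClass("SelTestResult",
  slots = c(testName = "character", table = "matrix", statistic = "numeric",
            ratio = "numeric", pValue = "numeric", alpha = "numeric",
            significant = "logical", flags = "character")
)

setValidity("SelTestResult", function(object) {
  if (!all(dim(object@table) == c(2L, 2L))) return("table must be 2x2")
  if (any(object@table < 0)) return("table entries must be non-negative")
  p <- object@pValue
  if (!is.na(p) && (p < 0 || p > 1)) return("pValue must be in [0, 1]")
  if (!is.na(object@ratio) && object@ratio < 0) {
    return("ratio must be non-negative when defined")
  }
  TRUE
})

SelTestResult <- function(testName, table, statistic = NA_real_,
                          ratio = NA_real_, pValue, alpha = 0.05,
                          flags = character(0)) {
  new("SelTestResult", testName = testName, table = table,
      statistic = as.numeric(statistic), ratio = as.numeric(ratio),
      pValue = as.numeric(pValue), alpha = alpha,
      significant = isTRUE(pValue < alpha), flags = flags)
}

#' @rdname SelTestResult-class
#' @param x A `SelTestResult`.
#' @export
testPValue <- function(x) {
  stopifnot(is(x, "SelTestResult"))
  x@pValue
}

#' @rdname SelTestResult-class
#' @export
testRatio <- function(x) {
  stopifnot(is(x, "SelTestResult"))
  x@ratio
}

#' @rdname SelTestResult-class
#' @export
testTable <- function(x) {
  stopifnot(is(x, "SelTestResult"))
  x@table
}

#' @rdname SelTestResult-class
#' @export
isSignificant <- function(x) {
  stopifnot(is(x, "SelTestResult"))
  x@significant
}

setMethod("show", "SelTestResult", function(object) {
  cat(sprintf("%s: p = %.4g%s%s%s\n", object@testName, object@pValue,
              if (!is.na(object@ratio))
                sprintf(", ratio = %.3f", object@ratio) else "",
              if (!is.na(object@statistic))
                sprintf(", statistic = %.3f", object@statistic) else "",
              if (object@significant) " *" else ""))
  print(object@table)
  if (length(object@flags) > 0) {
    cat("flags:", paste(object@flags, collapse = "; "), "\n")
  }
})

#' Per-stratum polymorphism and divergence tallies
#'
#' For each genomic stratum (exon, intron, optionally the LTR-derived part of
#' exon 1): the number of human-lineage substitutions (SNS), the number of
#' human polymorphisms (SNV), and the number of alignable, outgroup-concordant
#' sites. A polymorphic position is never double-counted as a substitution.
#'
#' @slot counts `data.frame` with columns `stratum`, `sns`, `snv`, `sites`.
#' @slot excludedColumns Alignment columns excluded (gap/N or
#'   chimpanzee-bonobo discordance).
#' @export
setClass("DivergenceCounts",
  slots = c(counts = "data.frame", excludedColumns = "integer")
)

setValidity("DivergenceCounts", function(object) {
  df <- object@counts
  need <- c("stratum", "sns", "snv", "sites")
  if (!all(need %in% names(df))) {
    return("counts needs columns stratum, sns, snv, sites")
  }
  if (any(df$sns < 0) || any(df$snv < 0) || any(df$sites < 0)) {
    return("counts must be non-negative")
  }
  if (any(df$sns > df$sites)) return("need sns <= sites per stratum")
  TRUE
})

#' Construct DivergenceCounts from per-stratum tallies
#' @param stratum,sns,snv,sites Parallel vectors of stratum labels and counts.
#' @param excludedColumns Number of excluded alignment columns.
#' @return A [DivergenceCounts-class] object.
#' @export
DivergenceCounts <- function(stratum, sns, snv, sites, excludedColumns = 0L) {
  new("DivergenceCounts",
      counts = data.frame(stratum = as.character(stratum),
                          sns = as.numeric(sns), snv = as.numeric(snv),
                          sites = as.numeric(sites),
                          stringsAsFactors = FALSE),
      excludedColumns = as.integer(excludedColumns))
}

#' @rdname DivergenceCounts
#' @param x A `DivergenceCounts`.
#' @export
divergenceTable <- function(x) {
  stopifnot(is(x, "DivergenceCounts"))
  x@counts
}

setMethod("show", "DivergenceCounts", function(object) {
  cat("DivergenceCounts (", object@excludedColumns,
      "alignment columns excluded )\n")
  print(object@counts, row.names = FALSE)
})

#' Aligned human-chimpanzee-bonobo trio
#'
#' Three gap-aligned sequences of equal length plus a map from alignment
#' columns to 1-based human genomic coordinates (NA at human gap columns).
#' Used to infer human-lineage substitutions by parsimony against the
#' chimpanzee-bonobo pair.
#'
#' @slot chrom Human chromosome name.
#' @slot human,chimp,bonobo Aligned sequences (upper-case, `-` for gaps).
#' @slot humanPos Integer vector, one entry per column.
#' @export
setClass("TrioAlignment",
  slots = c(chrom = "character", human = "character", chimp = "character",
            bonobo = "character", humanPos = "integer")
)

setValidity("TrioAlignment", function(object) {
  lens <- nchar(c(object@human, object@chimp, object@bonobo))
  if (length(unique(lens)) != 1L) return("aligned sequences must have equal length")
  if (length(object@humanPos) != lens[1]) {
    return("humanPos must have one entry per alignment column")
  }
  pos <- object@humanPos[!is.na(object@humanPos)]
  if (is.unsorted(pos, strictly = TRUE)) {
    return("humanPos must be strictly increasing over non-gap columns")
  }
  TRUE
})

#' Construct a TrioAlignment
#'
#' @param human,chimp,bonobo Aligned sequences as single strings.
#' @param chrom Human chromosome name.
#' @param humanStart 1-based genomic coordinate of the first non-gap human
#'   base; the column map is derived by counting non-gap human characters.
#' @return A [TrioAlignment-class] object.
#' @export
TrioAlignment <- function(human, chimp, bonobo, chrom = "synth1",
                          humanStart = 1L) {
  human <- toupper(human); chimp <- toupper(chimp); bonobo <- toupper(bonobo)
  hchar <- strsplit(human, "")[[1]]
  isbase <- hchar != "-"
  humanPos <- rep(NA_integer_, length(hchar))
  humanPos[isbase] <- humanStart - 1L + seq_len(sum(isbase))
  new("TrioAlignment", chrom = chrom, human = human, chimp = chimp,
      bonobo = bonobo, humanPos = humanPos)
}

#' @rdname TrioAlignment
#' @param x A `TrioAlignment`.
#' @export
alignmentLength <- function(x) {
  stopifnot(is(x, "TrioAlignment"))
  nchar(x@human)
}

#' @rdname TrioAlignment
#' @export
humanPositions <- function(x) {
  stopifnot(is(x, "TrioAlignment"))
  x@humanPos
}

setMethod("show", "TrioAlignment", function(object) {
  cat(sprintf("TrioAlignment on %s: %d columns, human span %d-%d\n",
              object@chrom, alignmentLength(object),
              min(object@humanPos, na.rm = TRUE),
              max(object@humanPos, na.rm = TRUE)))
})
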