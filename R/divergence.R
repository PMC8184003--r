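#' Read a human-chimpanzee-bonobo alignment from FASTA
#'
#' Expects a FASTA multiple sequence alignment with exactly three records,
#' human first, then chimpanzee and bonobo. The human genomic start
#' coordinate anchors the column-to-coordinate map.
#'
#' @param path Aligned FASTA.
#' @param chrom Human chromosome name.
#' @param humanStart 1-based position of the first non-gap human base.
#' @return A [TrioAlignment-class].
#' @export
readTrioAlignment <- function(path, chrom = "synth1", humanStart = 1L) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) != 3L) {
    stop("trio alignment must have exactly 3 records (human, chimp, bonobo); ",
         "got ", length(seqs))
  }
  if (length(unique(Biostrings::width(seqs))) != 1L) {
    stop("aligned sequences differ in length")
  }
  TrioAlignment(as.character(seqs[[1]]), as.character(seqs[[2]]),
                as.character(seqs[[3]]), chrom = chrom,
                humanStart = humanStart)
}

#' Parsimony call for one alignment column
#'
#' The ancestral base of the human lineage is taken as the
#' chimpanzee-bonobo consensus: when the two outgroups agree on a base, a
#' differing (non-gap) human base is a human-lineage substitution. Columns
#' where the outgroups disagree, or where any species shows a gap or
#' ambiguous base, are excluded from both the substitution numerator and the
#' site denominator.
#'
#' @param human,chimp,bonobo Single characters (vectorized).
#' @return Character vector:
#'   `"substitution_on_human_lineage"`, `"no_change"` or `"excluded"`.
#' @examples
#' inferAncestralState("A", "G", "G")  # substitution on the human lineage
#' inferAncestralState("G", "G", "A")  # excluded: ancestor ambiguous
#' @export
inferAncestralState <- function(human, chimp, bonobo) {
  human <- toupper(human); chimp <- toupper(chimp); bonobo <- toupper(bonobo)
  valid <- chimp %in% BASES & bonobo %in% BASES & human %in% BASES
  concordant <- chimp == bonobo
  out <- rep("excluded", length(human))
  ok <- valid & concordant
  out[ok & human != chimp] <- "substitution_on_human_lineage"
  out[ok & human == chimp] <- "no_change"
  out
}

#' Count substitutions and polymorphisms per stratum
#'
#' Walks the alignment columns, calls human-lineage substitutions by
#' [inferAncestralState()], and tallies per stratum: `sns` (substitution
#' columns), `snv` (polymorphic sites from `sites` falling on alignable,
#' non-excluded columns) and `sites` (all non-excluded columns). A position
#' that is polymorphic in humans is counted as an SNV only, never also as a
#' substitution (polymorphism takes precedence over apparent divergence).
#'
#' @param aln A [TrioAlignment-class].
#' @param sites An [SNVSites-class] of human polymorphisms on the same
#'   coordinates.
#' @param strata `data.frame` from [classifyRegion()]/[annotateSites()]
#'   covering the alignment's human positions (columns `pos`, `region`,
#'   `ltr_overlap`).
#' @param splitLtrExon If `TRUE` (default), exonic LTR-overlapping positions
#'   are additionally reported as a separate `exon_ltr` stratum; the plain
#'   `exon` stratum always includes them (the screen convention), so use the
#'   `exon_ltr` row to subtract them when an LTR-free exon estimate is
#'   wanted.
#' @return A [DivergenceCounts-class].
#' @export
countDivergence <- function(aln, sites, strata, splitLtrExon = TRUE) {
  stopifnot(is(aln, "TrioAlignment"), is(sites, "SNVSites"))
  h <- strsplit(aln@human, "")[[1]]
  c1 <- strsplit(aln@chimp, "")[[1]]
  b1 <- strsplit(aln@bonobo, "")[[1]]
  state <- inferAncestralState(h, c1, b1)
  pos <- aln@humanPos

  stab <- siteTable(sites)
  stab <- stab[stab$chrom == aln@chrom, , drop = FALSE]
  isPoly <- pos %in% stab$pos

  ridx <- match(pos, strata$pos)
  if (all(is.na(ridx[!is.na(pos)]))) {
    stop("stratum table does not cover the alignment's human coordinates")
  }
  region <- strata$region[ridx]
  ltr <- strata$ltr_overlap[ridx]

  usable <- state != "excluded" & !is.na(region)
  tallyFor <- function(sel) {
    c(sns = sum(usable & sel & state == "substitution_on_human_lineage" &
                  !isPoly),
      snv = sum(usable & sel & isPoly),
      sites = sum(usable & sel))
  }
  strataNames <- c("exon", "intron")
  rows <- lapply(strataNames, function(s) tallyFor(region == s))
  names(rows) <- strataNames
  if (splitLtrExon && any(usable & region == "exon" & ltr, na.rm = TRUE)) {
    rows$exon_ltr <- tallyFor(region == "exon" & ltr)
  }
  df <- do.call(rbind, rows)
  DivergenceCounts(stratum = rownames(df), sns = df[, "sns"],
                   snv = df[, "snv"], sites = df[, "sites"],
                   excludedColumns = sum(!usable))
}

.getStratum <- function(counts, s) {
  df <- divergenceTable(counts)
  i <- match(s, df$stratum)
  if (is.na(i)) stop("stratum not present in DivergenceCounts: ", s)
  df[i, ]
}

#' Exon versus intron divergence-ratio test
#'
#' Compares the per-alignable-site substitution rate of exons against
#' introns: `d_s = sns_s / sites_s`, headline ratio `d_exon / d_intron`, and
#' a two-sided Fisher exact test on
#' `[[sns_exon, sites_exon - sns_exon], [sns_intron, sites_intron - sns_intron]]`.
#' Under purifying selection on exonic sites, the ratio falls below one.
#'
#' @param counts A [DivergenceCounts-class].
#' @param exon,intron Stratum labels to contrast.
#' @param alpha Significance level.
#' @return A [SelTestResult-class] with the ratio in `testRatio()`.
#' @export
divergenceRatioTest <- function(counts, exon = "exon", intron = "intron",
                                alpha = 0.05) {
  e <- .getStratum(counts, exon)
  i <- .getStratum(counts, intron)
  if (e$sites <= 0 || i$sites <= 0) {
    stop("both strata need sites > 0 for the divergence ratio")
  }
  tab <- rbind(exon = c(sns = e$sns, other = e$sites - e$sns),
               intron = c(sns = i$sns, other = i$sites - i$sns))
  flags <- character(0)
  dIntron <- i$sns / i$sites
  ratio <- if (dIntron > 0) (e$sns / e$sites) / dIntron else NA_real_
  if (dIntron == 0) flags <- "intron divergence is zero; ratio undefined"
  SelTestResult("divergence ratio (Fisher)", tab, ratio = ratio,
                pValue = fisherTwoSided(tab), alpha = alpha, flags = flags)
}

#' Fixation-rate contrast (McDonald-Kreitman-style)
#'
#' Contrasts the substitutions-per-polymorphism rate of exons against
#' introns: ratio `(sns_exon / snv_exon) / (sns_intron / snv_intron)` with a
#' two-sided Fisher exact test on
#' `[[sns_exon, snv_exon], [sns_intron, snv_intron]]`. Purifying selection
#' removes exonic mutations before fixation while still letting them
#' segregate at low frequency, driving the ratio below one.
#'
#' @inheritParams divergenceRatioTest
#' @return A [SelTestResult-class].
#' @export
fixationRateContrast <- function(counts, exon = "exon", intron = "intron",
                                 alpha = 0.05) {
  e <- .getStratum(counts, exon)
  i <- .getStratum(counts, intron)
  if (e$snv <= 0 || i$snv <= 0) {
    stop("both strata need snv > 0 for the fixation-rate contrast")
  }
  tab <- rbind(exon = c(sns = e$sns, snv = e$snv),
               intron = c(sns = i$sns, snv = i$snv))
  flags <- character(0)
  denom <- i$sns / i$snv
  ratio <- if (denom > 0) (e$sns / e$snv) / denom else NA_real_
  if (denom == 0) flags <- "intron fixation rate is zero; ratio undefined"
  SelTestResult("fixation-rate contrast (Fisher)", tab, ratio = ratio,
                pValue = fisherTwoSided(tab), alpha = alpha, flags = flags)
}

#' Load per-stratum divergence counts from a TSV
#'
#' Accepts a generic counts table with columns `stratum`, `sns`, `snv` and
#' `sites` (the shape in which published per-locus polymorphism/substitution
#' tallies are distributed), for running the ratio tests without recounting
#' from an alignment.
#'
#' @param path TSV with a header.
#' @return A [DivergenceCounts-class].
#' @export
readDivergenceCounts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("stratum", "sns", "snv", "sites")
  if (!all(need %in% names(df))) {
    stop("counts TSV needs columns: ", paste(need, collapse = ", "))
  }
  DivergenceCounts(df$stratum, df$sns, df$snv, df$sites)
}
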