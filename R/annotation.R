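#' Read one transcript's gene model from a GTF file
#'
#' Extracts the exon (and CDS, if present) intervals of a single transcript.
#' The analysis transcript must be named explicitly; statistics for a locus
#' are reported for one stated isoform rather than an automatic canonical
#' pick.
#'
#' @param path GTF file.
#' @param transcriptId Transcript to extract.
#' @param biotype Override for the biotype; if `NULL` it is taken from the
#'   GTF's `transcript_type`/`transcript_biotype`/`gene_biotype` attribute
#'   and mapped to `lncRNA`, `protein_coding` or `other`.
#' @return A [GeneModel-class] object.
#' @export
readGeneModelGTF <- function(path, transcriptId, biotype = NULL) {
  gtf <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gtf)
  if (!"transcript_id" %in% colnames(meta)) {
    stop("GTF has no transcript_id attribute")
  }
  sel <- gtf[!is.na(meta$transcript_id) & meta$transcript_id == transcriptId]
  if (length(sel) == 0L) stop("transcript not found in GTF: ", transcriptId)
  type <- S4Vectors::mcols(sel)$type
  exons <- sel[type == "exon"]
  cds <- sel[type == "CDS"]
  if (length(exons) == 0L) stop("transcript has no exon records: ", transcriptId)
  if (is.null(biotype)) {
    cols <- intersect(c("transcript_type", "transcript_biotype", "gene_biotype",
                        "gene_type"), colnames(S4Vectors::mcols(exons)))
    raw <- if (length(cols) > 0) S4Vectors::mcols(exons)[[cols[1]]][1] else NA
    biotype <- if (is.na(raw)) "other"
      else if (raw %in% c("lncRNA", "lincRNA")) "lncRNA"
      else if (raw == "protein_coding") "protein_coding" else "other"
  }
  gid <- S4Vectors::mcols(exons)$gene_id[1]
  if (is.null(gid) || is.na(gid)) gid <- transcriptId
  GeneModel(
    geneId = gid, transcriptId = transcriptId,
    chrom = as.character(GenomicRanges::seqnames(exons))[1],
    exonStarts = GenomicRanges::start(exons),
    exonEnds = GenomicRanges::end(exons),
    strand = as.character(GenomicRanges::strand(exons))[1],
    cdsStarts = GenomicRanges::start(cds), cdsEnds = GenomicRanges::end(cds),
    biotype = biotype
  )
}

#' Read a RepeatMasker annotation
#'
#' Parses the whitespace-delimited RepeatMasker `.out` format (3 header
#' lines), or a BED file with the repeat name in the name column. RepeatMasker
#' query coordinates are 1-based inclusive; BED input is 0-based half-open and
#' is converted at the reader boundary (rtracklayer handles this).
#'
#' @param path `.out` or `.bed` file.
#' @return `GRanges` with metadata columns `repeat_name` and `repeat_class`.
#' @export
readRepeatMasker <- function(path) {
  if (grepl("\\.bed(\\.gz)?$", path)) {
    gr <- rtracklayer::import(path, format = "bed")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      repeat_name = S4Vectors::mcols(gr)$name,
      repeat_class = NA_character_)
    return(gr)
  }
  lines <- readLines(path)
  # .out: two header lines plus a blank separator, then data rows
  dat <- grep("^\\s*\\d", lines, value = TRUE)
  if (length(dat) == 0L) {
    return(GRanges(repeat_name = character(0), repeat_class = character(0)))
  }
  fields <- strsplit(trimws(dat), "\\s+")
  ok <- vapply(fields, length, integer(1)) >= 11L
  if (!all(ok)) stop("malformed RepeatMasker .out line(s): ",
                     paste(which(!ok)[1], collapse = ", "))
  getf <- function(i) vapply(fields, `[[`, character(1), i)
  gr <- GRanges(getf(5),
                IRanges(as.integer(getf(6)), as.integer(getf(7))))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(repeat_name = getf(10),
                                               repeat_class = getf(11))
  gr
}

#' Classify sites into exon / intron / intergenic strata with an LTR flag
#'
#' Region labels partition the genome relative to one transcript: positions
#' inside an exon are `exon`, positions inside the transcript span but not in
#' an exon are `intron`, everything else is `intergenic`. LTR-derived status
#' is orthogonal (the HERV-H-derived part of ESRG's exon 1 is both `exon` and
#' LTR-derived), so it is returned as a logical flag set when the position
#' falls in a repeat interval whose name is in `ltrNames`.
#'
#' @param x An [SNVSites-class] object, or an integer vector of 1-based
#'   positions (then `chrom` must be given).
#' @param gene A [GeneModel-class].
#' @param repeats `GRanges` from [readRepeatMasker()], or `NULL` for no
#'   repeat annotation.
#' @param ltrNames Repeat names counted as LTR-derived.
#' @param chrom Chromosome of `x` when `x` is a plain position vector.
#' @return `data.frame` with columns `chrom`, `pos`, `gene_id`, `region`
#'   (`exon`/`intron`/`intergenic`) and `ltr_overlap`.
#' @examples
#' gm <- GeneModel("g", "t", "synth1", c(101, 301), c(200, 400))
#' classifyRegion(c(150, 250, 450), gm, chrom = "synth1")
#' @export
classifyRegion <- function(x, gene, repeats = NULL,
                           ltrNames = c("LTR7", "HERV-H-int"),
                           chrom = NULL) {
  stopifnot(is(gene, "GeneModel"))
  geneChrom <- as.character(GenomicRanges::seqnames(gene@exons))[1]
  if (is(x, "SNVSites")) {
    tab <- siteTable(x)
    pos <- tab$pos
    chrom <- tab$chrom
  } else {
    pos <- as.integer(x)
    if (is.null(chrom)) chrom <- geneChrom
    chrom <- rep_len(chrom, length(pos))
  }
  if (length(pos) > 0 && any(chrom != geneChrom)) {
    stop("site(s) on a different chromosome than gene ", gene@geneId,
         " (", geneChrom, ")")
  }
  gr <- GRanges(chrom, IRanges(pos, width = 1L))
  inExon <- IRanges::overlapsAny(gr, gene@exons)
  span <- geneSpan(gene)
  inSpan <- IRanges::overlapsAny(gr, span)
  region <- ifelse(inExon, "exon", ifelse(inSpan, "intron", "intergenic"))
  ltr <- if (is.null(repeats) || length(repeats) == 0L) {
    rep(FALSE, length(pos))
  } else {
    ltrIv <- repeats[S4Vectors::mcols(repeats)$repeat_name %in% ltrNames]
    IRanges::overlapsAny(gr, ltrIv)
  }
  data.frame(chrom = chrom, pos = pos, gene_id = gene@geneId,
             region = region, ltr_overlap = ltr, stringsAsFactors = FALSE)
}

#' Classify variants as synonymous or nonsynonymous
#'
#' For sites in the CDS of a protein-coding transcript, substitutes the
#' alternate base into the reference codon (reverse-complementing on the
#' minus strand) and compares amino acids under the standard nuclear genetic
#' code; a stop gain counts as nonsynonymous. Sites in a lncRNA exon are
#' `noncoding`; exonic but non-CDS positions of coding genes (UTRs) and
#' non-exonic positions are `not_applicable`.
#'
#' @param sites An [SNVSites-class] object.
#' @param gene A [GeneModel-class].
#' @param genome Named [Biostrings::DNAStringSet] (names = chromosomes) or a
#'   path to a FASTA file.
#' @return Character vector, one of `synonymous`, `nonsynonymous`,
#'   `noncoding`, `not_applicable` per site.
#' @export
classifyCodingEffect <- function(sites, gene, genome) {
  stopifnot(is(sites, "SNVSites"), is(gene, "GeneModel"))
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  tab <- siteTable(sites)
  n <- nrow(tab)
  out <- rep("not_applicable", n)
  if (n == 0L) return(out)
  if (gene@biotype == "lncRNA") {
    reg <- classifyRegion(sites, gene)
    out[reg$region == "exon"] <- "noncoding"
    return(out)
  }
  if (gene@biotype != "protein_coding" || length(gene@cds) == 0L) return(out)

  chromName <- as.character(GenomicRanges::seqnames(gene@cds))[1]
  if (!chromName %in% names(genome)) {
    stop("chromosome ", chromName, " not found in genome sequence")
  }
  chromSeq <- genome[[chromName]]
  # genomic positions of the spliced CDS in genomic order, then
  # transcription order
  cdsPos <- unlist(lapply(seq_along(gene@cds), function(i) {
    seq(GenomicRanges::start(gene@cds)[i], GenomicRanges::end(gene@cds)[i])
  }))
  minus <- gene@txStrand == "-"
  txPos <- if (minus) rev(cdsPos) else cdsPos

  for (i in seq_len(n)) {
    if (tab$chrom[i] != chromName) next
    j <- match(tab$pos[i], txPos)   # position within the spliced CDS
    if (is.na(j)) next
    refGenome <- as.character(chromSeq[tab$pos[i]])
    if (refGenome != tab$ref[i]) {
      stop(sprintf("reference mismatch at %s:%d (VCF ref %s, genome %s)",
                   tab$chrom[i], tab$pos[i], tab$ref[i], refGenome))
    }
    codonIdx <- (j - 1L) %/% 3L
    inCodon <- j - codonIdx * 3L                 # 1, 2 or 3
    codonGenomic <- txPos[codonIdx * 3L + 1:3]   # transcription order
    bases <- vapply(codonGenomic, function(p) as.character(chromSeq[p]),
                    character(1))
    if (minus) bases <- complementBase(bases)
    altBase <- if (minus) complementBase(tab$alt[i]) else tab$alt[i]
    refCodon <- paste(bases, collapse = "")
    altBases <- bases
    altBases[inCodon] <- altBase
    altCodon <- paste(altBases, collapse = "")
    aaRef <- Biostrings::GENETIC_CODE[[refCodon]]
    aaAlt <- Biostrings::GENETIC_CODE[[altCodon]]
    out[i] <- if (identical(aaRef, aaAlt)) "synonymous" else "nonsynonymous"
  }
  out
}

#' Build the per-site stratum table
#'
#' Combines [classifyRegion()] and (when a genome sequence is supplied)
#' [classifyCodingEffect()] into the stratum table consumed by the
#' site-frequency and divergence modules.
#'
#' @inheritParams classifyRegion
#' @inheritParams classifyCodingEffect
#' @param sites An [SNVSites-class] object.
#' @return `data.frame` with columns chrom, pos, gene_id, region,
#'   ltr_overlap, coding_effect.
#' @export
annotateSites <- function(sites, gene, repeats = NULL, genome = NULL,
                          ltrNames = c("LTR7", "HERV-H-int")) {
  reg <- classifyRegion(sites, gene, repeats, ltrNames)
  reg$coding_effect <- if (!is.null(genome)) {
    classifyCodingEffect(sites, gene, genome)
  } else if (gene@biotype == "lncRNA") {
    ifelse(reg$region == "exon", "noncoding", "not_applicable")
  } else {
    rep("not_applicable", nrow(reg))
  }
  reg
}
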