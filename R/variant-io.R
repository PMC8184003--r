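#' Read bi-allelic SNVs with allele counts from a VCF
#'
#' Reads a population VCF and applies the site-level quality rules used for
#' gnomAD-style data: only single-nucleotide, bi-allelic records with
#' `FILTER = PASS` are retained. A position represented by a record with
#' several ALT alleles, or by several records, is multi-allelic and is
#' excluded entirely rather than decomposed. Allele counts are taken from the
#' `AC`/`AN` INFO fields; if absent they are derived from the genotype
#' columns.
#'
#' @param vcfPath Path to a VCF file (plain or bgzipped).
#' @param sampleChromosomes Nominal maximum `an`; defaults to the maximum
#'   observed `AN`.
#' @return An [SNVSites-class] object with `filter_pass = TRUE` throughout.
#' @examples
#' p <- samplePolymorphism(SimParams(seed = 1, nChrom = 200, m = 150))
#' vcf <- tempfile(fileext = ".vcf")
#' writeSiteVcf(p, vcf)
#' readSNVs(vcf)
#' @export
readSNVs <- function(vcfPath, sampleChromosomes = NULL) {
  if (!file.exists(vcfPath)) stop("VCF not found: ", vcfPath)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(vcfPath)),
    error = function(e) {
      stop("malformed VCF '", vcfPath, "': ", conditionMessage(e), call. = FALSE)
    })
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  if (n == 0L) return(SNVSites(character(0), integer(0), character(0),
                               character(0), integer(0), integer(0),
                               sampleChromosomes = sampleChromosomes))
  ref <- as.character(rr$REF)
  altL <- rr$ALT
  nAlt <- S4Vectors::elementNROWS(altL)
  alt1 <- rep(NA_character_, n)
  alt1[nAlt == 1L] <- as.character(unlist(altL[nAlt == 1L]))

  # positions seen in >1 record are multi-allelic even if each row has one ALT
  key <- paste0(as.character(GenomicRanges::seqnames(rr)), ":",
                GenomicRanges::start(rr))
  dupPos <- key %in% key[duplicated(key)]

  keep <- nAlt == 1L & !dupPos &
    nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    ref %in% BASES & alt1 %in% BASES
  filt <- VariantAnnotation::filt(vcf)
  keep <- keep & !is.na(filt) & filt == "PASS"
  if (!any(keep)) {
    return(SNVSites(character(0), integer(0), character(0), character(0),
                    integer(0), integer(0),
                    sampleChromosomes = sampleChromosomes))
  }

  acan <- .extractAcAn(vcf, keep)
  SNVSites(
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep],
    ref = ref[keep], alt = alt1[keep],
    ac = acan$ac, an = acan$an,
    filter_pass = TRUE, sampleChromosomes = sampleChromosomes
  )
}

# AC/AN from INFO, falling back to GT columns
.extractAcAn <- function(vcf, keep) {
  info <- VariantAnnotation::info(vcf)
  if (all(c("AC", "AN") %in% colnames(info))) {
    ac <- info$AC
    if (is(ac, "List") || is.list(ac)) {
      ac <- vapply(ac, function(v) as.integer(v[1]), integer(1))
    }
    an <- as.integer(info$AN)
    return(list(ac = as.integer(ac[keep]), an = an[keep]))
  }
  geno <- VariantAnnotation::geno(vcf)
  if (!"GT" %in% names(geno)) {
    stop("VCF has neither AC/AN INFO fields nor GT genotypes; ",
         "allele counts cannot be derived", call. = FALSE)
  }
  gt <- geno$GT[keep, , drop = FALSE]
  alleles <- apply(gt, 1, function(row) {
    toks <- unlist(strsplit(row, "[/|]"))
    toks <- toks[toks != "."]
    c(sum(toks == "1"), length(toks))
  })
  list(ac = as.integer(alleles[1, ]), an = as.integer(alleles[2, ]))
}

#' Read a per-position coverage summary table
#'
#' Expects a tab-separated file with a header and columns `chrom`, `pos` and
#' `frac_over_15x` (the fraction of individuals with depth at or above the
#' depth threshold at that position).
#'
#' @param path Path to the TSV.
#' @return `data.frame` with columns chrom, pos, frac.
#' @export
readCoverage <- function(path) {
  cov <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  fraccol <- intersect(c("frac_over_15x", "frac_over_threshold", "frac"),
                       names(cov))
  if (!all(c("chrom", "pos") %in% names(cov)) || length(fraccol) == 0) {
    stop("coverage table needs columns chrom, pos, frac_over_15x")
  }
  out <- data.frame(chrom = as.character(cov$chrom), pos = as.integer(cov$pos),
                    frac = as.numeric(cov[[fraccol[1]]]),
                    stringsAsFactors = FALSE)
  if (any(out$frac < 0 | out$frac > 1, na.rm = TRUE)) {
    stop("coverage fractions must lie in [0, 1]")
  }
  out
}

#' Apply the per-site coverage filter
#'
#' Retains sites where at least `minFrac` of individuals had depth at or
#' above `minDepth` (the table is assumed to encode that depth threshold, 15x
#' for the gnomAD summary files). Sites without a coverage row are dropped
#' and counted; if the fraction of such sites exceeds `mismatchThreshold`
#' the coverage table likely comes from a different genome build and a
#' warning (or error, with `onMismatch = "error"`) is raised.
#'
#' @param sites An [SNVSites-class] object.
#' @param coverage `data.frame` from [readCoverage()].
#' @param minDepth Depth threshold encoded by the table (informational).
#' @param minFrac Minimum fraction of individuals at that depth (0.95).
#' @param mismatchThreshold Fraction of sites without a coverage row above
#'   which a build mismatch is suspected.
#' @param onMismatch `"warn"` (default) or `"error"`.
#' @return Filtered [SNVSites-class]; the number of sites dropped for having
#'   no coverage row is attached as attribute `"droppedNoCoverage"`.
#' @export
applyCoverageFilter <- function(sites, coverage, minDepth = 15L,
                                minFrac = 0.95, mismatchThreshold = 0.5,
                                onMismatch = c("warn", "error")) {
  stopifnot(is(sites, "SNVSites"))
  onMismatch <- match.arg(onMismatch)
  if (length(sites) == 0L) return(sites)
  if (nrow(coverage) == 0L) {
    warning("empty coverage table: all ", length(sites), " sites dropped")
    out <- SNVSites(character(0), integer(0), character(0), character(0),
                    integer(0), integer(0),
                    sampleChromosomes = sites@sampleChromosomes)
    attr(out, "droppedNoCoverage") <- length(sites)
    return(out)
  }
  tab <- siteTable(sites)
  idx <- match(paste0(tab$chrom, ":", tab$pos),
               paste0(coverage$chrom, ":", coverage$pos))
  noCov <- is.na(idx)
  if (mean(noCov) > mismatchThreshold) {
    msg <- sprintf(
      "%.0f%% of sites have no coverage row; coverage table may be on a different genome build",
      100 * mean(noCov))
    if (onMismatch == "error") stop(msg) else warning(msg)
  } else if (any(noCov)) {
    message(sum(noCov), " site(s) without a coverage row dropped")
  }
  pass <- !noCov & coverage$frac[idx] >= minFrac
  out <- new("SNVSites", sites = sites@sites[pass],
             sampleChromosomes = sites@sampleChromosomes)
  attr(out, "droppedNoCoverage") <- sum(noCov)
  out
}

#' Write an SNVSites object as VCF
#'
#' Emits a minimal VCFv4.2 file carrying REF/ALT and the `AC`/`AN` INFO
#' fields; non-passing sites are written with `FILTER = FAIL`. The output
#' round-trips through [readSNVs()].
#'
#' @param sites An [SNVSites-class] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSiteVcf <- function(sites, path) {
  stopifnot(is(sites, "SNVSites"))
  tab <- siteTable(sites)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=lncsel",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Number of called chromosomes\">",
    "##FILTER=<ID=PASS,Description=\"Passed site quality filters\">",
    "##FILTER=<ID=FAIL,Description=\"Failed site quality filters\">",
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO"), collapse = "\t"))
  )
  rows <- if (nrow(tab) > 0) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tAC=%d;AN=%d",
            tab$chrom, tab$pos, tab$ref, tab$alt,
            ifelse(tab$filter_pass, "PASS", "FAIL"), tab$ac, tab$an)
  } else character(0)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write an SNVSites object as a site TSV
#'
#' @param sites An [SNVSites-class] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSiteTSV <- function(sites, path) {
  stopifnot(is(sites, "SNVSites"))
  utils::write.table(siteTable(sites)[, c("chrom", "pos", "ref", "alt",
                                          "ac", "an")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
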