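#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent named list), resolves
#' paths relative to the configuration file, checks that every referenced
#' input exists and that numeric parameters are in range, and fills in
#' defaults (m = 30,000; coverage 15x in 95% of individuals; 50-SNV screen
#' floor; phastCons threshold 0.9; 5% conserved cutoff; 40% detection and
#' mean count 5 for expression; alpha 0.05).
#'
#' @param config Path to a YAML file, or a named list.
#' @param require Character vector of path keys that must be present
#'   (callers pass the keys their stage needs).
#' @return Validated configuration list.
#' @export
validatePipelineConfig <- function(config, require = character(0)) {
  base <- "."
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    base <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(m = 30000L, min_snvs = 50L, alpha = 0.05,
                   min_coverage_frac = 0.95, phastcons_threshold = 0.9,
                   conserved_cutoff = 0.05, detect_frac = 0.4, min_mean = 5,
                   include_ltr_in_exon = TRUE,
                   ltr_names = c("LTR7", "HERV-H-int"), seed = 1L,
                   outdir = "results")
  config <- utils::modifyList(defaults, config)
  pathKeys <- c("vcf", "coverage", "gene_gtf", "repeats", "scores", "msa",
                "reference_bed", "screen_gtf", "counts", "metadata",
                "genome_fasta")
  for (k in intersect(pathKeys, names(config))) {
    pth <- config[[k]]
    if (!file.exists(pth)) pth <- file.path(base, config[[k]])
    if (!file.exists(pth)) stop("config path for '", k, "' not found: ",
                                config[[k]])
    config[[k]] <- pth
  }
  missing <- setdiff(require, names(config))
  if (length(missing) > 0) {
    stop("config is missing required key(s): ",
         paste(missing, collapse = ", "))
  }
  with(config, {
    stopifnot(m >= 2, min_snvs >= 1, alpha > 0, alpha < 1,
              min_coverage_frac >= 0, min_coverage_frac <= 1,
              phastcons_threshold >= 0, phastcons_threshold <= 1,
              conserved_cutoff >= 0, conserved_cutoff <= 1,
              detect_frac >= 0, detect_frac <= 1, min_mean >= 0)
  })
  if (!is.null(config$outdir) && !is.na(config$outdir)) {
    outbase <- config$outdir
    if (!grepl("^(/|[A-Za-z]:)", outbase)) {
      config$outdir <- file.path(base, outbase)
    }
  }
  config
}

.testToList <- function(x) {
  list(table = list(rownames = rownames(x@table),
                    counts = unname(apply(x@table, 1, as.numeric,
                                          simplify = FALSE))),
       ratio = x@ratio, statistic = x@statistic, p = x@pValue,
       alpha = x@alpha, significant = x@significant, flags = x@flags)
}

.sfsSummaryList <- function(sfs) {
  sf <- suppressWarnings(singletonFraction(sfs))
  list(m = sfs@m, n_sites_used = sfs@nSitesUsed,
       n_excluded_low_an = sfs@nExcludedLowAN,
       dropped_monomorphic_mass = sfs@droppedMass,
       singleton_fraction = sf$fraction)
}

#' Run the selection analysis end to end
#'
#' Orchestrates the full locus analysis: read and filter population SNVs,
#' stratify them against the gene model and repeat annotation, summarize
#' exonic conservation, build per-stratum downsampled spectra, contrast the
#' exonic singleton fraction against the neutral reference region, infer
#' human-lineage substitutions from the trio alignment and run the
#' divergence-ratio and fixation-rate Fisher contrasts, and (when a
#' multi-gene annotation is supplied) the genome-style singleton screen.
#' Writes TSV tables and a `report.json` into the configured output
#' directory; the printed statistics are the module return values, not
#' recomputations.
#'
#' @param config Path to a YAML configuration or a named list; see
#'   [validatePipelineConfig()]. Required keys: `vcf`, `coverage`,
#'   `gene_gtf`, `transcript_id`, `repeats`, `scores`, `msa`,
#'   `msa_human_start`, `reference_bed`.
#' @return The report, invisibly (a named list mirroring `report.json`).
#' @export
runSelectionAnalysis <- function(config) {
  cfg <- validatePipelineConfig(
    config, require = c("vcf", "coverage", "gene_gtf", "transcript_id",
                        "repeats", "scores", "msa", "msa_human_start",
                        "reference_bed"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  sites <- readSNVs(cfg$vcf)
  nRead <- length(sites)
  coverage <- readCoverage(cfg$coverage)
  sites <- applyCoverageFilter(sites, coverage,
                               minFrac = cfg$min_coverage_frac)
  gene <- readGeneModelGTF(cfg$gene_gtf, cfg$transcript_id)
  repeats <- readRepeatMasker(cfg$repeats)
  scores <- readScoreTrack(cfg$scores)
  aln <- readTrioAlignment(cfg$msa, chrom = cfg$msa_chrom %||% "synth1",
                           humanStart = cfg$msa_human_start)
  refRegion <- rtracklayer::import(cfg$reference_bed, format = "bed")

  strata <- classifyRegion(sites, gene, repeats, ltrNames = cfg$ltr_names)
  subsetSites <- function(keep) {
    new("SNVSites", sites = siteRanges(sites)[keep],
        sampleChromosomes = sampleChromosomes(sites))
  }
  exonSites <- subsetSites(strata$region == "exon")
  exonNoLtr <- subsetSites(strata$region == "exon" & !strata$ltr_overlap)
  intronSites <- subsetSites(strata$region == "intron")
  refSites <- subsetSites(IRanges::overlapsAny(siteRanges(sites), refRegion))

  consExon <- conservedFraction(geneExons(gene), scores,
                                threshold = cfg$phastcons_threshold,
                                geneId = gene@geneId)
  spanIv <- geneSpan(gene)
  consTranscript <- conservedFraction(spanIv, scores,
                                      threshold = cfg$phastcons_threshold,
                                      geneId = gene@geneId)
  consClass <- classifyLncrnaConservation(consExon,
                                          cutoff = cfg$conserved_cutoff)

  sfsExon <- buildSFS(exonSites, m = cfg$m)
  sfsExonNoLtr <- buildSFS(exonNoLtr, m = cfg$m)
  sfsIntron <- buildSFS(intronSites, m = cfg$m)
  sfsRef <- buildSFS(refSites, m = cfg$m)
  singletonTest <- singletonChi2Test(sfsExon, sfsRef, alpha = cfg$alpha)
  singletonTestNoLtr <- singletonChi2Test(sfsExonNoLtr, sfsRef,
                                          alpha = cfg$alpha)

  alnStrata <- classifyRegion(aln@humanPos[!is.na(aln@humanPos)], gene,
                              repeats, ltrNames = cfg$ltr_names)
  divCounts <- countDivergence(aln, sites, alnStrata)
  divTest <- divergenceRatioTest(divCounts, alpha = cfg$alpha)
  fixTest <- fixationRateContrast(divCounts, alpha = cfg$alpha)

  screen <- NULL
  if (!is.null(cfg$screen_gtf)) {
    screenGr <- rtracklayer::import(cfg$screen_gtf, format = "gtf")
    screenGr <- screenGr[S4Vectors::mcols(screenGr)$type == "exon"]
    ids <- S4Vectors::mcols(screenGr)$gene_id
    geneSites <- lapply(split(seq_along(screenGr), ids), function(ix) {
      subsetSites(IRanges::overlapsAny(siteRanges(sites), screenGr[ix]))
    })
    consClassScreen <- vapply(split(seq_along(screenGr), ids), function(ix) {
      prof <- conservedFraction(screenGr[ix], scores,
                                threshold = cfg$phastcons_threshold)
      if (prof$n_sites > 0 && !is.na(prof$frac_conserved) &&
          prof$frac_conserved > cfg$conserved_cutoff) "conserved" else "other"
    }, character(1))
    screen <- lncrnaSingletonScreen(geneSites, refSites,
                                    conservationClass = consClassScreen,
                                    minSNVs = cfg$min_snvs, m = cfg$m,
                                    alpha = cfg$alpha)
    utils::write.table(screen, file.path(cfg$outdir, "singleton_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  writeSiteTSV(sites, file.path(cfg$outdir, "filtered_sites.tsv"))
  writeSFS(sfsExon, file.path(cfg$outdir, "sfs_exon.tsv"))
  writeSFS(sfsIntron, file.path(cfg$outdir, "sfs_intron.tsv"))
  writeSFS(sfsRef, file.path(cfg$outdir, "sfs_reference.tsv"))
  utils::write.table(divergenceTable(divCounts),
                     file.path(cfg$outdir, "divergence_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  report <- list(
    gene = gene@geneId, transcript = gene@transcriptId, seed = cfg$seed,
    n_sites_read = nRead, n_sites_after_coverage = length(sites),
    n_dropped_no_coverage = attr(sites, "droppedNoCoverage"),
    conservation = list(
      exons = as.list(consExon), transcript = as.list(consTranscript),
      class = consClass, threshold = cfg$phastcons_threshold,
      cutoff = cfg$conserved_cutoff),
    sfs = list(exon = .sfsSummaryList(sfsExon),
               exon_no_ltr = .sfsSummaryList(sfsExonNoLtr),
               intron = .sfsSummaryList(sfsIntron),
               reference = .sfsSummaryList(sfsRef)),
    singleton_test = .testToList(singletonTest),
    singleton_test_excluding_ltr = .testToList(singletonTestNoLtr),
    divergence = list(counts = divergenceTable(divCounts),
                      excluded_columns = divCounts@excludedColumns),
    divergence_ratio_test = .testToList(divTest),
    fixation_rate_contrast = .testToList(fixTest),
    screen = screen
  )
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(report)
}

#' Run the cross-species expression screen
#'
#' Filters the count matrix to expressed genes, fits the interaction
#' differential-expression model and reports the focal gene's interaction
#' log2 fold change and its expression percentile in each species' iPSC
#' (and cardiomyocyte) group. Writes `de_table.tsv` and
#' `expression_report.json` into the output directory.
#'
#' @param config Path to a YAML configuration or a named list; required
#'   keys: `counts`, `metadata`, `focal_gene`.
#' @return The report, invisibly.
#' @export
runExpressionScreen <- function(config) {
  cfg <- validatePipelineConfig(config,
                                require = c("counts", "metadata",
                                            "focal_gene"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- readCountMatrix(cfg$counts)
  metadata <- readSampleMetadata(cfg$metadata)
  if (nrow(metadata) == 0) stop("empty sample metadata")
  keep <- sub("-", "_", metadata$cell_type) %in% c("iPSC", "iPSC_CM")
  metadata <- metadata[keep, , drop = FALSE]
  counts <- counts[, metadata$sample, drop = FALSE]

  filtered <- filterExpressed(counts, detectFrac = cfg$detect_frac,
                              minMean = cfg$min_mean)
  de <- interactionDE(filtered, metadata)
  de <- de[order(de$p), ]
  utils::write.table(de, file.path(cfg$outdir, "de_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  focal <- cfg$focal_gene
  percentiles <- list()
  for (sp in unique(metadata$species)) {
    for (ct in unique(sub("-", "_", metadata$cell_type))) {
      key <- paste(sp, ct, sep = "_")
      percentiles[[key]] <- tryCatch(
        expressionPercentile(filtered, metadata, focal, sp, ct),
        error = function(e) NA_real_)
    }
  }
  focalRow <- de[de$gene == focal, , drop = FALSE]
  report <- list(
    n_genes_input = nrow(counts), n_genes_after_filter = nrow(filtered),
    focal_gene = focal,
    focal_interaction_lfc = if (nrow(focalRow)) focalRow$lfc else NA,
    focal_p_adj = if (nrow(focalRow)) focalRow$p_adj else NA,
    focal_percentiles = percentiles,
    top_gene = de$gene[1]
  )
  jsonlite::write_json(report, file.path(cfg$outdir,
                                         "expression_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
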