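.geneModelToGtf <- function(gene) {
  ex <- gene@exons
  gr <- c(GenomicRanges::reduce(geneSpan(gene)), ex)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "lncsel",
    type = c("transcript", rep("exon", length(ex))),
    gene_id = gene@geneId, transcript_id = gene@transcriptId,
    transcript_type = gene@biotype)
  GenomicRanges::strand(gr) <- gene@txStrand
  gr
}

.screenGenesToGtf <- function(screenGenes) {
  ids <- S4Vectors::mcols(screenGenes)$gene_id
  gr <- screenGenes
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "lncsel", type = "exon", gene_id = ids,
    transcript_id = paste0(ids, "_tx"), transcript_type = "lncRNA")
  gr
}

#' Write a synthetic dataset to standard file formats
#'
#' Materializes a [simulateDataset()] result as the file set a real analysis
#' would consume — VCF, coverage TSV, GTF gene models, repeat BED,
#' bedGraph conservation track, trio-alignment FASTA, genome FASTA, count
#' and metadata TSVs — plus a manifest JSON recording the generator
#' parameters and a ready-to-run pipeline `config.yaml`. Outputs are
#' byte-identical across runs with identical parameters.
#'
#' @param dataset List from [simulateDataset()].
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
writeSyntheticData <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  paths <- list(
    vcf = p("sites.vcf"), coverage = p("coverage.tsv"),
    gene_gtf = p("gene.gtf"), repeats_bed = p("repeats.bed"),
    scores = p("scores.bedGraph"), msa = p("trio_alignment.fasta"),
    genome = p("genome.fa"), counts = p("counts.tsv"),
    metadata = p("metadata.tsv"), reference_bed = p("reference_region.bed"),
    manifest = p("manifest.json"), config = p("config.yaml")
  )
  writeSiteVcf(dataset$sites, paths$vcf)
  utils::write.table(dataset$coverage, paths$coverage, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rtracklayer::export(.geneModelToGtf(dataset$gene), paths$gene_gtf,
                      format = "gtf")
  rep_bed <- dataset$repeats
  S4Vectors::mcols(rep_bed) <- S4Vectors::DataFrame(
    name = S4Vectors::mcols(dataset$repeats)$repeat_name)
  rtracklayer::export(rep_bed, paths$repeats_bed, format = "bed")
  rtracklayer::export(dataset$scores, paths$scores, format = "bedGraph")

  aln <- dataset$alignment
  seqs <- Biostrings::BStringSet(c(human = aln@human, chimpanzee = aln@chimp,
                                   bonobo = aln@bonobo))
  Biostrings::writeXStringSet(seqs, paths$msa)
  genome <- Biostrings::DNAStringSet(dataset$humanSeq)
  names(genome) <- dataset$layout$chrom
  Biostrings::writeXStringSet(genome, paths$genome)

  utils::write.table(
    data.frame(gene = rownames(dataset$counts), dataset$counts,
               check.names = FALSE),
    paths$counts, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$metadata, paths$metadata, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rtracklayer::export(dataset$referenceRegion, paths$reference_bed,
                      format = "bed")
  if (!is.null(dataset$screenGenes)) {
    paths$screen_gtf <- p("screen_genes.gtf")
    rtracklayer::export(.screenGenesToGtf(dataset$screenGenes),
                        paths$screen_gtf, format = "gtf")
  }

  prm <- dataset$params
  manifest <- lapply(slotNames(prm), function(s) methods::slot(prm, s))
  names(manifest) <- slotNames(prm)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  config <- list(
    vcf = "sites.vcf", coverage = "coverage.tsv", gene_gtf = "gene.gtf",
    transcript_id = dataset$gene@transcriptId, repeats = "repeats.bed",
    scores = "scores.bedGraph", msa = "trio_alignment.fasta",
    msa_chrom = dataset$layout$chrom,
    msa_human_start = dataset$layout$alnStart,
    reference_bed = "reference_region.bed",
    counts = "counts.tsv", metadata = "metadata.tsv",
    focal_gene = "focal_lnc",
    m = prm@m, min_snvs = 50L, alpha = 0.05, min_coverage_frac = 0.95,
    phastcons_threshold = 0.9, conserved_cutoff = 0.05,
    detect_frac = 0.4, min_mean = 5,
    ltr_names = c("LTR7", "HERV-H-int"), seed = prm@seed,
    outdir = "results"
  )
  if (!is.null(dataset$screenGenes)) config$screen_gtf <- "screen_genes.gtf"
  yaml::write_yaml(config, paths$config)
  invisible(paths)
}
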