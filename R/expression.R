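#' Read a genes-by-samples count matrix and its sample metadata
#'
#' `readCountMatrix()` reads a TSV/CSV with gene identifiers in the first
#' column; `readSampleMetadata()` reads a TSV with columns `sample`,
#' `species` (`human`/`chimpanzee`) and `cell_type` (`iPSC`/`iPSC_CM`).
#'
#' @param path File path.
#' @return Integer matrix, or a `data.frame` of metadata.
#' @export
readCountMatrix <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' @rdname readCountMatrix
#' @export
readSampleMetadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample", "species", "cell_type")
  if (!all(need %in% names(md))) {
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  }
  md
}

#' Filter to expressed genes
#'
#' Keeps genes detected (count > 0) in at least `detectFrac` of the samples
#' and with a mean count of at least `minMean`, both computed over all
#' retained samples. Both boundaries are inclusive. Applied after subsetting
#' to the samples of interest.
#'
#' @param counts Genes-by-samples integer matrix.
#' @param detectFrac Minimum detection fraction (0.4).
#' @param minMean Minimum mean count (5).
#' @return The filtered matrix; number of dropped genes as attribute
#'   `"droppedGenes"`.
#' @export
filterExpressed <- function(counts, detectFrac = 0.4, minMean = 5) {
  stopifnot(is.matrix(counts), ncol(counts) > 0)
  detected <- rowMeans(counts > 0) >= detectFrac
  abundant <- rowMeans(counts) >= minMean
  keep <- detected & abundant
  if (!any(keep)) warning("no genes survive the expression filter")
  out <- counts[keep, , drop = FALSE]
  attr(out, "droppedGenes") <- sum(!keep)
  out
}

.checkDesign <- function(metadata) {
  metadata$species <- factor(metadata$species,
                             levels = c("chimpanzee", "human"))
  metadata$cell_type <- factor(sub("-", "_", metadata$cell_type),
                               levels = c("iPSC_CM", "iPSC"))
  if (anyNA(metadata$species) || anyNA(metadata$cell_type)) {
    stop("species must be human/chimpanzee and cell_type iPSC/iPSC_CM")
  }
  cells <- table(metadata$species, metadata$cell_type)
  if (any(cells < 2)) {
    bad <- which(cells < 2, arr.ind = TRUE)
    stop("need >= 2 samples per species x cell-type cell; short: ",
         paste(rownames(cells)[bad[, 1]], colnames(cells)[bad[, 2]],
               sep = ":", collapse = ", "))
  }
  metadata
}

#' Interaction-term differential expression between species
#'
#' Fits the per-gene negative-binomial generalized linear model of DESeq2
#' (median-of-ratios size factors, trended dispersion shrinkage, Wald tests,
#' no fold-change shrinkage) with species and cell-type factors plus their
#' interaction, and extracts the species-by-cell-type interaction
#' coefficient: the human-versus-chimpanzee log2 fold change that is
#' specific to the iPSC state, i.e. not explained by the species difference
#' seen in cardiomyocytes. Benjamini-Hochberg adjustment is applied across
#' genes.
#'
#' @param counts Filtered genes-by-samples integer matrix.
#' @param metadata `data.frame` with one row per column of `counts`
#'   (matched by `sample` or by order) and columns `species`, `cell_type`.
#' @return `data.frame`: gene, baseMean, lfc (interaction log2FC), se,
#'   stat, p, p_adj; ordered as the input genes.
#' @export
interactionDE <- function(counts, metadata) {
  stopifnot(is.matrix(counts))
  if (!is.null(metadata$sample) &&
      all(colnames(counts) %in% metadata$sample)) {
    metadata <- metadata[match(colnames(counts), metadata$sample), ,
                         drop = FALSE]
  }
  if (nrow(metadata) != ncol(counts)) {
    stop("metadata rows must match count-matrix columns")
  }
  metadata <- .checkDesign(metadata)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = round(counts), colData = S4Vectors::DataFrame(metadata),
    design = ~ species + cell_type + species:cell_type)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  res <- DESeq2::results(dds, name = "specieshuman.cell_typeiPSC")
  data.frame(gene = rownames(res), baseMean = res$baseMean,
             lfc = res$log2FoldChange, se = res$lfcSE, stat = res$stat,
             p = res$pvalue, p_adj = res$padj, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Expression percentile of a gene within a sample group
#'
#' Ranks genes by their size-factor-normalized mean expression within one
#' species-by-cell-type group, descending, ties averaged, and returns
#' `100 * (rank - 0.5) / n_genes` — so the most highly expressed gene of 100
#' sits at percentile 0.5 and the median gene of 101 at 50.
#'
#' @param counts Filtered genes-by-samples integer matrix.
#' @param metadata Sample metadata (see [interactionDE()]).
#' @param geneId Gene to look up.
#' @param species,cellType Group selectors.
#' @return Percentile in (0, 100); smaller = more highly expressed.
#' @export
expressionPercentile <- function(counts, metadata, geneId,
                                 species, cellType) {
  stopifnot(is.matrix(counts))
  if (!geneId %in% rownames(counts)) {
    stop("gene not present after filtering: ", geneId)
  }
  if (!is.null(metadata$sample) &&
      all(colnames(counts) %in% metadata$sample)) {
    metadata <- metadata[match(colnames(counts), metadata$sample), ,
                         drop = FALSE]
  }
  sf <- DESeq2::estimateSizeFactorsForMatrix(counts)
  norm <- sweep(counts, 2, sf, "/")
  sel <- metadata$species == species &
    sub("-", "_", metadata$cell_type) == sub("-", "_", cellType)
  if (!any(sel)) stop("no samples in group ", species, " x ", cellType)
  means <- rowMeans(norm[, sel, drop = FALSE])
  r <- rank(-means, ties.method = "average")
  unname(100 * (r[geneId] - 0.5) / length(means))
}
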