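## Absolute functional gene content: scale per-ASV predicted gene copies
## (PICRUSt2-style hidden-state predictions, consumed as data) by absolute
## ASV abundances expressed in genome equivalents.

#' Convert absolute ASV abundances to genome equivalents
#'
#' Absolute abundances are measured in 16S rRNA gene copies; dividing each
#' ASV by its predicted per-genome 16S copy number yields genome (cell)
#' equivalents, the correct weight for summing per-genome gene copies.
#'
#' @param absolute samples x ASVs absolute abundance matrix (16S copies per
#'   normalization unit).
#' @param copies16s named numeric vector: predicted 16S copies per genome
#'   for every ASV (>= 1).
#' @return samples x ASVs matrix of genome equivalents.
#' @export
genome_equivalents <- function(absolute, copies16s) {
  absolute <- as.matrix(absolute)
  missing <- setdiff(colnames(absolute), names(copies16s))
  if (length(missing))
    stop(sprintf("ASV(s) missing from the 16S copy table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  cp <- copies16s[colnames(absolute)]
  if (any(cp < 1)) stop("16S copies per genome must be >= 1", call. = FALSE)
  sweep(absolute, 2, cp, "/")
}

#' Inferred absolute gene-ortholog abundances
#'
#' \code{gene[s, k] = sum_a genomes[s, a] * gene_copies[a, k]}: the total
#' predicted copies of each KEGG ortholog carried by the community, in the
#' same normalization unit as the input abundances. Linear in the input, so
#' group contrasts on absolute abundances carry over to gene content.
#'
#' @param genomes samples x ASVs genome-equivalent matrix (from
#'   \code{\link{genome_equivalents}}).
#' @param gene_copies ASVs x orthologs matrix of predicted copies per
#'   genome.
#' @return samples x orthologs matrix.
#' @export
absolute_gene_abundance <- function(genomes, gene_copies) {
  genomes <- as.matrix(genomes)
  gene_copies <- as.matrix(gene_copies)
  if (!all(colnames(genomes) %in% rownames(gene_copies)))
    stop("gene-copy table does not cover all ASVs", call. = FALSE)
  gc <- gene_copies[colnames(genomes), , drop = FALSE]
  if (any(gc < 0)) stop("gene copies must be >= 0", call. = FALSE)
  genomes %*% gc
}
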