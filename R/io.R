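## Plain-text readers and writers for every table the pipeline exchanges.
## TSV is the native dialect; ASV count tables can also round-trip through
## BIOM (JSON) when the biomformat package is available.

#' Write an abundance/count matrix as TSV
#'
#' Taxa are written as rows (one \code{"#OTU ID"}-style sentinel header
#' column), samples as columns, the layout amplicon tools exchange.
#'
#' @param m samples x taxa matrix.
#' @param path output file.
#' @export
write_count_table <- function(m, path) {
  m <- as.matrix(m)
  df <- data.frame(feature_id = colnames(m), t(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- "#OTU ID"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an abundance/count matrix from TSV or BIOM
#'
#' TSV orientation is auto-detected through the header sentinel: a first
#' column named \code{#OTU ID} / \code{feature_id} / \code{taxon} means
#' taxa-as-rows; otherwise the first column is taken as the sample id.
#' \code{.biom} files are parsed with the biomformat package.
#'
#' @param path input file.
#' @return samples x taxa numeric matrix.
#' @export
read_count_table <- function(path) {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the biomformat package", call. = FALSE)
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")   # taxa x samples
    return(t(m))
  }
  header <- strsplit(readLines(path, n = 1L), "\t")[[1L]]
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  sentinel <- tolower(header[1L]) %in% c("#otu id", "feature_id", "taxon",
                                         "feature id")
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  if (sentinel) t(m) else m
}

#' Write a samples x taxa matrix as a BIOM (JSON) file
#'
#' @param m samples x taxa matrix.
#' @param path output .biom path.
#' @export
write_count_biom <- function(m, path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("writing BIOM requires the biomformat package", call. = FALSE)
  b <- biomformat::make_biom(t(as.matrix(m)))
  biomformat::write_biom(b, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write every raw file of a synthetic study to a directory
#'
#' Emits the file bundle a real study would provide: metadata TSV, ASV
#' count TSV (and BIOM when biomformat is installed), taxonomy TSV, qPCR /
#' ddPCR / MPN CSVs, the per-ASV gene-copy TSV (KO columns +
#' \code{16S_rRNA_Count}), the bile-acid peak-area CSV, and a
#' \code{truth/} subdirectory with the ground-truth tables used by
#' recovery tests.
#'
#' @param study a \code{synthetic_study}.
#' @param dir output directory (created).
#' @param biom also write counts.biom (default FALSE).
#' @return named character vector of written paths.
#' @export
write_study <- function(study, dir, biom = FALSE) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- c()
  pth <- function(f) file.path(dir, f)
  write_tsv(study$metadata, p["metadata"] <- pth("metadata.tsv"))
  write_tsv(study$taxonomy, p["taxonomy"] <- pth("taxonomy.tsv"))
  if (!is.null(study$asv_counts)) {
    write_count_table(study$asv_counts, p["counts"] <- pth("counts.tsv"))
    if (biom && requireNamespace("biomformat", quietly = TRUE))
      write_count_biom(study$asv_counts, p["counts_biom"] <- pth("counts.biom"))
  }
  if (!is.null(study$qpcr))
    write_csv(study$qpcr, p["qpcr"] <- pth("qpcr.csv"))
  if (!is.null(study$ddpcr))
    write_csv(study$ddpcr, p["ddpcr"] <- pth("ddpcr.csv"))
  if (!is.null(study$mpn))
    write_csv(study$mpn, p["mpn"] <- pth("mpn.csv"))
  write_tsv(study$gene_copy_table, p["gene_copies"] <- pth("gene_copies.tsv"))
  if (!is.null(study$bileacid_areas))
    write_csv(study$bileacid_areas,
              p["bileacid_areas"] <- pth("bileacid_areas.csv"))
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  write_tsv(data.frame(sample_id = names(study$truth$loads),
                       load = study$truth$loads, row.names = NULL),
            p["truth_loads"] <- file.path(tdir, "loads.tsv"))
  write_count_table(study$truth$absolute,
                    p["truth_absolute"] <- file.path(tdir, "absolute.tsv"))
  if (!is.null(study$truth$bileacid))
    write_tsv(data.frame(sample_id = names(study$truth$bileacid$total),
                         total = study$truth$bileacid$total,
                         frac_unconjugated =
                           study$truth$bileacid$frac_unconjugated,
                         frac_secondary =
                           study$truth$bileacid$frac_secondary,
                         row.names = NULL),
              p["truth_bileacid"] <- file.path(tdir, "bileacid.tsv"))
  p
}

#' Read the raw file bundle of a study directory
#'
#' Inverse of \code{\link{write_study}} for the raw inputs (ground truth is
#' not loaded).
#'
#' @param dir study directory.
#' @return list: metadata, taxonomy, asv_counts, qpcr, ddpcr, mpn,
#'   gene_copy_table, bileacid_areas (missing files are NULL).
#' @export
read_study <- function(dir) {
  rd <- function(f, csv = FALSE) {
    path <- file.path(dir, f)
    if (!file.exists(path)) return(NULL)
    if (csv) utils::read.csv(path, stringsAsFactors = FALSE)
    else utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  }
  counts <- if (file.exists(file.path(dir, "counts.tsv")))
    read_count_table(file.path(dir, "counts.tsv")) else NULL
  gene <- rd("gene_copies.tsv")
  list(metadata = rd("metadata.tsv"), taxonomy = rd("taxonomy.tsv"),
       asv_counts = counts, qpcr = rd("qpcr.csv", TRUE),
       ddpcr = rd("ddpcr.csv", TRUE), mpn = rd("mpn.csv", TRUE),
       gene_copy_table = gene,
       bileacid_areas = rd("bileacid_areas.csv", TRUE))
}
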