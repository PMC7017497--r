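## Absolute (quantitative) microbiome profiling: ASV counts + total loads
## -> contaminant-filtered absolute abundance tables with LLOD flags.
##
## Tables are base matrices, samples in rows, taxa/ASVs in columns, with
## dimnames carrying the identifiers. Flags travel as logical matrices of
## the same shape in the "llod" attribute.

#' Convert a count table to relative abundances
#'
#' @param counts samples x taxa matrix of non-negative read counts.
#' @return matrix of per-sample fractions (rows sum to 1); all-zero rows are
#'   left at zero and marked in the logical \code{attr(, "empty")} vector.
#' @export
to_relative <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!nrow(counts) || !ncol(counts)) stop("count table is empty", call. = FALSE)
  row_normalize(counts)
}

## Pad/truncate a lineage string to `level` ranks, QIIME2 "collapse"
## semantics: missing ranks become the empty placeholder "__", so ASVs
## unassigned below some rank group under their deepest assigned prefix.
collapse_label <- function(lineage, level) {
  parts <- strsplit(lineage, ";", fixed = TRUE)
  vapply(parts, function(p) {
    p <- trimws(p)
    p <- p[nzchar(p)]
    if (length(p) >= level) p <- p[seq_len(level)]
    else p <- c(p, rep("__", level - length(p)))
    paste(p, collapse = ";")
  }, character(1))
}

#' Collapse an abundance table to a taxonomic level
#'
#' Columns are summed over all ASVs (or finer taxa) sharing the lineage
#' prefix through \code{level}; lineages unassigned at \code{level} are
#' padded with the \code{"__"} placeholder so they group under their deepest
#' assigned prefix (the QIIME2 taxa "collapse" convention). Row sums are
#' conserved exactly.
#'
#' @param table samples x ASVs matrix (counts, relative or absolute).
#' @param taxonomy data.frame with columns \code{asv_id} and \code{lineage}
#'   (semicolon-separated ranks, Silva dialect), covering every column.
#' @param level integer rank depth (1 = domain ... 7 = species) or one of
#'   \code{"domain","phylum","class","order","family","genus","species"}.
#' @return samples x taxa matrix with collapsed lineage labels as colnames.
#' @export
collapse_taxa <- function(table, taxonomy, level) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus", "species")
  if (is.character(level)) {
    level <- match(tolower(level), ranks)
    if (is.na(level)) stop("unknown taxonomic level", call. = FALSE)
  }
  if (!is.numeric(level) || level < 1 || level > 7)
    stop("unknown taxonomic level", call. = FALSE)
  table <- as.matrix(table)
  assert_cols(taxonomy, c("asv_id", "lineage"), "taxonomy")
  idx <- match(colnames(table), taxonomy$asv_id)
  if (anyNA(idx)) {
    ## columns may already be lineage strings (re-collapse case)
    lin <- colnames(table)
  } else lin <- taxonomy$lineage[idx]
  lab <- collapse_label(lin, level)
  groups <- factor(lab, levels = unique(lab))
  out <- t(rowsum(t(table), groups))
  colnames(out) <- levels(groups)
  out
}

#' Flag contaminants by absence from large-intestine reference samples
#'
#' Any taxon with zero counts in every cecum-contents sample but nonzero
#' counts somewhere else is flagged: genuine gut taxa are expected to appear
#' in at least one cecum contents sample, which profiles the full lower-gut
#' community.
#'
#' @param counts samples x taxa count matrix.
#' @param metadata sample metadata with \code{sample_id}, \code{site},
#'   \code{material}.
#' @return data.frame of contaminant calls (taxon, flagged_by).
#' @export
flag_contaminants_prevalence <- function(counts, metadata) {
  counts <- as.matrix(counts)
  assert_cols(metadata, c("sample_id", "site", "material"), "metadata")
  cec <- metadata$sample_id[metadata$site == "CEC" &
                              metadata$material == "contents"]
  cec <- intersect(cec, rownames(counts))
  if (!length(cec))
    stop("no cecum contents samples in metadata", call. = FALSE)
  in_cec <- colSums(counts[cec, , drop = FALSE] > 0) > 0
  anywhere <- colSums(counts > 0) > 0
  taxa <- colnames(counts)[!in_cec & anywhere]
  if (!length(taxa))
    return(data.frame(taxon = character(), flagged_by = character(),
                      stringsAsFactors = FALSE))
  data.frame(taxon = taxa, flagged_by = "cecum_prevalence",
             stringsAsFactors = FALSE)
}

#' Score taxa for the reagent-contaminant frequency signature
#'
#' Reads contributed by a fixed ambient mass of contaminating DNA make up a
#' fraction of a sample's library that is inversely proportional to the
#' sample's total DNA concentration. For each taxon with enough nonzero
#' observations, the fit of log(frequency) against log(concentration) under
#' a contaminant model (slope fixed at -1, free intercept) is compared with
#' a biological model (constant frequency) by residual sums of squares:
#' \code{score = SSR_contam / (SSR_contam + SSR_biol)}. Scores near 0 mean
#' the contaminant model fits; taxa with \code{score < threshold} are
#' flagged.
#'
#' @param relative samples x taxa relative abundance matrix.
#' @param dna_concentration named (or aligned) per-sample total DNA
#'   concentration, strictly positive.
#' @param threshold flag cutoff (default 0.5; the score is symmetric around
#'   0.5 by construction).
#' @param min_nonzero minimum samples with nonzero frequency for a defined
#'   score (default 5).
#' @return data.frame (taxon, score, flagged_by) for all scorable taxa;
#'   \code{flagged_by} is \code{"frequency_score"} or \code{""}.
#' @export
score_contaminant_frequency <- function(relative, dna_concentration,
                                        threshold = 0.5, min_nonzero = 5) {
  relative <- as.matrix(relative)
  if (!is.null(names(dna_concentration)))
    dna_concentration <- dna_concentration[rownames(relative)]
  if (length(dna_concentration) != nrow(relative))
    stop("dna_concentration must align with rows of 'relative'", call. = FALSE)
  if (any(!is.finite(dna_concentration) | dna_concentration <= 0))
    stop("dna_concentration must be strictly positive", call. = FALSE)
  lc <- log(dna_concentration)
  res <- lapply(colnames(relative), function(tx) {
    f <- relative[, tx]
    use <- f > 0
    if (sum(use) < min_nonzero) return(NULL)
    lf <- log(f[use]); x <- lc[use]
    ## contaminant model: lf = b - x  (slope fixed at -1)
    ssr_con <- sum((lf + x - mean(lf + x))^2)
    ## biological model: lf = const
    ssr_bio <- sum((lf - mean(lf))^2)
    denom <- ssr_con + ssr_bio
    score <- if (denom > 0) ssr_con / denom else 0.5
    data.frame(taxon = tx, score = score,
               flagged_by = if (score < threshold) "frequency_score" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(taxon = character(), score = numeric(),
                      flagged_by = character(), stringsAsFactors = FALSE)
  out
}

## Organellar 16S signals of dietary origin (chloroplast amplicons and
## mitochondria, which Silva places under Rickettsiales).
is_organellar <- function(taxa) {
  grepl("chloroplast|mitochondri|rickettsiales", taxa, ignore.case = TRUE)
}

#' Remove flagged contaminant (and optionally organellar) taxa
#'
#' Relative tables are re-normalized to sum to 1 after removal; absolute
#' tables are \emph{not} rescaled, because dropping a contaminant removes
#' its (artifactual) mass rather than redistributing it.
#'
#' @param table samples x taxa matrix.
#' @param calls contaminant-call data.frame(s) with a \code{taxon} column
#'   (union taken).
#' @param keep_organellar keep chloroplast/mitochondrial taxa (default
#'   TRUE).
#' @param relative is \code{table} a relative-abundance table that must be
#'   re-normalized? Default auto: TRUE when all row sums are within 1e-6 of
#'   1.
#' @return the filtered matrix.
#' @export
remove_contaminants <- function(table, calls, keep_organellar = TRUE,
                                relative = NULL) {
  table <- as.matrix(table)
  drop <- unique(unlist(lapply(if (is.data.frame(calls)) list(calls) else calls,
                               function(d) d$taxon[d$flagged_by != ""])))
  if (!keep_organellar)
    drop <- union(drop, colnames(table)[is_organellar(colnames(table))])
  keep <- setdiff(colnames(table), drop)
  out <- table[, keep, drop = FALSE]
  if (is.null(relative))
    relative <- all(abs(rowSums(table) - 1) < 1e-6)
  if (relative) out <- row_normalize(out)
  out
}

#' Scale relative abundances to absolute abundances with total loads
#'
#' The central quantitative-profiling step: each sample row of fractions is
#' multiplied by that sample's independently measured total load. A per-cell
#' lower limit of detection (LLOD) equal to the load equivalent of a single
#' read at the sample's sequencing depth (or a configured floor) marks cells
#' that the assay cannot distinguish from zero; samples whose load itself is
#' below the assay LLOD have every cell flagged.
#'
#' @param relative samples x taxa matrix of fractions.
#' @param loads load table (data.frame from \code{\link{quantify_loads}} or
#'   a named numeric vector) covering every sample.
#' @param depth per-sample read depth used for the LLOD (named vector); if
#'   NULL no depth-based flag is set.
#' @param llod_floor optional absolute floor overriding the depth rule.
#' @return samples x taxa matrix in load units, with the logical LLOD flag
#'   matrix in \code{attr(, "llod")} and the unit in \code{attr(, "unit")}.
#' @export
to_absolute <- function(relative, loads, depth = NULL, llod_floor = NULL) {
  relative <- as.matrix(relative)
  if (is.data.frame(loads)) {
    lv <- stats::setNames(loads$value, loads$sample_id)
    lflag <- stats::setNames(loads$flag, loads$sample_id)
    unit <- unique(loads$unit)[1L]
  } else {
    lv <- loads; lflag <- stats::setNames(rep("ok", length(loads)), names(loads))
    unit <- "copies/unit"
  }
  missing <- setdiff(rownames(relative), names(lv))
  if (length(missing))
    stop(sprintf("missing load for sample(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  lv <- lv[rownames(relative)]
  out <- relative * lv
  llod_val <- if (!is.null(llod_floor)) rep(llod_floor, nrow(relative))
  else if (!is.null(depth)) lv / depth[rownames(relative)]
  else rep(0, nrow(relative))
  flags <- sweep(out, 1, llod_val, "<")
  flags[lflag[rownames(relative)] == "below_llod", ] <- TRUE
  attr(out, "llod") <- flags
  attr(out, "unit") <- unit
  out
}

#' Per-group mean abundance profiles
#'
#' Arithmetic mean of absolute abundances per experimental group (optionally
#' per site), plus the re-normalized relative version of each mean profile.
#'
#' @param absolute samples x taxa absolute abundance matrix.
#' @param metadata sample metadata with \code{sample_id}, \code{group} and
#'   optionally \code{site}.
#' @param by grouping columns in \code{metadata} (default
#'   \code{c("group","site")} intersected with available columns).
#' @return list with matrices \code{absolute} and \code{relative}, one row
#'   per group combination.
#' @export
mean_group_profile <- function(absolute, metadata, by = NULL) {
  absolute <- as.matrix(absolute)
  assert_cols(metadata, "sample_id", "metadata")
  by <- by %||% intersect(c("group", "site"), names(metadata))
  md <- metadata[match(rownames(absolute), metadata$sample_id), , drop = FALSE]
  key <- interaction(md[by], drop = TRUE, sep = ":")
  means <- rowsum(absolute, key) / as.vector(table(key))
  rel <- row_normalize(means)
  list(absolute = means, relative = rel)
}
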