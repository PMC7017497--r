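## Orchestration: the profiling driver, full pipeline runner with a run
## manifest, and input validation.

#' Contaminant-filtered absolute profiling of one study
#'
#' The central driver: counts -> relative abundances -> absolute scaling
#' with per-sample loads and LLOD flags -> contaminant calls (cecum
#' prevalence rule first, frequency score on the remaining taxa, union of
#' flags) -> filtered tables, collapsed to the requested taxonomic level.
#'
#' @param counts samples x ASVs count matrix.
#' @param taxonomy taxonomy data.frame (asv_id, lineage).
#' @param loads load table from \code{\link{quantify_loads}} (or named
#'   vector).
#' @param metadata sample metadata (needs site/material for the prevalence
#'   rule; optional \code{dna_conc} column for the frequency score).
#' @param level collapse level (default "order"; NULL = no collapse).
#' @param freq_threshold frequency-score flag cutoff (default 0.5).
#' @param keep_organellar keep chloroplast/mitochondrial taxa (default
#'   TRUE).
#' @return list: \code{relative_asv}, \code{absolute_asv} (unfiltered, with
#'   \code{"llod"} attr), \code{calls}, \code{relative}, \code{absolute}
#'   (filtered, collapsed), \code{llod} (flag matrix for \code{absolute}).
#' @export
profile_study <- function(counts, taxonomy, loads, metadata, level = "order",
                          freq_threshold = 0.5, keep_organellar = TRUE) {
  counts <- as.matrix(counts)
  rel <- to_relative(counts)
  depth <- stats::setNames(rowSums(counts), rownames(counts))
  absolute <- to_absolute(rel, loads, depth)

  calls_prev <- flag_contaminants_prevalence(counts, metadata)
  remaining <- setdiff(colnames(counts), calls_prev$taxon)
  calls_freq <- NULL
  if ("dna_conc" %in% names(metadata)) {
    dna <- stats::setNames(metadata$dna_conc, metadata$sample_id)
    dna <- dna[rownames(rel)]
    if (all(is.finite(dna) & dna > 0))
      calls_freq <- score_contaminant_frequency(
        rel[, remaining, drop = FALSE], dna, threshold = freq_threshold)
  }
  calls_prev$score <- rep(NA_real_, nrow(calls_prev))
  calls <- rbind(calls_prev[, c("taxon", "score", "flagged_by")],
                 if (!is.null(calls_freq))
                   calls_freq[, c("taxon", "score", "flagged_by")])

  abs_f <- remove_contaminants(absolute, calls, keep_organellar,
                               relative = FALSE)
  rel_f <- remove_contaminants(counts, calls, keep_organellar,
                               relative = TRUE)
  if (!is.null(level)) {
    abs_f <- collapse_taxa(abs_f, taxonomy, level)
    rel_f <- collapse_taxa(rel_f, taxonomy, level)
  }
  lv <- if (is.data.frame(loads))
    stats::setNames(loads$value, loads$sample_id)[rownames(abs_f)]
  else loads[rownames(abs_f)]
  llod <- sweep(abs_f, 1, lv / depth[rownames(abs_f)], "<")
  list(relative_asv = rel, absolute_asv = absolute, calls = calls,
       relative = rel_f, absolute = abs_f, llod = llod)
}

#' Absolute functional gene content of a profiled study
#'
#' Wraps \code{\link{genome_equivalents}} and
#' \code{\link{absolute_gene_abundance}} around a PICRUSt2-style gene-copy
#' table (KO columns plus \code{16S_rRNA_Count}).
#'
#' @param absolute_asv samples x ASVs absolute abundance matrix.
#' @param gene_copy_table data.frame: asv_id, one column per KO,
#'   \code{16S_rRNA_Count}.
#' @return samples x KO matrix.
#' @export
gene_content_study <- function(absolute_asv, gene_copy_table) {
  assert_cols(gene_copy_table, c("asv_id", "16S_rRNA_Count"),
              "gene copy table")
  cp <- stats::setNames(gene_copy_table[["16S_rRNA_Count"]],
                        gene_copy_table$asv_id)
  ko <- setdiff(names(gene_copy_table), c("asv_id", "16S_rRNA_Count"))
  gm <- as.matrix(gene_copy_table[, ko, drop = FALSE])
  rownames(gm) <- gene_copy_table$asv_id
  genomes <- genome_equivalents(absolute_asv, cp)
  absolute_gene_abundance(genomes, gm)
}

#' Quantify a bile-acid run end to end
#'
#' Drift correction, calibration on the embedded standard injections,
#' inverse calibration of sample responses, and pool summarization.
#'
#' @param areas raw long peak-area table (see
#'   \code{\link{gen_bileacid_run}} for the layout).
#' @param metadata sample metadata (sample_id, material,
#'   ba_dilution_chain).
#' @param panel species registry.
#' @return list: \code{fits}, \code{concentrations} (the
#'   \code{\link{quantify_bile_acids}} result), \code{summary} (per-sample
#'   pool summary on the per-sample amounts).
#' @export
bile_acid_study <- function(areas, metadata, panel = bile_acid_panel()) {
  corrected <- correct_drift(areas)
  std <- corrected[!is.na(corrected$standard_conc_um), ]
  std_resp <- do.call(rbind, lapply(split(std, std$injection_index),
                                    function(d) {
    full <- corrected[corrected$injection_index == d$injection_index[1L], ]
    data.frame(species = d$species,
               concentration_um = d$standard_conc_um,
               response = injection_response(full, panel)[
                 match(d$species, full$species)],
               stringsAsFactors = FALSE)
  }))
  fits <- fit_calibration(std_resp)
  smp <- corrected[corrected$sample_id %in% metadata$sample_id, ]
  conc <- quantify_bile_acids(smp, fits, metadata, panel)
  list(fits = fits, concentrations = conc,
       summary = summarize_ba_profile(conc$amount, panel))
}

#' Validate a study input bundle
#'
#' Schema checks per file plus cross-file referential checks: every counts
#' sample in the metadata, every ASV in the taxonomy and gene-copy table,
#' unique sample ids.
#'
#' @param inputs list as returned by \code{\link{read_study}}.
#' @return data.frame of violations (file, check, detail); zero rows when
#'   the bundle is consistent.
#' @export
validate_inputs <- function(inputs) {
  v <- list()
  note <- function(file, check, detail)
    v[[length(v) + 1L]] <<- data.frame(file = file, check = check,
                                       detail = detail,
                                       stringsAsFactors = FALSE)
  md <- inputs$metadata
  if (is.null(md)) note("metadata.tsv", "missing", "metadata not found")
  else {
    need <- setdiff(c("sample_id", "group", "site", "material"), names(md))
    if (length(need)) note("metadata.tsv", "schema",
                           paste("missing columns:",
                                 paste(need, collapse = ", ")))
    if (anyDuplicated(md$sample_id))
      note("metadata.tsv", "duplicate_sample_id",
           paste(unique(md$sample_id[duplicated(md$sample_id)]),
                 collapse = ", "))
  }
  cts <- inputs$asv_counts
  if (!is.null(cts) && !is.null(md)) {
    extra <- setdiff(rownames(cts), md$sample_id)
    if (length(extra)) note("counts.tsv", "sample_not_in_metadata",
                            paste(extra, collapse = ", "))
    if (any(cts < 0)) note("counts.tsv", "negative_counts", "")
  }
  tax <- inputs$taxonomy
  if (!is.null(cts) && !is.null(tax)) {
    extra <- setdiff(colnames(cts), tax$asv_id)
    if (length(extra)) note("taxonomy.tsv", "asv_not_in_taxonomy",
                            paste(extra, collapse = ", "))
  }
  gct <- inputs$gene_copy_table
  if (!is.null(cts) && !is.null(gct)) {
    extra <- setdiff(colnames(cts), gct$asv_id)
    if (length(extra)) note("gene_copies.tsv", "asv_not_in_gene_table",
                            paste(extra, collapse = ", "))
  }
  if (!length(v))
    return(data.frame(file = character(), check = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' Run the full pipeline on a (synthetic) study
#'
#' simulate -> quantify-loads -> profile -> genes -> bileacids -> stats,
#' writing each stage's outputs under \code{out_dir} and a JSON run
#' manifest with input checksums and row counts. Deterministic for a fixed
#' config (the seed lives in the config).
#'
#' @param config a \code{\link{simulation_config}}; alternatively a path to
#'   a directory of raw input files (the simulate stage is then skipped).
#' @param out_dir output directory.
#' @param level taxonomic collapse level for profiling.
#' @return the manifest (invisibly), also written to
#'   \code{manifest.json}.
#' @export
run_pipeline <- function(config, out_dir, level = "order") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  stage <- function(name, paths)
    stages[[name]] <<- lapply(paths, function(p)
      list(path = p, checksum = file_checksum(p),
           rows = length(readLines(p, warn = FALSE)) - 1L))

  raw_dir <- file.path(out_dir, "raw")
  if (inherits(config, "simulation_config")) {
    study <- generate_study(config)
    raw_paths <- write_study(study, raw_dir)
    stage("simulate", as.list(raw_paths))
  } else if (is.character(config) && dir.exists(config)) {
    raw_dir <- config
  } else stop("config must be a simulation_config or an input directory",
              call. = FALSE)

  inputs <- read_study(raw_dir)
  viol <- validate_inputs(inputs)
  if (nrow(viol))
    stop(sprintf("input validation failed at stage 'validate': %s",
                 paste(viol$check, viol$detail, collapse = "; ")),
         call. = FALSE)

  ## loads
  loads <- quantify_loads(inputs$qpcr, inputs$ddpcr, inputs$mpn,
                          inputs$metadata)
  p_loads <- file.path(out_dir, "loads.tsv")
  write_tsv(loads, p_loads)
  stage("quantify_loads", list(p_loads))

  ## profile (sequencing-based samples only)
  seq_loads <- loads[loads$method != "MPN" &
                       loads$sample_id %in% rownames(inputs$asv_counts), ]
  if (!all(rownames(inputs$asv_counts) %in% seq_loads$sample_id))
    stop("profile stage aborted: missing loads for counted samples",
         call. = FALSE)
  prof <- profile_study(inputs$asv_counts, inputs$taxonomy, seq_loads,
                        inputs$metadata, level = level)
  p_abs <- file.path(out_dir, "absolute.tsv")
  p_rel <- file.path(out_dir, "relative.tsv")
  p_flags <- file.path(out_dir, "absolute_flags.tsv")
  p_calls <- file.path(out_dir, "contaminant_calls.tsv")
  write_count_table(prof$absolute, p_abs)
  write_count_table(prof$relative, p_rel)
  write_count_table(prof$llod * 1, p_flags)
  write_tsv(prof$calls, p_calls)
  stage("profile", list(p_abs, p_rel, p_flags, p_calls))

  ## genes
  keep <- intersect(colnames(prof$absolute_asv),
                    inputs$gene_copy_table$asv_id)
  genes <- gene_content_study(prof$absolute_asv[, keep, drop = FALSE],
                              inputs$gene_copy_table)
  p_genes <- file.path(out_dir, "gene_abundance.tsv")
  write_count_table(genes, p_genes)
  stage("genes", list(p_genes))

  ## bile acids
  p_ba <- NULL
  if (!is.null(inputs$bileacid_areas)) {
    ba <- bile_acid_study(inputs$bileacid_areas, inputs$metadata)
    p_ba_conc <- file.path(out_dir, "bileacid_concentrations.tsv")
    p_ba_sum <- file.path(out_dir, "bileacid_summary.tsv")
    write_count_table(ba$concentrations$amount, p_ba_conc)
    write_tsv(ba$summary, p_ba_sum)
    stage("bileacids", list(p_ba_conc, p_ba_sum))
  }

  ## stats: PCA of log10-standardized absolute profiles; per-site group
  ## comparison of loads; lumenal-mucosal load correlation
  md <- inputs$metadata
  contents <- md$sample_id[md$material == "contents"]
  amat <- prof$absolute[rownames(prof$absolute) %in% contents, ,
                        drop = FALSE]
  pca <- run_pca(log10_standardize(amat),
                 n_components = min(5, nrow(amat) - 1L),
                 preprocessing = "log10_standardized_absolute")
  p_scores <- file.path(out_dir, "pca_scores.tsv")
  p_load <- file.path(out_dir, "pca_loadings.tsv")
  write_count_table(pca$scores, p_scores)
  write_count_table(pca$loadings, p_load)
  lt <- loads[match(contents, loads$sample_id), ]
  cmp <- do.call(rbind, lapply(split(seq_along(contents),
                                     md$site[match(contents,
                                                   md$sample_id)]),
                               function(i) {
    g <- md$group[match(contents[i], md$sample_id)]
    if (length(unique(g)) < 2) return(NULL)
    r <- compare_groups(log10(pmax(lt$value[i], 1)), g)
    cbind(site = md$site[match(contents[i], md$sample_id)][1L],
          kw_p = r$kw_p, r$pairwise)
  }))
  p_cmp <- file.path(out_dir, "load_comparisons.tsv")
  write_tsv(cmp, p_cmp)
  stage("stats", list(p_scores, p_load, p_cmp))

  manifest <- list(
    seed = if (inherits(config, "simulation_config")) config$seed else NA,
    package_version = as.character(utils::packageVersion("coproquant")),
    stages = stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
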