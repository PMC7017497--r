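## Whole-study generation: metadata, ground truth, and every raw input the
## pipeline consumes (ASV counts + taxonomy, qPCR/ddPCR/MPN tables,
## per-ASV gene copies, bile-acid peak areas).

upper_sites <- c("STM", "SI1", "SI2", "SI3")

## Per-sample true relative composition over biological ASVs, applying the
## behavior rules of the taxon panel.
true_composition <- function(tp, group, site, jitter_sd, noise) {
  base <- if (site %in% upper_sites) tp$w_upper else tp$w_lower
  w <- base * tp$weight
  if (group == "TC-F") {
    if (site %in% upper_sites) w[tp$behavior == "fecal"] <- 0
    if (site == "CEC") w[tp$behavior == "cecum_shifted"] <-
        w[tp$behavior == "cecum_shifted"] * 0.1
  }
  if (noise && jitter_sd > 0) {
    jit <- 10^stats::rnorm(length(w), 0, jitter_sd)
    w <- w * jit
  }
  w / sum(w)
}

## Dirichlet-multinomial (or multinomial / expectation) read counts.
draw_counts <- function(depth, p, overdispersion, noise) {
  if (!noise) return(depth * p)
  if (overdispersion > 0) {
    alpha <- p / overdispersion
    g <- stats::rgamma(length(p), shape = alpha)
    g[p == 0] <- 0
    p <- if (sum(g) > 0) g / sum(g) else p
  }
  as.numeric(stats::rmultinom(1L, depth, p))
}

#' Generate a complete synthetic study
#'
#' Draws per-sample total loads from the log-normal load model, per-sample
#' community composition from the taxon panel's behavior rules, read
#' counts multinomially at the configured depth (ambient contaminant DNA
#' competes with sample DNA for reads, so contaminant frequency scales
#' inversely with sample DNA concentration), and raw assay readouts for
#' every quantification route. The full ground truth is retained for
#' recovery tests.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param parts character subset of
#'   \code{c("counts","qpcr","ddpcr","mpn","bileacids")} to generate
#'   (default all); metadata and truth are always produced.
#' @return object of class \code{synthetic_study}: \code{metadata},
#'   \code{truth} (list: \code{loads}, \code{relative}, \code{absolute},
#'   \code{mucosal_loads}, \code{mpn_density}, \code{bileacid}),
#'   \code{asv_counts}, \code{taxonomy}, \code{qpcr}, \code{ddpcr},
#'   \code{mpn}, \code{gene_copy_table}, \code{bileacid_areas},
#'   \code{config}.
#' @export
generate_study <- function(config,
                           parts = c("counts", "qpcr", "ddpcr", "mpn",
                                     "bileacids")) {
  stopifnot(inherits(config, "simulation_config"))
  parts <- match.arg(parts, several.ok = TRUE)
  set.seed(config$seed)
  an <- config$assay_noise
  tp <- config$taxon_panel
  cp <- config$contaminant_panel
  noise <- config$noise

  mice <- sprintf("M%02d", seq_len(config$n_mice_per_group *
                                     length(config$groups)))
  mouse_group <- rep(config$groups, each = config$n_mice_per_group)

  ## ---- metadata -------------------------------------------------------
  md <- expand.grid(mouse_id = mice, site = config$sites,
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  md$group <- mouse_group[match(md$mouse_id, mice)]
  md$material <- "contents"
  muc <- data.frame(mouse_id = mice, site = "SI2",
                    group = mouse_group, material = "mucosa",
                    stringsAsFactors = FALSE)
  bile <- data.frame(mouse_id = mice, site = "BILE",
                     group = mouse_group, material = "bile",
                     stringsAsFactors = FALSE)
  md <- rbind(md[, c("mouse_id", "site", "group", "material")], muc, bile)
  md$sample_id <- paste(md$mouse_id, md$site, md$material, sep = ".")
  md$mass_g <- ifelse(md$material == "contents", an$mass_g, NA_real_)
  md$dna_input_ng <- ifelse(md$material == "mucosa", an$dna_input_ng,
                            NA_real_)
  md$dilution_chain <- ifelse(md$material == "contents",
                              an$elution_volume_ul / an$template_volume_ul,
                              NA_real_)
  md$template_volume_ul <- an$template_volume_ul
  md$ba_dilution_chain <- ifelse(md$material == "bile", an$ba_chain_bile,
                                 an$ba_chain_contents)
  md$depth <- config$sequencing_depth
  md <- md[, c("sample_id", "mouse_id", "group", "site", "material",
               "mass_g", "dna_input_ng", "dilution_chain",
               "template_volume_ul", "ba_dilution_chain", "depth")]

  contents <- md[md$material == "contents", ]
  key <- paste(contents$group, contents$site)
  lm_key <- paste(config$load_model$group, config$load_model$site)
  mi <- match(key, lm_key)
  if (anyNA(mi))
    stop_cfg("load_model", sprintf("no entry for %s",
                                   paste(unique(key[is.na(mi)]),
                                         collapse = ", ")))

  ## ---- true loads (copies per g contents) -----------------------------
  mu <- config$load_model$log10_mean[mi]
  sd <- config$load_model$log10_sd[mi]
  l10 <- if (noise) stats::rnorm(nrow(contents), mu, sd) else mu
  loads <- stats::setNames(10^l10, contents$sample_id)

  ## mucosal loads (copies per 100 ng DNA), correlated with the lumenal
  ## SI2 load of the same mouse
  si2 <- contents[contents$site == "SI2", ]
  base <- log10(loads[si2$sample_id]) + an$mucosa_offset_log10
  m10 <- if (noise) stats::rnorm(length(base), base, an$mucosa_sd_log10)
  else base
  muc_ids <- paste(si2$mouse_id, "SI2", "mucosa", sep = ".")
  mucosal <- stats::setNames(10^m10, muc_ids)

  ## extract concentration (copies/uL) and per-reaction copies / DNA conc
  conc_extract <- loads * an$mass_g / an$elution_volume_ul
  copies_rxn <- conc_extract * an$template_volume_ul
  dna_conc <- c(copies_rxn,
                stats::setNames(mucosal, muc_ids))  # mucosa: copies/rxn
  md$dna_conc <- dna_conc[md$sample_id]

  ## ---- true composition and counts ------------------------------------
  n_bio <- nrow(tp)
  rel <- matrix(0, nrow(contents) + length(muc_ids), n_bio,
                dimnames = list(c(contents$sample_id, muc_ids), tp$asv_id))
  seq_md <- md[md$material != "bile", ]   # contents rows then mucosa rows
  for (i in seq_len(nrow(seq_md)))
    rel[i, ] <- true_composition(tp, seq_md$group[i], seq_md$site[i],
                                 an$sample_jitter_sd, noise)
  seq_loads <- c(loads, mucosal)[rownames(rel)]
  absolute <- rel * seq_loads

  counts <- NULL
  if ("counts" %in% parts) {
    n_cont <- nrow(cp)
    counts <- matrix(0, nrow(rel), n_bio + n_cont,
                     dimnames = list(rownames(rel),
                                     c(tp$asv_id, cp$asv_id)))
    for (i in seq_len(nrow(rel))) {
      bio_mass <- rel[i, ] * md$dna_conc[match(rownames(rel)[i],
                                               md$sample_id)]
      amb <- if (n_cont) cp$ambient_copies else numeric()
      p <- c(bio_mass, amb)
      p <- p / sum(p)
      counts[i, ] <- draw_counts(config$sequencing_depth, p,
                                 config$overdispersion, noise)
    }
  }

  taxonomy <- data.frame(
    asv_id = c(tp$asv_id, cp$asv_id),
    lineage = c(tp$lineage, cp$lineage),
    confidence = 0.99, stringsAsFactors = FALSE)

  ## ---- quantification assays ------------------------------------------
  qpcr <- ddpcr <- mpn <- NULL
  assay_ids <- c(contents$sample_id, muc_ids)
  assay_rxn <- c(copies_rxn, mucosal)   # mucosa already per reaction
  if ("qpcr" %in% parts) {
    qpcr <- do.call(rbind, lapply(seq_along(assay_ids), function(i) {
      r <- gen_qpcr_run(assay_rxn[i], an$qpcr_intercept, an$qpcr_slope,
                        an$cq_sd, standards_copies = if (i == 1)
                          an$qpcr_standards else numeric(), noise = noise)
      if (nrow(r)) cbind(sample_id = assay_ids[i], r) else NULL
    }))
    std <- qpcr[qpcr$is_standard, ]
    std$sample_id <- "STANDARD"
    qpcr <- rbind(std, qpcr[!qpcr$is_standard, ])
  }
  if ("ddpcr" %in% parts) {
    conc_all <- c(conc_extract, mucosal / an$template_volume_ul)
    ddpcr <- do.call(rbind, lapply(seq_along(assay_ids), function(i) {
      lam0 <- conc_all[i] * an$droplet_volume_nl / 1000
      dil <- max(1, 10^ceiling(log10(lam0 / 0.5)))
      cbind(sample_id = assay_ids[i],
            gen_ddpcr_run(conc_all[i], an$n_droplets, an$droplet_volume_nl,
                          dil, noise = noise))
    }))
  }
  if ("mpn" %in% parts) {
    pilot <- contents[contents$group %in% c("TC-F", "CTRL"), ]
    dens <- loads[pilot$sample_id] / an$genome_16s_copies *
      an$culturable_fraction
    mpn <- do.call(rbind, lapply(seq_len(nrow(pilot)), function(i)
      cbind(sample_id = pilot$sample_id[i],
            gen_mpn_plate(dens[i], an$mpn_dilutions, an$mpn_replicates,
                          an$mpn_inoculum_ml, an$mpn_dilution_factor,
                          noise = noise))))
  }

  ## ---- gene copy table -------------------------------------------------
  ko_cols <- setdiff(names(tp), c("asv_id", "lineage", "taxon", "behavior",
                                  "weight", "w_upper", "w_lower",
                                  "copies_16s"))
  gene_copy_table <- data.frame(asv_id = c(tp$asv_id, cp$asv_id),
                                stringsAsFactors = FALSE)
  for (k in ko_cols) gene_copy_table[[k]] <- c(tp[[k]], rep(0, nrow(cp)))
  gene_copy_table[["16S_rRNA_Count"]] <- c(tp$copies_16s, rep(1, nrow(cp)))

  ## ---- bile acids ------------------------------------------------------
  ba_areas <- NULL; ba_truth <- NULL
  if ("bileacids" %in% parts) {
    ba_md <- md[md$material %in% c("contents", "bile"), ]
    bkey <- paste(ba_md$group, ifelse(ba_md$material == "bile", "BILE",
                                      ba_md$site))
    bm_key <- paste(config$bileacid_model$group, config$bileacid_model$site)
    bi <- match(bkey, bm_key)
    if (anyNA(bi))
      stop_cfg("bileacid_model", sprintf("no entry for %s",
                                         paste(unique(bkey[is.na(bi)]),
                                               collapse = ", ")))
    tot <- config$bileacid_model$total[bi]
    fu <- config$bileacid_model$frac_unconj[bi]
    fs <- config$bileacid_model$frac_secondary[bi]
    if (noise) {
      tot <- tot * 10^stats::rnorm(length(tot), 0, an$ba_total_log10_sd)
      jig <- function(f) inv_logit(stats::rnorm(length(f), logit(f),
                                                an$ba_logit_sd))
      fu <- jig(fu); fs <- jig(fs)
    }
    pools <- ba_species_split(tot, fu, fs)
    rownames(pools) <- ba_md$sample_id
    extract <- pools / ba_md$ba_dilution_chain
    ba_truth <- list(total = stats::setNames(tot, ba_md$sample_id),
                     frac_unconjugated = stats::setNames(fu, ba_md$sample_id),
                     frac_secondary = stats::setNames(fs, ba_md$sample_id),
                     amounts = pools)
    ba_areas <- gen_bileacid_run(extract, bile_acid_panel(),
                                 an$drift_slope, an$qc_every,
                                 an$peak_area_cv, an$cal_levels_um,
                                 an$cal_series, an$response_factor,
                                 an$is_response_factor, an$is_conc_um,
                                 noise = noise)
  }

  out <- list(metadata = md,
              truth = list(loads = loads, mucosal_loads = mucosal,
                           relative = rel, absolute = absolute,
                           mpn_density = if ("mpn" %in% parts)
                             dens else NULL,
                           bileacid = ba_truth),
              asv_counts = counts, taxonomy = taxonomy,
              qpcr = qpcr, ddpcr = ddpcr, mpn = mpn,
              gene_copy_table = gene_copy_table,
              bileacid_areas = ba_areas,
              config = config)
  class(out) <- "synthetic_study"
  out
}

## Split per-sample totals into per-species amounts through the
## conjugation x origin grid: cell masses are total x the product of the
## axis fractions (so the pool fractions are exact by construction), and
## fixed within-cell species weights.
ba_species_split <- function(total, frac_unconj, frac_secondary,
                             panel = bile_acid_panel()) {
  cell_w <- list(
    conj_primary = c(TCA = 0.45, TbMCA = 0.30, TaMCA = 0.10, TCDCA = 0.05,
                     GCA = 0.05, THCA = 0.03, GHCA = 0.01, GCDCA = 0.01),
    conj_secondary = c(TDCA = 0.45, TwMCA = 0.25, TUDCA = 0.12, TLCA = 0.05,
                       GDCA = 0.06, GHDCA = 0.03, GLCA = 0.02, GUDCA = 0.02),
    unconj_primary = c(CA = 0.40, bMCA = 0.35, aMCA = 0.12, HCA = 0.05,
                       CDCA = 0.08),
    unconj_secondary = c(DCA = 0.40, wMCA = 0.30, UDCA = 0.10, HDCA = 0.05,
                         MDCA = 0.10, LCA = 0.05))
  cell_w <- lapply(cell_w, function(w) w / sum(w))
  species <- unlist(lapply(cell_w, names), use.names = FALSE)
  n <- length(total)
  out <- matrix(0, n, length(species), dimnames = list(NULL, species))
  cells <- cbind(conj_primary = (1 - frac_unconj) * (1 - frac_secondary),
                 conj_secondary = (1 - frac_unconj) * frac_secondary,
                 unconj_primary = frac_unconj * (1 - frac_secondary),
                 unconj_secondary = frac_unconj * frac_secondary)
  off <- 0L
  for (cl in names(cell_w)) {
    w <- cell_w[[cl]]
    out[, off + seq_along(w)] <- outer(total * cells[, cl], w)
    off <- off + length(w)
  }
  out
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study:", nrow(x$metadata), "samples\n")
  cat("  groups:", paste(unique(x$metadata$group), collapse = ", "), "\n")
  if (!is.null(x$asv_counts))
    cat("  counts:", nrow(x$asv_counts), "samples x",
        ncol(x$asv_counts), "ASVs\n")
  for (nm in c("qpcr", "ddpcr", "mpn", "bileacid_areas"))
    if (!is.null(x[[nm]])) cat("  ", nm, ": ", nrow(x[[nm]]), " rows\n",
                               sep = "")
  invisible(x)
}
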