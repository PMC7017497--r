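## Simulation configuration: the parameterized ground-truth model of a
## four-group (coprophagic vs non-coprophagic) mouse study sampled at six
## gut sites, from which every raw pipeline input is generated.

#' Default taxon panel for the synthetic study
#'
#' A small community of order-level taxa, each realized as one or more
#' ASVs, covering the three qualitative response patterns of the study
#' design: \code{fecal} taxa (large-intestine anaerobes carried up the gut
#' by self-reinoculation; truly absent from the upper gut when coprophagy
#' is blocked), \code{true_small_intestine} taxa (stable across groups,
#' dominated by \emph{Lactobacillales}), and \code{cecum_shifted} taxa
#' (reduced in the non-coprophagic cecum only). Chloroplast amplicons of
#' dietary origin ride along as a \code{true_small_intestine}-behaving
#' organellar signal. Weights \code{w_upper} / \code{w_lower} set the base
#' composition in the stomach + small intestine and the cecum + colon;
#' \code{weight} splits an order across its ASVs. Per-genome 16S copy
#' numbers and KEGG-ortholog gene copies (bile salt hydrolase K01442,
#' beta-glucuronidase K01195, arylsulfatase K01130) drive the
#' functional-scaling stage.
#'
#' @return data.frame, one row per ASV.
#' @export
default_taxon_panel <- function() {
  tp <- utils::read.delim(text = "
asv_id|lineage|taxon|behavior|weight|w_upper|w_lower|copies_16s|K01442|K01195|K01130
ASV001|d__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__Lachnospiraceae;g__Blautia;s__|Clostridiales|fecal|0.5|0.30|0.45|8|2|3|1
ASV002|d__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__Ruminococcaceae;g__Faecalibacterium;s__|Clostridiales|fecal|0.3|0.30|0.45|8|2|3|1
ASV003|d__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__Lachnospiraceae;g__Roseburia;s__|Clostridiales|fecal|0.2|0.30|0.45|8|2|3|1
ASV004|d__Bacteria;p__Bacteroidetes;c__Bacteroidia;o__Bacteroidales;f__Muribaculaceae;g__Muribaculum;s__|Bacteroidales|fecal|0.6|0.15|0.32|4|1|4|2
ASV005|d__Bacteria;p__Bacteroidetes;c__Bacteroidia;o__Bacteroidales;f__Bacteroidaceae;g__Bacteroides;s__|Bacteroidales|fecal|0.4|0.15|0.32|4|1|4|2
ASV006|d__Bacteria;p__Firmicutes;c__Erysipelotrichia;o__Erysipelotrichales;f__Erysipelotrichaceae;g__Turicibacter;s__|Erysipelotrichales|fecal|1.0|0.04|0.08|6|1|1|0
ASV007|d__Bacteria;p__Verrucomicrobia;c__Verrucomicrobiae;o__Verrucomicrobiales;f__Akkermansiaceae;g__Akkermansia;s__|Verrucomicrobiales|fecal|1.0|0.02|0.03|2|0|2|1
ASV008|d__Bacteria;p__Firmicutes;c__Bacilli;o__Lactobacillales;f__Lactobacillaceae;g__Lactobacillus;s__|Lactobacillales|true_small_intestine|0.7|0.44|0.05|6|1|0|0
ASV009|d__Bacteria;p__Firmicutes;c__Bacilli;o__Lactobacillales;f__Lactobacillaceae;g__Lactobacillus;s__|Lactobacillales|true_small_intestine|0.3|0.44|0.05|6|1|0|0
ASV010|d__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Betaproteobacteriales;f__Burkholderiaceae;g__Parasutterella;s__|Betaproteobacteriales|cecum_shifted|1.0|0.02|0.05|3|0|1|1
ASV011|d__Bacteria;p__Cyanobacteria;c__Oxyphotobacteria;o__Chloroplast;f__;g__;s__|Chloroplast|true_small_intestine|1.0|0.03|0.02|1|0|0|0
", sep = "|", strip.white = TRUE, stringsAsFactors = FALSE)
  tp
}

#' Default reagent-contaminant panel
#'
#' Taxa with zero biological abundance in every sample whose reads arise
#' solely from a fixed ambient DNA mass per reaction, producing the
#' inverse-frequency signature against sample DNA concentration. They are
#' never present in the cecum community.
#'
#' @return data.frame: asv_id, lineage, taxon, ambient_copies,
#'   present_in_cecum (always FALSE).
#' @export
default_contaminant_panel <- function() {
  data.frame(
    asv_id = c("CONT01", "CONT02"),
    lineage = c(
      "d__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Pseudomonadales;f__Pseudomonadaceae;g__Pseudomonas;s__",
      "d__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Xanthomonadales;f__Xanthomonadaceae;g__Stenotrophomonas;s__"),
    taxon = c("Pseudomonadales", "Xanthomonadales"),
    ambient_copies = c(80, 30),
    present_in_cecum = FALSE,
    stringsAsFactors = FALSE)
}

#' Default total-load model
#'
#' Per-group, per-site log10 mean and SD of total 16S copies per gram of
#' lumenal contents. Blocking coprophagy (TC-F) lowers upper-gut loads by
#' roughly three orders of magnitude while leaving the large intestine
#' nearly unchanged; the three coprophagic groups share one profile.
#'
#' @return data.frame: group, site, log10_mean, log10_sd.
#' @export
default_load_model <- function() {
  sites <- c("STM", "SI1", "SI2", "SI3", "CEC", "COL")
  copro <- c(8.0, 8.0, 8.5, 9.0, 11.0, 11.0)
  tcf <- c(5.0, 5.0, 5.5, 6.5, 10.8, 10.9)
  groups <- c("TC-F", "TC-M", "WF", "CTRL")
  out <- expand.grid(group = groups, site = sites, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$log10_mean <- ifelse(out$group == "TC-F",
                           tcf[match(out$site, sites)],
                           copro[match(out$site, sites)])
  out$log10_sd <- 0.4
  out
}

#' Default bile-acid pool model
#'
#' Per group-class and site (plus gallbladder bile): the total bile-acid
#' pool and the fractions unconjugated and secondary. Pools peak in the
#' small intestine (roughly 10x the large intestine); in coprophagic
#' groups the unconjugated fraction rises from duodenum to ileum as digesta
#' meets microbial bile-salt-hydrolase activity, while the non-coprophagic
#' small intestine stays almost fully conjugated. Totals are nmol/g
#' contents (nmol/mL for bile).
#'
#' @return data.frame: group, site, total, frac_unconj, frac_secondary.
#' @export
default_bileacid_model <- function() {
  sites <- c("BILE", "STM", "SI1", "SI2", "SI3", "CEC", "COL")
  total <- c(20000, 300, 2000, 1500, 1000, 150, 100)
  fu_cop <- c(0.03, 0.60, 0.15, 0.35, 0.55, 0.75, 0.85)
  fu_tcf <- c(0.01, 0.02, 0.01, 0.01, 0.02, 0.05, 0.08)
  fs_cop <- c(0.12, 0.25, 0.15, 0.20, 0.25, 0.40, 0.45)
  fs_tcf <- c(0.04, 0.06, 0.05, 0.05, 0.06, 0.15, 0.35)
  groups <- c("TC-F", "TC-M", "WF", "CTRL")
  out <- expand.grid(group = groups, site = sites, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  i <- match(out$site, sites)
  tcf <- out$group == "TC-F"
  out$total <- total[i]
  out$frac_unconj <- ifelse(tcf, fu_tcf[i], fu_cop[i])
  out$frac_secondary <- ifelse(tcf, fs_tcf[i], fs_cop[i])
  out
}

#' Build a validated simulation configuration
#'
#' Defaults mirror the study design: 6 mice in each of four groups (TC-F
#' functional tail cups, TC-M mock tail cups, WF wire floor, CTRL standard
#' housing), six gut sites, sequencing depth 1e4 reads, triplicate qPCR
#' with a 10-fold standard series, ~20,000 droplets of 0.85 nL, an MPN
#' design of 8 ten-fold dilutions x 8 wells at 10 uL inoculum, a 7-point
#' bile-acid calibration (0.05-30 uM) run three times with a QC injection
#' every 8 runs.
#'
#' @param n_mice_per_group mice per group (default 6).
#' @param groups,sites closed label vocabularies.
#' @param seed integer RNG seed.
#' @param sequencing_depth reads per sample (>= 1).
#' @param taxon_panel,contaminant_panel,load_model,bileacid_model model
#'   tables (see the \code{default_*} constructors).
#' @param assay_noise list of assay noise/design constants; see Details.
#' @param overdispersion Dirichlet-multinomial overdispersion of read
#'   counts (0 = plain multinomial, the default).
#' @param noise FALSE switches every stochastic draw to its expectation
#'   (used by exact-recovery tests).
#' @details \code{assay_noise} fields and defaults: \code{cq_sd} 0.15
#'   cycles; \code{n_droplets} 20000; \code{droplet_volume_nl} 0.85;
#'   \code{mpn_dilutions} 8, \code{mpn_replicates} 8,
#'   \code{mpn_inoculum_ml} 1e-3 (volume of original sample in the first
#'   dilution's wells), \code{mpn_dilution_factor} 10;
#'   \code{peak_area_cv} 0.08; \code{drift_slope} -0.002 per injection;
#'   \code{qc_every} 8; \code{sample_jitter_sd} 0.3 (per-sample log10
#'   composition jitter); \code{ba_total_log10_sd} 0.2 and
#'   \code{ba_logit_sd} 0.3 (per-sample bile-acid pool jitter).
#' @return object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_mice_per_group = 6,
                              groups = c("TC-F", "TC-M", "WF", "CTRL"),
                              sites = c("STM", "SI1", "SI2", "SI3", "CEC", "COL"),
                              seed = 1,
                              sequencing_depth = 1e4,
                              taxon_panel = default_taxon_panel(),
                              contaminant_panel = default_contaminant_panel(),
                              load_model = default_load_model(),
                              bileacid_model = default_bileacid_model(),
                              assay_noise = list(),
                              overdispersion = 0,
                              noise = TRUE) {
  check_scalar_num(n_mice_per_group, "n_mice_per_group", lower = 1)
  check_scalar_num(seed, "seed")
  check_scalar_num(sequencing_depth, "sequencing_depth", lower = 1)
  check_scalar_num(overdispersion, "overdispersion", lower = 0)
  if (!length(groups)) stop_cfg("groups", "must be non-empty")
  if (!length(sites)) stop_cfg("sites", "must be non-empty")
  assert_cols(taxon_panel, c("asv_id", "lineage", "taxon", "behavior",
                             "weight", "w_upper", "w_lower", "copies_16s"),
              "taxon_panel")
  if (!all(taxon_panel$behavior %in%
           c("fecal", "true_small_intestine", "cecum_shifted")))
    stop_cfg("taxon_panel", "unknown behavior class")
  if (any(taxon_panel$copies_16s < 1))
    stop_cfg("taxon_panel", "16S copies per genome must be >= 1")
  assert_cols(load_model, c("group", "site", "log10_mean", "log10_sd"),
              "load_model")
  if (any(load_model$log10_sd < 0)) stop_cfg("load_model", "SDs must be >= 0")
  assert_cols(bileacid_model, c("group", "site", "total", "frac_unconj",
                                "frac_secondary"), "bileacid_model")
  fr <- c(bileacid_model$frac_unconj, bileacid_model$frac_secondary)
  if (any(fr < 0 | fr > 1))
    stop_cfg("bileacid_model", "fractions must be in [0, 1]")
  if (nrow(contaminant_panel) &&
      any(contaminant_panel$present_in_cecum))
    stop_cfg("contaminant_panel", "present_in_cecum must be FALSE")

  an <- utils::modifyList(list(
    cq_sd = 0.15, qpcr_intercept = 38, qpcr_slope = -1 / log10(1.95),
    qpcr_standards = 10^(2:8),
    n_droplets = 20000, droplet_volume_nl = 0.85,
    mpn_dilutions = 8, mpn_replicates = 8, mpn_inoculum_ml = 1e-3,
    mpn_dilution_factor = 10,
    peak_area_cv = 0.08, drift_slope = -0.002, qc_every = 8,
    sample_jitter_sd = 0.3, ba_total_log10_sd = 0.2, ba_logit_sd = 0.3,
    mucosa_offset_log10 = -2.5, mucosa_sd_log10 = 0.3,
    culturable_fraction = 0.3, genome_16s_copies = 6,
    mass_g = 0.05, elution_volume_ul = 200, template_volume_ul = 2,
    dna_input_ng = 100,
    ba_chain_contents = 100, ba_chain_bile = 10000,
    cal_levels_um = c(0.05, 0.1, 0.5, 1, 5, 10, 30), cal_series = 3,
    response_factor = 5e4, is_response_factor = 4e4, is_conc_um = 5),
    assay_noise)
  for (f in c("cq_sd", "peak_area_cv", "sample_jitter_sd"))
    check_scalar_num(an[[f]], f, lower = 0)
  check_scalar_num(an$n_droplets, "n_droplets", lower = 1)
  check_scalar_num(an$droplet_volume_nl, "droplet_volume_nl", lower = 1e-6)

  cfg <- list(n_mice_per_group = as.integer(n_mice_per_group),
              groups = groups, sites = sites, seed = as.integer(seed),
              sequencing_depth = sequencing_depth,
              taxon_panel = taxon_panel,
              contaminant_panel = contaminant_panel,
              load_model = load_model, bileacid_model = bileacid_model,
              assay_noise = an, overdispersion = overdispersion,
              noise = isTRUE(noise))
  class(cfg) <- "simulation_config"
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  %d mice x %d groups (%s)\n", x$n_mice_per_group,
              length(x$groups), paste(x$groups, collapse = ", ")))
  cat(sprintf("  sites: %s\n", paste(x$sites, collapse = ", ")))
  cat(sprintf("  depth %g reads, seed %d, noise %s\n",
              x$sequencing_depth, x$seed, if (x$noise) "on" else "off"))
  cat(sprintf("  %d biological ASVs, %d contaminants, %d bile-acid rows\n",
              nrow(x$taxon_panel), nrow(x$contaminant_panel),
              nrow(x$bileacid_model)))
  invisible(x)
}
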