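## Single-assay simulators. Each mirrors the physical measurement model the
## corresponding estimator inverts; with noise = FALSE every stochastic
## draw is replaced by its expectation (possibly non-integer), so that the
## estimators recover truth exactly.

#' Simulate one droplet digital PCR run
#'
#' Template molecules partition into droplets independently, so each
#' droplet is positive with probability \code{1 - exp(-lambda)} where
#' \code{lambda = true_conc / dilution * droplet volume} is the mean
#' occupancy.
#'
#' @param true_conc template concentration in copies/uL (>= 0).
#' @param n_droplets accepted droplets.
#' @param droplet_volume_nl droplet volume (nL).
#' @param dilution fold pre-dilution of the template.
#' @param noise FALSE returns the expected positive count.
#' @return one-row data.frame: n_droplets, n_positive, droplet_volume_nl,
#'   dilution.
#' @export
gen_ddpcr_run <- function(true_conc, n_droplets = 20000,
                          droplet_volume_nl = 0.85, dilution = 1,
                          noise = TRUE) {
  if (true_conc < 0) stop("true_conc must be >= 0", call. = FALSE)
  lambda <- true_conc / dilution * droplet_volume_nl / 1000
  p <- -expm1(-lambda)
  k <- if (noise) stats::rbinom(1L, n_droplets, p) else n_droplets * p
  data.frame(n_droplets = n_droplets, n_positive = k,
             droplet_volume_nl = droplet_volume_nl, dilution = dilution)
}

#' Simulate one MPN serial-dilution plate
#'
#' Wells at dilution step i receive volume \code{inoculum_ml /
#' dilution_factor^(i-1)} of the original sample and turn positive with
#' probability \code{1 - exp(-density * volume)}.
#'
#' @param true_density culturable cells per mL of original sample (>= 0).
#' @param n_dilutions serial dilution steps (default 8).
#' @param replicates wells per dilution (default 8).
#' @param inoculum_ml original-sample volume in the first dilution's wells
#'   (default 1e-3 mL: 10 uL of a 10x dilution).
#' @param dilution_factor step factor (default 10).
#' @param noise FALSE returns expected positive counts.
#' @return data.frame: dilution_index, volume_ml, n, p.
#' @export
gen_mpn_plate <- function(true_density, n_dilutions = 8, replicates = 8,
                          inoculum_ml = 1e-3, dilution_factor = 10,
                          noise = TRUE) {
  if (true_density < 0) stop("true_density must be >= 0", call. = FALSE)
  v <- inoculum_ml / dilution_factor^(seq_len(n_dilutions) - 1L)
  ppos <- -expm1(-true_density * v)
  p <- if (noise) stats::rbinom(n_dilutions, replicates, ppos)
  else replicates * ppos
  data.frame(dilution_index = seq_len(n_dilutions), volume_ml = v,
             n = replicates, p = p)
}

#' Simulate one qPCR measurement with its standard series
#'
#' Replicate Cq values follow \code{Normal(intercept + slope *
#' log10(copies), cq_sd)}; the run carries a 10-fold standard dilution
#' series measured with the same noise.
#'
#' @param true_copies template copies per reaction (> 0).
#' @param intercept,slope calibration line (slope in Cq per decade;
#'   -3.3219 at perfect efficiency).
#' @param cq_sd replicate Cq standard deviation.
#' @param n_replicates sample replicates (default 3).
#' @param standards_copies copy levels of the standard series.
#' @param noise FALSE makes all Cq deterministic.
#' @return data.frame: is_standard, standard_copies, replicate, cq.
#' @export
gen_qpcr_run <- function(true_copies, intercept = 38, slope = -1 / log10(1.95),
                         cq_sd = 0.15, n_replicates = 3,
                         standards_copies = 10^(2:8), noise = TRUE) {
  if (true_copies <= 0) stop("true_copies must be > 0", call. = FALSE)
  cq_of <- function(copies) {
    mu <- intercept + slope * log10(copies)
    if (noise) stats::rnorm(length(mu), mu, cq_sd) else mu
  }
  smp <- data.frame(is_standard = FALSE, standard_copies = NA_real_,
                    replicate = seq_len(n_replicates),
                    cq = cq_of(rep(true_copies, n_replicates)))
  if (!length(standards_copies)) return(smp)
  std <- data.frame(is_standard = TRUE, standard_copies = standards_copies,
                    replicate = 1L, cq = cq_of(standards_copies))
  rbind(smp, std)
}

#' Simulate a targeted LC-MS bile-acid run
#'
#' Analyte peak areas are proportional to extract concentration times a
#' species response factor, modulated by a linear sensitivity drift over
#' injection index and multiplicative log-normal noise. Deuterated internal
#' standards are present in every injection at a fixed concentration. A
#' pooled QC sample is injected first and then after every
#' \code{qc_every} injections; a 7-point external calibration series is
#' interleaved \code{cal_series} times (start / middle / end of the run).
#' UDCA and HDCA co-elute: their single merged peak carries the sum of the
#' two concentrations and is emitted under the label \code{"UDCA+HDCA"}.
#'
#' @param extract_um samples x species matrix of true extract
#'   concentrations (uM); colnames must be panel species.
#' @param panel species registry (maps species to internal standards).
#' @param drift_slope fractional sensitivity change per injection.
#' @param qc_every QC injection interval.
#' @param peak_area_cv multiplicative noise CV.
#' @param cal_levels_um calibration concentrations.
#' @param cal_series number of calibration replicates through the run.
#' @param response_factor,is_response_factor area per uM for analytes and
#'   internal standards.
#' @param is_conc_um internal-standard concentration (uM).
#' @param noise FALSE disables area noise (drift remains).
#' @return long data.frame: sample_id ("QC", "STD-<series>-<level>" or the
#'   sample id), injection_index, species, area, standard_conc_um.
#' @export
gen_bileacid_run <- function(extract_um, panel = bile_acid_panel(),
                             drift_slope = -0.002, qc_every = 8,
                             peak_area_cv = 0.08,
                             cal_levels_um = c(0.05, 0.1, 0.5, 1, 5, 10, 30),
                             cal_series = 3, response_factor = 5e4,
                             is_response_factor = 4e4, is_conc_um = 5,
                             noise = TRUE) {
  extract_um <- as.matrix(extract_um)
  species <- colnames(extract_um)
  if (any(extract_um < 0)) stop("extract concentrations must be >= 0",
                                call. = FALSE)
  ## merge the co-eluting pair before area generation
  merged <- panel[nzchar(panel$merged_with %||% ""), , drop = FALSE]
  for (i in seq_len(nrow(merged))) {
    a <- merged$species[i]; b <- merged$merged_with[i]
    if (all(c(a, b) %in% species)) {
      extract_um[, a] <- extract_um[, a] + extract_um[, b]
      colnames(extract_um)[colnames(extract_um) == a] <- paste0(a, "+", b)
      extract_um <- extract_um[, colnames(extract_um) != b, drop = FALSE]
      species <- colnames(extract_um)
    }
  }
  is_ids <- unique(panel$internal_standard[nzchar(panel$internal_standard)])
  qc_conc <- colMeans(extract_um)          # pooled QC sample

  ## assemble the injection queue: QC every qc_every injections, the
  ## calibration series split across the run, samples in order
  inject <- list()
  cal_q <- unlist(lapply(seq_len(cal_series), function(s)
    lapply(cal_levels_um, function(l) list(id = sprintf("STD-%d-%g", s, l),
                                           conc = NULL, std = l))),
    recursive = FALSE)
  n_smp <- nrow(extract_um)
  smp_q <- lapply(seq_len(n_smp), function(i)
    list(id = rownames(extract_um)[i], conc = extract_um[i, ], std = NA))
  ## order: first cal series, first half of samples, second series,
  ## second half, third series
  thirds <- split(smp_q, cut(seq_len(n_smp), breaks = max(1, cal_series - 1),
                             labels = FALSE))
  queue <- list()
  for (s in seq_len(cal_series)) {
    queue <- c(queue, cal_q[((s - 1) * length(cal_levels_um) + 1):
                              (s * length(cal_levels_um))])
    if (s <= length(thirds)) queue <- c(queue, thirds[[s]])
  }

  rows <- list()
  idx <- 0L
  emit <- function(id, conc, std, idx) {
    drift <- 1 + drift_slope * idx
    noise_mult <- function(n) if (noise)
      stats::rlnorm(n, -log(1 + peak_area_cv^2) / 2,
                    sqrt(log(1 + peak_area_cv^2))) else rep(1, n)
    a_area <- response_factor * conc * drift * noise_mult(length(conc))
    i_area <- is_response_factor * is_conc_um * drift *
      noise_mult(length(is_ids))
    data.frame(sample_id = id, injection_index = idx,
               species = c(names(conc), is_ids),
               area = c(a_area, i_area),
               standard_conc_um = c(rep(std, length(conc)),
                                    rep(NA_real_, length(is_ids))),
               stringsAsFactors = FALSE)
  }
  next_idx <- function() {
    if (idx %% qc_every == 0) {
      qc <- stats::setNames(qc_conc, species)
      rows[[length(rows) + 1L]] <<- emit("QC", qc, NA_real_, idx)
      idx <<- idx + 1L
    }
  }
  for (item in queue) {
    next_idx()
    conc <- if (is.null(item$conc))
      stats::setNames(rep(item$std, length(species)), species)
    else stats::setNames(item$conc, species)
    std <- if (is.null(item$conc)) item$std else NA_real_
    rows[[length(rows) + 1L]] <- emit(item$id, conc, std, idx)
    idx <- idx + 1L
  }
  ## closing QC so late samples are bracketed
  qc <- stats::setNames(qc_conc, species)
  rows[[length(rows) + 1L]] <- emit("QC", qc, NA_real_, idx)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
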