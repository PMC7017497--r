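## Targeted bile-acid LC-MS post-processing: QC-anchored drift correction,
## external calibration, concentration back-calculation, and pool
## summaries (fraction unconjugated, fraction secondary).

#' The default bile-acid species panel
#'
#' The 27-analyte murine panel used throughout the package: each species is
#' classified on the conjugation axis (tauro / glyco / unconjugated) and
#' the origin axis (primary = host-synthesized, secondary = microbially
#' transformed), and mapped to its deuterated (D4) internal standard. UDCA
#' and HDCA co-elute and are reported as one merged species.
#'
#' @param file optional path to a panel TSV overriding the shipped registry
#'   (columns: species, conjugation, class, internal_standard,
#'   merged_with).
#' @return data.frame registry.
#' @export
bile_acid_panel <- function(file = NULL) {
  file <- file %||% system.file("extdata", "bileacid_panel.tsv",
                                package = "coproquant")
  panel <- utils::read.delim(file, stringsAsFactors = FALSE)
  assert_cols(panel, c("species", "conjugation", "class",
                       "internal_standard"), "bile-acid panel")
  if (is.null(panel$merged_with)) panel$merged_with <- ""
  panel$merged_with[is.na(panel$merged_with)] <- ""
  panel$internal_standard[is.na(panel$internal_standard)] <- ""
  bad <- !panel$conjugation %in% c("tauro", "glyco", "unconjugated") |
    !panel$class %in% c("primary", "secondary")
  if (any(bad))
    stop(sprintf("unclassified panel species: %s",
                 paste(panel$species[bad], collapse = ", ")), call. = FALSE)
  panel
}

#' Correct instrumental drift with interspersed QC injections
#'
#' A pooled quality-control sample injected at regular intervals tracks the
#' drift of instrumental response. Per species, a piecewise-linear factor
#' through (QC area / first-QC area) is interpolated over injection index;
#' sample areas are divided by the factor at their own index. Injections
#' before the first (after the last) QC use the first (last) QC's factor.
#'
#' @param areas long-format injection table: columns \code{sample_id}
#'   (\code{"QC"} rows are the quality controls), \code{injection_index},
#'   \code{species}, \code{area} (internal-standard rows are species
#'   prefixed \code{"D4-"} and are corrected like any other species).
#' @return the table with \code{area} drift-corrected and the applied
#'   factor in column \code{drift_factor}.
#' @export
correct_drift <- function(areas) {
  assert_cols(areas, c("sample_id", "injection_index", "species", "area"),
              "peak-area table")
  qc <- areas[areas$sample_id == "QC", ]
  if (length(unique(qc$injection_index)) < 2) {
    warning("fewer than 2 QC injections; no drift correction applied")
    areas$drift_factor <- 1
    return(areas)
  }
  out <- split(areas, areas$species)
  out <- lapply(out, function(d) {
    q <- d[d$sample_id == "QC", ]
    q <- q[order(q$injection_index), ]
    if (nrow(q) < 2 || all(q$area <= 0)) { d$drift_factor <- 1; return(d) }
    fac <- q$area / q$area[1L]
    f <- stats::approx(q$injection_index, fac, xout = d$injection_index,
                       rule = 2)$y
    d$drift_factor <- f
    d$area <- d$area / f
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$injection_index, out$species), ]
}

#' Fit per-species external calibration curves
#'
#' Least-squares linear fit of (drift-corrected) response against known
#' concentration, pooling all replicate standard series. The response is
#' the internal-standard area ratio when the panel maps the species to an
#' internal standard present in the data, otherwise the raw corrected area.
#'
#' @param standards long table of standard injections: columns
#'   \code{species}, \code{concentration_um}, \code{response}.
#' @param weighting \code{"1/x"} (default; standard practice for LC-MS
#'   responses with roughly proportional error, it keeps the low end of the
#'   curve from being swamped by the top standards), \code{"1/x^2"}, or
#'   \code{"none"}.
#' @return data.frame of class \code{calibration_fit}: species, slope,
#'   intercept, r_squared, range_lo, range_hi, valid.
#' @export
fit_calibration <- function(standards, weighting = c("1/x", "1/x^2", "none")) {
  weighting <- match.arg(weighting)
  assert_cols(standards, c("species", "concentration_um", "response"),
              "calibration standards")
  res <- lapply(split(standards, standards$species), function(d) {
    if (length(unique(d$concentration_um)) < 2)
      stop(sprintf("species '%s': < 2 calibration levels", d$species[1L]),
           call. = FALSE)
    w <- switch(weighting, "1/x" = 1 / d$concentration_um,
                "1/x^2" = 1 / d$concentration_um^2, "none" = NULL)
    fit <- stats::lm(response ~ concentration_um, data = d, weights = w)
    co <- stats::coef(fit)
    sst <- sum((d$response - mean(d$response))^2)
    data.frame(species = d$species[1L],
               slope = unname(co[2L]), intercept = unname(co[1L]),
               r_squared = if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst
               else NA_real_,
               range_lo = min(d$concentration_um),
               range_hi = max(d$concentration_um),
               valid = unname(co[2L]) > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("calibration_fit", class(out))
  out
}

## Build the response (IS ratio where mapped, else raw area) for one
## injection's long rows. `wide`: data.frame species -> area for a single
## injection.
injection_response <- function(d, panel) {
  is_area <- stats::setNames(d$area, d$species)
  vapply(seq_len(nrow(d)), function(i) {
    sp <- d$species[i]
    row <- panel[panel$species == sp, ]
    if (nrow(row) && nzchar(row$internal_standard) &&
        row$internal_standard %in% d$species) {
      denom <- is_area[[row$internal_standard]]
      if (is.finite(denom) && denom > 0) return(d$area[i] / denom)
    }
    d$area[i]
  }, numeric(1))
}

#' Back-calculate bile-acid concentrations from corrected areas
#'
#' Responses (IS ratio where a matched internal standard exists) are
#' inverted through the calibration fits to extract concentrations (uM),
#' then scaled to per-sample amounts through the extraction dilution chain
#' recorded in the metadata: contents default x100 (extract in 9 volumes,
#' decant 10\%, reconstitute at x100 of the original sample), bile x10000
#' (pre-diluted x10 in ethanol and x10 in water before the same chain).
#' Values below the lowest calibration level are set to 0 and flagged
#' \code{below_lloq}; values above the highest level are reported but
#' flagged \code{above_range}. Merged co-eluting species (UDCA/HDCA) appear
#' once, under the merged label.
#'
#' @param areas drift-corrected long table (see \code{\link{correct_drift}};
#'   QC rows are ignored, internal-standard rows are used as denominators).
#' @param fits calibration fits from \code{\link{fit_calibration}}.
#' @param metadata sample metadata with \code{sample_id},
#'   \code{ba_dilution_chain} (fold factor extract -> sample) and
#'   \code{material}.
#' @param panel species registry (default \code{\link{bile_acid_panel}()}).
#' @return list: \code{extract_um} (samples x species extract
#'   concentrations), \code{amount} (samples x species per-sample amounts;
#'   nmol/g for contents, nmol/mL for bile), \code{flags} (character matrix
#'   "", "below_lloq", "above_range"), \code{unit} per sample.
#' @export
quantify_bile_acids <- function(areas, fits, metadata,
                                panel = bile_acid_panel()) {
  samples <- setdiff(unique(areas$sample_id), "QC")
  species <- fits$species
  rownames(fits) <- fits$species
  md <- metadata[match(samples, metadata$sample_id), , drop = FALSE]
  ext <- matrix(NA_real_, length(samples), length(species),
                dimnames = list(samples, species))
  flags <- matrix("", length(samples), length(species),
                  dimnames = list(samples, species))
  for (sid in samples) {
    d <- areas[areas$sample_id == sid, ]
    resp <- injection_response(d, panel)
    names(resp) <- d$species
    for (sp in species) {
      if (!sp %in% names(resp)) next
      f <- fits[sp, ]
      if (!f$valid) { flags[sid, sp] <- "invalid_fit"; next }
      conc <- (resp[[sp]] - f$intercept) / f$slope
      if (conc < f$range_lo) { ext[sid, sp] <- 0; flags[sid, sp] <- "below_lloq" }
      else if (conc > f$range_hi) { ext[sid, sp] <- conc
        flags[sid, sp] <- "above_range" }
      else ext[sid, sp] <- conc
    }
  }
  ## merge co-eluting pairs (by construction the areas already co-elute;
  ## a pair simulated separately arrives as two columns and is summed)
  if ("merged_with" %in% names(panel)) {
    for (i in which(nzchar(panel$merged_with))) {
      a <- panel$species[i]; b <- panel$merged_with[i]
      if (a %in% colnames(ext) && b %in% colnames(ext)) {
        lab <- paste0(a, "+", b)
        ext[, a] <- rowSums(ext[, c(a, b), drop = FALSE], na.rm = TRUE)
        colnames(ext)[colnames(ext) == a] <- lab
        ext <- ext[, colnames(ext) != b, drop = FALSE]
        flags[, a] <- ifelse(nzchar(flags[, a]), flags[, a], flags[, b])
        colnames(flags)[colnames(flags) == a] <- lab
        flags <- flags[, colnames(flags) != b, drop = FALSE]
      }
    }
  }
  chain <- md$ba_dilution_chain
  if (is.null(chain)) chain <- rep(100, length(samples))
  chain[is.na(chain)] <- 100
  amount <- ext * chain
  unit <- ifelse(md$material == "bile", "nmol/mL bile", "nmol/g contents")
  list(extract_um = ext, amount = amount, flags = flags,
       unit = stats::setNames(unit, samples))
}

#' Summarize bile-acid pools per sample
#'
#' Per sample: the total pool, the fraction unconjugated (free acids over
#' total) and the fraction secondary (microbially transformed species,
#' conjugated plus unconjugated, over total).
#'
#' @param conc samples x species concentration matrix (any consistent
#'   unit); merged labels such as \code{"UDCA+HDCA"} are resolved through
#'   the panel's first member.
#' @param panel species registry.
#' @return data.frame: sample_id, total, frac_unconjugated, frac_secondary.
#' @export
summarize_ba_profile <- function(conc, panel = bile_acid_panel()) {
  conc <- as.matrix(conc)
  base <- sub("\\+.*$", "", colnames(conc))
  idx <- match(base, panel$species)
  if (anyNA(idx))
    stop(sprintf("unclassified species: %s",
                 paste(colnames(conc)[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  unconj <- panel$conjugation[idx] == "unconjugated"
  second <- panel$class[idx] == "secondary"
  tot <- rowSums(conc, na.rm = TRUE)
  safe_tot <- ifelse(tot > 0, tot, NA_real_)
  data.frame(
    sample_id = rownames(conc),
    total = tot,
    frac_unconjugated = rowSums(conc[, unconj, drop = FALSE], na.rm = TRUE) /
      safe_tot,
    frac_secondary = rowSums(conc[, second, drop = FALSE], na.rm = TRUE) /
      safe_tot,
    stringsAsFactors = FALSE, row.names = NULL)
}
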