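make_area_table <- function(drift_slope = 0, conc = 2, n_samples = 10,
                            qc_every = 8, rf = 1e4) {
  ## minimal two-species run (one analyte + its IS) with QC bracketing
  rows <- list(); idx <- 0
  add <- function(id, c_an) {
    drift <- 1 + drift_slope * idx
    rows[[length(rows) + 1]] <<- data.frame(
      sample_id = id, injection_index = idx,
      species = c("CA", "D4-CA"),
      area = c(rf * c_an * drift, rf * 5 * drift),
      standard_conc_um = NA_real_, stringsAsFactors = FALSE)
    idx <<- idx + 1
  }
  for (i in seq_len(n_samples)) {
    if ((i - 1) %% qc_every == 0) add("QC", 3)
    add(paste0("s", i), conc)
  }
  add("QC", 3)
  do.call(rbind, rows)
}

test_that("drift correction restores constant responses", {
  ## constant QC areas: output identical to input
  tab <- make_area_table(drift_slope = 0)
  out <- correct_drift(tab)
  expect_equal(out$area[order(out$injection_index, out$species)],
               tab$area[order(tab$injection_index, tab$species)])

  ## linear decline: corrected constant-concentration series is constant
  tab <- make_area_table(drift_slope = -0.01)
  out <- correct_drift(tab)
  smp <- out[out$sample_id != "QC" & out$species == "CA", ]
  expect_lt(diff(range(smp$area)) / mean(smp$area), 1e-6)

  ## QC response follows the linear drift at its own injection index
  qc <- tab[tab$sample_id == "QC" & tab$species == "CA", ]
  expect_equal(qc$area[2] / qc$area[1],
               (1 - 0.01 * qc$injection_index[2]) /
                 (1 - 0.01 * qc$injection_index[1]), tolerance = 1e-9)

  ## fewer than 2 QCs: warning, no correction
  one <- tab[tab$injection_index <= 4, ]
  expect_warning(out1 <- correct_drift(one), "QC")
  expect_equal(out1$area, one$area)
})

test_that("calibration fit inverts standards and flags degenerate curves", {
  conc <- rep(c(0.05, 0.1, 0.5, 1, 5, 10, 30), 3)
  std <- data.frame(species = "TCA", concentration_um = conc,
                    response = 0.25 * conc)
  fits <- fit_calibration(std)
  expect_equal(fits$r_squared, 1, tolerance = 1e-12)
  expect_equal((0.25 * 5 - fits$intercept) / fits$slope, 5,
               tolerance = 1e-9)
  flat <- fit_calibration(data.frame(species = "X",
                                     concentration_um = c(1, 10),
                                     response = c(2, 2)))
  expect_false(flat$valid)
  expect_error(fit_calibration(data.frame(species = "X",
                                          concentration_um = 1,
                                          response = 1)), "levels")
})

test_that("quantification inverts calibration through the dilution chain", {
  cfg <- fast_config(61, noise = FALSE)
  st <- generate_study(cfg, parts = "bileacids")
  ba <- bile_acid_study(st$bileacid_areas, st$metadata)
  tru <- st$truth$bileacid$amounts
  est <- ba$concentrations$amount
  ## merged co-eluting pair appears once, as the sum
  expect_true("UDCA+HDCA" %in% colnames(est))
  expect_false("HDCA" %in% colnames(est))
  merged_tru <- tru[rownames(est), "UDCA"] + tru[rownames(est), "HDCA"]
  sid <- names(which.max(merged_tru))     # a sample with the pair in range
  expect_equal(est[sid, "UDCA+HDCA"], merged_tru[[sid]], tolerance = 1e-6)
  ## every species inside the validated range is recovered exactly
  common <- intersect(colnames(tru), colnames(est))
  chain <- st$metadata$ba_dilution_chain[
    match(rownames(est), st$metadata$sample_id)]
  in_range <- sweep(tru[rownames(est), common], 1, chain, "/") >= 0.05 &
    sweep(tru[rownames(est), common], 1, chain, "/") <= 30
  d <- abs(est[, common] / tru[rownames(est), common] - 1)
  expect_lt(max(d[in_range]), 1e-6)
  ## below-LLOQ cells are zeroed and flagged
  expect_true(all(est[, common][!in_range & d > 1e-6] == 0 |
                    tru[rownames(est), common][!in_range & d > 1e-6] /
                    chain > 30))
})

test_that("pool summaries compute the two fractions from the panel", {
  conc <- matrix(c(5, 0, 0), 1, dimnames = list("s1", c("TCA", "CA", "DCA")))
  s <- summarize_ba_profile(conc)
  expect_equal(s$frac_unconjugated, 0)
  expect_equal(s$frac_secondary, 0)

  conc <- matrix(c(5, 5, 0), 1, dimnames = list("s1", c("TCA", "CA", "DCA")))
  expect_equal(summarize_ba_profile(conc)$frac_unconjugated, 0.5)

  ## CA 4 + DCA 4 + TDCA 2: secondary = (4 + 2)/10
  conc <- matrix(c(4, 4, 2), 1, dimnames = list("s1", c("CA", "DCA", "TDCA")))
  s <- summarize_ba_profile(conc)
  expect_equal(s$frac_secondary, 0.6)
  expect_equal(s$frac_unconjugated, 0.8)
  expect_equal(s$total, 10)

  ## fractions invariant under uniform scaling
  s10 <- summarize_ba_profile(conc * 10)
  expect_equal(s10$frac_secondary, s$frac_secondary)
  expect_equal(s10$frac_unconjugated, s$frac_unconjugated)

  expect_error(summarize_ba_profile(
    matrix(1, 1, 1, dimnames = list("s", "NOT_A_SPECIES"))), "unclassified")
})

test_that("drift correction before quantification is a no-op on drift-free data", {
  cfg <- fast_config(62, noise = FALSE,
                     assay_noise = list(drift_slope = 0))
  st <- generate_study(cfg, parts = "bileacids")
  corrected <- correct_drift(st$bileacid_areas)
  key <- function(d) order(d$injection_index, d$species)
  expect_equal(corrected$area[key(corrected)],
               st$bileacid_areas$area[key(st$bileacid_areas)],
               tolerance = 1e-12)
})
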