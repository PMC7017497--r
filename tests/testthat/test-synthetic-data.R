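test_that("configuration validation names the offending field", {
  expect_error(simulation_config(sequencing_depth = 0), "sequencing_depth")
  expect_error(simulation_config(n_mice_per_group = 0), "n_mice_per_group")
  expect_error(simulation_config(assay_noise = list(cq_sd = -1)), "cq_sd")
  bad <- default_bileacid_model()
  bad$frac_unconj[1] <- 1.5
  expect_error(simulation_config(bileacid_model = bad), "bileacid_model")
  cp <- default_contaminant_panel()
  cp$present_in_cecum <- TRUE
  expect_error(simulation_config(contaminant_panel = cp),
               "contaminant_panel")
})

test_that("study dimensions follow the design arithmetic", {
  cfg <- fast_config(71)
  st <- generate_study(cfg, parts = "counts")
  md <- st$metadata
  ## 6 mice x 4 groups x 6 sites contents + SI2 mucosa + bile
  expect_equal(sum(md$material == "contents"), 6 * 4 * 6)
  expect_equal(sum(md$material == "mucosa"), 24)
  expect_equal(sum(md$material == "bile"), 24)
  expect_false(anyDuplicated(md$sample_id) > 0)
  ## counts cover contents + mucosa at the configured depth
  expect_equal(nrow(st$asv_counts), 144 + 24)
  expect_equal(unname(rowSums(st$asv_counts)),
               rep(cfg$sequencing_depth, 168))
})

test_that("same seed reproduces the study bit for bit", {
  a <- generate_study(fast_config(72))
  b <- generate_study(fast_config(72))
  expect_identical(a$asv_counts, b$asv_counts)
  expect_identical(a$qpcr, b$qpcr)
  expect_identical(a$ddpcr, b$ddpcr)
  expect_identical(a$mpn, b$mpn)
  expect_identical(a$bileacid_areas, b$bileacid_areas)
  c <- generate_study(fast_config(73))
  expect_false(identical(a$asv_counts, c$asv_counts))
})

test_that("true relative abundances sum to one before the draw", {
  st <- generate_study(fast_config(74), parts = "counts")
  expect_equal(unname(rowSums(st$truth$relative)),
               rep(1, nrow(st$truth$relative)), tolerance = 1e-12)
  ## contaminants have zero true biological abundance everywhere
  expect_false(any(default_contaminant_panel()$asv_id %in%
                     colnames(st$truth$relative)))
  ## yet draw reads through the ambient mechanism
  expect_gt(sum(st$asv_counts[, default_contaminant_panel()$asv_id]), 0)
})

test_that("behavior classes produce the three response patterns", {
  st <- generate_study(fast_config(75), parts = "counts")
  md <- st$metadata
  tp <- st$config$taxon_panel
  up <- c("STM", "SI1", "SI2", "SI3")
  tcf_up <- md$sample_id[md$group == "TC-F" & md$site %in% up &
                           md$material == "contents"]
  cop_up <- md$sample_id[md$group != "TC-F" & md$site %in% up &
                           md$material == "contents"]
  fecal <- tp$asv_id[tp$behavior == "fecal"]
  lacto <- tp$asv_id[tp$taxon == "Lactobacillales"]
  ## fecal taxa truly absent in TC-F upper gut, present in coprophagic
  expect_true(all(st$truth$relative[tcf_up, fecal] == 0))
  expect_true(all(rowSums(st$truth$relative[cop_up, fecal]) > 0))
  ## true small-intestine taxa present everywhere in the upper gut
  expect_true(all(st$truth$relative[c(tcf_up, cop_up), lacto] > 0))
  ## cecum-shifted taxa reduced in the TC-F cecum only
  shifted <- tp$asv_id[tp$behavior == "cecum_shifted"]
  tcf_cec <- md$sample_id[md$group == "TC-F" & md$site == "CEC" &
                            md$material == "contents"]
  cop_cec <- md$sample_id[md$group == "CTRL" & md$site == "CEC" &
                            md$material == "contents"]
  expect_lt(median(rowSums(st$truth$relative[tcf_cec, shifted,
                                             drop = FALSE])),
            median(rowSums(st$truth$relative[cop_cec, shifted,
                                             drop = FALSE])))
})

test_that("ddPCR generator honors the Poisson occupancy closed form", {
  ## lambda = ln 2 gives mean positive fraction 1/2
  conc <- log(2) / 0.00085
  r <- gen_ddpcr_run(conc, n_droplets = 20000, noise = FALSE)
  expect_equal(r$n_positive / r$n_droplets, 0.5, tolerance = 1e-12)
  expect_equal(gen_ddpcr_run(0)$n_positive, 0)
  expect_equal(gen_ddpcr_run(1e12)$n_positive, 20000)
})

test_that("MPN plate generator is monotone with the expected well pattern", {
  ## density giving lambda = ln 2 in the first dilution: expect 4/8 wells
  d <- log(2) / 1e-3
  pl <- gen_mpn_plate(d, noise = FALSE)
  expect_equal(pl$p[1], 4, tolerance = 1e-9)
  expect_true(all(diff(pl$p) <= 0))
  expect_true(all(gen_mpn_plate(0)$p == 0))
})

test_that("qPCR generator spaces standards by the slope per decade", {
  r <- gen_qpcr_run(1e5, intercept = 40, slope = -3.321928, cq_sd = 0,
                    noise = FALSE)
  std <- r[r$is_standard, ]
  expect_equal(diff(std$cq), rep(-3.321928, 6), tolerance = 1e-9)
  ## doubling template lowers Cq by one cycle at 100% efficiency
  r2 <- gen_qpcr_run(2e5, intercept = 40, slope = -3.321928,
                     standards_copies = numeric(), noise = FALSE)
  expect_equal(mean(r$cq[!r$is_standard]) - mean(r2$cq), 1,
               tolerance = 1e-6)
  ## noiseless triplicates identical
  expect_equal(length(unique(r$cq[!r$is_standard])), 1L)
  expect_error(gen_qpcr_run(0), "> 0")
})

test_that("bile-acid run layout carries QC bracketing and drift", {
  cfg <- fast_config(76, noise = FALSE,
                     assay_noise = list(drift_slope = -0.01))
  st <- generate_study(cfg, parts = "bileacids")
  ar <- st$bileacid_areas
  qc_idx <- sort(unique(ar$injection_index[ar$sample_id == "QC"]))
  ## QCs at 0, 8, 16, ... plus a closing bracket
  expect_equal(head(qc_idx, 3), c(0, 8, 16))
  ## QC response declines ~8% over 8 injections at slope -0.01
  qc <- ar[ar$sample_id == "QC" & ar$species == "TCA", ]
  qc <- qc[order(qc$injection_index), ]
  expect_equal(qc$area[2] / qc$area[1], 1 - 0.08, tolerance = 1e-9)
  ## standard series present three times at 7 levels
  std <- ar[grepl("^STD", ar$sample_id), ]
  expect_equal(length(unique(std$sample_id)), 21)
  ## internal standards in every injection
  expect_true(all(tapply(ar$species, ar$injection_index,
                         function(s) "D4-TCA" %in% s)))
})

test_that("contaminant read frequency tracks inverse DNA concentration", {
  st <- generate_study(fast_config(77), parts = "counts")
  md <- st$metadata
  seqd <- md[match(rownames(st$asv_counts), md$sample_id), ]
  rel <- to_relative(st$asv_counts)
  f <- rel[, "CONT01"]
  keep <- f > 0
  ## log-log slope against DNA concentration is close to -1
  sl <- coef(lm(log(f[keep]) ~ log(seqd$dna_conc[keep])))[2]
  expect_lt(sl, -0.8)
  expect_gt(sl, -1.2)
})

test_that("writers and readers round-trip the raw bundle losslessly", {
  st <- generate_study(fast_config(78))
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  expect_true(all(file.exists(paths)))
  back <- read_study(dir)
  expect_equal(back$asv_counts, st$asv_counts, tolerance = 1e-12)
  expect_equal(back$metadata$sample_id, st$metadata$sample_id)
  expect_equal(back$qpcr$cq, st$qpcr$cq, tolerance = 1e-12)
  expect_equal(back$ddpcr$n_positive, st$ddpcr$n_positive)
  expect_equal(back$mpn$p, st$mpn$p)
  expect_equal(back$bileacid_areas$area, st$bileacid_areas$area,
               tolerance = 1e-10)
  expect_equal(back$gene_copy_table, st$gene_copy_table,
               ignore_attr = TRUE)
})

test_that("BIOM round trip preserves the count matrix", {
  skip_if_not_installed("biomformat")
  st <- generate_study(fast_config(79), parts = "counts")
  f <- withr::local_tempfile(fileext = ".biom")
  write_count_biom(st$asv_counts, f)
  back <- read_count_table(f)
  expect_equal(back[rownames(st$asv_counts), colnames(st$asv_counts)],
               st$asv_counts, tolerance = 1e-12)
})
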