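test_that("standard curve recovers slope, efficiency and R^2 on exact data", {
  ## decade spacing of exactly 3.3219 cycles = 100% efficiency
  fit <- fit_standard_curve(10^(3:7), 35 - 3.321928 * (0:4))
  expect_equal(fit$slope, -3.321928, tolerance = 1e-6)
  expect_equal(fit$efficiency, 1, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_true(fit$valid)

  ## zero slope: fits, but flagged invalid
  flat <- fit_standard_curve(c(1e3, 1e5), c(30, 30))
  expect_false(flat$valid)

  expect_error(fit_standard_curve(1e4, 30), ">= 2")
  expect_error(fit_standard_curve(c(1e4, 1e4), c(30, 31)), "distinct")
})

test_that("qPCR back-calculation inverts the curve and propagates noise", {
  fit <- fit_standard_curve(10^(2:8), 40 - 3.321928 * (2:8))
  cq4 <- 40 - 3.321928 * 4
  ## sample at the 1e4 standard's Cq returns 1e4 copies
  est <- quantify_qpcr("s", rep(cq4, 3), fit)
  expect_equal(est$value, 1e4, tolerance = 1e-9)
  ## identical triplicates: CI width 0
  expect_equal(est$ci_hi - est$ci_lo, 0, tolerance = 1e-6)
  ## one cycle above the 1e4 standard: 10^(4 - 1/3.321928)
  est1 <- quantify_qpcr("s", rep(cq4 + 1, 3), fit)
  expect_equal(est1$value, 10^(4 - 1 / 3.321928), tolerance = 1e-9)
  expect_equal(est1$value, 5000, tolerance = 1e-4)
  ## two of three wells failing -> below LLOD
  est2 <- quantify_qpcr("s", c(cq4, NA, NA), fit)
  expect_identical(est2$flag, "below_llod")
  ## noisy triplicates give a CI containing the point estimate
  est3 <- quantify_qpcr("s", cq4 + c(-0.2, 0, 0.2), fit)
  expect_true(est3$ci_lo < est3$value && est3$value < est3$ci_hi)
})

test_that("ddPCR Poisson estimator matches the closed form and edge flags", {
  ## half the droplets positive: lambda = ln 2 -> 815.48 copies/uL
  est <- quantify_ddpcr("s", 20000, 10000)
  expect_equal(est$value, log(2) / 0.00085, tolerance = 1e-9)
  expect_equal(est$value, 815.5, tolerance = 1e-3)
  expect_identical(est$flag, "ok")

  expect_identical(quantify_ddpcr("s", 20000, 20000)$flag, "above_range")
  zero <- quantify_ddpcr("s", 20000, 0)
  expect_identical(zero$flag, "below_llod")
  expect_equal(zero$value, 0)
  expect_gt(zero$ci_hi, 0)

  ## strictly increasing in positives over the valid range
  vals <- vapply(c(10, 100, 1000, 5000, 19999), function(k)
    quantify_ddpcr("s", 20000, k)$value, numeric(1))
  expect_true(all(diff(vals) > 0))

  ## dilution scales linearly
  expect_equal(quantify_ddpcr("s", 20000, 10000, dilution = 10)$value,
               10 * est$value)
})

test_that("MPN maximum likelihood matches closed form and grid oracle", {
  ## single dilution, half positive: -ln(0.5)/v
  est <- estimate_mpn("s", 1e-3, 8, 4)
  expect_equal(est$value, -log(0.5) / 1e-3, tolerance = 1e-6)

  ## all-negative and all-positive plates
  neg <- estimate_mpn("s", 10^-(3:6), rep(8, 4), rep(0, 4))
  expect_identical(neg$flag, "below_llod")
  expect_equal(neg$value, 0)
  expect_gt(neg$ci_hi, 0)
  pos <- estimate_mpn("s", 10^-(3:6), rep(8, 4), rep(8, 4))
  expect_identical(pos$flag, "above_range")

  ## a multi-dilution pattern agrees with the dense grid oracle to 0.1%
  v <- 1e-3 / 10^(0:7)
  p <- c(8, 8, 5, 1, 0, 0, 0, 0)
  est <- estimate_mpn("s", v, 8, p)
  oracle <- grid_mpn_oracle(v, rep(8, 8), p)
  expect_equal(est$value, oracle, tolerance = 1e-3)

  ## CI contains the estimate
  expect_true(est$ci_lo < est$value && est$value < est$ci_hi)
})

test_that("load normalization applies the dilution chain and units", {
  est <- load_estimate <- data.frame(
    sample_id = "s", value = 1e5, unit = "copies/reaction",
    method = "qPCR", ci_lo = 9e4, ci_hi = 1.1e5, flag = "ok",
    stringsAsFactors = FALSE)
  contents <- data.frame(sample_id = "s", material = "contents",
                         mass_g = 0.1, dilution_chain = 100)
  out <- normalize_load(est, contents)
  expect_equal(out$value, 1e8)
  expect_identical(out$unit, "copies/g contents")

  mucosa <- data.frame(sample_id = "s", material = "mucosa",
                       dna_input_ng = 200)
  est$value <- 1e4
  out <- normalize_load(est, mucosa)
  expect_equal(out$value, 5e3)
  expect_identical(out$unit, "copies/100 ng mucosal DNA")

  bad <- data.frame(sample_id = "s", material = "contents", mass_g = NA)
  expect_error(normalize_load(est, bad), "mass_g")
})

test_that("batch load quantification prefers ddPCR and records methods", {
  cfg <- fast_config(41)
  st <- generate_study(cfg, parts = c("qpcr", "ddpcr", "mpn"))
  loads <- quantify_loads(st$qpcr, st$ddpcr, st$mpn, st$metadata)
  expect_true(all(c("ddPCR", "MPN") %in% loads$method))
  dd <- loads[loads$method == "ddPCR", ]
  tru <- c(st$truth$loads, st$truth$mucosal_loads)[dd$sample_id]
  relerr <- abs(dd$value / tru - 1)
  expect_lt(median(relerr), 0.1)
  ## qPCR-only table also works, through the shared standard series
  qonly <- quantify_loads(st$qpcr, NULL, NULL, st$metadata)
  tru_q <- c(st$truth$loads, st$truth$mucosal_loads)[qonly$sample_id]
  expect_lt(median(abs(qonly$value / tru_q - 1)), 0.15)
})
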