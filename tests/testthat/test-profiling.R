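test_that("relative conversion normalizes rows and flags empty samples", {
  m <- rbind(a = c(30, 70), b = c(0, 0), c = c(5, 0))
  rel <- to_relative(m)
  expect_equal(rel["a", ], c(0.3, 0.7), ignore_attr = TRUE)
  expect_equal(rel["c", ], c(1, 0), ignore_attr = TRUE)
  expect_true(attr(rel, "empty")["b"])
  expect_false(attr(rel, "empty")["a"])
  expect_error(to_relative(matrix(-1)), "non-negative")
})

test_that("taxonomic collapse follows padding semantics and conserves sums", {
  fx <- collapse_fixture()
  at_order <- collapse_taxa(fx$counts, fx$taxonomy, "order")
  ## hand-derived grouping: A1,A2,A3 share o__O1; A4 is o__O2; A5 is
  ## unassigned below phylum and keeps its deepest assigned prefix
  expect_setequal(colnames(at_order),
                  c("d__B;p__F;c__C1;o__O1", "d__B;p__F;c__C2;o__O2",
                    "d__B;p__F;__;__"))
  expect_equal(at_order["s1", "d__B;p__F;c__C1;o__O1"], 60)
  expect_equal(at_order["s1", "d__B;p__F;c__C2;o__O2"], 40)
  expect_equal(at_order["s1", "d__B;p__F;__;__"], 50)
  expect_equal(rowSums(at_order), rowSums(fx$counts))

  ## collapse at genus then order == collapse at order directly
  at_genus <- collapse_taxa(fx$counts, fx$taxonomy, "genus")
  redone <- collapse_taxa(at_genus, fx$taxonomy, "order")
  expect_equal(redone[, sort(colnames(redone))],
               at_order[, sort(colnames(at_order))])

  expect_error(collapse_taxa(fx$counts, fx$taxonomy, "strain"), "level")
})

test_that("prevalence rule flags taxa absent from all cecum samples", {
  calls <- flag_contaminants_prevalence(tiny_counts(), tiny_metadata())
  expect_identical(calls$taxon, "TX4")
  ## one read in one cecum sample rescues a taxon
  m <- tiny_counts(); m["s_cec1", "TX4"] <- 1
  expect_equal(nrow(flag_contaminants_prevalence(m, tiny_metadata())), 0L)
  ## taxon absent everywhere is vacuously not flagged
  m <- tiny_counts(); m[, "TX4"] <- 0
  expect_equal(nrow(flag_contaminants_prevalence(m, tiny_metadata())), 0L)
  md <- tiny_metadata(); md$site <- "STM"
  expect_error(flag_contaminants_prevalence(tiny_counts(), md), "cecum")
})

test_that("frequency score separates inverse-frequency from constant taxa", {
  conc <- c(1, 10, 100, 1000, 10000)
  rel <- cbind(contam = 0.01 / conc, biol = rep(0.02, 5))
  rel <- cbind(rel, rest = 1 - rowSums(rel))
  rownames(rel) <- paste0("s", 1:5)
  calls <- score_contaminant_frequency(rel, conc)
  sc <- setNames(calls$score, calls$taxon)
  expect_lt(sc["contam"], 1e-9)           # SSR_contam = 0
  expect_equal(sc[["biol"]], 1)           # SSR_biol = 0
  expect_identical(calls$flagged_by[calls$taxon == "contam"],
                   "frequency_score")
  expect_identical(calls$flagged_by[calls$taxon == "biol"], "")
  ## fewer than five nonzero samples: taxon not scored
  rel2 <- rel; rel2[1:2, "contam"] <- 0
  calls2 <- score_contaminant_frequency(rel2, conc)
  expect_false("contam" %in% calls2$taxon)
  expect_error(score_contaminant_frequency(rel, c(-1, conc[-1])),
               "positive")
})

test_that("contaminant removal renormalizes relative but not absolute", {
  rel <- matrix(c(0.2, 0.3, 0.5), 1, dimnames = list("s", c("a", "b", "c")))
  calls <- data.frame(taxon = "a", flagged_by = "frequency_score")
  out <- remove_contaminants(rel, calls)
  expect_equal(out["s", ], c(b = 0.375, c = 0.625))

  abs <- matrix(c(2e5, 3e5, 5e5), 1, dimnames = list("s", c("a", "b", "c")))
  out <- remove_contaminants(abs, calls, relative = FALSE)
  expect_equal(unname(rowSums(out)), 8e5)

  org <- matrix(1, 1, 2,
                dimnames = list("s", c("o__Chloroplast", "o__Other")))
  none <- data.frame(taxon = character(), flagged_by = character())
  expect_true("o__Chloroplast" %in%
                colnames(remove_contaminants(org, none,
                                             keep_organellar = TRUE)))
  expect_false("o__Chloroplast" %in%
                 colnames(remove_contaminants(org, none,
                                              keep_organellar = FALSE)))
})

test_that("absolute scaling multiplies by loads and flags LLOD cells", {
  rel <- matrix(c(0.25, 0.75), 1, dimnames = list("s", c("a", "b")))
  out <- to_absolute(rel, c(s = 4e6))
  expect_equal(out["s", ], c(a = 1e6, b = 3e6))

  ## a load flagged below LLOD flags the whole row
  loads <- data.frame(sample_id = "s", value = 4e6, unit = "copies/g",
                      method = "ddPCR", ci_lo = NA, ci_hi = NA,
                      flag = "below_llod")
  out <- to_absolute(rel, loads)
  expect_true(all(attr(out, "llod")["s", ]))

  ## depth-based LLOD: cells under one read-equivalent are flagged
  rel2 <- matrix(c(0.00005, 0.99995), 1, dimnames = list("s", c("a", "b")))
  out2 <- to_absolute(rel2, c(s = 1e6), depth = c(s = 1e4))
  expect_true(attr(out2, "llod")["s", "a"])
  expect_false(attr(out2, "llod")["s", "b"])

  expect_error(to_absolute(rel, c(other = 1)), "missing load")
})

test_that("round trip counts -> relative -> absolute conserves structure", {
  set.seed(33)
  m <- matrix(rpois(50, 20), 5, 10,
              dimnames = list(paste0("s", 1:5), paste0("t", 1:10)))
  rel <- to_relative(m)
  loads <- setNames(rowSums(m) * 7, rownames(m))
  abs <- to_absolute(rel, loads)
  expect_equal(unname(rowSums(abs)), unname(loads))
  expect_equal(abs / 7, m, ignore_attr = TRUE)
})

test_that("group mean profiles average absolute and renormalize relative", {
  m <- rbind(s1 = c(1e6, 0), s2 = c(0, 1e6), s3 = c(5, 5))
  colnames(m) <- c("a", "b")
  md <- data.frame(sample_id = c("s1", "s2", "s3"),
                   group = c("g1", "g1", "g2"), stringsAsFactors = FALSE)
  prof <- mean_group_profile(m, md, by = "group")
  expect_equal(prof$absolute["g1", ], c(a = 5e5, b = 5e5))
  expect_equal(prof$relative["g1", ], c(a = 0.5, b = 0.5))
  expect_equal(prof$absolute["g2", ], c(a = 5, b = 5))
})
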