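## Independent oracles and small fixture builders shared across tests.

## Dense two-stage grid search over log10(lambda) maximizing the MPN
## likelihood directly (no calls into the estimator under test).
grid_mpn_oracle <- function(volumes, n, p) {
  loglik <- function(lam) {
    ll <- 0
    for (i in seq_along(volumes)) {
      lv <- lam * volumes[i]
      term <- if (p[i] > 0) p[i] * log(-expm1(-lv)) else 0
      ll <- ll + term - (n[i] - p[i]) * lv
    }
    ll
  }
  coarse <- seq(-2, 12, by = 0.01)
  ll <- vapply(10^coarse, loglik, numeric(1))
  best <- coarse[which.max(ll)]
  fine <- seq(best - 0.02, best + 0.02, by = 1e-5)
  llf <- vapply(10^fine, loglik, numeric(1))
  10^fine[which.max(llf)]
}

## A tiny hand-checkable count table: 4 samples (2 cecum contents),
## 4 taxa, with taxon "TX4" absent from both cecum samples.
tiny_counts <- function() {
  m <- rbind(
    s_cec1 = c(30, 70, 0, 0),
    s_cec2 = c(10, 80, 10, 0),
    s_stm1 = c(5, 0, 0, 95),
    s_stm2 = c(50, 25, 25, 0))
  colnames(m) <- c("TX1", "TX2", "TX3", "TX4")
  m
}

tiny_metadata <- function() {
  data.frame(
    sample_id = c("s_cec1", "s_cec2", "s_stm1", "s_stm2"),
    group = c("CTRL", "CTRL", "CTRL", "CTRL"),
    site = c("CEC", "CEC", "STM", "STM"),
    material = "contents",
    stringsAsFactors = FALSE)
}

## 5-ASV taxonomy with assignment depth varying from species-level down to
## phylum-level, for the collapse semantics checks.
collapse_fixture <- function() {
  tax <- data.frame(
    asv_id = paste0("A", 1:5),
    lineage = c(
      "d__B;p__F;c__C1;o__O1;f__F1;g__G1;s__S1",
      "d__B;p__F;c__C1;o__O1;f__F2",
      "d__B;p__F;c__C1;o__O1",
      "d__B;p__F;c__C2;o__O2;f__F3;g__G2;s__S2",
      "d__B;p__F"),
    stringsAsFactors = FALSE)
  m <- matrix(c(10, 20, 30, 40, 50,
                1, 2, 3, 4, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), tax$asv_id))
  list(counts = m, taxonomy = tax)
}

## Fast study config for replicate-heavy tests.
fast_config <- function(seed, ...) {
  simulation_config(seed = seed, ...)
}
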