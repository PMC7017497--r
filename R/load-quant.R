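## Total microbial load estimation from raw quantification assays.
##
## Three independent routes to the same quantity (total 16S rRNA gene copies,
## or culturable cells, per sample):
##   * qPCR   -- back-calculation through a run-specific standard curve,
##   * ddPCR  -- the Poisson partition estimator on droplet counts,
##   * MPN    -- maximum likelihood on the positive/negative well pattern of
##               a replicated serial-dilution culture assay.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of quantification cycle (Cq) on log10 input copies
#' over a dilution series of a quantified standard. The amplification
#' efficiency is derived from the slope as \code{10^(-1/slope) - 1}
#' (1.0 = perfect doubling per cycle, slope -3.3219).
#'
#' @param copies numeric vector of known standard input copies (> 0).
#' @param cq numeric vector of observed Cq values, same length.
#' @return An object of class \code{standard_curve} with elements
#'   \code{slope}, \code{intercept}, \code{r_squared}, \code{efficiency},
#'   \code{n}, \code{valid} (slope must be negative), and the standard
#'   points used.
#' @examples
#' fit <- fit_standard_curve(10^(3:7), 35 - 3.3219 * (0:4))
#' fit$efficiency  # 1.0 at perfect doubling
#' @export
fit_standard_curve <- function(copies, cq) {
  if (length(copies) != length(cq))
    stop("'copies' and 'cq' must have equal length", call. = FALSE)
  keep <- is.finite(copies) & is.finite(cq)
  copies <- copies[keep]; cq <- cq[keep]
  if (length(copies) < 2L || any(copies <= 0))
    stop("standard-curve fit requires >= 2 finite points with copies > 0",
         call. = FALSE)
  x <- log10(copies)
  if (length(unique(x)) < 2L)
    stop("standard-curve fit requires >= 2 distinct copy levels", call. = FALSE)
  fit <- stats::lm(cq ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  ss_tot <- sum((cq - mean(cq))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_
  out <- list(slope = slope, intercept = intercept, r_squared = r2,
              efficiency = 10^(-1 / slope) - 1,
              n = length(copies), valid = slope < 0,
              vcov = suppressWarnings(stats::vcov(fit)),
              df = fit$df.residual,
              standards = data.frame(copies = copies, cq = cq))
  class(out) <- "standard_curve"
  out
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("qPCR standard curve (", x$n, " points)\n", sep = "")
  cat(sprintf("  Cq = %.4f + %.4f * log10(copies)\n", x$intercept, x$slope))
  cat(sprintf("  R^2 = %.5f, efficiency = %.3f%s\n", x$r_squared,
              x$efficiency, if (!x$valid) "  [INVALID: slope >= 0]" else ""))
  invisible(x)
}

## Constructor for the one-row load-estimate record shared by all three
## estimators. Units are carried as data, never implied.
load_estimate <- function(sample_id, value, unit, method,
                          ci_lo = NA_real_, ci_hi = NA_real_, flag = "ok") {
  data.frame(sample_id = as.character(sample_id), value = value, unit = unit,
             method = method, ci_lo = ci_lo, ci_hi = ci_hi, flag = flag,
             stringsAsFactors = FALSE)
}

#' Back-calculate copies from qPCR triplicates through a standard curve
#'
#' Triplicate Cq values are averaged after dropping non-amplifying wells
#' (\code{NA}); if fewer than two wells amplified the sample is flagged
#' \code{below_llod}. Copies per reaction are \code{10^((meanCq -
#' intercept)/slope)}; the 95% CI propagates the t-based CI of the mean Cq
#' through the curve.
#'
#' @param sample_id sample identifier.
#' @param cq numeric vector of replicate Cq values; \code{NA} = no
#'   amplification.
#' @param fit a \code{standard_curve}.
#' @param min_copies detection floor in copies per reaction; estimates below
#'   it are flagged \code{below_llod}. Default: the smallest standard on the
#'   curve.
#' @return one-row data.frame (see \code{\link{fit_standard_curve}} for the
#'   curve; columns sample_id, value, unit, method, ci_lo, ci_hi, flag).
#'   \code{value} is in copies per reaction.
#' @export
quantify_qpcr <- function(sample_id, cq, fit, min_copies = NULL) {
  stopifnot(inherits(fit, "standard_curve"))
  if (!fit$valid) stop("standard curve is invalid (slope >= 0)", call. = FALSE)
  min_copies <- min_copies %||% min(fit$standards$copies)
  ok <- is.finite(cq)
  if (sum(ok) < 2L)
    return(load_estimate(sample_id, 0, "copies/reaction", "qPCR",
                         flag = "below_llod"))
  cqv <- cq[ok]
  m <- mean(cqv)
  x0 <- (m - fit$intercept) / fit$slope      # log10 copies
  value <- 10^x0
  ## delta-method variance of the inverse prediction, combining triplicate
  ## noise with the calibration-line uncertainty
  se_q2 <- stats::var(cqv) / length(cqv)
  v_curve <- if (!is.null(fit$vcov))
    (fit$vcov[1, 1] + x0^2 * fit$vcov[2, 2] + 2 * x0 * fit$vcov[1, 2])
  else 0
  v_x <- (se_q2 + v_curve) / fit$slope^2
  ## Welch-Satterthwaite df across the two variance components
  df <- if (v_x > 0) {
    num <- (se_q2 + v_curve)^2
    den <- se_q2^2 / max(length(cqv) - 1L, 1L) +
      v_curve^2 / max(fit$df %||% Inf, 1L)
    if (den > 0) num / den else Inf
  } else Inf
  half <- stats::qt(0.975, df = df) * sqrt(v_x)
  ci <- 10^(x0 + c(-1, 1) * half)
  flag <- if (value < min_copies) "below_llod" else "ok"
  load_estimate(sample_id, value, "copies/reaction", "qPCR",
                ci[1L], ci[2L], flag)
}

#' Poisson partition estimate from droplet digital PCR counts
#'
#' With \code{k} of \code{n} droplets positive, the mean occupancy is
#' \code{lambda = -ln((n - k)/n)} copies per droplet and the template
#' concentration \code{lambda / droplet volume * dilution}. The 95% CI is
#' the exact (Clopper-Pearson) binomial interval on the positive fraction
#' propagated through the same transform.
#'
#' @param sample_id sample identifier.
#' @param n_droplets accepted droplet count (> 0).
#' @param n_positive positive droplet count.
#' @param droplet_volume_nl droplet volume in nanoliters (default 0.85,
#'   the usual vendor value for the QX200 system).
#' @param dilution fold dilution of the template before partitioning.
#' @param llod_positives droplets required for a call (default 3); below it
#'   the estimate is flagged \code{below_llod}.
#' @return one-row data.frame; \code{value} in copies per microliter of the
#'   undiluted template.
#' @examples
#' quantify_ddpcr("s1", 20000, 10000)$value  # ~815.5 copies/uL
#' @export
quantify_ddpcr <- function(sample_id, n_droplets, n_positive,
                           droplet_volume_nl = 0.85, dilution = 1,
                           llod_positives = 3) {
  if (n_droplets <= 0) stop("n_droplets must be > 0", call. = FALSE)
  if (n_positive < 0 || n_positive > n_droplets)
    stop("n_positive must be in [0, n_droplets]", call. = FALSE)
  if (droplet_volume_nl <= 0) stop("droplet_volume_nl must be > 0", call. = FALSE)
  v_ul <- droplet_volume_nl / 1000
  conc <- function(k) -log1p(-k / n_droplets) / v_ul * dilution
  ## exact binomial CI on the positive fraction (normal approximation for
  ## non-integer counts, which arise only in expectation-mode simulations)
  ci <- if (n_positive == round(n_positive))
    stats::binom.test(round(n_positive), n_droplets)$conf.int
  else {
    ph <- n_positive / n_droplets
    pmin(1, pmax(0, ph + c(-1, 1) * 1.96 * sqrt(ph * (1 - ph) / n_droplets)))
  }
  if (n_positive == n_droplets)
    return(load_estimate(sample_id, Inf, "copies/uL", "ddPCR",
                         conc(ci[1L] * n_droplets), Inf, flag = "above_range"))
  value <- conc(n_positive)
  est <- load_estimate(sample_id, value, "copies/uL", "ddPCR",
                       conc(ci[1L] * n_droplets), conc(ci[2L] * n_droplets))
  if (n_positive < llod_positives) {
    est$flag <- "below_llod"
    if (n_positive == 0) est$value <- 0
  }
  est
}

## Negative log-likelihood of an MPN plate at density lambda (per mL).
## volumes: inoculum volume of *original* sample per well at each dilution
## (mL); n: wells; p: positive wells. Non-integer p is allowed (expectation
## mode used by noise-free simulations).
mpn_negloglik <- function(lambda, volumes, n, p) {
  lv <- lambda * volumes
  ppos <- -expm1(-lv)                       # 1 - exp(-lambda v)
  ll <- numeric(length(lv))
  pos <- p > 0
  ll[pos] <- p[pos] * log(ppos[pos])
  ll <- ll - (n - p) * lv
  -sum(ll)
}

#' Most probable number (MPN) from a serial-dilution culture assay
#'
#' Maximum-likelihood density of culturable cells given the positive /
#' negative pattern of replicated wells across a serial dilution: each well
#' inoculated with volume \code{v_i} of original sample is positive with
#' probability \code{1 - exp(-lambda v_i)}. The likelihood is maximized by a
#' 1-D search on log10(lambda); the 95% CI uses the log-normal
#' approximation on ln(MPN) with the observed Fisher information.
#'
#' @param sample_id sample identifier.
#' @param volumes_ml inoculum volume of original sample per well at each
#'   dilution (mL), strictly decreasing.
#' @param n replicates per dilution (scalar or vector).
#' @param p positive wells per dilution.
#' @return one-row data.frame; \code{value} in MPN per mL of original
#'   sample. All-negative plates are flagged \code{below_llod} (value 0,
#'   upper bound reported); all-positive plates \code{above_range}.
#' @examples
#' # single dilution, half the wells positive: closed form -ln(0.5)/v
#' estimate_mpn("s", 1e-3, 8, 4)$value  # 693.1
#' @export
estimate_mpn <- function(sample_id, volumes_ml, n, p) {
  if (length(volumes_ml) < 1L) stop("need >= 1 dilution level", call. = FALSE)
  n <- rep_len(n, length(volumes_ml))
  if (any(p < 0 | p > n)) stop("positives must satisfy 0 <= p <= n", call. = FALSE)
  if (any(volumes_ml <= 0)) stop("volumes must be > 0", call. = FALSE)
  if (all(p == 0)) {
    ## LLOD: upper bound from the all-negative likelihood at the 95% level
    upper <- log(20) / sum(n * volumes_ml)   # P(all neg) = 0.05
    return(load_estimate(sample_id, 0, "MPN/mL", "MPN", 0, upper,
                         flag = "below_llod"))
  }
  if (all(p == n)) {
    lower <- stats::uniroot(function(l)
      sum(n * log(-expm1(-l * volumes_ml))) - log(0.05),
      lower = 1e-12, upper = 1e18, tol = 1e-9)$root
    return(load_estimate(sample_id, Inf, "MPN/mL", "MPN", lower, Inf,
                         flag = "above_range"))
  }
  opt <- stats::optimize(function(loglam)
    mpn_negloglik(10^loglam, volumes_ml, n, p),
    interval = c(-9, 15), tol = 1e-10)
  lambda <- 10^opt$minimum
  ## observed Fisher information in ln(lambda)
  lv <- lambda * volumes_ml
  info <- sum(n * lv^2 * exp(-lv) / (-expm1(-lv)))
  se_ln <- if (info > 0) 1 / sqrt(info) else NA_real_
  ci <- lambda * exp(c(-1, 1) * 1.96 * se_ln)
  load_estimate(sample_id, lambda, "MPN/mL", "MPN", ci[1L], ci[2L])
}

#' Normalize a per-reaction load to the sample reporting unit
#'
#' Lumenal-contents samples are reported as copies per gram of total
#' contents via the recorded extraction dilution chain (elution volume /
#' template volume x any pre-dilution); mucosal samples as copies per
#' 100 ng of extracted DNA.
#'
#' @param estimate one-row load estimate with \code{value} in copies per
#'   reaction (or copies/uL already scaled to the reaction).
#' @param sample one row of the sample metadata table with columns
#'   \code{material} ("contents" or "mucosa"), \code{mass_g} or
#'   \code{dna_input_ng}, and \code{dilution_chain} (fold factor from
#'   reaction back to the whole extract).
#' @return the estimate with \code{value}, \code{ci_lo}, \code{ci_hi}
#'   rescaled and \code{unit} updated.
#' @export
normalize_load <- function(estimate, sample) {
  stopifnot(is.data.frame(estimate), nrow(estimate) == 1L)
  material <- as.character(sample$material)
  if (material == "contents") {
    if (is.null(sample$mass_g) || is.na(sample$mass_g))
      stop(sprintf("sample '%s': missing mass_g for contents normalization",
                   estimate$sample_id), call. = FALSE)
    chain <- sample$dilution_chain %||% 1
    if (is.na(chain)) chain <- 1
    f <- chain / sample$mass_g
    unit <- if (estimate$method == "MPN") "MPN/g contents" else "copies/g contents"
  } else if (material == "mucosa") {
    if (is.null(sample$dna_input_ng) || is.na(sample$dna_input_ng))
      stop(sprintf("sample '%s': missing dna_input_ng for mucosa normalization",
                   estimate$sample_id), call. = FALSE)
    f <- 100 / sample$dna_input_ng
    unit <- "copies/100 ng mucosal DNA"
  } else {
    stop(sprintf("sample '%s': unknown material '%s'",
                 estimate$sample_id, material), call. = FALSE)
  }
  estimate$value <- estimate$value * f
  estimate$ci_lo <- estimate$ci_lo * f
  estimate$ci_hi <- estimate$ci_hi * f
  estimate$unit <- unit
  estimate
}

#' Estimate loads for a whole study from raw assay tables
#'
#' Batch driver over the long-format assay tables written by the simulator
#' (or produced by instrument exports): per sample, ddPCR is used when a
#' run is present, otherwise qPCR; the chosen method is recorded in the
#' \code{method} column. MPN plates, when present, yield additional
#' culturable-load rows.
#'
#' @param qpcr qPCR long table (sample_id, replicate, cq, is_standard,
#'   standard_copies) or NULL.
#' @param ddpcr ddPCR table (sample_id, n_droplets, n_positive,
#'   droplet_volume_nl, dilution) or NULL.
#' @param mpn MPN table (sample_id, dilution_index, volume_ml, n, p) or NULL.
#' @param metadata sample metadata data.frame (sample_id, material, mass_g,
#'   dna_input_ng, dilution_chain).
#' @param prefer which molecular assay wins when both exist ("ddPCR" or
#'   "qPCR").
#' @return data.frame of normalized load estimates, one row per sample (plus
#'   MPN rows), columns sample_id, value, unit, method, ci_lo, ci_hi, flag.
#' @export
quantify_loads <- function(qpcr = NULL, ddpcr = NULL, mpn = NULL, metadata,
                           prefer = c("ddPCR", "qPCR")) {
  prefer <- match.arg(prefer)
  assert_cols(metadata, c("sample_id", "material"), "metadata")
  rownames(metadata) <- metadata$sample_id
  out <- list()

  qpcr_fit <- NULL
  if (!is.null(qpcr) && nrow(qpcr)) {
    assert_cols(qpcr, c("sample_id", "cq", "is_standard"), "qpcr table")
    std <- qpcr[qpcr$is_standard, ]
    if (nrow(std)) qpcr_fit <- fit_standard_curve(std$standard_copies, std$cq)
  }

  dd_ids <- if (!is.null(ddpcr)) unique(ddpcr$sample_id) else character()
  qp_ids <- if (!is.null(qpcr)) unique(qpcr$sample_id[!qpcr$is_standard]) else character()
  for (sid in union(dd_ids, qp_ids)) {
    use_dd <- sid %in% dd_ids && (prefer == "ddPCR" || !(sid %in% qp_ids))
    if (!sid %in% rownames(metadata))
      stop(sprintf("assay sample '%s' absent from metadata", sid), call. = FALSE)
    smp <- metadata[sid, ]
    if (use_dd) {
      r <- ddpcr[ddpcr$sample_id == sid, ][1L, ]
      est <- quantify_ddpcr(sid, r$n_droplets, r$n_positive,
                            r$droplet_volume_nl %||% 0.85, r$dilution %||% 1)
      ## copies/uL x template volume -> copies/reaction
      tv <- smp$template_volume_ul %||% 1
      if (is.na(tv)) tv <- 1
      est$value <- est$value * tv; est$ci_lo <- est$ci_lo * tv
      est$ci_hi <- est$ci_hi * tv; est$unit <- "copies/reaction"
    } else {
      if (is.null(qpcr_fit))
        stop("qPCR table has no standard series; cannot build a curve",
             call. = FALSE)
      cq <- qpcr$cq[qpcr$sample_id == sid & !qpcr$is_standard]
      est <- quantify_qpcr(sid, cq, qpcr_fit)
    }
    out[[length(out) + 1L]] <- normalize_load(est, smp)
  }

  if (!is.null(mpn) && nrow(mpn)) {
    assert_cols(mpn, c("sample_id", "volume_ml", "n", "p"), "mpn table")
    for (sid in unique(mpn$sample_id)) {
      pl <- mpn[mpn$sample_id == sid, ]
      pl <- pl[order(-pl$volume_ml), ]
      est <- estimate_mpn(sid, pl$volume_ml, pl$n, pl$p)
      if (sid %in% rownames(metadata)) {
        smp <- metadata[sid, ]
        if (identical(as.character(smp$material), "contents") &&
            !is.na(smp$mass_g %||% NA)) {
          ## MPN wells are inoculated from a suspension of the original
          ## contents; volume_ml already refers to original sample, so only
          ## the mass normalization applies.
          f <- (smp$suspension_ml_per_g %||% 1) / 1
          est$value <- est$value * f; est$ci_lo <- est$ci_lo * f
          est$ci_hi <- est$ci_hi * f
          est$unit <- "MPN/g contents"
        }
      }
      out[[length(out) + 1L]] <- est
    }
  }
  do.call(rbind, out)
}
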