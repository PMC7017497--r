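## Statistical layer: compositional / absolute-abundance PCA, rank-based
## group comparisons with FDR control, and load correlations.

#' Centered log-ratio transform of a relative abundance table
#'
#' A pseudocount equal to the global minimum non-zero value of the table is
#' added to zero cells only, then each row is transformed as
#' \code{ln(x) - mean(ln(x))}. CLR output rows sum to zero, and the
#' transform is invariant to per-sample scaling of the input counts.
#'
#' @param relative samples x taxa matrix of fractions (rows sum to 1 before
#'   the pseudocount).
#' @return samples x taxa real matrix.
#' @export
clr_transform <- function(relative) {
  x <- as.matrix(relative)
  if (any(rowSums(x) <= 0)) stop("all-zero row in relative table", call. = FALSE)
  nz <- x[x > 0]
  pc <- min(nz)
  x[x == 0] <- pc
  lx <- log(x)
  lx - rowMeans(lx)
}

#' Log10-transform and standardize an absolute abundance table
#'
#' Per feature (column): \code{(log10(x) - mean) / sd} with the sample
#' (n-1) standard deviation. Zeros (below-LLOD cells) are replaced by
#' \code{floor} before the log; zero-variance features are dropped with a
#' warning.
#'
#' @param absolute samples x taxa matrix, non-negative.
#' @param floor replacement for zero cells; default: smallest positive cell
#'   divided by 10.
#' @return standardized matrix (possibly fewer columns).
#' @export
log10_standardize <- function(absolute, floor = NULL) {
  x <- as.matrix(absolute)
  if (is.null(floor)) {
    pos <- x[x > 0]
    if (!length(pos)) stop("table has no positive cells", call. = FALSE)
    floor <- min(pos) / 10
  }
  x[x <= 0] <- floor
  lx <- log10(x)
  sds <- apply(lx, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep))
    warning(sprintf("dropping %d zero-variance feature(s)", sum(!keep)))
  lx <- lx[, keep, drop = FALSE]
  scale(lx, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

#' Principal component analysis with a deterministic sign convention
#'
#' PCA of the column-centered matrix (no further scaling; apply
#' \code{\link{clr_transform}} or \code{\link{log10_standardize}} first).
#' Each component's sign is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param x samples x features numeric matrix.
#' @param n_components number of components to retain (default all).
#' @param preprocessing tag recorded on the model (free-form, e.g.
#'   "clr_relative" or "log10_standardized_absolute").
#' @return object of class \code{pca_model}: \code{scores},
#'   \code{loadings}, \code{explained_variance} (fractions),
#'   \code{center}, \code{preprocessing}.
#' @export
run_pca <- function(x, n_components = NULL, preprocessing = "none") {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA requires >= 2 samples", call. = FALSE)
  k_max <- min(nrow(x) - 1L, ncol(x))
  k <- n_components %||% k_max
  if (k > k_max) stop("n_components exceeds min(samples - 1, features)",
                      call. = FALSE)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  sco <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; sco[, j] <- -sco[, j] }
  }
  out <- list(scores = sco, loadings = rot,
              explained_variance = ev[seq_len(k)],
              center = p$center, preprocessing = preprocessing)
  class(out) <- "pca_model"
  out
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA model (", nrow(x$scores), " samples, ",
      ncol(x$loadings), " components, preprocessing: ",
      x$preprocessing, ")\n", sep = "")
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n")
  invisible(x)
}

#' Kruskal-Wallis omnibus plus pairwise Wilcoxon-Mann-Whitney with FDR
#'
#' The omnibus test uses the tie-corrected Kruskal-Wallis statistic;
#' pairwise two-sided Wilcoxon-Mann-Whitney tests are exact when both group
#' sizes are <= \code{exact_max} (and the data are tie-free), otherwise the
#' normal approximation with continuity correction is used.
#' Benjamini-Hochberg adjustment is applied across the pairwise family.
#'
#' @param values numeric vector of per-sample values.
#' @param groups factor/character of group labels, >= 2 groups with n >= 2.
#' @param pairs optional 2-column matrix / list of group pairs to test
#'   (default: all pairs).
#' @param exact_max largest group size for exact MWU (default 8).
#' @return object of class \code{group_comparison}: \code{kw_statistic},
#'   \code{kw_p}, and data.frame \code{pairwise} (group1, group2, p, q).
#' @export
compare_groups <- function(values, groups, pairs = NULL, exact_max = 8) {
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) < 2) stop(">= 2 groups required", call. = FALSE)
  if (any(table(groups) < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (stats::var(values) == 0) {
    kw <- list(statistic = 0, p.value = 1)
  } else kw <- stats::kruskal.test(values, groups)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(levels(groups), 2))
  } else pairs <- matrix(unlist(pairs), ncol = 2, byrow = is.list(pairs))
  pw <- apply(pairs, 1, function(pr) {
    v1 <- values[groups == pr[1]]; v2 <- values[groups == pr[2]]
    if (stats::var(c(v1, v2)) == 0) return(1)
    exact <- length(v1) <= exact_max && length(v2) <= exact_max
    suppressWarnings(
      stats::wilcox.test(v1, v2, exact = exact, correct = TRUE)$p.value)
  })
  out <- list(kw_statistic = unname(kw$statistic), kw_p = kw$p.value,
              pairwise = data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                                    p = pw, q = stats::p.adjust(pw, "BH"),
                                    stringsAsFactors = FALSE))
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi^2 = %.3f, p = %.3g\n",
              x$kw_statistic, x$kw_p))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Feature-wise group comparisons across a table
#'
#' Applies \code{\link{compare_groups}} to every column; BH adjustment is
#' done within the pairwise family of each feature.
#'
#' @param mat samples x features matrix.
#' @param groups per-sample group labels.
#' @param ... passed to \code{\link{compare_groups}}.
#' @return data.frame (feature, kw_p, group1, group2, p, q), one row per
#'   feature x pair.
#' @export
compare_features <- function(mat, groups, ...) {
  mat <- as.matrix(mat)
  res <- lapply(colnames(mat) %||% seq_len(ncol(mat)), function(f) {
    cg <- compare_groups(mat[, f], groups, ...)
    cbind(feature = f, kw_p = cg$kw_p, cg$pairwise)
  })
  do.call(rbind, res)
}

#' Correlation between paired lumenal and mucosal loads
#'
#' Pearson correlation of the log10-transformed paired loads with a
#' two-sided p value (total loads are compared on the log scale, matching
#' how they are analyzed and displayed).
#'
#' @param lumenal,mucosal positive paired load vectors (n >= 3).
#' @return list: \code{r}, \code{p}, \code{n}.
#' @export
correlate_loads <- function(lumenal, mucosal) {
  keep <- is.finite(lumenal) & is.finite(mucosal) & lumenal > 0 & mucosal > 0
  x <- log10(lumenal[keep]); y <- log10(mucosal[keep])
  if (length(x) < 3) stop("need >= 3 complete positive pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in loads", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
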