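## Replicate and cross-assay correlation, and sample-level PCA on
## log-transformed RPM values.

#' Log-RPM sample matrix
#'
#' Builds the transcripts x samples matrix of `log2(rpm + pseudocount)`
#' used for correlation and PCA. By default the transcript universe is
#' restricted to transcripts with a nonzero count in at least one sample.
#'
#' @param cm a `crac_counts` (RPM is computed if missing).
#' @param samples sample ids to include (default all).
#' @param pseudocount added before the log (default 1).
#' @param universe `"nonzero_any"` or `"all"`.
#' @return Numeric matrix with a `pseudocount` attribute.
#' @export
sample_matrix <- function(cm, samples = NULL, pseudocount = 1,
                          universe = c("nonzero_any", "all")) {
  stopifnot(inherits(cm, "crac_counts"))
  universe <- match.arg(universe)
  if (is.null(cm$rpm)) cm <- rpm_normalize(cm)
  if (is.null(samples)) samples <- cm$samples$sample
  m <- cm$rpm[, samples, drop = FALSE]
  if (universe == "nonzero_any")
    m <- m[rowSums(cm$counts[, samples, drop = FALSE]) > 0, , drop = FALSE]
  out <- log2(m + pseudocount)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Correlation between two samples
#'
#' Pearson on the transformed values; Spearman is Pearson on mid-ranks
#' (average ranks for ties).
#'
#' @param sm matrix from [sample_matrix()].
#' @param a,b column names or indices.
#' @param method `"spearman"` or `"pearson"`.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
correlate <- function(sm, a, b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  x <- sm[, a]; y <- sm[, b]
  if (length(x) < 3L) stop("correlate requires at least 3 transcripts")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance in sample ",
         if (sd(x) == 0) a else b)
  cor(x, y, method = method)
}

#' All-pairs correlation matrix
#'
#' @inheritParams correlate
#' @return Symmetric sample x sample matrix.
#' @export
correlate_matrix <- function(sm, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  cor(sm, method = method)
}

#' Sample-level principal component analysis
#'
#' Samples are the observations, transcripts the features; features are
#' centered (no unit-variance scaling, all features share the log-RPM
#' scale) and components come from the singular value decomposition. Signs
#' follow a deterministic convention: the largest-magnitude loading of
#' each component is positive.
#'
#' @param sm matrix from [sample_matrix()] with at least 2 samples.
#' @return An object of class `crac_pca` with `coords` (samples x PCs) and
#'   `var_explained` (percent per component, non-increasing, summing to
#'   100 over all components).
#' @export
pca_samples <- function(sm) {
  if (ncol(sm) < 2L) stop("pca_samples requires at least 2 samples")
  pr <- prcomp(t(sm), center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(pr$rotation))) {
    j <- which.max(abs(pr$rotation[, k]))
    if (pr$rotation[j, k] < 0) {
      pr$rotation[, k] <- -pr$rotation[, k]
      pr$x[, k] <- -pr$x[, k]
    }
  }
  ve <- 100 * pr$sdev^2 / sum(pr$sdev^2)
  structure(list(coords = pr$x, var_explained = ve), class = "crac_pca")
}

#' @export
print.crac_pca <- function(x, ...) {
  cat("<crac_pca>", nrow(x$coords), "samples;",
      paste0("PC", seq_along(x$var_explained), " ",
             sprintf("%.1f%%", x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.crac_pca <- function(x, ...) {
  graphics::plot(x$coords[, 1], x$coords[, 2],
                 xlab = sprintf("PC1 (%.1f%%)", x$var_explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)", x$var_explained[2]), ...)
  graphics::text(x$coords[, 1], x$coords[, 2], rownames(x$coords),
                 pos = 3, cex = 0.7)
  invisible(x)
}
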