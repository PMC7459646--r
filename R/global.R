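#' Select high-variance CpG sites
#'
#' Retains sites whose across-sample variance of percent methylation lies
#' strictly above the given percentile of the site-variance distribution
#' (ties at the threshold are excluded).
#'
#' @param pm numeric matrix of percent methylation, sites x samples (e.g.
#'   \code{methPercent} of a united set).
#' @param percentile variance percentile in [0, 100), default 95.
#' @return the row-subset matrix, with the variance vector attached as
#'   attribute \code{"variance"}.
#' @export
selectHighVarianceSites <- function(pm, percentile = 95) {
  stopifnot(ncol(pm) >= 2L)
  mu <- rowMeans(pm)
  v <- rowSums((pm - mu)^2) / (ncol(pm) - 1L)
  thr <- stats::quantile(v, percentile / 100, type = 7, names = FALSE)
  keep <- v > thr
  if (!any(keep))
    warning("no site exceeds the variance threshold (constant matrix?)")
  out <- pm[keep, , drop = FALSE]
  attr(out, "variance") <- v[keep]
  out
}

#' Embed samples in two dimensions
#'
#' \code{method = "pca"} returns the first two principal-component scores of
#' the centered sample-by-site matrix; \code{method = "tsne"} runs an exact
#' t-SNE (suited to the small sample counts of an RRBS design) with the
#' given perplexity. Both are deterministic under \code{seed}.
#'
#' @param pm percent-methylation matrix, sites x samples.
#' @param method "tsne" or "pca".
#' @param perplexity t-SNE perplexity (default 2); must satisfy
#'   perplexity < (n_samples - 1) / 3.
#' @param seed integer seed for the t-SNE initialisation.
#' @return matrix n_samples x 2 with rownames = sample names.
#' @export
embedSamples <- function(pm, method = c("tsne", "pca"), perplexity = 2,
                         seed = 1L) {
  method <- match.arg(method)
  x <- t(pm)                      # samples x sites
  n <- nrow(x)
  if (method == "pca") {
    sc <- stats::prcomp(x, center = TRUE, scale. = FALSE)$x
    if (ncol(sc) == 1L) sc <- cbind(sc, 0)
    out <- sc[, 1:2, drop = FALSE]
    colnames(out) <- c("PC1", "PC2")
    return(out)
  }
  if (n < 4L)
    stop("t-SNE needs >= 4 samples at perplexity 2")
  if (perplexity >= (n - 1) / 3)
    stop("validation error: perplexity must be < (n_samples - 1) / 3")
  out <- .tsneExact(x, perplexity = perplexity, seed = seed)
  rownames(out) <- rownames(x)
  colnames(out) <- c("tSNE1", "tSNE2")
  out
}

#' Ward clustering and sample correlation
#'
#' Ward-linkage hierarchical clustering (\code{ward.D2}) of samples on
#' Euclidean distances over the site profiles, plus the Pearson correlation
#' matrix between samples.
#'
#' @param pm percent-methylation matrix, sites x samples; must be complete
#'   (united sites guarantee this).
#' @return list with \code{hclust} (a \code{stats::hclust} tree) and
#'   \code{correlation} (samples x samples Pearson matrix).
#' @export
clusterSamples <- function(pm) {
  stopifnot(ncol(pm) >= 2L)
  if (anyNA(pm)) stop("missing values; cluster united sites only")
  d <- stats::dist(t(pm))
  list(hclust = stats::hclust(d, method = "ward.D2"),
       correlation = stats::cor(pm))
}
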