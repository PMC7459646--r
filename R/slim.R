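#' SLIM q-values: sliding-linear-model FDR estimation
#'
#' Estimates the proportion of true null hypotheses pi0 with a sliding
#' linear model on the empirical p-value CDF, then converts p-values to
#' q-values. The CDF of a uniform-plus-signal p-value mixture is, away from
#' the signal concentrated near zero, a straight line of slope pi0; the
#' estimator evaluates the empirical CDF on a fine grid, fits a least-squares
#' line in each of \code{nWindows} sliding windows covering
#' [\code{lambdaStart}, 1], and takes the slope of the window with the
#' smallest residual standard error (the most linear stretch), clamped to
#' [0, 1]. q-values are then
#' \eqn{q_{(i)} = \min_{j \ge i} \; \pi_0 \, m \, p_{(j)} / j},
#' i.e. the Benjamini-Hochberg transform scaled by pi0 - so they are
#' monotone in p and never exceed the BH-adjusted values.
#'
#' With fewer than 10 p-values the CDF is too coarse for the sliding fit;
#' the function then falls back to Benjamini-Hochberg (pi0 = 1) with a
#' warning.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param lambdaStart left edge of the sliding-window range (default 0.1,
#'   keeping windows clear of the signal peak near zero).
#' @param nWindows number of sliding windows (default 10).
#' @param nBins grid resolution for the empirical CDF (default 100).
#' @return list with \code{qvalues} (same order as \code{p}) and \code{pi0}.
#' @export
#' @examples
#' set.seed(1)
#' res <- slimQvalues(runif(1000))
#' res$pi0
slimQvalues <- function(p, lambdaStart = 0.1, nWindows = 10, nBins = 100) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no NAs")
  m <- length(p)
  if (m < 10L) {
    warning("fewer than 10 p-values; falling back to Benjamini-Hochberg")
    return(list(qvalues = stats::p.adjust(p, "BH"), pi0 = 1))
  }
  grid <- seq(0, 1, length.out = nBins + 1L)[-1]
  Fhat <- stats::ecdf(p)(grid)
  width <- (1 - lambdaStart) / 2
  starts <- seq(lambdaStart, 1 - width, length.out = nWindows)
  slope <- rse <- rep(NA_real_, nWindows)
  for (i in seq_len(nWindows)) {
    sel <- grid >= starts[i] & grid <= starts[i] + width + 1e-12
    x <- grid[sel]; y <- Fhat[sel]
    b <- stats::cov(x, y) / stats::var(x)
    a <- mean(y) - b * mean(x)
    slope[i] <- b
    rse[i] <- sqrt(sum((y - a - b * x)^2) / max(1L, length(x) - 2L))
  }
  pi0 <- min(1, max(0, slope[which.min(rse)]))
  o <- order(p)
  qo <- pi0 * m * p[o] / seq_len(m)
  qo <- rev(cummin(rev(qo)))
  qo <- pmin(qo, 1)
  q <- numeric(m)
  q[o] <- qo
  list(qvalues = q, pi0 = pi0)
}
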