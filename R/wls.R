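#' Weighted least-squares baseline estimate
#'
#' The classical per-Q estimator: independently at each grid point,
#' minimises `sum_n (I_n(Q_m) - [A S]_n)^2 / sigma_{n,m}^2`. By the
#' Gauss-Markov theorem this is the minimum-variance linear unbiased
#' estimator under heteroscedastic uncorrelated noise. The covariance of
#' the estimate at each Q is `(A^T W_m A)^{-1}` with
#' `W_m = diag(1 / sigma_{n,m}^2)` (no degrees-of-freedom correction);
#' error bars are the square roots of its diagonal.
#'
#' No smoothing couples neighbouring Q points, and no regularisation is
#' applied: a rank-deficient or underdetermined design is an error (never a
#' silent pseudo-inverse), so comparisons against [fitGPR()] stay honest.
#'
#' @param data a [ContrastScatteringSet-class] with N >= L samples and a
#'   full-column-rank design.
#' @param wantCov keep the full block covariance (l-major / Q-minor order;
#'   entries coupling different Q points are exactly zero)?
#' @param ... unused.
#' @return a [PartialEstimate-class] with `metadata()$method == "wls"`.
#' @examples
#' sim <- generateCoreShell(CoreShellParams(nQ = 20), seed = 1)
#' wls <- fitWLS(sim$data)
#' @rdname fitWLS
#' @export
setMethod("fitWLS", "ContrastScatteringSet",
  function(data, wantCov = FALSE, ...) {
    validObject(data)
    d <- contrastDeltas(data)
    .checkDuplicateContrasts(d)
    A <- buildDesignMatrix(d)
    res <- wlsSolve(A, intensities(data), sigmas(data), wantCov = wantCov)
    pairs <- pairIndexOrder(ncol(d) + 1L)
    .newPartialEstimate(
      qValues(data), res$mean, res$stderr, pairs,
      .pairLabels(pairs, componentNames(data)),
      method = "wls", cov = res$cov
    )
  })

#' @param A N x L design matrix.
#' @param intensities,sigmas N x M matrices.
#' @rdname fitWLS
#' @export
wlsSolve <- function(A, intensities, sigmas, wantCov = FALSE) {
  A <- as.matrix(A)
  intensities <- as.matrix(intensities)
  sigmas <- as.matrix(sigmas)
  n <- nrow(A); l <- ncol(A); m <- ncol(intensities)
  if (n < l)
    stop(sprintf(
      "underdetermined system: %d samples for %d partial functions", n, l
    ))
  if (qr(A)$rank < l)
    stop(
      "the contrast design matrix is rank deficient (this is a property ",
      "of the contrasts alone, independent of Q); add samples with ",
      "different contrasts"
    )
  if (any(sigmas <= 0)) stop("all sigmas must be strictly positive")
  meanMat <- matrix(NA_real_, l, m)
  stderrMat <- matrix(NA_real_, l, m)
  cov <- if (wantCov) matrix(0, l * m, l * m) else NULL
  for (k in seq_len(m)) {
    w <- 1 / sigmas[, k]^2
    AtWA <- crossprod(A, A * w)
    Vk <- chol2inv(chol(AtWA))
    meanMat[, k] <- Vk %*% crossprod(A, w * intensities[, k])
    stderrMat[, k] <- sqrt(diag(Vk))
    if (wantCov) {
      idx <- (seq_len(l) - 1L) * m + k   # l-major / Q-minor positions
      cov[idx, idx] <- Vk
    }
  }
  list(mean = meanMat, stderr = stderrMat, cov = cov)
}
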