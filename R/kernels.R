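#' Create a kernel specification
#'
#' @param family kernel family: `"gaussian"`, `"matern32"` or `"matern52"`.
#'   The Gaussian kernel assumes infinitely differentiable (very smooth)
#'   functions; the Matern kernels with nu = 3/2 and 5/2 assume once and
#'   twice differentiable functions respectively.
#' @param alpha amplitude: the prior variance of S_l(Q) at each point.
#'   Larger `alpha` weakens the smoothing effect of the prior; in the limit
#'   the estimate approaches weighted least squares.
#' @param lengthScale length scale l on the Q axis (1/Angstrom). Larger `l`
#'   makes the estimated functions flatter.
#' @param tau white-kernel scale; `tau^2` is added on the kernel diagonal.
#'   A small positive value (default `1e-5`) stabilises the Gaussian kernel
#'   in particular.
#' @param logQ measure distances on log(Q) instead of Q (off by default).
#' @return a [KernelSpec-class].
#' @examples
#' KernelSpec("matern52", alpha = 10, lengthScale = 0.1)
#' @export
KernelSpec <- function(family = c("matern52", "matern32", "gaussian"),
                       alpha = 1, lengthScale = 0.1, tau = 1e-5,
                       logQ = FALSE) {
  family <- match.arg(family, .KERNEL_FAMILIES)
  new("KernelSpec",
    family = family, alpha = as.numeric(alpha),
    lengthScale = as.numeric(lengthScale), tau = as.numeric(tau),
    logQ = isTRUE(logQ)
  )
}

setMethod("show", "KernelSpec", function(object) {
  cat(sprintf(
    "KernelSpec: %s (alpha = %g, l = %g, tau = %g%s)\n",
    object@family, object@alpha, object@lengthScale, object@tau,
    if (object@logQ) ", log-Q axis" else ""
  ))
})

.stationaryFactor <- function(family, r, l) {
  u <- r / l
  switch(family,
    gaussian = exp(-u^2 / 2),
    matern32 = {
      s <- sqrt(3) * u
      (1 + s) * exp(-s)
    },
    matern52 = {
      s <- sqrt(5) * u
      (1 + s + s^2 / 3) * exp(-s)
    },
    stop("unknown kernel family: ", family)
  )
}

#' Evaluate a kernel function
#'
#' Computes k(P, Q) for the stationary families with r = |P - Q|:
#' Gaussian `alpha * exp(-r^2 / (2 l^2))`; Matern 3/2
#' `alpha * (1 + sqrt(3) r / l) * exp(-sqrt(3) r / l)`; Matern 5/2
#' `alpha * (1 + sqrt(5) r / l + 5 r^2 / (3 l^2)) * exp(-sqrt(5) r / l)`.
#' The white-kernel term `tau^2 * [P == Q]` is added on top.
#'
#' @param spec a [KernelSpec-class].
#' @param P,Q numeric vectors of Q values (recycled to a common length).
#' @return numeric vector of covariances.
#' @examples
#' sp <- KernelSpec("gaussian", alpha = 1, lengthScale = 0.1, tau = 0)
#' kernelValue(sp, 0.1, 0.2) # exp(-1/2)
#' @export
kernelValue <- function(spec, P, Q) {
  stopifnot(is(spec, "KernelSpec"))
  validObject(spec)
  if (any(P < 0) || any(Q < 0)) stop("Q values must be non-negative")
  same <- abs(P - Q) == 0
  if (spec@logQ) {
    P <- log(P); Q <- log(Q)
  }
  r <- abs(P - Q)
  spec@alpha * .stationaryFactor(spec@family, r, spec@lengthScale) +
    spec@tau^2 * as.numeric(same)
}

#' Build the prior covariance over the Q grid
#'
#' Evaluates the kernel on all pairs of grid points: D\[m, m'\] =
#' k(Q_m, Q_m'). The result is symmetric with diagonal `alpha + tau^2`, and
#' positive semidefinite up to numerical tolerance (eigenvalues above
#' `-1e-10 * alpha` are accepted downstream; Cholesky factorisations add an
#' escalating diagonal jitter when needed, see [fitGPR()]).
#'
#' @param spec a [KernelSpec-class].
#' @param q numeric vector of Q grid values.
#' @return M x M symmetric covariance matrix.
#' @examples
#' kernelMatrix(KernelSpec("matern32", tau = 0), c(0.01, 0.02, 0.04))
#' @export
kernelMatrix <- function(spec, q) {
  stopifnot(is(spec, "KernelSpec"))
  validObject(spec)
  q <- as.numeric(q)
  if (any(!is.finite(q)) || any(q < 0)) stop("Q values must be non-negative")
  x <- if (spec@logQ) log(q) else q
  r <- abs(outer(x, x, "-"))
  D <- spec@alpha * .stationaryFactor(spec@family, r, spec@lengthScale)
  D <- (D + t(D)) / 2
  diag(D) <- spec@alpha + spec@tau^2
  D
}

# Cholesky with escalating diagonal jitter: relative 1e-12 escalated x10 up
# to 1e-6 of `scale`; each escalation is logged with message(). Failure past
# 1e-6 raises a conditioning error naming the kernel.
.cholJitter <- function(C, scale = mean(diag(C)), context = "covariance") {
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (!is.null(R)) return(R)
  jitter <- 1e-12
  while (jitter <= 1e-6) {
    message(sprintf(
      "Cholesky of %s failed; adding jitter %g * %g to the diagonal",
      context, jitter, scale
    ))
    R <- tryCatch(chol(C + diag(jitter * scale, nrow(C))),
                  error = function(e) NULL)
    if (!is.null(R)) return(R)
    jitter <- jitter * 10
  }
  stop(sprintf(
    "covariance factorization failed for %s even with jitter up to 1e-6; ",
    context
  ), "the kernel is too ill-conditioned for this grid", call. = FALSE)
}
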