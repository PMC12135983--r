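#' Core-shell sphere simulation settings
#'
#' Builds the settings for the validation study: a monodisperse core-shell
#' sphere (core radius 50 A, shell thickness 10 A; core and shell SLDs 4.0
#' and 1.0 x 1e-6/A^2) dispersed in D2O/H2O mixtures at eight D2O fractions
#' covering the full contrast series, including the core match point
#' (phi_D = 0.66) and the shell match point (phi_D = 0.22). The Q grid
#' defaults to 100 log-spaced points over \[0.004, 0.4\] 1/A, so roughly half
#' the points fall below the 0.05 1/A low-Q cut used by [subsetLowQ()].
#'
#' @param rCore,tShell core radius and shell thickness, Angstrom.
#' @param rhoCore,rhoShell,rhoD2O,rhoH2O SLDs in 1e-6/Angstrom^2. The water
#'   endpoints 6.36 and -0.56 are the standard D2O/H2O values and place the
#'   match points at the printed solvent compositions.
#' @param phiD D2O volume fractions, one sample per value.
#' @param scale overall intensity prefactor; the default `NA` uses
#'   1/V_outer^2 so forward intensities are O(1-10) (arbitrary units; the
#'   absolute scale is irrelevant to estimator behaviour because the noise
#'   is multiplicative).
#' @param noiseSigma relative noise level: scalar (default 0.05) or an
#'   N x M matrix for per-point control.
#' @param qValues explicit Q grid; overrides `nQ`/`qMin`/`qMax`.
#' @param nQ,qMin,qMax log-spaced default grid settings.
#' @param seed default RNG seed for [generateCoreShell()] (`NA`: none).
#' @return a [CoreShellParams-class].
#' @examples
#' CoreShellParams()
#' @export
CoreShellParams <- function(rCore = 50, tShell = 10,
                            rhoCore = 4.0, rhoShell = 1.0,
                            rhoD2O = 6.36, rhoH2O = -0.56,
                            phiD = c(1.0, 0.90, 0.80, 0.66, 0.40, 0.22,
                                     0.10, 0.0),
                            scale = NA_real_, noiseSigma = 0.05,
                            qValues = NULL, nQ = 100, qMin = 0.004,
                            qMax = 0.4, seed = NA_real_) {
  if (is.null(qValues))
    qValues <- exp(seq(log(qMin), log(qMax), length.out = nQ))
  new("CoreShellParams",
    rCore = rCore, tShell = tShell, rhoCore = rhoCore,
    rhoShell = rhoShell, rhoD2O = rhoD2O, rhoH2O = rhoH2O,
    phiD = phiD, scale = scale, noiseSigma = noiseSigma,
    qValues = as.numeric(qValues), seed = as.numeric(seed)
  )
}

setMethod("show", "CoreShellParams", function(object) {
  cat(sprintf(
    "CoreShellParams: R_core = %g A, t_shell = %g A, SLD core/shell = %g/%g\n",
    object@rCore, object@tShell, object@rhoCore, object@rhoShell
  ))
  cat(sprintf(
    "%d contrasts (phi_D = %s), %d Q points in [%g, %g] 1/A\n",
    length(object@phiD), paste(object@phiD, collapse = ", "),
    length(object@qValues), min(object@qValues), max(object@qValues)
  ))
})

.effectiveScale <- function(params) {
  if (!is.na(params@scale)) return(params@scale)
  vOuter <- 4 / 3 * pi * (params@rCore + params@tShell)^3
  1 / vOuter^2
}

#' Sphere scattering amplitude factor
#'
#' The normalised amplitude of a homogeneous sphere,
#' `f(x) = 3 (sin x - x cos x) / x^3`, with the removable singularity
#' `f(0) = 1` handled by the series `1 - x^2/10 + x^4/280` for `x < 1e-3`.
#'
#' @param x dimensionless argument Q * R, non-negative.
#' @return numeric vector of amplitude factors in (-0.22, 1\].
#' @examples
#' sphereForm(c(0, pi)) # 1, 3/pi^2
#' @export
sphereForm <- function(x) {
  if (any(x < 0)) stop("'x' must be non-negative")
  out <- numeric(length(x))
  small <- x < 1e-3
  out[small] <- 1 - x[small]^2 / 10 + x[small]^4 / 280
  xb <- x[!small]
  out[!small] <- 3 * (sin(xb) - xb * cos(xb)) / xb^3
  out
}

#' Solvent scattering length density of a D2O/H2O mixture
#'
#' Linear mixing in the D2O volume fraction:
#' `phi_D * rho_D2O + (1 - phi_D) * rho_H2O`.
#'
#' @param phiD D2O fraction(s) in \[0, 1\].
#' @param params a [CoreShellParams-class] supplying the endpoint SLDs.
#' @return solvent SLD(s) in 1e-6/Angstrom^2.
#' @examples
#' solventSLD(0.66) # ~4.0: the core match point
#' solventSLD(0.22) # ~1.0: the shell match point
#' @export
solventSLD <- function(phiD, params = CoreShellParams()) {
  if (any(!is.finite(phiD)) || any(phiD < 0) || any(phiD > 1))
    stop("'phiD' must lie in [0, 1]")
  phiD * params@rhoD2O + (1 - phiD) * params@rhoH2O
}

#' Ground-truth partial scattering functions of the core-shell sphere
#'
#' With core amplitude `A_C(Q) = V_c f(Q R_core)`, outer-sphere amplitude
#' `A_O(Q) = V_o f(Q (R_core + t_shell))` and shell amplitude
#' `A_S = A_O - A_C` (V = 4 pi r^3 / 3), the three partial scattering
#' functions are `S_CC = scale * A_C^2`, `S_CS = scale * A_C A_S` and
#' `S_SS = scale * A_S^2`, so that for any contrast pair the intensity
#' `I0 = dRho_C^2 S_CC + 2 dRho_C dRho_S S_CS + dRho_S^2 S_SS` reproduces
#' the two-shell sphere model. Because a single particle's amplitudes are
#' proportional, `S_CS^2 = S_CC * S_SS` exactly at every Q.
#'
#' @param params a [CoreShellParams-class].
#' @return 3 x M matrix with rows `S_core.core`, `S_core.shell`,
#'   `S_shell.shell` (canonical pair order for p = 3).
#' @examples
#' S <- truePartials(CoreShellParams(nQ = 10))
#' all.equal(S[2, ]^2, S[1, ] * S[3, ])
#' @export
truePartials <- function(params = CoreShellParams()) {
  validObject(params)
  q <- params@qValues
  sc <- .effectiveScale(params)
  vC <- 4 / 3 * pi * params@rCore^3
  rO <- params@rCore + params@tShell
  vO <- 4 / 3 * pi * rO^3
  aC <- vC * sphereForm(q * params@rCore)
  aS <- vO * sphereForm(q * rO) - aC
  S <- rbind(sc * aC^2, sc * aC * aS, sc * aS^2)
  rownames(S) <- c("S_core.core", "S_core.shell", "S_shell.shell")
  S
}

# evaluate expr with a temporary RNG state seeded at `seed`
.withSeed <- function(seed, expr) {
  if (is.na(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Generate a noisy core-shell contrast series
#'
#' Simulates the validation data set: one sample per D2O fraction, with
#' contrasts `dRho_core = rho_core - rho_solvent` and `dRho_shell =
#' rho_shell - rho_solvent`, noise-free intensities assembled from
#' [truePartials()] through the contrast design matrix, and multiplicative
#' Gaussian noise `I = I0 * (1 + eta)`, `eta ~ N(0, sigma_{n,m}^2)`. The
#' reported uncertainty is the generator's true standard deviation of I,
#' `sigma_{n,m} * |I0|`. Sample names follow the D2O percentage (CS100,
#' CS090, ...). Output is bit-identical for a fixed seed; the caller's RNG
#' state is left untouched.
#'
#' @param params a [CoreShellParams-class].
#' @param seed RNG seed; defaults to the seed stored in `params`.
#' @return list with `data` (a [ContrastScatteringSet-class]), `truth`
#'   (3 x M matrix of ground-truth partial scattering functions),
#'   `noiseFree` (N x M matrix of noise-free intensities) and `params`.
#' @examples
#' sim <- generateCoreShell(CoreShellParams(nQ = 20), seed = 7)
#' sim$data
#' @export
generateCoreShell <- function(params = CoreShellParams(),
                              seed = params@seed) {
  validObject(params)
  q <- params@qValues
  n <- length(params@phiD); m <- length(q)
  rhoSolv <- solventSLD(params@phiD, params)
  deltas <- cbind(
    core = params@rhoCore - rhoSolv,
    shell = params@rhoShell - rhoSolv
  )
  rownames(deltas) <- sprintf("CS%03d", round(params@phiD * 100))
  S <- truePartials(params)
  A <- buildDesignMatrix(deltas)
  I0 <- A %*% S
  sg <- params@noiseSigma
  if (!is.matrix(sg)) sg <- matrix(sg, n, m)
  eta <- .withSeed(seed, matrix(rnorm(n * m), n, m)) * sg
  ContrastScatteringSet(
    q, intensities = I0 * (1 + eta), sigmas = sg * abs(I0),
    deltaRho = deltas
  ) -> cse
  list(data = cse, truth = S, noiseFree = I0, params = params)
}

#' Restrict a data set to the low-Q range
#'
#' Keeps only grid points with `Q < qMax` (strict inequality). With the
#' default cut at 0.05 1/A this selects the low-Q subset of the core-shell
#' study, which excludes the oscillatory high-Q region where single grid
#' points carry extreme relative errors; the full data set is simply the
#' unfiltered object.
#'
#' @param data a [ContrastScatteringSet-class].
#' @param qMax strict upper bound on Q, 1/Angstrom.
#' @return the row-subsetted [ContrastScatteringSet-class].
#' @examples
#' sim <- generateCoreShell(CoreShellParams(nQ = 20), seed = 1)
#' subsetLowQ(sim$data)
#' @export
subsetLowQ <- function(data, qMax = 0.05) {
  stopifnot(is(data, "ContrastScatteringSet"))
  keep <- qValues(data) < qMax
  if (!any(keep))
    stop(sprintf("no grid points below Q = %g 1/A", qMax))
  data[keep, ]
}

#' Mean squared error against ground truth
#'
#' `(1 / (L M)) * sum_{l,m} (S_hat_l(Q_m) - S_true_l(Q_m))^2`.
#'
#' @param est a [PartialEstimate-class], or an L x M matrix of estimates.
#' @param truth L x M matrix of true partial scattering functions on the
#'   same grid (subset it to match `est` if the fit used [subsetLowQ()]).
#' @return single numeric MSE.
#' @examples
#' mseEstimate(matrix(1, 2, 3), matrix(0, 2, 3)) # 1
#' @export
mseEstimate <- function(est, truth) {
  m <- if (is(est, "PartialEstimate")) estimateMeans(est) else as.matrix(est)
  truth <- as.matrix(truth)
  if (!identical(dim(m), dim(truth)))
    stop(sprintf(
      "estimate is %d x %d but truth is %d x %d",
      nrow(m), ncol(m), nrow(truth), ncol(truth)
    ))
  mean((m - truth)^2)
}

#' Effect of mis-stated observation errors
#'
#' Refits the same noisy realisation with the reported uncertainties
#' multiplied by `factor` (the data themselves unchanged), emulating under-
#' (`factor < 1`) or over-estimated (`factor > 1`) error bars. For each
#' factor and partial function it reports the total variation of the
#' estimate `sum_m |S(Q_{m+1}) - S(Q_m)|` (waviness) and the mean posterior
#' standard error. Understated errors make the data look more reliable than
#' they are, producing wavy estimates; overstated errors inflate the error
#' bars.
#'
#' @param params a [CoreShellParams-class].
#' @param factors multipliers applied to the reported sigmas.
#' @param spec a [KernelSpec-class]; `NULL` selects Matern 5/2 parameters
#'   by log marginal likelihood on the correctly specified data.
#' @param seed RNG seed for the single noisy realisation.
#' @param qMax low-Q restriction applied before fitting (`Inf`: none).
#' @return data.frame with columns `factor`, `pair`, `totalVariation`,
#'   `meanStderr`.
#' @export
errorMisspecStudy <- function(params = CoreShellParams(),
                              factors = c(0.5, 1, 2), spec = NULL,
                              seed = params@seed, qMax = 0.05) {
  sim <- generateCoreShell(params, seed = seed)
  data <- if (is.finite(qMax)) subsetLowQ(sim$data, qMax) else sim$data
  if (is.null(spec))
    spec <- bestSpec(gridSearch(data, families = "matern52"))
  out <- lapply(factors, function(f) {
    scaled <- data
    SummarizedExperiment::assay(scaled, "sigma") <-
      SummarizedExperiment::assay(data, "sigma") * f
    est <- fitGPR(scaled, spec)
    mu <- estimateMeans(est)
    data.frame(
      factor = f, pair = pairLabels(est),
      totalVariation = rowSums(abs(mu[, -1, drop = FALSE] -
                                   mu[, -ncol(mu), drop = FALSE])),
      meanStderr = rowMeans(errorBars(est)),
      row.names = NULL
    )
  })
  do.call(rbind, out)
}
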