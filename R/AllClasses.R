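#' @import methods
#' @importFrom stats dlnorm dnorm median rnorm setNames
#' @importFrom utils packageVersion read.table write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assayNames rowData colData
#' @importFrom S4Vectors metadata DataFrame
NULL

.KERNEL_FAMILIES <- c("gaussian", "matern32", "matern52")
.HYPER_FAMILIES <- c("gaussian", "lognormal", "uniform")

#' Kernel specification for the smoothness prior
#'
#' A `KernelSpec` bundles the stationary kernel family and its parameters:
#' the amplitude `alpha` (the prior variance scale of each partial scattering
#' function; larger `alpha` means a weaker smoothing effect), the length
#' scale `l` on the Q axis (in the same reciprocal-Angstrom units as Q;
#' larger `l` means flatter estimates), and the white-kernel weight `tau`
#' whose square is added on the diagonal as a stabilising nugget.
#'
#' @slot family one of `"gaussian"`, `"matern32"`, `"matern52"`.
#' @slot alpha positive prior-variance scale.
#' @slot lengthScale positive length scale on the Q axis (1/Angstrom).
#' @slot tau non-negative white-kernel scale.
#' @slot logQ logical; if `TRUE`, distances are measured on log(Q) rather
#'   than Q. Off by default.
#'
#' @seealso [KernelSpec()], [kernelValue()], [kernelMatrix()]
#' @exportClass KernelSpec
setClass("KernelSpec",
  representation(
    family = "character",
    alpha = "numeric",
    lengthScale = "numeric",
    tau = "numeric",
    logQ = "logical"
  ),
  prototype(
    family = "matern52", alpha = 1, lengthScale = 0.1, tau = 1e-5,
    logQ = FALSE
  )
)

setValidity("KernelSpec", function(object) {
  msg <- character()
  if (length(object@family) != 1L || !object@family %in% .KERNEL_FAMILIES)
    msg <- c(msg, sprintf(
      "'family' must be one of %s",
      paste(sQuote(.KERNEL_FAMILIES), collapse = ", ")
    ))
  for (s in c("alpha", "lengthScale")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single finite positive number", s))
  }
  if (length(object@tau) != 1L || !is.finite(object@tau) || object@tau < 0)
    msg <- c(msg, "'tau' must be a single finite non-negative number")
  if (length(object@logQ) != 1L || is.na(object@logQ))
    msg <- c(msg, "'logQ' must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Multi-contrast scattering data on a shared Q grid
#'
#' `ContrastScatteringSet` extends
#' [SummarizedExperiment::SummarizedExperiment] to hold a CV-SANS contrast
#' series: rows are the M points of the shared Q grid, columns are the N
#' samples measured at different solvent contrasts. Two assays are required,
#' `intensity` (absolute intensities I_n(Q_m)) and `sigma` (their one-sigma
#' uncertainties, strictly positive). `rowData()$Q` carries the Q grid
#' (strictly increasing, positive, in 1/Angstrom) and `colData()$deltaRho`
#' is the N x (p-1) matrix of contrasts Delta-rho (solute SLD minus solvent
#' SLD, in 1e-6/Angstrom^2), one column per solute component.
#'
#' @seealso [ContrastScatteringSet()] for the constructor, [fitGPR()],
#'   [fitWLS()], [generateCoreShell()]
#' @exportClass ContrastScatteringSet
setClass("ContrastScatteringSet",
  contains = "SummarizedExperiment"
)

setValidity("ContrastScatteringSet", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("intensity", "sigma") %in% an))
    return("assays 'intensity' and 'sigma' are required")
  q <- SummarizedExperiment::rowData(object)$Q
  if (is.null(q)) return("rowData()$Q (the Q grid) is required")
  if (length(q) < 2L)
    msg <- c(msg, "the Q grid must contain at least two points")
  if (any(!is.finite(q)) || any(q <= 0))
    msg <- c(msg, "Q values must be finite and positive")
  if (is.unsorted(q, strictly = TRUE))
    msg <- c(msg, "Q values must be strictly increasing")
  dr <- SummarizedExperiment::colData(object)$deltaRho
  if (is.null(dr)) return("colData()$deltaRho (the contrast matrix) is required")
  dr <- as.matrix(dr)
  if (nrow(dr) != ncol(object) || ncol(dr) < 1L)
    msg <- c(msg, "deltaRho must have one row per sample and >= 1 component")
  if (any(!is.finite(dr)))
    msg <- c(msg, "contrast values must be finite")
  sg <- SummarizedExperiment::assay(object, "sigma")
  if (any(!is.finite(sg)) || any(sg <= 0))
    msg <- c(msg, "all sigma values must be finite and strictly positive")
  if (any(!is.finite(SummarizedExperiment::assay(object, "intensity"))))
    msg <- c(msg, "all intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' Posterior (or WLS) estimate of the partial scattering functions
#'
#' `PartialEstimate` extends
#' [SummarizedExperiment::SummarizedExperiment]: rows are the M Q-grid
#' points, columns are the L = p(p-1)/2 partial scattering functions in
#' canonical pair order (1,1), (1,2), ..., (p-1,p-1). Assays `mean` and
#' `stderr` hold the point estimates S_l(Q_m) and their one-sigma error
#' bars. `metadata()` records the estimation method (`"gpr"` or `"wls"`),
#' the [KernelSpec] used (GPR only), the log marginal likelihood, the full
#' posterior covariance when requested (an LM x LM matrix in l-major,
#' Q-minor order), and negativity / Cauchy-Schwarz diagnostics.
#'
#' @seealso [fitGPR()], [fitWLS()], [estimateMeans()], [errorBars()]
#' @exportClass PartialEstimate
setClass("PartialEstimate",
  contains = "SummarizedExperiment"
)

setValidity("PartialEstimate", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("mean", "stderr") %in% an))
    return("assays 'mean' and 'stderr' are required")
  if (is.null(SummarizedExperiment::rowData(object)$Q))
    return("rowData()$Q is required")
  se <- SummarizedExperiment::assay(object, "stderr")
  if (any(!is.finite(se)) || any(se < 0))
    msg <- c(msg, "stderr must be finite and non-negative")
  md <- S4Vectors::metadata(object)
  if (is.null(md$method) || !md$method %in% c("gpr", "wls"))
    msg <- c(msg, "metadata()$method must be 'gpr' or 'wls'")
  if (length(msg)) msg else TRUE
})

#' Flattened linear system for the reordered estimation problem
#'
#' Holds the design matrix B = A (x) E_M of the vectorised problem
#' I-tilde = B S-tilde + noise, with the observation vector, the diagonal of
#' the noise covariance, and both index maps. Latent entries are ordered
#' l-major / Q-minor (S_1(Q_1) ... S_1(Q_M), S_2(Q_1), ...); observations are
#' n-major / Q-minor.
#'
#' @slot design the (NM) x (LM) matrix B.
#' @slot observations numeric NM vector of stacked intensities.
#' @slot noiseVar numeric NM vector of per-observation variances sigma^2.
#' @slot rowIndex data.frame with columns `n`, `m` mapping rows of B.
#' @slot colIndex data.frame with columns `l`, `m` mapping columns of B.
#'
#' @seealso [flattenSystem()]
#' @exportClass FlatSystem
setClass("FlatSystem",
  representation(
    design = "matrix",
    observations = "numeric",
    noiseVar = "numeric",
    rowIndex = "data.frame",
    colIndex = "data.frame"
  )
)

setValidity("FlatSystem", function(object) {
  msg <- character()
  if (nrow(object@design) != length(object@observations))
    msg <- c(msg, "design rows must match observations length")
  if (length(object@noiseVar) != length(object@observations))
    msg <- c(msg, "noiseVar length must match observations length")
  if (any(object@noiseVar <= 0)) msg <- c(msg, "noiseVar must be positive")
  if (nrow(object@rowIndex) != nrow(object@design) ||
      nrow(object@colIndex) != ncol(object@design))
    msg <- c(msg, "index maps must match the design dimensions")
  if (length(msg)) msg else TRUE
})

#' Core-shell sphere simulation settings
#'
#' Ground-truth settings of the core-shell validation study: a spherical
#' core of radius `rCore` wrapped in a shell of thickness `tShell`,
#' dispersed in D2O/H2O mixtures whose scattering length density follows
#' linear mixing in the D2O fraction. Noise is multiplicative Gaussian with
#' relative standard deviation `noiseSigma`.
#'
#' @slot rCore core radius, Angstrom.
#' @slot tShell shell thickness, Angstrom.
#' @slot rhoCore,rhoShell core/shell scattering length densities,
#'   1e-6/Angstrom^2.
#' @slot rhoD2O,rhoH2O solvent endpoint SLDs, 1e-6/Angstrom^2.
#' @slot phiD D2O volume fractions of the contrast series (one sample each).
#' @slot scale overall intensity prefactor; `NA` means 1/V_outer^2 so that
#'   forward intensities are O(1-10) in arbitrary units.
#' @slot noiseSigma relative noise level (scalar, or an N x M matrix for
#'   per-point control).
#' @slot qValues the shared Q grid, 1/Angstrom.
#' @slot seed integer RNG seed used by [generateCoreShell()] when no seed is
#'   passed explicitly (`NA` leaves the RNG stream alone).
#'
#' @seealso [CoreShellParams()], [generateCoreShell()], [truePartials()]
#' @exportClass CoreShellParams
setClass("CoreShellParams",
  representation(
    rCore = "numeric", tShell = "numeric",
    rhoCore = "numeric", rhoShell = "numeric",
    rhoD2O = "numeric", rhoH2O = "numeric",
    phiD = "numeric", scale = "numeric",
    noiseSigma = "ANY", qValues = "numeric", seed = "numeric"
  )
)

setValidity("CoreShellParams", function(object) {
  msg <- character()
  if (object@rCore <= 0 || object@tShell <= 0)
    msg <- c(msg, "rCore and tShell must be positive")
  if (any(object@phiD < 0) || any(object@phiD > 1))
    msg <- c(msg, "phiD fractions must lie in [0, 1]")
  ns <- object@noiseSigma
  if (!(is.numeric(ns) || is.matrix(ns)) || any(ns <= 0))
    msg <- c(msg, "noiseSigma must be positive")
  if (is.matrix(ns) &&
      !identical(dim(ns), c(length(object@phiD), length(object@qValues))))
    msg <- c(msg, "matrix noiseSigma must be N x M")
  q <- object@qValues
  if (length(q) < 2L || any(q <= 0) || is.unsorted(q, strictly = TRUE))
    msg <- c(msg, "qValues must be >= 2 strictly increasing positive values")
  if (!is.na(object@scale) && object@scale <= 0)
    msg <- c(msg, "scale must be positive")
  if (length(msg)) msg else TRUE
})

#' Hyper-prior over kernel parameters
#'
#' Independent hyper-prior distributions for the kernel amplitude `alpha`
#' and length scale `l`, used by [mapObjective()] for MAP selection. Each
#' parameter gets a family (`"gaussian"`, `"lognormal"` or `"uniform"`), a
#' location and a scale. For the Gaussian family the location/scale are the
#' mean and standard deviation; for the log-normal they are the median and
#' the log-scale standard deviation; for the uniform they are the lower and
#' upper bounds.
#'
#' @slot alphaFamily,lFamily hyper-prior family per parameter.
#' @slot alphaLocation,lLocation centre (or lower bound for uniform).
#' @slot alphaScale,lScale scale (or upper bound for uniform), positive.
#'
#' @seealso [HyperPrior()], [mapObjective()]
#' @exportClass HyperPrior
setClass("HyperPrior",
  representation(
    alphaFamily = "character", alphaLocation = "numeric",
    alphaScale = "numeric",
    lFamily = "character", lLocation = "numeric", lScale = "numeric"
  ),
  prototype(
    alphaFamily = "lognormal", alphaLocation = 1, alphaScale = 2,
    lFamily = "lognormal", lLocation = 0.1, lScale = 2
  )
)

setValidity("HyperPrior", function(object) {
  msg <- character()
  for (p in c("alpha", "l")) {
    fam <- slot(object, paste0(p, "Family"))
    loc <- slot(object, paste0(p, "Location"))
    sc <- slot(object, paste0(p, "Scale"))
    if (!fam %in% .HYPER_FAMILIES)
      msg <- c(msg, sprintf("unknown hyper-prior family '%s'", fam))
    if (fam == "uniform") {
      if (!is.finite(loc) || !is.finite(sc) || loc >= sc)
        msg <- c(msg, sprintf("uniform bounds for %s must be ordered", p))
    } else {
      if (!is.finite(sc) || sc <= 0)
        msg <- c(msg, sprintf("hyper-prior scale for %s must be positive", p))
      if (fam == "lognormal" && (!is.finite(loc) || loc <= 0))
        msg <- c(msg, sprintf("lognormal location for %s must be positive", p))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Result of a kernel-parameter grid search
#'
#' @slot bestSpec the winning [KernelSpec].
#' @slot objectiveName `"lml"` or `"map"`.
#' @slot table data.frame with one row per evaluated specification
#'   (columns `family`, `alpha`, `l`, `tau`, `objective`), sorted
#'   deterministically by family, alpha, l.
#' @slot tiesBrokenBy note describing the tie rule applied.
#'
#' @seealso [gridSearch()]
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(
    bestSpec = "KernelSpec",
    objectiveName = "character",
    table = "data.frame",
    tiesBrokenBy = "character"
  )
)

setValidity("SelectionResult", function(object) {
  if (!object@objectiveName %in% c("lml", "map"))
    return("objectiveName must be 'lml' or 'map'")
  TRUE
})
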