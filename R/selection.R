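#' Log marginal likelihood of the intensities under a kernel
#'
#' The evidence of the linear-Gaussian model with the latent partial
#' scattering functions integrated out:
#' `log N(I-tilde; 0, B Ktilde B^T + Sigma-tilde)`, i.e.
#' `-1/2 y^T C^{-1} y - 1/2 log det C - (NM/2) log(2 pi)` with
#' `C = (A A^T) (x) D + diag(sigma^2)`. The log-determinant comes from the
#' same whitened Cholesky factorisation used by [gprPosterior()]
#' (`log det C = log det(I + W^T W) + sum log sigma^2`), never from a raw
#' determinant.
#'
#' @param data a [ContrastScatteringSet-class].
#' @param spec a [KernelSpec-class].
#' @param ... unused.
#' @return a single numeric value.
#' @examples
#' sim <- generateCoreShell(CoreShellParams(nQ = 20), seed = 1)
#' logMarginalLikelihood(sim$data, KernelSpec("matern52", alpha = 10))
#' @rdname logMarginalLikelihood
#' @export
setMethod("logMarginalLikelihood",
  signature(data = "ContrastScatteringSet", spec = "KernelSpec"),
  function(data, spec, ...) {
    validObject(data)
    A <- buildDesignMatrix(contrastDeltas(data))
    D <- kernelMatrix(spec, qValues(data))
    gprEvidence(A, intensities(data), sigmas(data), D,
                context = spec@family)
  })

#' @param A,intensities,sigmas,D,context plain-matrix interface as in
#'   [gprPosterior()].
#' @rdname logMarginalLikelihood
#' @export
gprEvidence <- function(A, intensities, sigmas, D, context = "kernel") {
  sys <- .gprFactor(A, intensities, sigmas, D, context = context)
  .gprLogEvidence(sys)
}

#' Create a hyper-prior over kernel parameters
#'
#' @param alpha,l lists `list(family, location, scale)` describing the
#'   hyper-prior for the amplitude and the length scale. Families:
#'   `"gaussian"` (location = mean, scale = sd), `"lognormal"` (location =
#'   median, scale = sdlog) and `"uniform"` (location = lower, scale =
#'   upper bound). The default is a weakly informative log-normal for both,
#'   which respects positivity.
#' @return a [HyperPrior-class].
#' @examples
#' HyperPrior(alpha = list("gaussian", 10, 100),
#'            l = list("lognormal", 0.1, 2))
#' @export
HyperPrior <- function(alpha = list("lognormal", 1, 2),
                       l = list("lognormal", 0.1, 2)) {
  pick <- function(x) {
    x <- as.list(x)
    names(x) <- c("family", "location", "scale")[seq_along(x)]
    x
  }
  a <- pick(alpha); b <- pick(l)
  new("HyperPrior",
    alphaFamily = match.arg(a$family, .HYPER_FAMILIES),
    alphaLocation = as.numeric(a$location),
    alphaScale = as.numeric(a$scale),
    lFamily = match.arg(b$family, .HYPER_FAMILIES),
    lLocation = as.numeric(b$location), lScale = as.numeric(b$scale)
  )
}

setMethod("show", "HyperPrior", function(object) {
  cat(sprintf(
    "HyperPrior: alpha ~ %s(%g, %g), l ~ %s(%g, %g)\n",
    object@alphaFamily, object@alphaLocation, object@alphaScale,
    object@lFamily, object@lLocation, object@lScale
  ))
})

# Log hyper-prior density at a single parameter value. The Gaussian family
# drops its normalizing constant (pure quadratic penalty, so the MAP
# objective reduces exactly to the LML as the scale grows); log-normal and
# uniform use their full log-densities. Only theta-independent additive
# terms differ between these conventions, so the argmax is unaffected.
.hyperLogDensity <- function(family, x, location, scale) {
  switch(family,
    gaussian = -(x - location)^2 / (2 * scale^2),
    lognormal = dlnorm(x, meanlog = log(location), sdlog = scale,
                       log = TRUE),
    uniform = ifelse(x >= location & x <= scale, 0, -Inf),
    stop("unknown hyper-prior family: ", family)
  )
}

#' MAP objective: evidence plus log hyper-prior
#'
#' The objective maximised by MAP selection of the kernel parameters:
#' `logMarginalLikelihood(data, spec) + log p(alpha) + log p(l)`. With a
#' Gaussian hyper-prior the penalty is
#' `-(alpha - alpha0)^2 / (2 beta1^2) - (l - l0)^2 / (2 beta2^2)`
#' (normalizing constants dropped), so as `beta1, beta2 -> Inf` the
#' objective converges to the log marginal likelihood and MAP selection
#' becomes empirical Bayes. Parameters outside a uniform hyper-prior's
#' support score `-Inf` (excluded, not an error).
#'
#' @param data a [ContrastScatteringSet-class].
#' @param spec a [KernelSpec-class].
#' @param hyper a [HyperPrior-class].
#' @return a single numeric value (possibly `-Inf`).
#' @export
mapObjective <- function(data, spec, hyper) {
  stopifnot(is(hyper, "HyperPrior"))
  validObject(hyper)
  pen <- .hyperLogDensity(hyper@alphaFamily, spec@alpha,
                          hyper@alphaLocation, hyper@alphaScale) +
    .hyperLogDensity(hyper@lFamily, spec@lengthScale,
                     hyper@lLocation, hyper@lScale)
  if (!is.finite(pen) && pen == -Inf) return(-Inf)
  logMarginalLikelihood(data, spec) + pen
}

.defaultGrid <- function() 10^seq(-3, 2, length.out = 6)

.selectBest <- function(tab, tol = 1e-6) {
  best <- max(tab$objective[is.finite(tab$objective)])
  cand <- tab[is.finite(tab$objective) & tab$objective >= best - tol, ,
              drop = FALSE]
  # ties within tol: prefer the smaller length scale, then smaller alpha,
  # then the first listed family
  cand <- cand[order(cand$l, cand$alpha, match(cand$family,
                                               unique(tab$family))), ,
               drop = FALSE]
  cand[1L, , drop = FALSE]
}

#' Kernel-parameter selection by grid search
#'
#' Evaluates the selection objective (log marginal likelihood, or the MAP
#' objective under a hyper-prior) at every combination of kernel family,
#' amplitude and length scale, and returns the full objective table plus
#' the argmax. Ties within `1e-6` are broken towards the smaller length
#' scale (a slightly less flat prior is the safer choice), then the smaller
#' amplitude. With `refine = TRUE` a single finer pass doubles the grid
#' density around the winner (geometric midpoints towards its grid
#' neighbours) and re-selects.
#'
#' Per-family winners are reported side by side in the table; the objective
#' is not used to pick a family automatically (evidence differences between
#' kernel families are typically too small to be meaningful), but the
#' overall argmax across the requested families is returned as `bestSpec`.
#'
#' @param data a [ContrastScatteringSet-class].
#' @param families character vector of kernel families to scan.
#' @param alphaGrid,lGrid numeric grids for amplitude and length scale
#'   (default: 6 log-spaced points each over 1e-3 ... 1e2).
#' @param tau fixed white-kernel scale(s); a vector scans each value.
#' @param objective `"lml"` or `"map"`.
#' @param hyper a [HyperPrior-class] (required for `objective = "map"`).
#' @param refine add one local refinement pass around the winner?
#' @param logQ passed to [KernelSpec()].
#' @return a [SelectionResult-class].
#' @examples
#' sim <- generateCoreShell(CoreShellParams(nQ = 15), seed = 1)
#' sel <- gridSearch(sim$data, families = "matern52",
#'                   alphaGrid = c(1, 10), lGrid = c(0.03, 0.1))
#' bestSpec(sel)
#' @rdname gridSearch
#' @export
gridSearch <- function(data, families = c("gaussian", "matern32", "matern52"),
                       alphaGrid = .defaultGrid(), lGrid = .defaultGrid(),
                       tau = 1e-5, objective = c("lml", "map"),
                       hyper = NULL, refine = FALSE, logQ = FALSE) {
  objective <- match.arg(objective)
  families <- match.arg(families, .KERNEL_FAMILIES, several.ok = TRUE)
  if (objective == "map" && is.null(hyper))
    stop("'hyper' is required for the MAP objective")
  if (!length(alphaGrid) || !length(lGrid)) stop("grids must be non-empty")
  evalOne <- function(family, a, l, t) {
    sp <- KernelSpec(family, alpha = a, lengthScale = l, tau = t,
                     logQ = logQ)
    tryCatch(
      if (objective == "lml") logMarginalLikelihood(data, sp)
      else mapObjective(data, sp, hyper),
      error = function(e) structure(NA_real_, msg = conditionMessage(e))
    )
  }
  evalTable <- function(av, lv) {
    g <- expand.grid(
      family = families, alpha = sort(unique(av)), l = sort(unique(lv)),
      tau = tau, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    g$objective <- mapply(evalOne, g$family, g$alpha, g$l, g$tau)
    g
  }
  tab <- evalTable(alphaGrid, lGrid)
  if (all(!is.finite(tab$objective)))
    stop("all grid evaluations failed or scored -Inf; nothing to select")
  if (refine) {
    w <- .selectBest(tab)
    mids <- function(grid, x) {
      grid <- sort(unique(grid))
      i <- which.min(abs(grid - x))
      out <- x
      if (i > 1L) out <- c(out, sqrt(grid[i - 1L] * grid[i]))
      if (i < length(grid)) out <- c(out, sqrt(grid[i] * grid[i + 1L]))
      out
    }
    extra <- evalTable(mids(alphaGrid, w$alpha), mids(lGrid, w$l))
    tab <- unique(rbind(tab, extra))
  }
  tab <- tab[order(match(tab$family, families), tab$alpha, tab$l, tab$tau), ]
  rownames(tab) <- NULL
  w <- .selectBest(tab)
  new("SelectionResult",
    bestSpec = KernelSpec(w$family, alpha = w$alpha, lengthScale = w$l,
                          tau = w$tau, logQ = logQ),
    objectiveName = objective, table = tab,
    tiesBrokenBy = "objective ties within 1e-6 broken by smaller l, then smaller alpha"
  )
}

#' @param x a [SelectionResult-class].
#' @rdname gridSearch
#' @export
setMethod("bestSpec", "SelectionResult", function(x) x@bestSpec)

#' @rdname gridSearch
#' @export
setMethod("objectiveTable", "SelectionResult", function(x) x@table)

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult (%s objective, %d evaluations)\n",
              object@objectiveName, nrow(object@table)))
  show(object@bestSpec)
  perFam <- lapply(split(object@table, object@table$family), .selectBest)
  for (f in names(perFam))
    cat(sprintf("  %s winner: alpha = %g, l = %g (objective %.4f)\n",
                f, perFam[[f]]$alpha, perFam[[f]]$l,
                perFam[[f]]$objective))
})
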