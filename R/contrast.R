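#' Construct a multi-contrast scattering data set
#'
#' Assembles intensities, uncertainties and contrasts measured at N solvent
#' contrasts on one shared Q grid into a [ContrastScatteringSet-class].
#'
#' @param q numeric vector of M Q values (1/Angstrom), strictly increasing
#'   and positive, M >= 2.
#' @param intensities N x M matrix of intensities I_n(Q_m) (rows = samples).
#' @param sigmas N x M matrix of one-sigma uncertainties, strictly positive.
#' @param deltaRho N x (p-1) matrix of contrasts Delta-rho_{n,i}
#'   (1e-6/Angstrom^2), one column per solute component.
#' @param sampleNames optional character vector of N sample labels.
#' @param componentNames optional character vector of p-1 solute labels.
#'
#' @return a [ContrastScatteringSet-class].
#' @examples
#' q <- c(0.01, 0.02, 0.05)
#' cs <- ContrastScatteringSet(
#'   q,
#'   intensities = rbind(c(1, 2, 3), c(4, 5, 6)),
#'   sigmas = matrix(0.1, 2, 3),
#'   deltaRho = cbind(c(1, 2))
#' )
#' qValues(cs)
#' @export
ContrastScatteringSet <- function(q, intensities, sigmas, deltaRho,
                                  sampleNames = NULL,
                                  componentNames = NULL) {
  intensities <- as.matrix(intensities)
  sigmas <- as.matrix(sigmas)
  deltaRho <- as.matrix(deltaRho)
  n <- nrow(intensities)
  if (!identical(dim(intensities), dim(sigmas)))
    stop("'intensities' and 'sigmas' must have identical dimensions")
  if (ncol(intensities) != length(q))
    stop("number of intensity columns must match length(q)")
  if (nrow(deltaRho) != n)
    stop("'deltaRho' must have one row per sample")
  if (is.null(sampleNames))
    sampleNames <- rownames(intensities)
  if (is.null(sampleNames))
    sampleNames <- sprintf("sample%02d", seq_len(n))
  if (is.null(componentNames))
    componentNames <- colnames(deltaRho)
  if (is.null(componentNames))
    componentNames <- sprintf("component%d", seq_len(ncol(deltaRho)))
  colnames(deltaRho) <- componentNames
  rownames(deltaRho) <- sampleNames
  cd <- S4Vectors::DataFrame(row.names = sampleNames)
  cd$deltaRho <- deltaRho
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = t(intensities), sigma = t(sigmas)),
    rowData = S4Vectors::DataFrame(Q = as.numeric(q)),
    colData = cd
  )
  colnames(se) <- sampleNames
  new("ContrastScatteringSet", se)
}

#' Accessors for `ContrastScatteringSet`
#'
#' `qValues()` returns the shared Q grid; `intensities()` and `sigmas()`
#' return N x M matrices (samples in rows, matching the flattening
#' conventions of [flattenSystem()]); `contrastDeltas()` the N x (p-1)
#' contrast matrix; `componentNames()` the solute labels.
#'
#' @param x a [ContrastScatteringSet-class].
#' @return see Description.
#' @name ContrastScatteringSet-accessors
NULL

#' @rdname ContrastScatteringSet-accessors
#' @export
setMethod("qValues", "ContrastScatteringSet", function(x)
  as.numeric(SummarizedExperiment::rowData(x)$Q))

#' @rdname ContrastScatteringSet-accessors
#' @export
setMethod("intensities", "ContrastScatteringSet", function(x)
  t(SummarizedExperiment::assay(x, "intensity")))

#' @rdname ContrastScatteringSet-accessors
#' @export
setMethod("sigmas", "ContrastScatteringSet", function(x)
  t(SummarizedExperiment::assay(x, "sigma")))

#' @rdname ContrastScatteringSet-accessors
#' @export
setMethod("contrastDeltas", "ContrastScatteringSet", function(x)
  as.matrix(SummarizedExperiment::colData(x)$deltaRho))

#' @rdname ContrastScatteringSet-accessors
#' @export
setMethod("componentNames", "ContrastScatteringSet", function(x)
  colnames(contrastDeltas(x)))

setMethod("show", "ContrastScatteringSet", function(object) {
  q <- qValues(object)
  cat(sprintf(
    "ContrastScatteringSet: %d samples x %d Q points [%g, %g] 1/A\n",
    ncol(object), nrow(object), min(q), max(q)
  ))
  cat(sprintf(
    "components (%d): %s\n", length(componentNames(object)),
    paste(componentNames(object), collapse = ", ")
  ))
  cat(sprintf("samples: %s\n", paste(colnames(object), collapse = ", ")))
})

#' Canonical ordering of component pairs
#'
#' For a p-component system (p-1 solutes plus solvent) the L = p(p-1)/2
#' partial scattering functions are indexed by unordered solute pairs
#' (i, j), i <= j. This returns the canonical lexicographic order
#' (1,1), (1,2), ..., (1,p-1), (2,2), ..., (p-1,p-1) used everywhere in the
#' package for the flattened latent vector and for output files.
#'
#' @param p total number of components (including the solvent), p >= 2.
#' @return integer matrix with L rows and columns `i`, `j`.
#' @examples
#' pairIndexOrder(3) # (1,1), (1,2), (2,2)
#' @export
pairIndexOrder <- function(p) {
  if (length(p) != 1L || !is.finite(p) || p < 2 || p != round(p))
    stop("'p' must be a single integer >= 2")
  p <- as.integer(p)
  idx <- do.call(rbind, lapply(seq_len(p - 1L), function(i)
    cbind(i = i, j = seq.int(i, p - 1L))))
  storage.mode(idx) <- "integer"
  idx
}

.pairLabels <- function(pairs, componentNames = NULL) {
  if (is.null(componentNames))
    componentNames <- as.character(seq_len(max(pairs)))
  paste0("S_", componentNames[pairs[, "i"]], ".", componentNames[pairs[, "j"]])
}

#' Build the contrast design matrix
#'
#' Maps contrasts to the N x L design matrix A of the linear model
#' I_n(Q) = sum_l A\[n, l\] S_l(Q): the column for a self pair (i, i) is
#' Delta-rho_{n,i}^2 and for a cross pair (i, j), i < j, is
#' 2 Delta-rho_{n,i} Delta-rho_{n,j} (the factor 2 lives in A, so each
#' cross-term S_ij is reported once per unordered pair). Columns follow
#' [pairIndexOrder()].
#'
#' @param contrasts a [ContrastScatteringSet-class], or an N x (p-1) matrix
#'   of contrasts.
#' @return N x L numeric matrix with pair labels as column names; units
#'   (1e-6/Angstrom^2)^2.
#' @examples
#' buildDesignMatrix(rbind(c(2, 3))) # 4, 12, 9
#' @export
buildDesignMatrix <- function(contrasts) {
  d <- if (is(contrasts, "ContrastScatteringSet"))
    contrastDeltas(contrasts) else as.matrix(contrasts)
  if (any(!is.finite(d))) stop("contrast values must be finite")
  p <- ncol(d) + 1L
  pairs <- pairIndexOrder(p)
  A <- vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, "i"]; j <- pairs[k, "j"]
    fac <- if (i == j) 1 else 2
    fac * d[, i] * d[, j]
  }, numeric(nrow(d)))
  A <- matrix(A, nrow = nrow(d))
  colnames(A) <- .pairLabels(pairs, colnames(d))
  rownames(A) <- rownames(d)
  A
}

.checkDuplicateContrasts <- function(d) {
  if (anyDuplicated(round(d, 12)))
    warning(
      "two samples have identical contrasts; the system is degenerate ",
      "and the estimate pools them", call. = FALSE
    )
}

#' Flatten the multi-contrast model into one linear system
#'
#' Vectorises the model I_n(Q_m) = sum_l A\[n, l\] S_l(Q_m) + noise into
#' I-tilde = B S-tilde + eps with B = A (x) E_M (Kronecker product with the
#' M x M identity). The latent vector is ordered l-major / Q-minor and the
#' observation vector n-major / Q-minor, so row (n, m) sits at position
#' (n-1)M + m and column (l, m) at (l-1)M + m.
#'
#' @param A N x L design matrix from [buildDesignMatrix()].
#' @param intensities N x M intensity matrix.
#' @param sigmas N x M matrix of one-sigma uncertainties.
#' @return a [FlatSystem-class].
#' @examples
#' fs <- flattenSystem(rbind(c(1, 2), c(3, 4)),
#'                     intensities = matrix(1, 2, 3),
#'                     sigmas = matrix(0.1, 2, 3))
#' dim(fs@design) # 6 x 6
#' @export
flattenSystem <- function(A, intensities, sigmas) {
  A <- as.matrix(A)
  intensities <- as.matrix(intensities)
  sigmas <- as.matrix(sigmas)
  if (nrow(intensities) != nrow(A))
    stop("'intensities' must have one row per sample (row of A)")
  if (!identical(dim(intensities), dim(sigmas)))
    stop("'intensities' and 'sigmas' must have identical dimensions")
  if (any(sigmas <= 0)) stop("all sigmas must be strictly positive")
  n <- nrow(A); l <- ncol(A); m <- ncol(intensities)
  B <- kronecker(A, diag(m))
  new("FlatSystem",
    design = B,
    observations = as.vector(t(intensities)),
    noiseVar = as.vector(t(sigmas))^2,
    rowIndex = data.frame(
      n = rep(seq_len(n), each = m), m = rep(seq_len(m), n)
    ),
    colIndex = data.frame(
      l = rep(seq_len(l), each = m), m = rep(seq_len(m), l)
    )
  )
}

setMethod("show", "FlatSystem", function(object) {
  cat(sprintf(
    "FlatSystem: %d observations x %d latent values (N=%d, M=%d, L=%d)\n",
    nrow(object@design), ncol(object@design),
    max(object@rowIndex$n), max(object@rowIndex$m), max(object@colIndex$l)
  ))
})
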