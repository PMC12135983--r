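# Independent brute-force oracles. These deliberately use the generic dense
# formulas (explicit Kronecker products, solve(), determinant()) rather than
# any code path shared with the package's estimators.

# General-nu Matern kernel through the modified Bessel function.
maternBessel <- function(r, l, nu, alpha = 1) {
  out <- rep(alpha, length(r))
  pos <- r > 0
  s <- sqrt(2 * nu) * r[pos] / l
  out[pos] <- alpha * 2^(1 - nu) / gamma(nu) * s^nu * besselK(s, nu)
  out
}

# Precision-form posterior: V = B^T Sigma^-1 B + K^-1, mu = V^-1 B^T
# Sigma^-1 y, computed with plain dense solves.
densePosterior <- function(A, I, Sg, D) {
  M <- ncol(I); L <- ncol(A)
  B <- kronecker(A, diag(M))
  K <- kronecker(diag(L), D)
  SigInv <- diag(1 / as.vector(t(Sg))^2)
  y <- as.vector(t(I))
  V <- t(B) %*% SigInv %*% B + solve(K)
  cov <- solve(V)
  cov <- (cov + t(cov)) / 2
  mu <- cov %*% t(B) %*% SigInv %*% y
  list(
    mean = matrix(mu, nrow = L, ncol = M, byrow = TRUE),
    cov = cov,
    stderr = matrix(sqrt(diag(cov)), nrow = L, ncol = M, byrow = TRUE)
  )
}

# Dense multivariate-normal log-density of the observations with the latent
# functions integrated out.
denseLogEvidence <- function(A, I, Sg, D) {
  M <- ncol(I); L <- ncol(A)
  B <- kronecker(A, diag(M))
  C <- B %*% kronecker(diag(L), D) %*% t(B) + diag(as.vector(t(Sg))^2)
  y <- as.vector(t(I))
  ld <- as.numeric(determinant(C, logarithm = TRUE)$modulus)
  -0.5 * drop(y %*% solve(C, y)) - 0.5 * ld -
    0.5 * length(y) * log(2 * pi)
}

# Small random well-conditioned instance for the low-level matrix API.
randomInstance <- function(seed, N = 4, M = 5, L = 3) {
  set.seed(seed)
  q <- sort(runif(M, 0.01, 0.3))
  A <- matrix(runif(N * L, 0.5, 2), N, L)
  Sg <- matrix(runif(N * M, 0.05, 0.2), N, M)
  I <- matrix(rnorm(N * M), N, M)
  D <- kernelMatrix(KernelSpec("matern52", alpha = 2, lengthScale = 0.1,
                               tau = 1e-3), q)
  list(q = q, A = A, Sg = Sg, I = I, D = D)
}

relErr <- function(x, y) max(abs(x - y) / pmax(abs(y), 1e-12))
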