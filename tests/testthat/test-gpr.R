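test_that("prior covariance is block-diagonal with identical kernel blocks", {
  q <- c(0.01, 0.05)
  sp <- KernelSpec("matern52", alpha = 2, lengthScale = 0.1, tau = 1e-4)
  D <- kernelMatrix(sp, q)
  K1 <- priorCovariance(sp, q, 1)
  expect_equal(K1, D)
  K3 <- priorCovariance(sp, q, 3)
  expect_equal(dim(K3), c(6L, 6L))
  for (b in 0:2)
    expect_equal(K3[b * 2 + 1:2, b * 2 + 1:2], D)
  offBlocks <- K3
  for (b in 0:2) offBlocks[b * 2 + 1:2, b * 2 + 1:2] <- 0
  expect_equal(max(abs(offBlocks)), 0) # independence across functions
})

test_that("scalar case reproduces the conjugate closed form", {
  a <- 1.7; k <- 0.8; sigma <- 0.3; y <- 2.1
  post <- gprPosterior(
    A = matrix(a, 1, 1), intensities = matrix(y, 1, 1),
    sigmas = matrix(sigma, 1, 1), D = matrix(k, 1, 1), wantCov = TRUE
  )
  expect_equal(post$mean[1, 1], k * a * y / (a^2 * k + sigma^2))
  expect_equal(post$cov[1, 1], k * sigma^2 / (a^2 * k + sigma^2))
  expect_equal(post$stderr[1, 1],
               sqrt(k * sigma^2 / (a^2 * k + sigma^2)))
  # prior-only limit: zero design leaves the prior untouched
  none <- gprPosterior(matrix(0, 1, 1), matrix(y, 1, 1),
                       matrix(sigma, 1, 1), matrix(k, 1, 1))
  expect_equal(none$mean[1, 1], 0)
  expect_equal(none$stderr[1, 1], sqrt(k))
})

test_that("function-space posterior matches the dense precision-form oracle", {
  for (seed in c(1, 7, 23)) {
    inst <- randomInstance(seed, N = 5, M = 8, L = 3)
    post <- gprPosterior(inst$A, inst$I, inst$Sg, inst$D, wantCov = TRUE)
    oracle <- densePosterior(inst$A, inst$I, inst$Sg, inst$D)
    expect_lt(relErr(post$mean, oracle$mean), 1e-8)
    expect_lt(relErr(post$stderr, oracle$stderr), 1e-8)
    expect_lt(max(abs(post$cov - oracle$cov)) / max(abs(oracle$cov)), 1e-8)
    # stderr^2 is the covariance diagonal under the l-major index map
    expect_equal(as.vector(t(post$stderr))^2, diag(post$cov),
                 tolerance = 1e-10)
  }
})

test_that("posterior variance shrinks below the prior and with less noise", {
  sim <- generateCoreShell(CoreShellParams(nQ = 30), seed = 5)
  spec <- KernelSpec("matern52", alpha = 10, lengthScale = 0.1)
  est <- fitGPR(sim$data, spec)
  priorSd <- sqrt(10 + 1e-10)
  expect_true(all(errorBars(est) < priorSd))
  # scaling all sigmas down strictly reduces every posterior variance
  shrunk <- sim$data
  SummarizedExperiment::assay(shrunk, "sigma") <-
    SummarizedExperiment::assay(sim$data, "sigma") * 0.5
  est2 <- fitGPR(shrunk, spec)
  expect_true(all(errorBars(est2) <= errorBars(est)))
  # strict wherever the variance has not already collapsed to roundoff zero
  pos <- errorBars(est) > 0
  expect_true(all(errorBars(est2)[pos] < errorBars(est)[pos]))
})

test_that("the GPR posterior approaches WLS as the prior variance grows", {
  sim <- generateCoreShell(CoreShellParams(nQ = 25), seed = 9)
  wls <- estimateMeans(fitWLS(sim$data))
  gaps <- vapply(c(1e6, 1e9, 1e12), function(a) {
    mu <- estimateMeans(fitGPR(sim$data,
                               KernelSpec("matern52", alpha = a,
                                          lengthScale = 0.1, tau = 1e-5)))
    relErr(mu, wls)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0)) # monotone approach
  expect_lt(gaps[3], 1e-4)
})

test_that("an extremely long length scale flattens the estimate", {
  # tau = 0: the rank-1 flat prior; a nonzero nugget would correctly let
  # the posterior track isolated very-low-sigma points instead
  sim <- generateCoreShell(CoreShellParams(), seed = 13)
  dataA <- subsetLowQ(sim$data)
  qr <- diff(range(qValues(dataA)))
  est <- suppressMessages(
    fitGPR(dataA, KernelSpec("matern52", alpha = 10,
                             lengthScale = 1e6 * qr, tau = 0))
  )
  mu <- estimateMeans(est)
  relRange <- apply(mu, 1, function(x)
    (max(x) - min(x)) / (abs(mean(x)) + 1e-12))
  expect_true(all(relRange < 1e-3))
})

test_that("fit results expose diagnostics and provenance", {
  sim <- generateCoreShell(CoreShellParams(nQ = 20), seed = 2)
  spec <- KernelSpec("matern52", alpha = 10, lengthScale = 0.1)
  est <- fitGPR(sim$data, spec, wantCov = TRUE)
  md <- S4Vectors::metadata(est)
  expect_identical(md$method, "gpr")
  expect_s4_class(md$kernel, "KernelSpec")
  expect_true(is.finite(md$logMarginalLikelihood))
  expect_true(is.numeric(md$diagnostics$negativeBeyond2Sigma))
  V <- posteriorCovariance(est)
  expect_equal(dim(V), c(60L, 60L))
  expect_equal(V, t(V))
  expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8 * max(diag(V)))
  # duplicate contrasts only warn
  dup <- sim$data[, c(1, 1, 2, 3)]
  expect_warning(fitGPR(dup, spec), "identical contrasts")
})
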