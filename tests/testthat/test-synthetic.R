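test_that("sphere amplitude handles the removable singularity smoothly", {
  expect_equal(sphereForm(0), 1)
  expect_equal(sphereForm(pi), 3 / pi^2)
  # series branch joins the direct formula continuously
  xs <- c(9.99e-4, 1.001e-3)
  expect_lt(abs(diff(sphereForm(xs))), 1e-8)
  expect_equal(sphereForm(1e-4), 1 - 1e-8 / 10, tolerance = 1e-12)
  expect_error(sphereForm(-1), "non-negative")
})

test_that("solvent SLD mixes linearly and hits the match points", {
  p <- CoreShellParams()
  expect_equal(solventSLD(1), 6.36)
  expect_equal(solventSLD(0), -0.56)
  expect_equal(solventSLD(0.66), 4.0, tolerance = 0.05) # core match
  expect_equal(solventSLD(0.22), 1.0, tolerance = 0.05) # shell match
  expect_equal(solventSLD(0.5), (6.36 - 0.56) / 2)
  expect_error(solventSLD(1.2), "\\[0, 1\\]")
})

test_that("ground-truth partials obey the forward model identities", {
  p <- CoreShellParams(nQ = 40)
  q <- p@qValues
  S <- truePartials(p)
  sc <- cvsansGP:::.effectiveScale(p)
  vC <- 4 / 3 * pi * 50^3
  vO <- 4 / 3 * pi * 60^3
  # Q -> 0 limits (first grid point at Q = 0.004 is within the plateau)
  S0 <- truePartials(CoreShellParams(qValues = c(1e-6, 1e-5)))
  expect_equal(unname(S0[1, 1]) / sc, vC^2, tolerance = 1e-6)
  expect_equal(unname(S0[3, 1]) / sc, (vO - vC)^2, tolerance = 1e-6)
  expect_equal(unname(S0[2, 1]) / sc, vC * (vO - vC), tolerance = 1e-6)
  # single-particle amplitudes are proportional: Cauchy-Schwarz equality
  expect_equal(S[2, ]^2, S[1, ] * S[3, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  # at the core match point the low-Q intensity is dominated by the shell
  # term (residual core contrast ~0.007e-6/A^2 leaves a ~0.7% cross-term
  # contribution at the forward limit, growing towards the subset edge)
  rhoS <- solventSLD(0.66, p)
  dC <- 4.0 - rhoS; dS <- 1.0 - rhoS
  I0 <- dC^2 * S[1, ] + 2 * dC * dS * S[2, ] + dS^2 * S[3, ]
  expect_lt(abs(I0[1] / (dS^2 * S[3, 1]) - 1), 0.01)
  expect_lt(max(abs(I0[q < 0.05] / (dS^2 * S[3, q < 0.05]) - 1)), 0.02)
})

test_that("assembled intensities reproduce the two-shell sphere model", {
  p <- CoreShellParams(nQ = 25)
  sim <- generateCoreShell(p, seed = 1)
  # independent direct evaluation of the concentric-sphere amplitude
  q <- qValues(sim$data)
  sc <- cvsansGP:::.effectiveScale(p)
  for (n in c(1, 4, 8)) {
    rhoSolv <- solventSLD(p@phiD[n], p)
    amp <- (4.0 - rhoSolv) * (4 / 3 * pi * 50^3) * sphereForm(q * 50) +
      (1.0 - rhoSolv) *
        ((4 / 3 * pi * 60^3) * sphereForm(q * 60) -
         (4 / 3 * pi * 50^3) * sphereForm(q * 50))
    expect_equal(sim$noiseFree[n, ], sc * amp^2, tolerance = 1e-10)
  }
})

test_that("the noise model is multiplicative, seeded and calibrated", {
  p <- CoreShellParams(nQ = 20)
  s1 <- generateCoreShell(p, seed = 42)
  s2 <- generateCoreShell(p, seed = 42)
  expect_identical(intensities(s1$data), intensities(s2$data))
  s3 <- generateCoreShell(p, seed = 43)
  expect_false(identical(intensities(s1$data), intensities(s3$data)))
  # reported sigma is the true standard deviation of I: sigma * |I0|
  expect_equal(unname(sigmas(s1$data)), unname(0.05 * abs(s1$noiseFree)))
  # vanishing noise returns the noise-free curves
  s0 <- generateCoreShell(CoreShellParams(nQ = 20, noiseSigma = 1e-12),
                          seed = 1)
  expect_equal(intensities(s0$data), s0$noiseFree, tolerance = 1e-9,
               ignore_attr = TRUE)
  # Monte-Carlo check of E[I / I0] = 1 over ~16k draws
  big <- generateCoreShell(CoreShellParams(nQ = 2000), seed = 7)
  ratio <- intensities(big$data) / big$noiseFree
  expect_lt(abs(mean(ratio) - 1), 3 * 0.05 / sqrt(length(ratio)))
  expect_equal(stats::sd(ratio), 0.05, tolerance = 0.05)
  # the generator leaves the caller's RNG stream untouched
  set.seed(99); before <- .Random.seed
  invisible(generateCoreShell(p, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("the low-Q subset applies a strict boundary", {
  p <- CoreShellParams(qValues = c(0.01, 0.02, 0.05, 0.1))
  sim <- generateCoreShell(p, seed = 1)
  a <- subsetLowQ(sim$data)
  expect_equal(qValues(a), c(0.01, 0.02)) # 0.05 excluded by strict <
  expect_true(all(qValues(a) %in% qValues(sim$data)))
  expect_equal(intensities(a), intensities(sim$data)[, 1:2])
  expect_error(subsetLowQ(sim$data, 0.005), "no grid points")
  full <- generateCoreShell(CoreShellParams(), seed = 1)
  expect_true(all(qValues(subsetLowQ(full$data)) < 0.05))
})

test_that("the MSE metric averages squared errors over all curves", {
  expect_equal(mseEstimate(matrix(1, 2, 3), matrix(1, 2, 3)), 0)
  expect_equal(mseEstimate(matrix(2, 2, 3), matrix(1, 2, 3)), 1)
  set.seed(5)
  est <- matrix(rnorm(12), 3, 4); truth <- matrix(rnorm(12), 3, 4)
  acc <- 0
  for (l in 1:3) for (m in 1:4) acc <- acc + (est[l, m] - truth[l, m])^2
  expect_equal(mseEstimate(est, truth), acc / 12)
  expect_error(mseEstimate(est, truth[, 1:3]), "3 x 4")
})

test_that("a small white kernel rescues the Gaussian kernel", {
  # smoothest kernel is most sensitive to the nugget; Matern 5/2 barely moves
  found <- FALSE
  for (seed in 1:3) {
    sim <- generateCoreShell(CoreShellParams(), seed = seed)
    dataA <- subsetLowQ(sim$data)
    truthA <- sim$truth[, qValues(sim$data) < 0.05]
    mseFor <- function(fam, tau)
      mseEstimate(fitGPR(dataA, KernelSpec(fam, alpha = 10,
                                           lengthScale = 0.1, tau = tau)),
                  truthA)
    m52 <- c(mseFor("matern52", 0), mseFor("matern52", 1e-5))
    expect_lt(abs(diff(m52)) / m52[1], 0.2)
    g <- c(mseFor("gaussian", 0), mseFor("gaussian", 1e-5))
    if (g[2] <= g[1]) found <- TRUE
  }
  expect_true(found)
})

test_that("the error-misspecification study reports both symptoms", {
  rep <- errorMisspecStudy(CoreShellParams(nQ = 60), seed = 11,
                           spec = KernelSpec("matern52", alpha = 10,
                                             lengthScale = 0.1))
  expect_setequal(unique(rep$factor), c(0.5, 1, 2))
  expect_equal(nrow(rep), 9L)
  by <- split(rep, rep$factor)
  # overstated errors inflate the error bars
  expect_true(all(by[["2"]]$meanStderr > by[["1"]]$meanStderr))
  # understated errors cannot shrink them
  expect_true(all(by[["0.5"]]$meanStderr < by[["1"]]$meanStderr))
})
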