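test_that("kernel values match their closed forms", {
  for (fam in c("gaussian", "matern32", "matern52")) {
    sp <- KernelSpec(fam, alpha = 2.5, lengthScale = 0.07, tau = 0)
    expect_equal(kernelValue(sp, 0.1, 0.1), 2.5) # r = 0 -> alpha
  }
  g <- KernelSpec("gaussian", alpha = 1, lengthScale = 0.1, tau = 0)
  expect_equal(kernelValue(g, 0.1, 0.2), exp(-1 / 2))
  m52 <- KernelSpec("matern52", alpha = 1, lengthScale = 0.1, tau = 0)
  expect_equal(kernelValue(m52, 0, 0.1),
               (1 + sqrt(5) + 5 / 3) * exp(-sqrt(5)))
  # white kernel adds tau^2 only on exact coincidence
  spt <- KernelSpec("matern32", alpha = 1, lengthScale = 0.1, tau = 0.01)
  expect_equal(kernelValue(spt, 0.2, 0.2), 1 + 1e-4)
  expect_equal(kernelValue(spt, 0.2, 0.2 + 1e-9),
               kernelValue(KernelSpec("matern32", 1, 0.1, tau = 0),
                           0.2, 0.2 + 1e-9))
  expect_error(KernelSpec("matern52", alpha = -1), "positive")
  expect_error(KernelSpec("matern52", lengthScale = 0), "positive")
})

test_that("closed-form Matern kernels agree with the Bessel-function form", {
  r <- seq(0, 0.5, by = 0.01)
  l <- 0.12; alpha <- 3
  m32 <- KernelSpec("matern32", alpha = alpha, lengthScale = l, tau = 0)
  m52 <- KernelSpec("matern52", alpha = alpha, lengthScale = l, tau = 0)
  expect_equal(kernelValue(m32, r, 0 * r), maternBessel(r, l, 3 / 2, alpha),
               tolerance = 1e-10)
  expect_equal(kernelValue(m52, r, 0 * r), maternBessel(r, l, 5 / 2, alpha),
               tolerance = 1e-10)
})

test_that("kernel matrices are symmetric, stationary and near-PSD", {
  set.seed(11)
  q <- sort(runif(6, 0.01, 0.4))
  for (fam in c("gaussian", "matern32", "matern52")) {
    sp <- KernelSpec(fam, alpha = 2, lengthScale = 0.08, tau = 1e-5)
    D <- kernelMatrix(sp, q)
    expect_equal(D, t(D))
    expect_equal(diag(D), rep(2 + 1e-10, 6))
    # stationarity: shifting the whole grid leaves D unchanged
    expect_equal(kernelMatrix(sp, q + 0.05), D, tolerance = 1e-12)
    expect_gte(min(eigen(D, symmetric = TRUE)$values), -1e-10 * 2)
    # monotone decay in r
    rGrid <- seq(0, 1, by = 0.02)
    v <- kernelValue(KernelSpec(fam, 2, 0.08, tau = 0), rGrid, 0 * rGrid)
    expect_true(all(diff(v) <= 1e-14))
  }
  # single-point grid
  expect_equal(
    kernelMatrix(KernelSpec("gaussian", alpha = 3, tau = 0.1), 0.05),
    matrix(3 + 0.01, 1, 1)
  )
  # flat-prior limit: enormous length scale makes all entries ~ alpha
  flat <- kernelMatrix(KernelSpec("matern52", alpha = 2,
                                  lengthScale = 1e6 * diff(range(q)),
                                  tau = 0), q)
  expect_equal(max(abs(flat - 2)), 0, tolerance = 1e-5)
})

test_that("white kernel shifts the spectrum exactly by tau^2", {
  q <- exp(seq(log(0.01), log(0.3), length.out = 8))
  base <- KernelSpec("matern32", alpha = 1.5, lengthScale = 0.1, tau = 0)
  withTau <- KernelSpec("matern32", alpha = 1.5, lengthScale = 0.1,
                        tau = 0.02)
  e0 <- eigen(kernelMatrix(base, q), symmetric = TRUE)$values
  e1 <- eigen(kernelMatrix(withTau, q), symmetric = TRUE)$values
  expect_equal(e1, e0 + 0.02^2, tolerance = 1e-12)
})

test_that("families order as expected in smoothness (spectral decay)", {
  q <- exp(seq(log(0.004), log(0.4), length.out = 40))
  effRank <- function(fam) {
    ev <- eigen(kernelMatrix(KernelSpec(fam, alpha = 1, lengthScale = 0.1,
                                        tau = 0), q),
                symmetric = TRUE, only.values = TRUE)$values
    sum(ev > 1e-8 * ev[1]) # eigenvalues carrying mass
  }
  # smoother prior = faster spectral decay = lower effective rank
  expect_lt(effRank("gaussian"), effRank("matern52"))
  expect_lte(effRank("matern52"), effRank("matern32"))
})
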