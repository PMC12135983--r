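test_that("evidence matches the scalar normal and the dense oracle", {
  # N = M = L = 1, a = 1, k = 1, sigma^2 = 1, y = 0: variance 2 at zero
  lml <- gprEvidence(matrix(1, 1, 1), matrix(0, 1, 1), matrix(1, 1, 1),
                     matrix(1, 1, 1))
  expect_equal(lml, -0.5 * log(2 * pi * 2))
  for (seed in c(4, 31)) {
    inst <- randomInstance(seed, N = 4, M = 6, L = 3)
    got <- gprEvidence(inst$A, inst$I, inst$Sg, inst$D)
    want <- denseLogEvidence(inst$A, inst$I, inst$Sg, inst$D)
    expect_lt(abs(got - want) / abs(want), 1e-8)
  }
})

test_that("evidence in l is single-peaked on core-shell data", {
  sim <- generateCoreShell(CoreShellParams(), seed = 17)
  dataA <- subsetLowQ(sim$data)
  lGrid <- 10^seq(-3, 2, length.out = 6)
  lml <- vapply(lGrid, function(l)
    logMarginalLikelihood(dataA, KernelSpec("matern52", alpha = 10,
                                            lengthScale = l)),
    numeric(1))
  k <- which.max(lml)
  # rises to the peak and falls after it, allowing one grid-step wiggle
  viol <- sum(diff(lml[seq_len(k)]) < 0) +
    sum(diff(lml[k:length(lml)]) > 0)
  expect_lte(viol, 1)
})

test_that("MAP objective reduces to the evidence for diffuse hyper-priors", {
  sim <- generateCoreShell(CoreShellParams(nQ = 15), seed = 2)
  spec <- KernelSpec("matern52", alpha = 8, lengthScale = 0.07)
  lml <- logMarginalLikelihood(sim$data, spec)
  diffuse <- HyperPrior(alpha = list("gaussian", 1, 1e12),
                        l = list("gaussian", 1, 1e12))
  expect_equal(mapObjective(sim$data, spec, diffuse), lml,
               tolerance = 1e-10)
  # Gaussian hyper-prior centred at the spec: penalty exactly zero
  centred <- HyperPrior(alpha = list("gaussian", 8, 2),
                        l = list("gaussian", 0.07, 0.01))
  expect_equal(mapObjective(sim$data, spec, centred), lml)
  # log-normal at its median keeps the density's own constant
  ln <- HyperPrior(alpha = list("lognormal", 8, 0.5),
                   l = list("lognormal", 0.07, 0.3))
  expect_equal(
    mapObjective(sim$data, spec, ln) - lml,
    -log(8 * 0.5 * sqrt(2 * pi)) - log(0.07 * 0.3 * sqrt(2 * pi))
  )
  # outside a uniform support the spec is excluded, not an error
  uni <- HyperPrior(alpha = list("uniform", 10, 20),
                    l = list("uniform", 0.001, 1))
  expect_identical(mapObjective(sim$data, spec, uni), -Inf)
  expect_error(HyperPrior(alpha = list("uniform", 5, 2)), "ordered")
})

test_that("grid search returns an exhaustive, reproducible table", {
  sim <- generateCoreShell(CoreShellParams(nQ = 20), seed = 6)
  one <- gridSearch(sim$data, families = "matern32", alphaGrid = 3,
                    lGrid = 0.05)
  expect_equal(nrow(objectiveTable(one)), 1L)
  expect_equal(bestSpec(one)@alpha, 3)
  expect_equal(bestSpec(one)@lengthScale, 0.05)

  sel <- gridSearch(sim$data, families = c("matern32", "matern52"),
                    alphaGrid = c(1, 10), lGrid = c(0.03, 0.1))
  tab <- objectiveTable(sel)
  expect_equal(nrow(tab), 8L)
  expect_true(all(is.finite(tab$objective)))
  best <- max(tab$objective)
  sp <- bestSpec(sel)
  got <- tab$objective[tab$family == sp@family & tab$alpha == sp@alpha &
                         tab$l == sp@lengthScale]
  expect_equal(got, best)
  # bit-identical rerun
  sel2 <- gridSearch(sim$data, families = c("matern32", "matern52"),
                     alphaGrid = c(1, 10), lGrid = c(0.03, 0.1))
  expect_identical(objectiveTable(sel2), tab)
  # refinement only adds rows and never loses the incumbent
  ref <- gridSearch(sim$data, families = "matern52",
                    alphaGrid = c(1, 10), lGrid = c(0.03, 0.1),
                    refine = TRUE)
  expect_gt(nrow(objectiveTable(ref)), 4L)
  expect_gte(max(objectiveTable(ref)$objective),
             max(objectiveTable(sel)$objective))
})

test_that("evidence penalizes the effectively flat (WLS-limit) prior", {
  sim <- generateCoreShell(CoreShellParams(), seed = 8)
  dataA <- subsetLowQ(sim$data)
  sel <- gridSearch(dataA, families = "matern52",
                    alphaGrid = c(10, 1e12), lGrid = 0.1)
  expect_equal(bestSpec(sel)@alpha, 10)
})

test_that("tie-breaking prefers the smaller length scale, then amplitude", {
  tab <- data.frame(
    family = "matern52", alpha = c(1, 2, 1), l = c(0.2, 0.1, 0.1),
    tau = 0, objective = c(5, 5 + 2e-7, 5 - 5e-7)
  )
  pick <- cvsansGP:::.selectBest(tab)
  expect_equal(pick$l, 0.1)
  expect_equal(pick$alpha, 1)
  # adding a constant to every objective value leaves the argmax unchanged
  tab2 <- tab; tab2$objective <- tab2$objective + 123.456
  expect_equal(cvsansGP:::.selectBest(tab2)[, c("alpha", "l")],
               pick[, c("alpha", "l")])
})
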