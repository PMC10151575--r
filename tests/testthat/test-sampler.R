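# Sampler behaviour on small simulated datasets.  Chain lengths are short:
# these tests check mechanics (determinism, invariants, gross calibration);
# the parameter-recovery checks at benchmark scale live in test-acceptance.R.

test_that("seeded threshold-model runs are bit-identical", {
  g <- makeGeno(n = 120, p = 80, seed = 4)
  set.seed(10)
  tr <- simulateBinaryTrait(g, nQtl = 8, h2 = 0.4, nHyq = 5)
  ch <- chainConfig(300, 100, 5, seed = 99, pi = 0.9)
  f1 <- fitThresholdMarkerModel(tr$dataset, g, ch, prior = "BayesB")
  f2 <- fitThresholdMarkerModel(tr$dataset, g, ch, prior = "BayesB")
  expect_identical(f1@samples, f2@samples)

  pi1 <- estimatePi(tr$dataset, g, ch)
  pi2 <- estimatePi(tr$dataset, g, ch)
  expect_identical(pi1$pi, pi2$pi)
})

test_that("saved liabilities always carry the sign implied by the phenotype", {
  g <- makeGeno(n = 100, p = 60, seed = 6)
  set.seed(3)
  tr <- simulateBinaryTrait(g, nQtl = 5, h2 = 0.3, nHyq = 4)
  fit <- fitThresholdMarkerModel(tr$dataset, g,
                                 chainConfig(200, 50, 5, seed = 1, pi = 0.9),
                                 prior = "BayesC", saveLiabilities = TRUE)
  liab <- fit@samples$liabilities
  y <- tr$dataset@phenotype
  expect_true(all(liab[, y == 1L] > 0))
  expect_true(all(liab[, y == 0L] <= 0))
})

test_that("degenerate inputs are rejected with clear errors", {
  g <- makeGeno(n = 40, p = 30, seed = 7)
  hyq <- factor(rep(c("a", "b"), 20))
  all1 <- new("TraitData", sowId = g@ids, phenotype = rep(1L, 40),
              hyq = hyq, parity = rep(2L, 40), tag = "X")
  expect_error(fitThresholdMarkerModel(all1, g), "threshold")

  ds <- new("TraitData", sowId = c(g@ids[-1], "ghost"),
            phenotype = rep(c(0L, 1L), 20), hyq = hyq,
            parity = rep(2L, 40), tag = "X")
  expect_error(fitThresholdMarkerModel(ds, g), "ghost")
  expect_error(fitBinaryAnimalModel(all1, genomicRelationship(g)),
               "threshold")
})

test_that("pure-noise traits yield near-zero genetic variance share", {
  set.seed(40)
  sc <- simScenario(nSows = 600, nMarkers = 300, nChromosomes = 3,
                    nQtl = 10, ldRho = 0, seed = 40)
  g <- simulateGenotypes(sc, nInd = 600)
  for (seed in 1:2) {
    set.seed(seed)
    tr <- simulateBinaryTrait(g, nQtl = 10, h2 = 0, nHyq = 5)
    fit <- fitThresholdMarkerModel(tr$dataset, g,
                                   chainConfig(1200, 300, 5, seed = seed,
                                               pi = 1 - 1e-9),
                                   prior = "BayesB")
    share <- mean(fit@samples$geneticVar / (fit@samples$geneticVar + 1))
    expect_lt(share, 0.05)
  }
})

test_that("Bayes-Cpi pushes pi towards 1 for sparse and null architectures", {
  g <- benchGeno()
  set.seed(51)
  tr <- simulateBinaryTrait(g, nQtl = 10, h2 = 0.4)
  est <- estimatePi(tr$dataset, g, chainConfig(3000, 1000, 10, seed = 51))
  expect_gt(est$pi, 0.95)
  expect_lte(est$pi, 1)

  set.seed(52)
  null <- simulateBinaryTrait(g, nQtl = 10, h2 = 0)
  est0 <- estimatePi(null$dataset, g, chainConfig(3000, 1000, 10, seed = 52))
  expect_gt(est0$pi, 0.9)
})

test_that("duplicated trait gives genetic correlation near one", {
  g <- makeGeno(n = 250, p = 150, chroms = 3, seed = 9)
  set.seed(5)
  tr <- simulateBinaryTrait(g, nQtl = 10, h2 = 0.5, nHyq = 5)
  ds <- data.frame(sowId = tr$dataset@sowId,
                   phenotype = as.numeric(tr$dataset@phenotype),
                   hyq = as.character(tr$dataset@hyq))
  fit <- fitBivariateLinear(ds, ds, g, chainConfig(1200, 300, 5, seed = 7))
  rg <- geneticCorrelation(fit)
  expect_gt(mean(rg$samples > 0.95), 0.9)
})

test_that("bivariate covariance samples admit a Cholesky factorization", {
  g <- makeGeno(n = 200, p = 100, chroms = 2, seed = 13)
  set.seed(6)
  bv <- simulateBivariateTraits(g, nQtl = 10, h2 = 0.3, rg = 0.5,
                                nPerTrait = 120, overlap = 0.5, nHyq = 4)
  fit <- fitBivariateLinear(bv$dataset1, bv$dataset2, g,
                            chainConfig(600, 200, 5, seed = 3))
  for (nm in c("geneticCov", "G0", "R")) {
    s <- fit@samples[[nm]]
    ok <- apply(s, 1, function(v) {
      m <- matrix(c(v[1], v[2], v[2], v[3]), 2)
      !inherits(try(chol(m + 1e-10 * diag(2)), silent = TRUE), "try-error")
    })
    expect_true(all(ok))
  }
})

test_that("complete-case mode needs at least two doubly phenotyped sows", {
  g <- makeGeno(n = 30, p = 20, seed = 17)
  d1 <- data.frame(sowId = g@ids[1:10], phenotype = rnorm(10), hyq = "a")
  d2 <- data.frame(sowId = g@ids[20:30], phenotype = rnorm(11), hyq = "a")
  expect_error(fitBivariateLinear(d1, d2, g, completeCase = TRUE),
               "complete-case")
})

test_that("animal model heritability is permutation-stable and seeded", {
  g <- makeGeno(n = 200, p = 150, chroms = 3, seed = 19)
  set.seed(8)
  tr <- simulateBinaryTrait(g, nQtl = 10, h2 = 0.4, nHyq = 5)
  G <- genomicRelationship(g)
  ch <- chainConfig(800, 200, 5, seed = 44)
  f1 <- fitBinaryAnimalModel(tr$dataset, G, ch)
  f2 <- fitBinaryAnimalModel(tr$dataset, G, ch)
  expect_identical(f1@samples$h2, f2@samples$h2)

  # marker-permutation invariance of the heritability posterior (within MC
  # error): permuting marker columns leaves G unchanged up to numerics
  perm <- sample(ncol(g@dose))
  gP <- genotypeData(g@dose[, perm],
                     data.frame(marker = g@map$marker[perm], chrom = "1",
                                pos = seq_len(ncol(g@dose)) * 100L),
                     ids = g@ids)
  f3 <- fitBinaryAnimalModel(tr$dataset, genomicRelationship(gP), ch)
  expect_lt(abs(mean(f1@samples$h2) - mean(f3@samples$h2)), 0.05)
})
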