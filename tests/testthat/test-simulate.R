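test_that("haplotype LD follows the Markov parameter", {
  set.seed(71)
  sc0 <- simScenario(nSows = 2000, nMarkers = 60, nChromosomes = 1,
                     ldRho = 0, nQtl = 5, seed = 71)
  g0 <- simulateGenotypes(sc0, nInd = 2000)
  adj0 <- sapply(seq_len(59), function(j) cor(g0@dose[, j], g0@dose[, j + 1]))
  expect_lt(max(abs(adj0)), 0.08)

  sc9 <- simScenario(nSows = 2000, nMarkers = 60, nChromosomes = 1,
                     ldRho = 0.9, nQtl = 5, seed = 71)
  g9 <- simulateGenotypes(sc9, nInd = 2000)
  adj9 <- sapply(seq_len(59), function(j) cor(g9@dose[, j], g9@dose[, j + 1]))
  expect_gt(mean(adj9), 0.5)

  expect_error(simScenario(ldRho = 1), "ldRho")
})

test_that("genotype simulation is reproducible under a fixed seed", {
  sc <- simScenario(nSows = 50, nMarkers = 40, nChromosomes = 2, nQtl = 5,
                    seed = 5)
  set.seed(5); g1 <- simulateGenotypes(sc, nInd = 50)
  set.seed(5); g2 <- simulateGenotypes(sc, nInd = 50)
  expect_identical(g1@dose, g2@dose)
  expect_identical(g1@map, g2@map)
})

test_that("record generator respects removal structure and clean QC", {
  set.seed(72)
  sc <- simScenario(nSows = 2000, nMarkers = 80, nChromosomes = 2,
                    nQtl = 10, seed = 72)
  g <- simulateGenotypes(sc, nInd = 2000)
  sim <- simulatePopRecords(g, sc)
  rec <- sim$records

  # no record after the removal parity
  rm <- rec[!is.na(rec$removal_parity), c("sow_id", "removal_parity")]
  for (i in seq_len(nrow(rm)))
    expect_equal(sum(rec$sow_id == rm$sow_id[i] &
                       rec$parity > rm$removal_parity[i]), 0L)

  # QC-clean by construction
  qc <- qcFilter(rec)
  expect_identical(qc$records, rec)

  # missing sire fraction close to the scenario value
  first <- rec[!duplicated(rec$sow_id), ]
  expect_lt(abs(mean(is.na(first$sire)) - sc$missingSireFrac), 0.01)

  # prolapse cases are about a tenth of culls in parities 2-6
  across <- codeAcrossParity(rec)
  expect_gt(mean(across@phenotype), 0.05)
  expect_lt(mean(across@phenotype), 0.20)
})

test_that("per-parity prolapse incidence matches the scenario targets", {
  set.seed(73)
  sc <- simScenario(nSows = 20000, nMarkers = 60, nChromosomes = 2,
                    nQtl = 10, seed = 73)
  g <- simulateGenotypes(sc, nInd = 20000)
  sim <- simulatePopRecords(g, sc)
  rec <- sim$records
  for (p in 2:6) {
    atRisk <- rec$sow_id[rec$parity == p]
    cases <- rec$sow_id[rec$parity == p & rec$removal_reason == "POP" &
                          !is.na(rec$removal_parity) & rec$removal_parity == p]
    inc <- sc$incidenceByParity[[as.character(p)]]
    half <- qnorm(0.995) * sqrt(inc * (1 - inc) / length(atRisk))
    # empirical-quantile threshold: rate is exact up to rounding, the
    # binomial 99% band is a generous envelope
    expect_lt(abs(length(cases) / length(atRisk) - inc), half + 1 / length(atRisk))
  }
})

test_that("ground truth reports realized parameters near their targets", {
  set.seed(74)
  sc <- simScenario(nSows = 4000, nMarkers = 200, nChromosomes = 4,
                    nQtl = 40, seed = 74)
  g <- simulateGenotypes(sc, nInd = 4000)
  sim <- simulatePopRecords(g, sc)
  tr <- truthReport(sim$truth)
  for (p in as.character(2:6))
    expect_lt(abs(tr$realizedH2[[p]] - sc$h2ByParity[[p]]), 0.05)
  adj <- sapply(1:5, function(k) tr$realizedRg[k, k + 1])
  expect_lt(max(abs(adj - sc$rgAdjacent)), 0.1)
  expect_equal(length(tr$qtl), 40L)
})

test_that("perfect correlation and single-QTL bookkeeping are exact", {
  set.seed(75)
  sc1 <- simScenario(nSows = 800, nMarkers = 60, nChromosomes = 2,
                     nQtl = 10, rgAdjacent = 1, seed = 75)
  g <- simulateGenotypes(sc1, nInd = 800)
  sim <- simulatePopRecords(g, sc1)
  adj <- sapply(1:5, function(k) sim$truth$realizedRg[k, k + 1])
  expect_true(all(abs(adj - 1) < 1e-8))

  # single QTL: the genetic share of liability variance follows the
  # variance bookkeeping of the generator to numerical accuracy
  set.seed(76)
  scq <- simScenario(nSows = 1500, nMarkers = 40, nChromosomes = 1,
                     nQtl = 1, seed = 76)
  gq <- simulateGenotypes(scq, nInd = 1500)
  simq <- simulatePopRecords(gq, scq)
  h2 <- scq$h2ByParity[["2"]]
  expect_lt(abs(simq$truth$realizedH2[["2"]] - h2), 0.05)
})

test_that("engineered window share hits its target exactly", {
  set.seed(77)
  sc <- simScenario(nSows = 1000, nMarkers = 200, nChromosomes = 4,
                    nQtl = 10, seed = 77)
  g <- simulateGenotypes(sc, nInd = 1000)
  w <- assignWindows(g)
  tr <- simulateWindowTrait(g, w, targetShare = 0.02)
  expect_equal(tr$realizedShare, 0.02, tolerance = 1e-10)
  expect_lt(abs(tr$realizedH2 - 0.4), 0.05)
})
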