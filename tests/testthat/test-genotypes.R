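test_that("genomic relationship equals the brute-force VanRaden form", {
  dose <- matrix(c(0, 1, 2, 1,
                   2, 1, 0, 0,
                   1, 1, 1, 2), nrow = 3, byrow = TRUE)
  map <- data.frame(marker = paste0("m", 1:4), chrom = "1",
                    pos = c(0L, 100L, 200L, 300L))
  g <- genotypeData(dose, map, ids = c("i1", "i2", "i3"))
  G <- genomicRelationship(g)

  # independent brute-force oracle
  p <- colMeans(dose) / 2
  W <- sweep(dose, 2, 2 * p, "-")
  Gref <- W %*% t(W) / (2 * sum(p * (1 - p)))
  expect_lt(max(abs(G@mat - Gref)), 1e-12)
})

test_that("identical genotypes give off-diagonal equal to diagonal", {
  dose <- rbind(rep(1, 6), rep(1, 6), c(0, 2, 0, 2, 0, 2))
  map <- data.frame(marker = paste0("m", 1:6), chrom = "1", pos = 0:5 * 10L)
  G <- genomicRelationship(genotypeData(dose, map))
  expect_equal(G@mat[1, 2], G@mat[1, 1])
})

test_that("monomorphic-only input is rejected", {
  dose <- matrix(2, 3, 4)
  map <- data.frame(marker = paste0("m", 1:4), chrom = "1", pos = 0:3 * 10L)
  expect_error(genomicRelationship(genotypeData(dose, map)),
               "no informative markers")
})

test_that("genomic relationship is invariant to marker order", {
  g <- makeGeno(n = 50, p = 60, seed = 11)
  perm <- sample(60)
  map2 <- data.frame(marker = g@map$marker[perm], chrom = "1",
                     pos = sort(sample(1e6, 60)))
  g2 <- genotypeData(g@dose[, perm], map2, ids = g@ids)
  G1 <- genomicRelationship(g)
  G2 <- genomicRelationship(g2)
  expect_lt(max(abs(G1@mat - G2@mat)), 1e-10)
})

test_that("unrelated simulated cohort has near-zero mean relationship", {
  set.seed(99)
  sc <- simScenario(nSows = 200, nMarkers = 2000, nChromosomes = 10,
                    ldRho = 0, nQtl = 10, seed = 99)
  g <- simulateGenotypes(sc, nInd = 200)
  G <- genomicRelationship(g)
  off <- G@mat[lower.tri(G@mat)]
  expect_lt(abs(mean(off)), 0.02)
})

test_that("pedigree A reproduces textbook values", {
  # two founders
  A0 <- pedigreeRelationship(data.frame(id = c("f1", "f2"), sire = NA,
                                        dam = NA))
  expect_equal(A0@mat, diag(2))

  # sire-dam-offspring trio
  trio <- pedigreeRelationship(
    data.frame(id = c("s", "d", "o"), sire = c(NA, NA, "s"),
               dam = c(NA, NA, "d")))
  m <- relMatrix(trio)
  expect_equal(m["s", "o"], 0.5)
  expect_equal(m["d", "o"], 0.5)
  expect_equal(m["o", "o"], 1.0)

  # full sibs 0.5; their (inbred) offspring has diagonal 1.25
  ped <- data.frame(id = c("s", "d", "a", "b", "x"),
                    sire = c(NA, NA, "s", "s", "a"),
                    dam = c(NA, NA, "d", "d", "b"))
  m <- relMatrix(pedigreeRelationship(ped))
  expect_equal(m["a", "b"], 0.5)
  expect_equal(m["x", "x"], 1.25)

  # order independence: shuffled input, same values
  m2 <- relMatrix(pedigreeRelationship(ped[c(4, 1, 5, 2, 3), ]))
  expect_equal(m2[rownames(m), colnames(m)], m)
})

test_that("pedigree cycles are detected", {
  ped <- data.frame(id = c("a", "b"), sire = c("b", "a"), dam = NA)
  expect_error(pedigreeRelationship(ped), "cycle")
})

test_that("window assignment uses half-open 1 Mb bins", {
  map <- data.frame(marker = c("a", "b", "c"), chrom = c("1", "1", "14"),
                    pos = c(999999L, 1000000L, 8500000L))
  w <- assignWindows(map)
  expect_equal(w@table$mb, c(0L, 1L, 8L))
  expect_equal(w@table$window, c("1_0", "1_1", "14_8"))
  expect_error(assignWindows(data.frame(marker = "a", chrom = "1",
                                        pos = -5L)), "negative")
})

test_that("windows partition the marker set", {
  set.seed(12)
  pos <- sort(sample(0:(10e6 - 1), 100))
  map <- data.frame(marker = sprintf("m%03d", 1:100), chrom = "2", pos = pos)
  w <- assignWindows(map)
  counts <- table(w@table$window)
  expect_equal(sum(counts), 100L)
  # enumeration oracle: per-window membership by arithmetic
  expect_equal(unname(counts[sprintf("2_%d", 0:9)][!is.na(counts[sprintf("2_%d", 0:9)])]),
               unname(table(floor(pos / 1e6))[as.character(sort(unique(floor(pos / 1e6))))]),
               ignore_attr = TRUE)
})

test_that("gene-dropped genomic relationships approach pedigree A with more markers", {
  set.seed(21)
  scSmall <- simScenario(nSows = 150, nMarkers = 300, nChromosomes = 3,
                         nQtl = 10, nSires = 10, nDams = 30, seed = 21)
  scBig <- simScenario(nSows = 150, nMarkers = 2400, nChromosomes = 3,
                       nQtl = 10, nSires = 10, nDams = 30, seed = 21)
  ids <- sprintf("sow%05d", 1:150)
  ped <- simulatePedigree(scSmall, ids)
  A <- relMatrix(pedigreeRelationship(ped))[ids, ids]
  dev <- vapply(list(scSmall, scBig), function(sc) {
    founders <- simulateGenotypes(sc, nInd = sc$nSires + sc$nDams,
                                  ids = ped$id[is.na(ped$sire)],
                                  returnHaplotypes = TRUE)
    dropped <- geneDrop(founders, ped)
    keep <- match(ids, dropped$genotypes@ids)
    g <- genotypeData(dropped$genotypes@dose[keep, ], dropped$genotypes@map,
                      ids = ids)
    mean(abs(relMatrix(genomicRelationship(g))[ids, ids] - A))
  }, 0)
  expect_lt(dev[2], dev[1])
  expect_lt(dev[2], 0.1)
})

test_that("mean imputation fills missing doses with twice the frequency", {
  dose <- rbind(c(0, 2, NA), c(2, NA, 1), c(1, 1, 1))
  map <- data.frame(marker = c("a", "b", "c"), chrom = "1", pos = 0:2 * 10L)
  g <- imputeMean(genotypeData(dose, map))
  expect_equal(g@dose[1, 3], 1)      # mean of (1, 1)
  expect_equal(g@dose[2, 2], 1.5)    # mean of (2, 1)
})
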