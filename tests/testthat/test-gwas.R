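# Window decomposition on constructed chains: a PosteriorChain is built
# directly so the expected variance shares are known exactly.

makeChainFixture <- function(geno, effectRows, pip = NULL) {
  p <- ncol(geno@dose)
  cfg <- chainConfig(nrow(effectRows) * 5L + 5L, 5L, 5L, seed = 1, pi = 0.9)
  if (is.null(pip)) pip <- colMeans(effectRows != 0)
  new("PosteriorChain", model = "threshold_marker",
      samples = list(effects = effectRows,
                     geneticVar = rep(1, nrow(effectRows))),
      markerIds = geno@map$marker, ids = geno@ids, config = cfg,
      info = list(link = "PROBIT", prior = "BayesB",
                  pip = stats::setNames(pip, geno@map$marker)))
}

test_that("a single causal marker puts 100% of variance in its window", {
  g <- makeGeno(n = 80, p = 60, chroms = 3, seed = 23)
  w <- assignWindows(g)
  eff <- matrix(0, 10, 60)
  eff[, 7] <- 0.8                      # one marker, constant effect
  chain <- makeChainFixture(g, eff)
  res <- windowVariancePosterior(chain, g, w)
  target <- w@table$window[7]
  expect_equal(res$pct_var[res$window == target], 100)
  expect_true(all(res$pct_var[res$window != target] == 0))
  expect_equal(res$wppa[res$window == target], 1)
  expect_true(all(res$wppa[res$window != target] == 0))
  expect_equal(res$top_snp[res$window == target], g@map$marker[7])
  expect_equal(sum(res$n_snps), 60L)
})

test_that("two equal unlinked causal markers split variance evenly", {
  set.seed(61)
  sc <- simScenario(nSows = 3000, nMarkers = 40, nChromosomes = 2,
                    ldRho = 0, nQtl = 2, seed = 61)
  g <- simulateGenotypes(sc, nInd = 3000)
  # matched frequencies: overwrite two markers with p = 0.5 draws
  g@dose[, 5] <- rbinom(3000, 2, 0.5)
  g@dose[, 25] <- rbinom(3000, 2, 0.5)   # marker 25 is on chromosome 2
  w <- assignWindows(g)
  eff <- matrix(0, 20, 40)
  eff[, 5] <- 1; eff[, 25] <- 1
  res <- windowVariancePosterior(makeChainFixture(g, eff), g, w)
  shares <- res$pct_var[res$pct_var > 0]
  expect_equal(length(shares), 2L)
  expect_lt(max(abs(shares - 50)), 5)
})

test_that("window shares of unlinked markers sum to about 100%", {
  set.seed(62)
  sc <- simScenario(nSows = 800, nMarkers = 200, nChromosomes = 4,
                    ldRho = 0, nQtl = 20, seed = 62)
  g <- simulateGenotypes(sc, nInd = 800)
  w <- assignWindows(g)
  eff <- matrix(rnorm(15 * 200, 0, 0.1), 15, 200)   # dense random effects
  res <- windowVariancePosterior(makeChainFixture(g, eff), g, w)
  expect_gt(sum(res$pct_var), 95)
  expect_lt(sum(res$pct_var), 105)
})

test_that("wppa is monotone non-increasing in rho", {
  g <- makeGeno(n = 100, p = 50, chroms = 2, seed = 27)
  w <- assignWindows(g)
  set.seed(3)
  eff <- matrix(rnorm(20 * 50, 0, 0.2), 20, 50)
  res <- windowVariancePosterior(makeChainFixture(g, eff), g, w)
  rhos <- c(0.01, 0.05, 0.2, 0.5)
  wmat <- sapply(rhos, function(r) wppa(res, r))
  expect_true(all(diff(t(wmat)) <= 1e-12))
  expect_error(wppa(res, 0), "rho")
})

test_that("significance calls use a strict 1% rule", {
  tab <- makeWindowTable(c(2.23, 1.51, 1.10, 1.93, 1.18, 1.14, 0.99, 1.0,
                           0.5, 0))
  hits <- callSignificant(tab)
  expect_equal(nrow(hits), 6L)
  expect_equal(hits$pct_var, sort(c(2.23, 1.51, 1.10, 1.93, 1.18, 1.14),
                                  decreasing = TRUE))
  expect_false(any(hits$pct_var == 1.0))      # boundary excluded
  expect_equal(nrow(callSignificant(makeWindowTable(rep(0, 5)))), 0L)
})

test_that("regional aggregation sums the anchor and its flanks", {
  tab <- makeWindowTable(c(0, 0.5, 0.5, 0.5, 0.5, 0.5, 0))
  # anchor mb = 3 (middle of the 0.5 run), flank 2 -> 5 x 0.5
  r <- regionalAggregate(tab, "1", 3L)
  expect_equal(r$pct_var_total, 2.5)
  expect_equal(regionalAggregate(tab, "1", 3L, flankMb = 0L)$pct_var_total,
               0.5)
  # anchor with empty flanks
  lone <- makeWindowTable(c(0, 0, 1.7, 0, 0))
  expect_equal(regionalAggregate(lone, "1", 2L)$pct_var_total, 1.7)
  # truncation at the chromosome end
  expect_equal(regionalAggregate(tab, "1", 0L)$pct_var_total, 1.0)
  expect_error(regionalAggregate(tab, "99", 1L), "chromosome")
})

test_that("manhattan table orders windows along the genome", {
  tab <- makeWindowTable(runif(4))
  tab$chrom <- c("2", "1", "10", "2")
  tab$mb <- c(5L, 3L, 0L, 1L)
  out <- manhattanTable(tab)
  expect_equal(out$chrom, c("1", "2", "2", "10"))   # numeric chromosome order
  expect_equal(out$mb, c(3L, 1L, 5L, 0L))
  expect_equal(out$pos_index, 1:4)
  empty <- manhattanTable(tab[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("the packaged genome-scan table reproduces its printed totals", {
  tab <- examplePOPWindows()
  expect_equal(nrow(tab), 6L)
  sig <- callSignificant(tab)
  expect_equal(nrow(sig), 6L)
  expect_lt(abs(sum(tab$pct_var) - 9.0), 0.1)
  expect_equal(sum(tab$pct_region_p2), 6.11, tolerance = 1e-9)
  expect_equal(sum(tab$pct_region_p3), 5.40, tolerance = 1e-9)
  expect_equal(sum(tab$pct_region_p4), 4.19, tolerance = 1e-9)
  expect_equal(sum(tab$pct_region_p5), 6.55, tolerance = 1e-9)
  expect_equal(sum(tab$pct_region_p6), 3.33, tolerance = 1e-9)
})
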