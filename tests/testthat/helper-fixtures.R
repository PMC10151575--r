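# Fixtures built in code: a hand-sized sow record set and small genotype sets.

# one clean sow: parity records 1..upTo, optionally removed in `rmParity`
makeSow <- function(id, farm = "A", entry = as.Date("2016-02-01"),
                    upTo = 3L, rmParity = NA, reason = "NONE",
                    sire = "s1", dam = "d1", died = FALSE,
                    gestation = 114L, overdueParity = NA) {
  rows <- list()
  insem <- entry
  last <- if (is.na(rmParity)) upTo else rmParity
  for (p in seq_len(last)) {
    gest <- if (!is.na(overdueParity) && p == overdueParity) 117L else gestation
    farrow <- insem + gest
    removed <- !is.na(rmParity) && p == rmParity
    rows[[p]] <- data.frame(
      sow_id = id, farm = farm, parity = p, insem_date = insem,
      farrow_date = farrow,
      removal_date = if (removed) farrow + 15L else as.Date(NA),
      removal_parity = if (removed) p else NA_integer_,
      removal_reason = if (removed) reason else "NONE",
      total_born = 14L, sire = sire, dam = dam,
      died = removed && died, stringsAsFactors = FALSE)
    insem <- farrow + 152L
  }
  do.call(rbind, rows)
}

bindSows <- function(...) {
  out <- do.call(rbind, list(...))
  rownames(out) <- NULL
  out
}

# benchmark-scale genotype set (3,000 sows x 1,000 markers, 100 x 1 Mb
# windows), built once per session and reused across test files
.fixtureCache <- new.env(parent = emptyenv())
benchGeno <- function() {
  if (is.null(.fixtureCache$bench)) {
    set.seed(20240901)
    sc <- simScenario(nSows = 3000, nMarkers = 1000, nChromosomes = 10,
                      markerSpacingBp = 100000L, nQtl = 20, seed = 20240901)
    .fixtureCache$bench <- simulateGenotypes(sc, nInd = 3000)
  }
  .fixtureCache$bench
}

# small genotype set with LD, deterministic under the given seed
makeGeno <- function(n = 200, p = 200, chroms = 2, ld = 0.3, seed = 42) {
  set.seed(seed)
  sc <- simScenario(nSows = n, nMarkers = p, nChromosomes = chroms,
                    ldRho = ld, nQtl = min(10L, p), seed = seed)
  simulateGenotypes(sc, nInd = n)
}

# window results table shaped like a genome-scan report
makeWindowTable <- function(pct) {
  data.frame(chrom = rep("1", length(pct)), mb = seq_along(pct) - 1L,
             window = sprintf("1_%d", seq_along(pct) - 1L),
             n_snps = 10L, pct_var = pct, wppa = 0.5,
             top_snp = sprintf("snp%d", seq_along(pct)), top_pip = 0.1,
             stringsAsFactors = FALSE)
}
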