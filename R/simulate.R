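## Synthetic sow cohorts: LD-structured genotypes, pedigrees with gene
## dropping, and multi-parity prolapse records generated under a
## liability-threshold model with a sparse QTL architecture.  The generator
## supplies the ground truth for every downstream test.

#' Simulation scenario
#'
#' Defaults emulate a multiplier-herd sow cohort: 2-6 parity records per
#' sow, liability-scale heritability declining with parity (0.41 down to
#' 0.15), adjacent-parity genetic correlation 0.7, prolapse incidence per
#' parity rising from 0.4% to 3% of sows present with roughly 10% of culls
#' due to prolapse, a sparse architecture (40 QTL of 2,000 markers,
#' pi = 0.98), two herds with quarterly contemporary groups, and 2% of sows
#' with missing sire (pooled semen).
#'
#' @param nSows number of sows.
#' @param nMarkers markers (spread evenly over chromosomes).
#' @param nChromosomes chromosomes; markers are placed on a uniform grid of
#'   \code{markerSpacingBp}.
#' @param markerSpacingBp distance between adjacent markers (default 25 kb).
#' @param mafRange stationary minor-allele-frequency range.
#' @param ldRho adjacent-marker haplotype allele correlation in [0,1).
#' @param nQtl causal markers.
#' @param h2ByParity named numeric, liability heritability per parity 1..6.
#' @param rgAdjacent adjacent-parity genetic correlation of marker effects
#'   (decays as \code{rgAdjacent^|k-l|}).
#' @param incidenceByParity named numeric, prolapse probability per parity
#'   among sows present.
#' @param cullOtherFactor other-reason culling hazard as a multiple of the
#'   prolapse incidence (default 9, making prolapse ~10\% of culls).
#' @param nHerds,nYears herd and entry-year structure for HYQ groups.
#' @param hyqSd standard deviation of HYQ contemporary-group effects on the
#'   liability scale.
#' @param missingSireFrac fraction of sows with blank sire id.
#' @param nSires,nDams founder counts for the pedigree.
#' @param seed RNG seed.
#' @return a list of class \code{"SimScenario"}.
#' @export
simScenario <- function(nSows = 5000L, nMarkers = 2000L, nChromosomes = 10L,
                        markerSpacingBp = 25000L,
                        mafRange = c(0.05, 0.5), ldRho = 0.5, nQtl = 40L,
                        h2ByParity = c(`1` = 0.41, `2` = 0.41, `3` = 0.35,
                                       `4` = 0.28, `5` = 0.22, `6` = 0.15),
                        rgAdjacent = 0.7,
                        incidenceByParity = c(`1` = 0.0035, `2` = 0.004,
                                              `3` = 0.010, `4` = 0.018,
                                              `5` = 0.030, `6` = 0.025),
                        cullOtherFactor = 9, nHerds = 2L, nYears = 5L,
                        hyqSd = 0.2, missingSireFrac = 0.02,
                        nSires = max(2L, nSows %/% 40L),
                        nDams = max(2L, nSows %/% 8L), seed = 1L) {
  if (ldRho < 0 || ldRho >= 1) stop("ldRho must be in [0,1)")
  if (nQtl > nMarkers) stop("nQtl cannot exceed nMarkers")
  stopifnot(all(h2ByParity >= 0 & h2ByParity <= 1),
            all(incidenceByParity > 0 & incidenceByParity < 1),
            rgAdjacent >= 0, rgAdjacent <= 1)
  structure(list(nSows = as.integer(nSows), nMarkers = as.integer(nMarkers),
                 nChromosomes = as.integer(nChromosomes),
                 markerSpacingBp = as.integer(markerSpacingBp),
                 mafRange = mafRange, ldRho = ldRho, nQtl = as.integer(nQtl),
                 h2ByParity = h2ByParity, rgAdjacent = rgAdjacent,
                 incidenceByParity = incidenceByParity,
                 cullOtherFactor = cullOtherFactor, nHerds = as.integer(nHerds),
                 nYears = as.integer(nYears), hyqSd = hyqSd,
                 missingSireFrac = missingSireFrac,
                 nSires = as.integer(nSires), nDams = as.integer(nDams),
                 seed = as.integer(seed)),
            class = "SimScenario")
}

# haplotype matrix (nHap x p) from a first-order Markov chain along each
# chromosome: stationary frequency p_k per marker, adjacent-allele
# correlation rho (conditional probabilities clamped to [0,1], so the
# realized correlation can fall slightly short when frequencies differ)
.markovHaplotypes <- function(nHap, freq, chromEnds, rho) {
  p <- length(freq)
  H <- matrix(0L, nHap, p)
  start <- 1L
  for (end in chromEnds) {
    H[, start] <- rbinom(nHap, 1L, freq[start])
    if (end > start) for (j in (start + 1L):end) {
      pj <- freq[j]; pk <- freq[j - 1L]
      shift <- rho * sqrt(pj * (1 - pj) / (pk * (1 - pk)))
      pcond <- pmin(1, pmax(0, pj + shift * (H[, j - 1L] - pk)))
      H[, j] <- rbinom(nHap, 1L, pcond)
    }
    start <- end + 1L
  }
  H
}

.scenarioMap <- function(scenario) {
  perChrom <- rep(scenario$nMarkers %/% scenario$nChromosomes,
                  scenario$nChromosomes)
  extra <- scenario$nMarkers - sum(perChrom)
  if (extra > 0) perChrom[seq_len(extra)] <- perChrom[seq_len(extra)] + 1L
  chrom <- rep(seq_len(scenario$nChromosomes), perChrom)
  pos <- unlist(lapply(perChrom, function(k)
    seq(0L, by = scenario$markerSpacingBp, length.out = k)))
  data.frame(marker = sprintf("snp%05d", seq_len(scenario$nMarkers)),
             chrom = as.character(chrom), pos = as.integer(pos))
}

#' Simulate LD-structured genotypes
#'
#' Haplotypes follow a first-order Markov chain along each chromosome with
#' adjacent-allele correlation \code{ldRho} and stationary frequencies drawn
#' from \code{mafRange}; doses are the sum of two independent haplotypes.
#' Markers sit on a uniform grid (default 1 per 25 kb).
#'
#' @param scenario a \code{\link{simScenario}}.
#' @param nInd number of individuals (default \code{scenario$nSows}).
#' @param ids individual ids.
#' @param returnHaplotypes also return the two haplotype matrices (needed
#'   for gene dropping).
#' @return a \linkS4class{GenotypeData}; with \code{returnHaplotypes}, a
#'   list \code{(genotypes, hap1, hap2)}.
#' @export
simulateGenotypes <- function(scenario, nInd = scenario$nSows,
                              ids = sprintf("sow%05d", seq_len(nInd)),
                              returnHaplotypes = FALSE) {
  map <- .scenarioMap(scenario)
  freq <- runif(scenario$nMarkers, scenario$mafRange[1L], scenario$mafRange[2L])
  chromEnds <- cumsum(table(factor(map$chrom, levels = unique(map$chrom))))
  h1 <- .markovHaplotypes(nInd, freq, chromEnds, scenario$ldRho)
  h2 <- .markovHaplotypes(nInd, freq, chromEnds, scenario$ldRho)
  geno <- genotypeData(h1 + h2, map, ids = ids)
  if (returnHaplotypes) list(genotypes = geno, hap1 = h1, hap2 = h2) else geno
}

#' Simulate a sow pedigree
#'
#' Founder sires and dams (unrelated), sows assigned a random sire and dam.
#'
#' @param scenario a \code{\link{simScenario}}.
#' @param sowIds sow identifiers.
#' @return data.frame with columns \code{id}, \code{sire}, \code{dam};
#'   founders first with NA parents.
#' @export
simulatePedigree <- function(scenario, sowIds = sprintf("sow%05d",
                                                        seq_len(scenario$nSows))) {
  sires <- sprintf("sire%04d", seq_len(scenario$nSires))
  dams <- sprintf("dam%04d", seq_len(scenario$nDams))
  rbind(data.frame(id = c(sires, dams), sire = NA_character_,
                   dam = NA_character_),
        data.frame(id = sowIds,
                   sire = sample(sires, length(sowIds), replace = TRUE),
                   dam = sample(dams, length(sowIds), replace = TRUE)))
}

#' Gene dropping through a pedigree
#'
#' Transmits founder haplotypes to descendants: each gamete copies one of
#' the parent's two haplotypes, switching at crossovers placed as a Poisson
#' process along each chromosome (1 cM/Mb).
#'
#' @param founders list \code{(genotypes, hap1, hap2)} from
#'   \code{simulateGenotypes(..., returnHaplotypes = TRUE)} for the founder
#'   individuals, whose ids must match the pedigree's founders.
#' @param pedigree data.frame \code{id, sire, dam}; founders (NA parents)
#'   must be in \code{founders}.
#' @return list \code{(genotypes, hap1, hap2)} for all pedigree members.
#' @export
geneDrop <- function(founders, pedigree) {
  map <- founders$genotypes@map
  p <- nrow(map)
  chromIdx <- split(seq_len(p), factor(map$chrom, levels = unique(map$chrom)))
  ids <- as.character(pedigree$id)
  n <- length(ids)
  H1 <- matrix(0L, n, p); H2 <- matrix(0L, n, p)
  fid <- founders$genotypes@ids
  pos <- setNames(seq_len(n), ids)
  gamete <- function(h_a, h_b) {
    g <- integer(p)
    for (idx in chromIdx) {
      lenMb <- (map$pos[idx[length(idx)]] - map$pos[idx[1L]]) / 1e6
      ncross <- rpois(1L, lenMb / 100)
      cur <- sample(1:2, 1L)
      if (ncross == 0L) {
        g[idx] <- if (cur == 1L) h_a[idx] else h_b[idx]
      } else {
        breaks <- sort(sample(idx[-1L], min(ncross, length(idx) - 1L)))
        segs <- split(idx, findInterval(idx, breaks))
        for (s in segs) {
          g[s] <- if (cur == 1L) h_a[s] else h_b[s]
          cur <- 3L - cur
        }
      }
    }
    g
  }
  for (i in seq_len(n)) {
    s <- pedigree$sire[i]; d <- pedigree$dam[i]
    if (is.na(s) && is.na(d)) {
      j <- match(ids[i], fid)
      if (is.na(j)) stop("founder ", ids[i], " has no genotypes")
      H1[i, ] <- founders$hap1[j, ]
      H2[i, ] <- founders$hap2[j, ]
    } else {
      si <- pos[[s]]; di <- pos[[d]]
      H1[i, ] <- gamete(H1[si, ], H2[si, ])
      H2[i, ] <- gamete(H1[di, ], H2[di, ])
    }
  }
  list(genotypes = genotypeData(H1 + H2, map, ids = ids), hap1 = H1, hap2 = H2)
}

# AR(1) marker effects across parities: corr(beta_k, beta_l) = rg^|k-l|.
# Innovations are orthogonalized against the previous parity's effects so the
# sample adjacent-parity correlation equals rg (not just in expectation).
.parityEffects <- function(nQtl, nParity, rg) {
  if (nQtl < 4L) {  # too few QTL to orthogonalize; plain AR(1)
    B <- matrix(0, nQtl, nParity)
    B[, 1L] <- rnorm(nQtl)
    if (nParity > 1L) for (j in 2:nParity)
      B[, j] <- rg * B[, j - 1L] + sqrt(1 - rg^2) * rnorm(nQtl)
    return(B)
  }
  std <- function(x) as.numeric(scale(x))
  B <- matrix(0, nQtl, nParity)
  B[, 1L] <- std(rnorm(nQtl))
  if (nParity > 1L) for (j in 2:nParity) {
    v <- rnorm(nQtl)
    v <- std(residuals(lm(v ~ B[, j - 1L])))
    B[, j] <- rg * B[, j - 1L] + sqrt(1 - rg^2) * v
  }
  B
}

#' Simulate multi-parity prolapse records
#'
#' Liability-threshold data generator.  Per parity j, each sow's liability
#' is \eqn{l_{ij} = g_{ij} + hyq_{ij} + e_{ij}} with genetic values from a
#' sparse set of QTL whose effects are correlated across parities
#' (AR(1) with parameter \code{rgAdjacent}), scaled so the realized
#' liability heritability matches \code{h2ByParity}.  A sow develops
#' prolapse in the first parity where her liability exceeds that parity's
#' threshold (set at the empirical quantile matching
#' \code{incidenceByParity} among sows at risk); other-reason culling is an
#' independent per-parity hazard of \code{cullOtherFactor} times the
#' prolapse incidence.  Removed sows generate no later parity records.
#'
#' @param genotypes sow \linkS4class{GenotypeData}.
#' @param scenario a \code{\link{simScenario}}.
#' @param pedigree optional pedigree data.frame supplying sire/dam ids.
#' @return list with \code{records} (sow record data.frame) and
#'   \code{truth} (QTL ids, per-parity scaled effects, liabilities, HYQ
#'   effects, realized heritabilities and genetic-correlation matrix, and
#'   per-parity case labels).
#' @export
simulatePopRecords <- function(genotypes, scenario, pedigree = NULL) {
  n <- length(genotypes@ids)
  nPar <- 6L
  M <- sweep(genotypes@dose, 2L, colMeans(genotypes@dose), "-")
  qtl <- sort(sample(ncol(M), scenario$nQtl))
  Braw <- .parityEffects(scenario$nQtl, nPar, scenario$rgAdjacent)
  h2 <- scenario$h2ByParity[as.character(seq_len(nPar))]
  G <- matrix(0, n, nPar)
  B <- matrix(0, scenario$nQtl, nPar)
  for (j in seq_len(nPar)) {
    g <- M[, qtl, drop = FALSE] %*% Braw[, j]
    sc <- if (h2[j] > 0) sqrt(h2[j] / max(var(as.numeric(g)), 1e-12)) else 0
    B[, j] <- Braw[, j] * sc
    G[, j] <- g * sc
  }
  E <- sapply(seq_len(nPar), function(j) rnorm(n, 0, sqrt(1 - h2[j])))

  farm <- sprintf("farm%d", sample(scenario$nHerds, n, replace = TRUE))
  entry <- as.Date("2015-01-01") +
    sample(0:(scenario$nYears * 365L - 1L), n, replace = TRUE)
  hyqEff <- new.env(parent = emptyenv())
  hyqValue <- function(labels) {
    vapply(labels, function(lb) {
      if (!exists(lb, envir = hyqEff, inherits = FALSE))
        assign(lb, rnorm(1L, 0, scenario$hyqSd), envir = hyqEff)
      get(lb, envir = hyqEff)
    }, 0, USE.NAMES = FALSE)
  }

  inc <- scenario$incidenceByParity[as.character(seq_len(nPar))]
  atRisk <- rep(TRUE, n)
  insem <- entry
  rows <- vector("list", nPar)
  removal <- data.frame(parity = rep(NA_integer_, n), reason = "NONE",
                        date = as.Date(NA), died = FALSE,
                        stringsAsFactors = FALSE)
  liab <- matrix(NA_real_, n, nPar)
  popCase <- matrix(FALSE, n, nPar)
  for (j in seq_len(nPar)) {
    idx <- which(atRisk)
    if (!length(idx)) break
    lt <- as.POSIXlt(insem[idx])
    hyqLab <- sprintf("%s_%d_Q%d", farm[idx], lt$year + 1900L,
                      (lt$mon %/% 3L) + 1L)
    l <- G[idx, j] + hyqValue(hyqLab) + E[idx, j]
    liab[idx, j] <- l
    thr <- quantile(l, 1 - inc[j], names = FALSE, type = 7)
    pop <- l > thr
    popCase[idx, j] <- pop
    pOther <- min(0.9, scenario$cullOtherFactor * inc[j])
    other <- !pop & runif(length(idx)) < pOther
    farrow <- insem[idx] + 113L + sample(0:3, length(idx), replace = TRUE)
    beforeFarrow <- runif(length(idx)) < 0.4
    rmDate <- as.Date(ifelse(beforeFarrow, insem[idx] + 80L, farrow + 20L),
                      origin = "1970-01-01")
    farrowRec <- farrow
    farrowRec[(pop | other) & beforeFarrow] <- NA
    removed <- pop | other
    removal$parity[idx[removed]] <- j
    removal$reason[idx[pop]] <- "POP"
    removal$reason[idx[other & !pop]] <- "OTHER"
    removal$date[idx[removed]] <- rmDate[removed]
    removal$died[idx[removed]] <- runif(sum(removed)) < 0.2
    rows[[j]] <- data.frame(
      sow_id = genotypes@ids[idx], farm = farm[idx], parity = j,
      insem_date = insem[idx], farrow_date = farrowRec,
      removal_date = as.Date(ifelse(removed, rmDate, NA), origin = "1970-01-01"),
      removal_parity = ifelse(removed, j, NA_integer_),
      removal_reason = ifelse(pop, "POP", ifelse(other, "OTHER", "NONE")),
      total_born = rpois(length(idx), 14L),
      sire = NA_character_, dam = NA_character_,
      died = removal$died[idx], stringsAsFactors = FALSE)
    atRisk[idx[removed]] <- FALSE
    insem[idx] <- farrow + 152L  # wean + re-service: next parity
  }
  records <- do.call(rbind, rows)
  records <- records[order(records$sow_id, records$parity), ]
  rownames(records) <- NULL

  # removal metadata lives on every record of the sow; reason on the removal
  # parity only (earlier records of a removed sow keep NONE)
  recRm <- !is.na(records$removal_parity) &
    records$parity == records$removal_parity
  records$removal_date[!recRm] <- NA
  records$removal_parity[!recRm] <- NA_integer_
  records$removal_reason[!recRm] <- "NONE"
  records$died[!recRm] <- FALSE

  if (!is.null(pedigree)) {
    m <- match(records$sow_id, pedigree$id)
    records$sire <- pedigree$sire[m]
    records$dam <- pedigree$dam[m]
  } else {
    records$sire <- sprintf("sire%04d",
                            sample(scenario$nSires, nrow(records), replace = TRUE))
    records$dam <- sprintf("dam%04d",
                           sample(scenario$nDams, nrow(records), replace = TRUE))
    # parents constant within sow
    first <- !duplicated(records$sow_id)
    records$sire <- records$sire[first][match(records$sow_id,
                                              records$sow_id[first])]
    records$dam <- records$dam[first][match(records$sow_id,
                                            records$sow_id[first])]
  }
  blank <- records$sow_id %in%
    sample(genotypes@ids, round(scenario$missingSireFrac * n))
  records$sire[blank] <- NA

  realizedH2 <- vapply(seq_len(nPar), function(j)
    var(G[, j]) / (var(G[, j]) + var(E[, j])), 0)
  realizedRg <- suppressWarnings(cor(G))
  dimnames(realizedRg) <- list(seq_len(nPar), seq_len(nPar))
  truth <- list(qtl = genotypes@map$marker[qtl], qtlIndex = qtl, effects = B,
                liabilities = liab, popCase = popCase,
                realizedH2 = setNames(realizedH2, seq_len(nPar)),
                realizedRg = realizedRg,
                hyqEffects = as.list(hyqEff),
                warning = if (min(inc) * n < 10)
                  "fewer than 10 expected cases in at least one parity" else NULL)
  list(records = records, truth = truth)
}

#' Summarize simulation ground truth
#'
#' @param truth the \code{truth} component of
#'   \code{\link{simulatePopRecords}} output.
#' @return list with realized per-parity heritabilities, the realized
#'   genetic-correlation matrix, QTL window identities and per-QTL
#'   liability-variance shares (parity 2).
#' @export
truthReport <- function(truth) {
  list(realizedH2 = truth$realizedH2, realizedRg = truth$realizedRg,
       qtl = truth$qtl, nCasesByParity = colSums(truth$popCase))
}

#' Simulate a single-parity binary trait for recovery benchmarks
#'
#' Probit-liability trait on an existing genotype set: \code{nQtl} causal
#' markers, liability heritability \code{h2}, HYQ-style group effects, and
#' a case fraction set by thresholding at the empirical liability quantile.
#' The default case fraction of 0.5 maximizes the information per record,
#' the standard choice for parameter-recovery benchmarks of binary-trait
#' models.
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param nQtl causal markers.
#' @param h2 liability heritability.
#' @param caseFraction fraction of cases (default 0.5).
#' @param nHyq number of contemporary groups.
#' @param hyqSd sd of group effects.
#' @param qtlIndex optional fixed causal marker indices.
#' @param effects optional fixed raw effects (length \code{nQtl}).
#' @return list with \code{dataset} (a \linkS4class{TraitData}),
#'   \code{qtlIndex}, \code{beta} (scaled effects), \code{realizedH2},
#'   \code{liability}.
#' @export
simulateBinaryTrait <- function(genotypes, nQtl = 20L, h2 = 0.4,
                                caseFraction = 0.5, nHyq = 20L, hyqSd = 0.2,
                                qtlIndex = NULL, effects = NULL) {
  n <- length(genotypes@ids)
  M <- sweep(genotypes@dose, 2L, colMeans(genotypes@dose), "-")
  if (is.null(qtlIndex)) qtlIndex <- sort(sample(ncol(M), nQtl))
  if (is.null(effects)) effects <- rnorm(length(qtlIndex))
  g <- as.numeric(M[, qtlIndex, drop = FALSE] %*% effects)
  sc <- if (h2 > 0) sqrt(h2 / max(var(g), 1e-12)) else 0
  g <- g * sc
  hyq <- factor(sprintf("g%02d", sample(nHyq, n, replace = TRUE)))
  hyqEff <- rnorm(nHyq, 0, hyqSd)[as.integer(hyq)]
  e <- rnorm(n, 0, sqrt(max(1 - h2, 1e-12)))
  l <- g + hyqEff + e
  thr <- quantile(l, 1 - caseFraction, names = FALSE)
  ds <- new("TraitData", sowId = genotypes@ids,
            phenotype = as.integer(l > thr), hyq = hyq,
            parity = rep(2L, n), tag = "SIMULATED")
  list(dataset = ds, qtlIndex = qtlIndex, beta = effects * sc,
       realizedH2 = var(g) / (var(g) + var(e)), liability = l)
}

#' Simulate a trait with an engineered window share
#'
#' Adds a single-window QTL cluster on top of a polygenic background and
#' rescales it so that the window carries exactly \code{targetShare} of the
#' realized genetic variance, for genome-scan calibration.
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param windows a \linkS4class{WindowMap} on the genotypes.
#' @param targetWindow window label (e.g. \code{"3_4"}); defaults to a
#'   central window.
#' @param targetShare the window's share of total genetic variance.
#' @param nWindowQtl QTL inside the target window (default 1: a single
#'   causal variant carries the window's share).
#' @param nBgQtl background QTL (placed off the target chromosome).
#' @param h2 liability heritability.
#' @param caseFraction fraction of cases.
#' @param nHyq,hyqSd contemporary-group structure.
#' @param windowQtlIndex optional fixed marker index (or indices) for the
#'   window QTL; default draws central markers of the window, keeping the
#'   signal's linkage disequilibrium inside the window.
#' @return as \code{\link{simulateBinaryTrait}}, plus \code{targetWindow}
#'   and \code{realizedShare}.
#' @export
simulateWindowTrait <- function(genotypes, windows, targetWindow = NULL,
                                targetShare = 0.02, nWindowQtl = 1L,
                                nBgQtl = 40L, h2 = 0.4, caseFraction = 0.5,
                                nHyq = 20L, hyqSd = 0.2,
                                windowQtlIndex = NULL) {
  tab <- windows@table
  if (is.null(targetWindow)) {
    counts <- table(tab$window)
    targetWindow <- names(counts)[which.max(counts >= nWindowQtl)]
  }
  inWin <- which(tab$window == targetWindow)
  if (length(inWin) < nWindowQtl)
    stop("target window holds fewer than nWindowQtl markers")
  targetChrom <- tab$chrom[inWin[1L]]
  M <- sweep(genotypes@dose, 2L, colMeans(genotypes@dose), "-")
  if (is.null(windowQtlIndex)) {
    mid <- ceiling(length(inWin) / 2)
    pick <- unique(pmin(pmax(mid + seq_len(nWindowQtl) - 1L -
                               (nWindowQtl - 1L) %/% 2L, 1L),
                        length(inWin)))
    winQtl <- inWin[pick]
  } else {
    winQtl <- windowQtlIndex
    if (!all(winQtl %in% inWin))
      stop("windowQtlIndex outside the target window")
    nWindowQtl <- length(winQtl)
  }
  bgPool <- which(tab$chrom != targetChrom)
  bgQtl <- sort(sample(bgPool, nBgQtl))
  gw <- as.numeric(M[, winQtl, drop = FALSE] %*% rnorm(nWindowQtl))
  bw <- rnorm(nBgQtl)
  gb <- as.numeric(M[, bgQtl, drop = FALSE] %*% bw)
  # scale the window cluster so var(c gw) / var(gb + c gw) = targetShare
  a <- var(gw); b <- var(gb); d <- cov(gw, gb); s <- targetShare
  cc <- (2 * s * d + sqrt(4 * s^2 * d^2 + 4 * a * (1 - s) * s * b)) /
    (2 * a * (1 - s))
  g <- gb + cc * gw
  share <- var(cc * gw) / var(g)
  n <- length(genotypes@ids)
  sc <- sqrt(h2 / max(var(g), 1e-12))
  g <- g * sc
  hyq <- factor(sprintf("g%02d", sample(nHyq, n, replace = TRUE)))
  hyqEff <- rnorm(nHyq, 0, hyqSd)[as.integer(hyq)]
  e <- rnorm(n, 0, sqrt(max(1 - h2, 1e-12)))
  l <- g + hyqEff + e
  thr <- quantile(l, 1 - caseFraction, names = FALSE)
  ds <- new("TraitData", sowId = genotypes@ids,
            phenotype = as.integer(l > thr), hyq = hyq,
            parity = rep(2L, n), tag = "SIMULATED")
  list(dataset = ds, qtlIndex = c(winQtl, bgQtl),
       realizedH2 = var(g) / (var(g) + var(e)),
       targetWindow = targetWindow, realizedShare = share, liability = l)
}

#' Simulate two genetically correlated Gaussian traits
#'
#' Shared/specific decomposition of marker effects giving genetic
#' correlation \code{rg} between two traits recorded on partially
#' overlapping sets of individuals -- the benchmark for the bivariate
#' linear model.  Gaussian phenotypes are used because the bivariate model
#' is linear.
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param nQtl causal markers (shared positions).
#' @param h2 heritability of each trait.
#' @param rg genetic correlation.
#' @param nPerTrait individuals recorded per trait.
#' @param overlap fraction of each trait's individuals recorded on both.
#' @param nHyq,hyqSd contemporary-group structure.
#' @return list with \code{dataset1}, \code{dataset2} (data.frames with
#'   \code{sowId}, \code{phenotype}, \code{hyq}), \code{realizedRg}.
#' @export
simulateBivariateTraits <- function(genotypes, nQtl = 30L, h2 = 0.3,
                                    rg = 0.7, nPerTrait = 2000L,
                                    overlap = 0.5, nHyq = 20L, hyqSd = 0.2) {
  n <- length(genotypes@ids)
  nBoth <- round(overlap * nPerTrait)
  need <- 2L * nPerTrait - nBoth
  if (need > n) stop("not enough genotyped individuals for the design")
  picks <- sample(n, need)
  both <- picks[seq_len(nBoth)]
  only1 <- picks[nBoth + seq_len(nPerTrait - nBoth)]
  only2 <- picks[nPerTrait + seq_len(nPerTrait - nBoth)]
  M <- sweep(genotypes@dose, 2L, colMeans(genotypes@dose), "-")
  qtl <- sort(sample(ncol(M), nQtl))
  u <- rnorm(nQtl)
  b1 <- u
  b2 <- rg * u + sqrt(1 - rg^2) * rnorm(nQtl)
  g1 <- as.numeric(M[, qtl, drop = FALSE] %*% b1)
  g2 <- as.numeric(M[, qtl, drop = FALSE] %*% b2)
  # condition the realized genetic correlation on the target: replace g2 by
  # the rg-mixture of standardized g1 and the part of g2 orthogonal to g1
  # (both stay in the span of the QTL doses)
  g1 <- as.numeric(scale(g1))
  r2 <- as.numeric(scale(residuals(lm(g2 ~ g1))))
  g2 <- rg * g1 + sqrt(1 - rg^2) * r2
  g1 <- g1 * sqrt(h2)
  g2 <- g2 * sqrt(h2 / var(g2))
  hyq <- sprintf("g%02d", sample(nHyq, n, replace = TRUE))
  hyqEff <- rnorm(nHyq, 0, hyqSd)[as.integer(factor(hyq))]
  y1 <- g1 + hyqEff + rnorm(n, 0, sqrt(1 - h2))
  y2 <- g2 + hyqEff + rnorm(n, 0, sqrt(1 - h2))
  set1 <- sort(c(both, only1)); set2 <- sort(c(both, only2))
  list(dataset1 = data.frame(sowId = genotypes@ids[set1],
                             phenotype = y1[set1], hyq = hyq[set1],
                             stringsAsFactors = FALSE),
       dataset2 = data.frame(sowId = genotypes@ids[set2],
                             phenotype = y2[set2], hyq = hyq[set2],
                             stringsAsFactors = FALSE),
       realizedRg = cor(g1, g2), qtlIndex = qtl)
}
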