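## R-side model fitting: builds designs, sets priors, dispatches to the
## compiled Gibbs kernels and wraps results as PosteriorChain objects.

#' MCMC chain settings
#'
#' Defaults follow the package's GWAS convention (50,000 iterations, 5,000
#' burn-in, save every 100th); bivariate genetic-correlation runs use
#' \code{chainConfig(120000, 20000, 100)}.
#'
#' @param nIter total iterations.
#' @param burnIn discarded iterations.
#' @param thin saving interval.
#' @param seed RNG seed.
#' @param pi prior exclusion probability; \code{NA} means estimate (Bayes-Cpi).
#' @return a \linkS4class{ChainConfig}.
#' @export
chainConfig <- function(nIter = 50000L, burnIn = 5000L, thin = 100L,
                        seed = 1L, pi = NA_real_) {
  new("ChainConfig", nIter = as.integer(nIter), burnIn = as.integer(burnIn),
      thin = as.integer(thin), seed = as.integer(seed), pi = as.numeric(pi))
}

# full-rank dummy design: HYQ levels (no intercept; absorbs the mean) plus,
# optionally, parity contrasts (first analysed parity as reference)
.fixedDesign <- function(dataset, includeParity = FALSE) {
  hyq <- droplevels(dataset@hyq)
  counts <- table(hyq)
  if (any(counts == 0))
    stop("empty HYQ level: ", paste(names(counts)[counts == 0], collapse = ", "))
  X <- stats::model.matrix(~ 0 + hyq)
  colnames(X) <- paste0("HYQ:", levels(hyq))
  if (includeParity) {
    par <- factor(dataset@parity)
    if (nlevels(par) > 1L) {
      P <- stats::model.matrix(~ par)[, -1L, drop = FALSE]
      colnames(P) <- paste0("parity:", levels(par)[-1L])
      X <- cbind(X, P)
    }
  }
  X
}

# doses for the dataset's sows, centred by twice the allele frequency
.alignedDoses <- function(dataset, genotypes, center = TRUE) {
  miss <- setdiff(dataset@sowId, genotypes@ids)
  if (length(miss))
    stop("sows without genotypes: ", paste(head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) sprintf(" (+%d more)", length(miss) - 5L) else "")
  genotypes <- imputeMean(genotypes)
  M <- genotypes@dose[match(dataset@sowId, genotypes@ids), , drop = FALSE]
  if (center) M <- sweep(M, 2L, colMeans(M), "-")
  M
}

# scaled-inverse-chi-square scale for marker-effect variance from a prior h2
.markerScale <- function(M, priorH2, pi, nu, varE = 1) {
  varG <- priorH2 / (1 - priorH2) * varE
  sum2pq <- sum(apply(M, 2L, var)) # after centring, ~ sum 2 p q under HWE
  varBeta <- varG / ((1 - pi) * max(sum2pq, 1e-8))
  varBeta * (nu - 2) / nu
}

# accept a TraitData or a data.frame(sowId, phenotype, hyq); phenotypes may
# be continuous for linear models
.asTraitLike <- function(x) {
  if (is(x, "TraitData"))
    return(list(sowId = x@sowId, phenotype = as.numeric(x@phenotype),
                hyq = x@hyq, tag = x@tag))
  if (is.data.frame(x) && all(c("sowId", "phenotype", "hyq") %in% names(x)))
    return(list(sowId = as.character(x$sowId),
                phenotype = as.numeric(x$phenotype),
                hyq = factor(x$hyq), tag = "DATAFRAME"))
  stop("expected a TraitData or a data.frame with sowId, phenotype, hyq")
}

.checkBinary <- function(dataset) {
  y <- dataset@phenotype
  if (all(y == 0L) || all(y == 1L))
    stop("no liability threshold identifiable: phenotype has a single class")
  y
}

#' Fit a univariate threshold (probit) marker-effects model
#'
#' Gibbs sampler with latent-liability augmentation for
#' \deqn{Probit(y) = HYQ + \sum_n m_n \beta_n \delta_n + e,\quad e \sim N(0,1).}
#' Priors on marker effects: \code{"BayesB"} (point mass at zero with
#' probability \code{pi}, marker-specific variances), \code{"BayesC"}
#' (point mass, common variance; with \code{pi = NA} the Bayes-Cpi sampler
#' estimates \code{pi}), or \code{"BayesC0"} (all markers in, common
#' variance; equivalent to GBLUP).  Residual variance is fixed at 1.
#'
#' @param dataset a \linkS4class{TraitData}.
#' @param genotypes a \linkS4class{GenotypeData} covering the dataset's sows.
#' @param chain a \linkS4class{ChainConfig}.
#' @param prior marker-effect prior.
#' @param includeParity add removal parity as a fixed effect (across-parity
#'   analyses).
#' @param priorH2 prior liability-scale heritability used to scale the
#'   marker-effect variance prior (default 0.3).
#' @param nu scaled-inverse-chi-square degrees of freedom (default 4).
#' @param fixedPriorVar variance of the weak normal prior on fixed effects
#'   (default 4, i.e. sd 2 on the latent scale).  Threshold models need it
#'   to anchor contemporary groups whose outcomes are all 0 or all 1; set
#'   to \code{Inf} for a flat prior.
#' @param saveLiabilities keep saved latent liabilities (for diagnostics).
#' @return a \linkS4class{PosteriorChain} of model \code{"threshold_marker"}.
#' @export
fitThresholdMarkerModel <- function(dataset, genotypes, chain = chainConfig(),
                                    prior = c("BayesB", "BayesC", "BayesC0"),
                                    includeParity = FALSE, priorH2 = 0.3,
                                    nu = 4, fixedPriorVar = 4,
                                    saveLiabilities = FALSE) {
  prior <- match.arg(prior)
  y <- .checkBinary(dataset)
  X <- .fixedDesign(dataset, includeParity)
  M <- .alignedDoses(dataset, genotypes)
  pi0 <- chain@pi
  estimate <- is.na(pi0)
  if (estimate && prior == "BayesB")
    stop("Bayes-B needs a fixed pi; estimate it first with estimatePi()")
  if (estimate) pi0 <- 0.5
  if (prior == "BayesC0") { pi0 <- 0; estimate <- FALSE }
  prior_type <- match(prior, c("BayesC0", "BayesC", "BayesB")) - 1L
  scale_var <- .markerScale(M, priorH2, pi0, nu)
  set.seed(chain@seed)
  res <- .cpp_threshold_marker(as.integer(y), X, M, prior_type, pi0, estimate,
                               chain@nIter, chain@burnIn, chain@thin, nu,
                               scale_var, fixedPriorVar, saveLiabilities)
  samples <- list(effects = res$effects, fixed = res$fixed,
                  geneticVar = as.numeric(res$genvar),
                  pi = as.numeric(res$pi), sigma2Marker = as.numeric(res$sigma2))
  if (saveLiabilities) samples$liabilities <- res$liab
  colnames(samples$effects) <- genotypes@map$marker
  colnames(samples$fixed) <- colnames(X)
  new("PosteriorChain", model = "threshold_marker", samples = samples,
      markerIds = genotypes@map$marker, ids = dataset@sowId, config = chain,
      info = list(link = "PROBIT", prior = prior, pi = pi0,
                  estimatePi = estimate, varE = 1,
                  pip = setNames(as.numeric(res$pip), genotypes@map$marker),
                  tag = dataset@tag))
}

#' Estimate the prior exclusion probability with Bayes-Cpi
#'
#' Runs the threshold Bayes-C sampler with a uniform prior on \eqn{\pi}
#' (the probability that a marker is excluded) and returns its posterior
#' mean, to be plugged into a Bayes-B genome scan.
#'
#' @inheritParams fitThresholdMarkerModel
#' @return list with \code{pi} (posterior mean) and \code{chain}
#'   (the \linkS4class{PosteriorChain}).
#' @export
estimatePi <- function(dataset, genotypes, chain = chainConfig(),
                       includeParity = FALSE, priorH2 = 0.3, nu = 4) {
  chain@pi <- NA_real_
  fit <- fitThresholdMarkerModel(dataset, genotypes, chain, prior = "BayesC",
                                 includeParity = includeParity,
                                 priorH2 = priorH2, nu = nu)
  list(pi = mean(fit@samples$pi), chain = fit)
}

#' Fit a bivariate linear Bayes-C0 marker model
#'
#' For the same binary trait expressed in two parities: phenotypes are
#' treated as 0/1 on the linear scale, every marker carries a bivariate
#' effect \eqn{(\beta_k, \beta_l) \sim MVN(0, G_0)} with 2x2 inverse-Wishart
#' updates for \eqn{G_0} and the residual covariance R.  Sows observed in
#' only one parity have the other trait imputed from the residual
#' conditional implied by R (data augmentation); \code{completeCase = TRUE}
#' restricts to sows observed in both.  Each saved sample stores the 2x2
#' genome-wide genetic covariance of the marker-based genomic values, from
#' which \code{\link{geneticCorrelation}} builds the posterior.
#'
#' @param dataset1,dataset2 \linkS4class{TraitData} objects for the two
#'   parities.
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param chain a \linkS4class{ChainConfig} (convention: 120,000 / 20,000 /
#'   100 at full scale).
#' @param nu inverse-Wishart degrees of freedom (default 4).
#' @param priorVar prior diagonal for the G and R scale matrices.
#' @param completeCase use only sows phenotyped in both parities.
#' @return a \linkS4class{PosteriorChain} of model \code{"bivariate_linear"}.
#' @export
fitBivariateLinear <- function(dataset1, dataset2, genotypes,
                               chain = chainConfig(120000L, 20000L, 100L),
                               nu = 4, priorVar = 0.05, completeCase = FALSE) {
  d1 <- .asTraitLike(dataset1)
  d2 <- .asTraitLike(dataset2)
  ids <- union(d1$sowId, d2$sowId)
  if (completeCase) {
    ids <- intersect(d1$sowId, d2$sowId)
    if (length(ids) < 2L)
      stop("fewer than 2 sows with both phenotypes in complete-case mode")
  }
  miss <- setdiff(ids, genotypes@ids)
  if (length(miss))
    stop("sows without genotypes: ", paste(head(miss, 5L), collapse = ", "))
  n <- length(ids)
  Y <- matrix(0, n, 2L)
  obs <- matrix(0L, n, 2L)
  k1 <- d1$sowId %in% ids; k2 <- d2$sowId %in% ids
  i1 <- match(d1$sowId[k1], ids)
  i2 <- match(d2$sowId[k2], ids)
  Y[i1, 1L] <- d1$phenotype[k1]; obs[i1, 1L] <- 1L
  Y[i2, 2L] <- d2$phenotype[k2]; obs[i2, 2L] <- 1L

  # trait-specific HYQ designs on the union (zero rows for unobserved sows)
  mkX <- function(ds, keep, rows) {
    hyq <- droplevels(factor(as.character(ds$hyq)[keep]))
    X <- matrix(0, n, nlevels(hyq))
    X[cbind(rows, as.integer(hyq))] <- 1
    colnames(X) <- paste0("HYQ:", levels(hyq))
    X
  }
  X1 <- mkX(d1, k1, i1)
  X2 <- mkX(d2, k2, i2)
  # guard all-zero columns (cannot happen by construction, but keep rank)
  geno <- imputeMean(genotypes)
  M <- geno@dose[match(ids, geno@ids), , drop = FALSE]
  M <- sweep(M, 2L, colMeans(M), "-")
  p <- ncol(M)
  sum2pq <- sum(apply(M, 2L, var))
  Sg <- diag(2) * priorVar / max(sum2pq, 1e-8) * (nu - 2) / nu
  Sr <- diag(2) * 0.5
  set.seed(chain@seed)
  res <- .cpp_bivariate_linear(Y, obs, X1, X2, M, chain@nIter, chain@burnIn,
                               chain@thin, nu, Sg, Sr)
  colnames(res$gencov) <- colnames(res$G) <- colnames(res$R) <-
    c("v11", "v12", "v22")
  samples <- list(geneticCov = res$gencov, G0 = res$G, R = res$R)
  new("PosteriorChain", model = "bivariate_linear", samples = samples,
      markerIds = genotypes@map$marker, ids = ids, config = chain,
      info = list(link = "LINEAR", prior = "BayesC0",
                  tags = c(d1$tag, d2$tag),
                  nBoth = sum(obs[, 1L] & obs[, 2L])))
}

#' Fit a threshold animal model with a relationship matrix
#'
#' Latent-liability Gibbs sampler for
#' \deqn{link(y) = Xb + Za + e,\quad a \sim N(0, K\sigma^2_a)}
#' with K a pedigree or genomic relationship matrix.  The liability residual
#' variance is fixed by the link: 1 for \code{"PROBIT"}, \eqn{\pi^2/3} for
#' \code{"LOGIT"} (probit augmentation on the logit residual scale; an
#' approximation to a logistic-residual threshold model).  Breeding values
#' are updated in the eigenbasis of the stabilized K, where their full
#' conditional is diagonal.
#'
#' @param dataset a \linkS4class{TraitData}.
#' @param K a \linkS4class{RelationshipMatrix} covering the dataset ids.
#' @param chain a \linkS4class{ChainConfig}.
#' @param link \code{"PROBIT"} or \code{"LOGIT"}.
#' @param includeParity add removal parity as a fixed effect.
#' @param priorH2 prior heritability for the additive-variance scale.
#' @param nu scaled-inverse-chi-square degrees of freedom.
#' @param fixedPriorVar variance of the weak normal prior on fixed effects
#'   (default 4; \code{Inf} = flat), anchoring all-0/all-1 contemporary
#'   groups on the latent scale.
#' @param stabilize blending weight passed to
#'   \code{\link{stabilizeRelationship}}.
#' @return a \linkS4class{PosteriorChain} of model \code{"animal_threshold"}
#'   whose samples include per-iteration heritability
#'   \eqn{h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_e)}.
#' @export
fitBinaryAnimalModel <- function(dataset, K, chain = chainConfig(),
                                 link = c("PROBIT", "LOGIT"),
                                 includeParity = FALSE, priorH2 = 0.3,
                                 nu = 4, fixedPriorVar = 4,
                                 stabilize = 0.99) {
  link <- match.arg(link)
  y <- .checkBinary(dataset)
  miss <- setdiff(dataset@sowId, K@ids)
  if (length(miss))
    stop("ids missing from relationship matrix: ",
         paste(head(miss, 5L), collapse = ", "))
  X <- .fixedDesign(dataset, includeParity)
  # reject phenotypes constant within every contemporary group
  ph_by <- tapply(y, droplevels(dataset@hyq), function(v) length(unique(v)))
  if (all(ph_by == 1L))
    stop("phenotype is constant within every HYQ cell; no residual contrast")
  Ksub <- stabilizeRelationship(
    new("RelationshipMatrix", ids = dataset@sowId,
        mat = K@mat[match(dataset@sowId, K@ids), match(dataset@sowId, K@ids),
                    drop = FALSE], kind = K@kind),
    weight = stabilize)
  eig <- eigen(Ksub@mat, symmetric = TRUE)
  d <- pmax(eig$values, 1e-8)
  varE <- if (link == "PROBIT") 1 else pi^2 / 3
  scale_a <- priorH2 / (1 - priorH2) * varE * (nu - 2) / nu
  set.seed(chain@seed)
  res <- .cpp_animal_threshold(as.integer(y), X, eig$vectors, d, varE,
                               chain@nIter, chain@burnIn, chain@thin, nu,
                               scale_a, fixedPriorVar, FALSE)
  samples <- list(sigma2A = as.numeric(res$sigma2a), h2 = as.numeric(res$h2),
                  fixed = res$fixed)
  colnames(samples$fixed) <- colnames(X)
  new("PosteriorChain", model = "animal_threshold", samples = samples,
      markerIds = character(0), ids = dataset@sowId, config = chain,
      info = list(link = link, varE = varE, kind = K@kind,
                  ebv = setNames(as.numeric(res$ebv), dataset@sowId),
                  tag = dataset@tag))
}

#' Persist a posterior chain as TSV
#'
#' Writes the scalar and vector sample components (one row per saved sample)
#' to a tab-separated file; matrix components wider than \code{maxCols}
#' columns are skipped.
#'
#' @param chain a \linkS4class{PosteriorChain}.
#' @param path output TSV path.
#' @param maxCols widest matrix component to include (default 50).
#' @return path, invisibly.
#' @export
writeChainTSV <- function(chain, path, maxCols = 50L) {
  keep <- list()
  for (nm in names(chain@samples)) {
    s <- chain@samples[[nm]]
    if (is.numeric(s) && is.null(dim(s))) keep[[nm]] <- s
    else if (is.matrix(s) && ncol(s) <= maxCols) {
      cn <- colnames(s); if (is.null(cn)) cn <- seq_len(ncol(s))
      for (j in seq_len(ncol(s))) keep[[paste0(nm, ".", cn[j])]] <- s[, j]
    }
  }
  write.table(as.data.frame(keep), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
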