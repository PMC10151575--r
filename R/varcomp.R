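## Posterior summaries: heritability by scale, observed-scale conversion,
## genetic-correlation posteriors, HPD intervals.

#' Shortest (highest posterior density) interval
#'
#' The shortest contiguous interval containing \code{ceiling(mass * n)} of
#' the sorted samples.
#'
#' @param samples numeric vector of posterior samples (>= 2 finite values).
#' @param mass interval mass in (0,1), default 0.95.
#' @return named numeric vector \code{c(lower, upper)}.
#' @export
hpdInterval <- function(samples, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0,1)")
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  if (n < 2L) stop("need at least 2 finite samples")
  k <- ceiling(mass * n)
  if (k >= n) return(c(lower = x[1L], upper = x[n]))
  starts <- seq_len(n - k + 1L)
  widths <- x[starts + k - 1L] - x[starts]
  i <- starts[which.min(widths)]
  c(lower = x[i], upper = x[i + k - 1L])
}

#' Heritability summary from a posterior chain
#'
#' Per-sample liability-scale heritability
#' \eqn{h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_e)} with the link's fixed
#' residual variance (1 for probit, \eqn{\pi^2/3} for the logit scale),
#' summarized as posterior mean, sd (reported where REML software reports an
#' SE) and 95% HPD interval.
#'
#' @param chain a \linkS4class{PosteriorChain} from a threshold marker or
#'   animal model (or a numeric vector of additive-variance samples).
#' @param link \code{"PROBIT"} or \code{"LOGIT"}; defaults to the chain's.
#' @param mass HPD mass.
#' @return list with \code{scale}, \code{mean}, \code{sd}, \code{hpd95},
#'   \code{samples}, \code{nSamples}.
#' @export
heritabilityFromChain <- function(chain, link = NULL, mass = 0.95) {
  if (is(chain, "PosteriorChain")) {
    if (is.null(link)) link <- chain@info$link
    va <- switch(chain@model,
                 threshold_marker = chain@samples$geneticVar,
                 animal_threshold = chain@samples$sigma2A,
                 stop("no genetic-variance samples in a ", chain@model, " chain"))
  } else {
    va <- as.numeric(chain)
    if (is.null(link)) link <- "PROBIT"
  }
  if (!length(va)) stop("empty chain")
  ve <- if (identical(link, "LOGIT")) pi^2 / 3 else 1
  h2 <- va / (va + ve)
  list(scale = paste0("UNDERLYING_", link), mean = mean(h2), sd = sd(h2),
       hpd95 = hpdInterval(h2, mass), samples = h2, nSamples = length(h2))
}

#' Liability-to-observed scale heritability conversion
#'
#' Dempster-Lerner transformation for a binary trait with incidence p:
#' \deqn{h^2_{obs} = h^2_{u} \; z^2 / (p (1 - p))}
#' where t is the upper-p standard-normal quantile and z the normal density
#' at t.  The normal-liability z is used irrespective of the scale on which
#' the underlying estimate was obtained.
#'
#' @param h2Underlying heritability on the underlying scale, in [0,1].
#' @param incidence trait incidence in (0,1).
#' @return observed-scale heritability, clipped to [0,1].
#' @export
underlyingToObserved <- function(h2Underlying, incidence) {
  if (any(incidence <= 0) || any(incidence >= 1))
    stop("incidence must be in (0,1)")
  if (any(h2Underlying < 0) || any(h2Underlying > 1))
    stop("h2Underlying must be in [0,1]")
  t <- qnorm(1 - incidence)
  z <- dnorm(t)
  pmin(1, pmax(0, h2Underlying * z^2 / (incidence * (1 - incidence))))
}

#' Genetic-correlation posterior from a bivariate chain
#'
#' Per saved sample, the genome-wide genetic covariance divided by the
#' product of the genome-wide genetic standard deviations; samples with
#' either genetic variance below \code{tol} are dropped and counted.
#'
#' @param chain a bivariate \linkS4class{PosteriorChain} (or an nx3 matrix
#'   of \code{v11, v12, v22} covariance samples).
#' @param mass HPD mass.
#' @param tol variance floor below which a sample is degenerate.
#' @return list with \code{samples}, \code{mean}, \code{hpd95},
#'   \code{nDropped}.
#' @export
geneticCorrelation <- function(chain, mass = 0.95, tol = 1e-12) {
  cv <- if (is(chain, "PosteriorChain")) {
    if (chain@model != "bivariate_linear")
      stop("genetic correlation needs a bivariate chain")
    chain@samples$geneticCov
  } else as.matrix(chain)
  ok <- cv[, 1L] > tol & cv[, 3L] > tol
  if (!any(ok)) stop("all covariance samples degenerate")
  rg <- cv[ok, 2L] / sqrt(cv[ok, 1L] * cv[ok, 3L])
  rg <- pmin(1, pmax(-1, rg))
  list(samples = rg, mean = mean(rg), hpd95 = hpdInterval(rg, mass),
       nDropped = sum(!ok))
}

#' Genetic-parameter summary table
#'
#' Builds a results table in the layout of a between-parity genetic-parameter
#' report: heritabilities (mean, sd, HPD) per analysis and genetic
#' correlations per parity pair.
#'
#' @param h2List named list of \code{heritabilityFromChain} results.
#' @param rgList named list (names like \code{"2_3"}) of
#'   \code{geneticCorrelation} results.
#' @return data.frame with columns \code{analysis}, \code{parameter},
#'   \code{estimate}, \code{sd}, \code{hpd_lower}, \code{hpd_upper},
#'   \code{scale}.
#' @export
geneticParameterTable <- function(h2List = list(), rgList = list()) {
  rows <- list()
  for (nm in names(h2List)) {
    h <- h2List[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      analysis = nm, parameter = "h2", estimate = h$mean, sd = h$sd,
      hpd_lower = h$hpd95[["lower"]], hpd_upper = h$hpd95[["upper"]],
      scale = h$scale)
  }
  for (nm in names(rgList)) {
    r <- rgList[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      analysis = nm, parameter = "rg", estimate = r$mean, sd = sd(r$samples),
      hpd_lower = r$hpd95[["lower"]], hpd_upper = r$hpd95[["upper"]],
      scale = "GENETIC_CORRELATION")
  }
  if (!length(rows))
    return(data.frame(analysis = character(0), parameter = character(0),
                      estimate = numeric(0), sd = numeric(0),
                      hpd_lower = numeric(0), hpd_upper = numeric(0),
                      scale = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
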