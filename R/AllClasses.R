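#' @import methods
#' @importFrom stats var cor cov sd dnorm pnorm qnorm rnorm runif rbinom rpois quantile setNames aggregate model.matrix lm residuals
#' @importFrom utils read.csv write.csv read.table write.table head
#' @useDynLib swinePOP, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Binary trait dataset for one analysis
#'
#' Holds the 0/1 phenotype (culled for pelvic organ prolapse vs other),
#' herd-year-quarter (HYQ) contemporary-group labels and, for the
#' across-parity analysis, the removal-parity label, for one model fit.
#'
#' @slot sowId character vector of sow identifiers (unique).
#' @slot phenotype integer vector of 0/1 outcomes, parallel to \code{sowId}.
#' @slot hyq factor of herd-year-quarter contemporary groups.
#' @slot parity integer vector: removal parity (across-parity analysis) or
#'   the single analysed parity.
#' @slot tag analysis tag, \code{"ACROSS"} or \code{"PARITY_k"}.
#'
#' @export
setClass("TraitData",
  representation(sowId = "character", phenotype = "integer",
                 hyq = "factor", parity = "integer", tag = "character"),
  validity = function(object) {
    n <- length(object@sowId)
    if (length(object@phenotype) != n || length(object@hyq) != n)
      return("sowId, phenotype and hyq must have equal length")
    if (n && !all(object@phenotype %in% 0:1))
      return("phenotype entries must be 0 or 1")
    if (anyDuplicated(object@sowId))
      return("a sow may appear only once per dataset")
    if (n && any(table(droplevels(object@hyq)) < 1))
      return("every HYQ level needs at least one observation")
    TRUE
  })

#' SNP genotypes with a marker map
#'
#' Allele-count (dose) matrix, individuals by markers, entries 0/1/2 with
#' \code{NA} for missing, plus a per-marker map (chromosome, position in bp).
#'
#' @slot ids character vector of individual ids (rownames of \code{dose}).
#' @slot dose numeric matrix, \code{length(ids)} x p, entries in {0,1,2,NA}.
#' @slot map data.frame with columns \code{marker}, \code{chrom}, \code{pos}
#'   (bp, 0-based); positions strictly increasing within chromosome.
#'
#' @export
setClass("GenotypeData",
  representation(ids = "character", dose = "matrix", map = "data.frame"),
  validity = function(object) {
    if (nrow(object@dose) != length(object@ids))
      return("dose must have one row per id")
    if (ncol(object@dose) != nrow(object@map))
      return("map must have one row per marker")
    if (!all(c("marker", "chrom", "pos") %in% names(object@map)))
      return("map needs columns marker, chrom, pos")
    d <- object@dose
    if (length(d) && any(d < 0 | d > 2, na.rm = TRUE))
      return("dose entries must lie in [0, 2] (NA = missing)")
    if (any(object@map$pos < 0))
      return("negative marker position")
    for (ch in unique(object@map$chrom)) {
      p <- object@map$pos[object@map$chrom == ch]
      if (is.unsorted(p, strictly = TRUE))
        return(sprintf("positions not strictly increasing on chromosome %s", ch))
    }
    TRUE
  })

#' Additive relationship matrix
#'
#' Symmetric relationship matrix from pedigree (A, tabular method) or SNP
#' genotypes (G, VanRaden method 1).
#'
#' @slot ids individual ids, aligned with rows/columns.
#' @slot mat symmetric numeric matrix.
#' @slot kind \code{"PEDIGREE_A"} or \code{"GENOMIC_G"}.
#'
#' @export
setClass("RelationshipMatrix",
  representation(ids = "character", mat = "matrix", kind = "character"),
  validity = function(object) {
    if (nrow(object@mat) != ncol(object@mat)) return("matrix must be square")
    if (nrow(object@mat) != length(object@ids)) return("ids must match dimension")
    if (!object@kind %in% c("PEDIGREE_A", "GENOMIC_G"))
      return("kind must be PEDIGREE_A or GENOMIC_G")
    if (max(abs(object@mat - t(object@mat))) > 1e-8) return("matrix must be symmetric")
    TRUE
  })

#' Non-overlapping 1 Mb window assignment
#'
#' Maps every marker to the 1 Mb window (chromosome, floor(pos / 1e6)) that
#' contains it; windows are half-open \code{[k Mb, (k+1) Mb)}.
#'
#' @slot table data.frame with columns \code{marker}, \code{chrom}, \code{mb},
#'   \code{window} (label "chrom_mb"), one row per marker in map order.
#' @slot nWindows number of non-empty windows (used as the default WPPA
#'   threshold denominator).
#' @slot nWindowsSpan number of windows spanned by the map, counting empty
#'   windows between the first and last marker of each chromosome.
#'
#' @export
setClass("WindowMap",
  representation(table = "data.frame", nWindows = "integer",
                 nWindowsSpan = "integer"),
  validity = function(object) {
    if (!all(c("marker", "chrom", "mb", "window") %in% names(object@table)))
      return("table needs columns marker, chrom, mb, window")
    if (object@nWindows != length(unique(object@table$window)))
      return("nWindows must equal number of distinct windows")
    TRUE
  })

#' MCMC chain settings
#'
#' @slot nIter total iterations.
#' @slot burnIn iterations discarded; \code{burnIn < nIter}.
#' @slot thin save every \code{thin}-th post-burn-in iteration.
#' @slot seed RNG seed.
#' @slot pi prior exclusion probability for Bayes-B/Bayes-C, or \code{NA}
#'   to estimate it (Bayes-Cpi).
#'
#' @export
setClass("ChainConfig",
  representation(nIter = "integer", burnIn = "integer", thin = "integer",
                 seed = "integer", pi = "numeric"),
  validity = function(object) {
    if (object@burnIn >= object@nIter) return("burnIn must be < nIter")
    if (object@thin < 1L) return("thin must be >= 1")
    if (!is.na(object@pi) && (object@pi < 0 || object@pi >= 1))
      return("pi must be in [0,1) or NA to estimate")
    TRUE
  })

#' Saved posterior samples from a Gibbs run
#'
#' Thinned post-burn-in samples.  Which components are present depends on
#' the model: marker-effects runs carry per-sample marker effects (already
#' multiplied by the inclusion indicator), per-marker posterior inclusion
#' probabilities and per-sample genome-wide genetic variance; bivariate runs
#' carry 2x2 genetic covariance samples; animal-model runs carry additive
#' variance and heritability samples.
#'
#' @slot model one of \code{"threshold_marker"}, \code{"bivariate_linear"},
#'   \code{"animal_threshold"}.
#' @slot samples named list of sample matrices/vectors (rows = saved samples).
#' @slot markerIds marker ids for effect columns (marker models).
#' @slot ids ids of the analysed individuals.
#' @slot config the \code{ChainConfig} used.
#' @slot info misc named list (link, prior, residual variance, pi used, ...).
#'
#' @export
setClass("PosteriorChain",
  representation(model = "character", samples = "list", markerIds = "character",
                 ids = "character", config = "ChainConfig", info = "list"),
  validity = function(object) {
    cfg <- object@config
    nsave <- floor((cfg@nIter - cfg@burnIn) / cfg@thin)
    lens <- vapply(object@samples, NROW, 0L)
    if (length(lens) && any(lens != nsave))
      return(sprintf("all sample components must hold %d saved samples", nsave))
    TRUE
  })

setMethod("show", "TraitData", function(object) {
  cat(sprintf("TraitData [%s]: %d sows, %d cases (%.1f%%), %d HYQ levels\n",
              object@tag, length(object@sowId), sum(object@phenotype),
              100 * mean(object@phenotype), nlevels(droplevels(object@hyq))))
})

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d individuals x %d markers on %d chromosome(s)\n",
              length(object@ids), nrow(object@map),
              length(unique(object@map$chrom))))
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat(sprintf("RelationshipMatrix (%s): %d individuals, mean diagonal %.3f\n",
              object@kind, length(object@ids), mean(diag(object@mat))))
})

setMethod("show", "WindowMap", function(object) {
  cat(sprintf("WindowMap: %d markers in %d non-empty 1 Mb windows (%d spanned)\n",
              nrow(object@table), object@nWindows, object@nWindowsSpan))
})

setMethod("show", "PosteriorChain", function(object) {
  cat(sprintf("PosteriorChain [%s]: %d saved samples (nIter %d, burnIn %d, thin %d)\n",
              object@model, nSamples(object), object@config@nIter,
              object@config@burnIn, object@config@thin))
  cat("  components:", paste(names(object@samples), collapse = ", "), "\n")
})
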