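## Window-based genome-scan summaries from threshold marker-effects chains:
## per-1 Mb-window % of genetic variance, WPPA, PIPs, significance calls and
## +/- 2 Mb regional aggregation.

#' Posterior window variance decomposition
#'
#' For every saved sample, the genomic value of each individual within a
#' window is the sum of dose x sampled effect over the window's markers; the
#' window's genetic variance is the variance of those values across
#' individuals, and its proportion is taken against the genome-wide genetic
#' variance of the same sample (ratio first, then averaged over samples).
#'
#' @param chain a threshold-marker \linkS4class{PosteriorChain}.
#' @param genotypes the \linkS4class{GenotypeData} the chain was fitted on.
#' @param windows a \linkS4class{WindowMap} on the same marker set.
#' @param rho WPPA threshold proportion; default \code{1 / nWindows}
#'   (non-empty windows).
#' @return data.frame, one row per non-empty window: \code{chrom}, \code{mb},
#'   \code{window}, \code{n_snps}, \code{pct_var}, \code{wppa},
#'   \code{top_snp}, \code{top_pip}; attribute \code{"prop_samples"} holds
#'   the per-sample window proportion matrix, attribute \code{"rho"} the
#'   threshold used.
#' @export
windowVariancePosterior <- function(chain, genotypes, windows, rho = NULL) {
  if (chain@model != "threshold_marker")
    stop("window decomposition needs a threshold marker-effects chain")
  if (!identical(chain@markerIds, windows@table$marker))
    stop("marker sets of chain and window map disagree")
  if (!identical(chain@markerIds, as.character(genotypes@map$marker)))
    stop("marker sets of chain and genotypes disagree")
  if (is.null(rho)) rho <- 1 / windows@nWindows
  if (rho <= 0) stop("rho must be positive")
  eff <- chain@samples$effects                   # nsave x p
  geno <- imputeMean(genotypes)
  M <- geno@dose[match(chain@ids, geno@ids), , drop = FALSE]
  nsave <- nrow(eff)
  g_all <- M %*% t(eff)                          # n x nsave genomic values
  totvar <- apply(g_all, 2L, var)
  win_split <- split(seq_len(ncol(M)), windows@table$window)
  win_names <- names(win_split)
  prop <- matrix(0, nsave, length(win_names),
                 dimnames = list(NULL, win_names))
  for (w in seq_along(win_split)) {
    idx <- win_split[[w]]
    gw <- M[, idx, drop = FALSE] %*% t(eff[, idx, drop = FALSE])
    vw <- apply(gw, 2L, var)
    prop[, w] <- ifelse(totvar > 0, vw / totvar, 0)
  }
  pip <- chain@info$pip
  tab <- windows@table
  first <- !duplicated(tab$window)
  meta <- tab[first, c("chrom", "mb", "window")]
  meta <- meta[match(win_names, meta$window), ]
  res <- data.frame(
    chrom = meta$chrom, mb = meta$mb, window = win_names,
    n_snps = vapply(win_split, length, 0L),
    pct_var = 100 * colMeans(prop),
    wppa = colMeans(prop > rho),
    top_snp = vapply(win_split, function(idx)
      tab$marker[idx][which.max(pip[tab$marker[idx]])], ""),
    top_pip = vapply(win_split, function(idx)
      max(pip[tab$marker[idx]]), 0),
    row.names = NULL)
  res <- res[order(res$chrom, res$mb), ]
  rownames(res) <- NULL
  attr(res, "prop_samples") <- prop
  attr(res, "rho") <- rho
  res
}

#' Window posterior probability of association
#'
#' Fraction of saved samples in which a window's share of the genome-wide
#' genetic variance exceeds \code{rho}.
#'
#' @param results output of \code{\link{windowVariancePosterior}} (carries
#'   the per-sample proportions).
#' @param rho threshold proportion (> 0).
#' @return named numeric vector of per-window WPPA.
#' @export
wppa <- function(results, rho) {
  if (rho <= 0) stop("rho must be positive")
  prop <- attr(results, "prop_samples")
  if (is.null(prop)) stop("results lack per-sample window proportions")
  w <- colMeans(prop > rho)
  w[match(results$window, colnames(prop))]
}

#' Significant windows
#'
#' Windows whose posterior mean share of genetic variance strictly exceeds
#' \code{minPct} percent, sorted by share (descending), ties broken by
#' genome position.
#'
#' @param results a window result data.frame with \code{pct_var}.
#' @param minPct threshold in percent (default 1.0, strict inequality).
#' @return the qualifying rows.
#' @export
callSignificant <- function(results, minPct = 1.0) {
  hits <- results[results$pct_var > minPct, , drop = FALSE]
  hits <- hits[order(-hits$pct_var, hits$chrom, hits$mb), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Regional aggregation around an anchor window
#'
#' Sums the window shares over \code{[anchor - flankMb, anchor + flankMb]}
#' on the anchor's chromosome (truncated at the chromosome ends; absent
#' windows contribute zero), the convention used to confirm across-parity
#' signals in by-parity scans.
#'
#' @param results window result data.frame (\code{chrom}, \code{mb},
#'   \code{pct_var}).
#' @param chrom,mb anchor window.
#' @param flankMb flank width in Mb (default 2).
#' @return list with \code{chrom}, \code{mb}, \code{flank_mb},
#'   \code{pct_var_total}, \code{n_windows}.
#' @export
regionalAggregate <- function(results, chrom, mb, flankMb = 2L) {
  on_chr <- results[results$chrom == as.character(chrom), , drop = FALSE]
  if (!nrow(on_chr)) stop("no windows on chromosome ", chrom)
  sel <- on_chr$mb >= mb - flankMb & on_chr$mb <= mb + flankMb
  list(chrom = as.character(chrom), mb = as.integer(mb),
       flank_mb = as.integer(flankMb),
       pct_var_total = sum(on_chr$pct_var[sel]),
       n_windows = sum(sel))
}

#' Genome-ordered window table
#'
#' Per-window rows in genome order (chromosome, Mb) with share of genetic
#' variance and WPPA -- the tabular form of a Manhattan-style window plot.
#'
#' @param results window result data.frame.
#' @return data.frame ordered by genome position with a cumulative window
#'   index column \code{pos_index}.
#' @export
manhattanTable <- function(results) {
  if (!nrow(results)) {
    out <- results
    out$pos_index <- integer(0)
    return(out)
  }
  num <- suppressWarnings(as.numeric(results$chrom))
  key <- if (anyNA(num)) order(results$chrom, results$mb) else order(num, results$mb)
  out <- results[key, , drop = FALSE]
  out$pos_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write window results as TSV
#'
#' @param results window result data.frame.
#' @param path output TSV path.
#' @return path, invisibly.
#' @export
writeWindowTSV <- function(results, path) {
  keep <- intersect(c("chrom", "mb", "window", "n_snps", "pct_var", "wppa",
                      "top_snp", "top_pip"), names(results))
  write.table(results[keep], path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Example genome-scan window summary
#'
#' Loads the packaged example table of significant-window candidates from a
#' sow prolapse genome scan: per 1 Mb window the SNP count, WPPA and % of
#' genetic variance in the across-parity analysis, and the +/- 2 Mb regional
#' shares in each by-parity analysis.
#'
#' @return data.frame with columns \code{chrom}, \code{mb}, \code{n_snps},
#'   \code{wppa}, \code{pct_var}, \code{pct_region_p2} .. \code{pct_region_p6}.
#' @export
examplePOPWindows <- function() {
  path <- system.file("extdata", "pop_gwas_windows.tsv", package = "swinePOP",
                      mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(chrom = "character"))
}
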