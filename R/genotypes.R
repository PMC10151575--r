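## Genotype containers, relationship matrices and 1 Mb window assignment.

#' Construct a GenotypeData object
#'
#' @param dose numeric matrix of allele counts (individuals x markers),
#'   entries 0/1/2 or NA.
#' @param map data.frame with columns \code{marker}, \code{chrom}, \code{pos}
#'   (base pairs); rows parallel to the columns of \code{dose}.
#' @param ids individual ids; defaults to rownames of \code{dose}.
#' @return a \linkS4class{GenotypeData}.
#' @export
genotypeData <- function(dose, map, ids = rownames(dose)) {
  if (is.null(ids)) ids <- sprintf("ind%d", seq_len(nrow(dose)))
  map$marker <- as.character(map$marker)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  rownames(map) <- NULL
  dose <- unname(as.matrix(dose))
  storage.mode(dose) <- "double"
  new("GenotypeData", ids = as.character(ids), dose = dose, map = map)
}

#' Mean-impute missing allele doses
#'
#' Replaces missing doses with the per-marker mean dose (2 x allele
#' frequency).  The analysis samplers require complete dose matrices.
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @return a \linkS4class{GenotypeData} without missing entries.
#' @export
imputeMean <- function(genotypes) {
  d <- genotypes@dose
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2L]]
  }
  initialize(genotypes, dose = d)
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' \deqn{G = W W' / (2 \sum_k p_k (1 - p_k))}
#' with W the dose matrix column-centred by twice the observed allele
#' frequency.  Monomorphic markers carry no information and are dropped.
#'
#' @param genotypes a \linkS4class{GenotypeData}; missing doses are
#'   mean-imputed first.
#' @return a \linkS4class{RelationshipMatrix} of kind \code{GENOMIC_G}.
#' @export
genomicRelationship <- function(genotypes) {
  genotypes <- imputeMean(genotypes)
  d <- genotypes@dose
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no informative markers: all markers are monomorphic")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  w <- sweep(d, 2L, 2 * p, "-")
  g <- tcrossprod(w) / (2 * sum(p * (1 - p)))
  new("RelationshipMatrix", ids = genotypes@ids,
      mat = (g + t(g)) / 2, kind = "GENOMIC_G")
}

#' Pedigree additive relationship matrix (tabular method)
#'
#' Recursive tabular construction of the numerator relationship matrix A;
#' unknown parents contribute zero relationship.
#'
#' @param pedigree data.frame with columns \code{id}, \code{sire}, \code{dam}
#'   (NA for unknown parents).  Rows are reordered so parents precede
#'   offspring; a cycle is an error.
#' @return a \linkS4class{RelationshipMatrix} of kind \code{PEDIGREE_A}.
#' @export
pedigreeRelationship <- function(pedigree) {
  id <- as.character(pedigree$id)
  sire <- as.character(pedigree$sire)
  dam <- as.character(pedigree$dam)
  sire[!is.na(sire) & !(sire %in% id)] <- NA  # unlisted parents act as unknown
  dam[!is.na(dam) & !(dam %in% id)] <- NA
  n <- length(id)
  if (anyDuplicated(id)) stop("duplicate individual ids in pedigree")

  # topological sort; detect cycles
  ord <- integer(0)
  placed <- setNames(rep(FALSE, n), id)
  remaining <- seq_len(n)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) {
      (is.na(sire[i]) || placed[sire[i]]) && (is.na(dam[i]) || placed[dam[i]])
    }, TRUE)]
    if (!length(ready))
      stop("pedigree cycle involving: ", paste(id[remaining], collapse = " -> "))
    ord <- c(ord, ready)
    placed[id[ready]] <- TRUE
    remaining <- setdiff(remaining, ready)
  }

  a <- matrix(0, n, n)
  pos <- setNames(seq_len(n), id[ord])
  s_i <- ifelse(is.na(sire[ord]), 0L, pos[sire[ord]])
  d_i <- ifelse(is.na(dam[ord]), 0L, pos[dam[ord]])
  for (i in seq_len(n)) {
    si <- s_i[i]; di <- d_i[i]
    a[i, i] <- 1 + if (si > 0L && di > 0L) 0.5 * a[si, di] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (si > 0L) a[j, si] else rep(0, i - 1L)) +
                    (if (di > 0L) a[j, di] else rep(0, i - 1L)))
      a[i, j] <- aij
      a[j, i] <- aij
    }
  }
  # return in the input id order
  back <- order(ord)
  new("RelationshipMatrix", ids = id, mat = a[back, back, drop = FALSE],
      kind = "PEDIGREE_A")
}

#' Stabilize a relationship matrix
#'
#' Blends with the identity, \code{w * K + (1 - w) * I}, so the matrix is
#' safely positive definite before factorization.
#'
#' @param K a \linkS4class{RelationshipMatrix}.
#' @param weight blending weight on K (default 0.99).
#' @return a stabilized \linkS4class{RelationshipMatrix}.
#' @export
stabilizeRelationship <- function(K, weight = 0.99) {
  initialize(K, mat = weight * K@mat + (1 - weight) * diag(nrow(K@mat)))
}

#' Assign markers to non-overlapping 1 Mb windows
#'
#' Window k on a chromosome covers base-pair positions
#' \code{[k * 1e6, (k + 1) * 1e6)}; the window label is the Mb integer k.
#' Empty windows are absent from the table but counted in
#' \code{nWindowsSpan}.
#'
#' @param map marker map data.frame (\code{marker}, \code{chrom}, \code{pos})
#'   or a \linkS4class{GenotypeData}.
#' @param windowBp window size in bp (default 1e6).
#' @return a \linkS4class{WindowMap}.
#' @export
assignWindows <- function(map, windowBp = 1e6) {
  if (is(map, "GenotypeData")) map <- markerMap(map)
  if (any(map$pos < 0)) stop("negative marker position")
  mb <- as.integer(floor(map$pos / windowBp))
  tab <- data.frame(marker = as.character(map$marker),
                    chrom = as.character(map$chrom), mb = mb,
                    window = sprintf("%s_%d", map$chrom, mb),
                    stringsAsFactors = FALSE)
  span <- sum(vapply(split(tab$mb, tab$chrom),
                     function(x) max(x) - min(x) + 1L, 0L))
  new("WindowMap", table = tab,
      nWindows = length(unique(tab$window)), nWindowsSpan = as.integer(span))
}
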