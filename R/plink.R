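## PLINK bed/bim/fam and CSV genotype round-tripping.
##
## bed layout: magic bytes 0x6c 0x1b, mode byte 0x01 (SNP-major), then one
## byte-padded block of 2-bit codes per marker, individuals in fam order.
## 2-bit codes (little-endian within byte): 00 = hom A1 (dose 2 of A1),
## 01 = missing, 10 = het, 11 = hom A2.  We count the A1 allele, so
## code 00 -> 2, 10 -> 1, 11 -> 0.

.BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))
.BED_CODE_TO_DOSE <- c(2, NA, 1, 0)  # indexed by code 00,01,10,11 (+1)

#' Read genotypes from PLINK bed/bim/fam
#'
#' SNP-major bed files only.  bim positions are 1-based and converted to the
#' package's 0-based convention on read.
#'
#' @param prefix path prefix; \code{<prefix>.bed/.bim/.fam} must exist.
#' @return a \linkS4class{GenotypeData}.
#' @export
readPlink <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE,
                    col.names = c("chrom", "marker", "cm", "pos", "a1", "a2"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  fam <- read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  ids <- as.character(fam[[2L]])
  n <- length(ids)
  p <- nrow(bim)
  for (ch in unique(bim$chrom)) {
    pp <- bim$pos[bim$chrom == ch]
    if (is.unsorted(pp, strictly = TRUE))
      stop(sprintf("bim positions not strictly increasing on chromosome %s", ch))
  }
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3L)
  if (length(magic) < 3L || !identical(magic, .BED_MAGIC))
    stop("not a SNP-major PLINK bed file (bad magic bytes)")
  bpm <- ceiling(n / 4)  # bytes per marker block
  raw <- readBin(con, "raw", bpm * p)
  if (length(raw) != bpm * p) stop("truncated bed file")
  codes <- .bedUnpack(raw, n, p, bpm)
  dose <- matrix(.BED_CODE_TO_DOSE[codes + 1L], n, p)
  rownames(dose) <- ids
  genotypeData(dose, data.frame(marker = bim$marker, chrom = bim$chrom,
                                pos = bim$pos - 1L), ids = ids)
}

# unpack 2-bit codes: returns n x p integer matrix of codes 0..3
.bedUnpack <- function(raw, n, p, bpm) {
  v <- as.integer(raw)
  dim(v) <- c(bpm, p)
  codes <- matrix(0L, n, p)
  for (k in 0:3) {  # individual slot within byte
    rows <- seq.int(k + 1L, by = 4L, length.out = ceiling((n - k) / 4))
    rows <- rows[rows <= n]
    if (!length(rows)) next
    byte <- v[ceiling(rows / 4), , drop = FALSE]
    codes[rows, ] <- (byte %/% 4L^k) %% 4L
  }
  codes
}

#' Write genotypes as PLINK bed/bim/fam
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param prefix output path prefix.
#' @return prefix, invisibly.
#' @export
writePlink <- function(genotypes, prefix) {
  map <- genotypes@map
  d <- genotypes@dose
  n <- nrow(d); p <- ncol(d)
  write.table(data.frame(map$chrom, map$marker, 0, map$pos + 1L, "A", "B"),
              paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(genotypes@ids, genotypes@ids, 0, 0, 0, -9),
              paste0(prefix, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  dose_to_code <- function(x) {
    code <- integer(length(x))
    code[is.na(x)] <- 1L
    code[!is.na(x) & x == 2] <- 0L
    code[!is.na(x) & x == 1] <- 2L
    code[!is.na(x) & x == 0] <- 3L
    code
  }
  bpm <- ceiling(n / 4)
  out <- raw(3 + bpm * p)
  out[1:3] <- .BED_MAGIC
  mult <- 4L^(0:3)
  for (j in seq_len(p)) {
    code <- dose_to_code(d[, j])
    length(code) <- bpm * 4L  # pad with NA -> treated as 0 below
    code[is.na(code)] <- 0L
    bytes <- colSums(matrix(code * mult, 4L, bpm))
    out[3 + (j - 1) * bpm + seq_len(bpm)] <- as.raw(bytes)
  }
  writeBin(out, paste0(prefix, ".bed"))
  invisible(prefix)
}

#' Read a dose matrix and marker map from CSV
#'
#' Dose CSV: rows = individuals with an \code{id} column, remaining header
#' columns are marker ids.  Map CSV: columns \code{marker}, \code{chrom},
#' \code{pos}.
#'
#' @param dosePath dose CSV path.
#' @param mapPath marker map CSV path.
#' @return a \linkS4class{GenotypeData}.
#' @export
readDoseCSV <- function(dosePath, mapPath) {
  d <- read.csv(dosePath, check.names = FALSE,
                colClasses = list(id = "character"))
  map <- read.csv(mapPath, stringsAsFactors = FALSE)
  ids <- d$id
  d <- as.matrix(d[setdiff(names(d), "id")])
  if (!identical(colnames(d), as.character(map$marker)))
    stop("dose columns and map markers disagree")
  rownames(d) <- ids
  genotypeData(d, map, ids = ids)
}

#' Write a dose matrix and marker map as CSV
#'
#' @param genotypes a \linkS4class{GenotypeData}.
#' @param dosePath dose CSV path.
#' @param mapPath marker map CSV path.
#' @return dosePath, invisibly.
#' @export
writeDoseCSV <- function(genotypes, dosePath, mapPath) {
  d <- doseMatrix(genotypes)
  df <- data.frame(id = genotypes@ids, d, check.names = FALSE)
  write.csv(df, dosePath, row.names = FALSE, quote = FALSE)
  write.csv(genotypes@map, mapPath, row.names = FALSE, quote = FALSE)
  invisible(dosePath)
}

#' Write / read a relationship matrix as CSV
#'
#' CSV with an \code{id} header column and one column per individual.
#'
#' @param K a \linkS4class{RelationshipMatrix}.
#' @param path CSV path.
#' @param kind relationship kind when reading.
#' @return the path / a \linkS4class{RelationshipMatrix}.
#' @export
writeRelationshipCSV <- function(K, path) {
  df <- data.frame(id = K@ids, K@mat, check.names = FALSE)
  colnames(df) <- c("id", K@ids)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeRelationshipCSV
#' @export
readRelationshipCSV <- function(path, kind = "GENOMIC_G") {
  df <- read.csv(path, check.names = FALSE, colClasses = list(id = "character"))
  ids <- df$id
  m <- as.matrix(df[-1L])
  dimnames(m) <- NULL
  new("RelationshipMatrix", ids = ids, mat = (m + t(m)) / 2, kind = kind)
}
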