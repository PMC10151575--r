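## Sow life-history records: parsing, quality control and binary trait coding.
##
## A record set is a data.frame with one row per sow x parity:
##   sow_id, farm, parity, insem_date, farrow_date, removal_date,
##   removal_parity, removal_reason (POP/OTHER/NONE), total_born, sire, dam,
##   died.  Dates are Date class; absent values are NA.

.RECORD_COLS <- c("sow_id", "farm", "parity", "insem_date", "farrow_date",
                  "removal_date", "removal_parity", "removal_reason",
                  "total_born", "sire", "dam", "died")

#' Read sow life-history records from CSV
#'
#' Expects header columns \code{sow_id, farm, parity, insem_date, farrow_date,
#' removal_date, removal_parity, removal_reason, total_born, sire, dam, died}
#' with ISO-8601 dates; empty strings are treated as absent.
#'
#' @param path CSV file path.
#' @return data.frame of sow records with parsed \code{Date} columns.
#' @export
readSowRecords <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = list(sow_id = "character", farm = "character",
                                   sire = "character", dam = "character"))
  missing_cols <- setdiff(.RECORD_COLS, names(df))
  if (length(missing_cols))
    stop("records CSV is missing columns: ", paste(missing_cols, collapse = ", "))
  for (col in c("insem_date", "farrow_date", "removal_date")) {
    raw <- as.character(df[[col]])
    raw[!nzchar(raw) | is.na(raw)] <- NA
    parsed <- as.Date(raw, format = "%Y-%m-%d")
    bad <- !is.na(raw) & is.na(parsed)
    if (any(bad))
      stop(sprintf("unparseable %s for sow(s): %s", col,
                   paste(unique(df$sow_id[bad]), collapse = ", ")))
    df[[col]] <- parsed
  }
  for (col in c("sire", "dam"))
    df[[col]][!nzchar(df[[col]]) | is.na(df[[col]])] <- NA
  df$removal_reason[is.na(df$removal_reason) | !nzchar(df$removal_reason)] <- "NONE"
  df$died <- as.logical(df$died)
  validateSowRecords(df)
  df
}

#' Validate a sow record set
#'
#' Enforces the record invariants: known removal reasons, farrowing after
#' insemination, removal date present iff reason is not NONE, and at most
#' one record per sow x parity.
#'
#' @param records sow record data.frame.
#' @return the records, invisibly.
#' @export
validateSowRecords <- function(records) {
  if (!all(records$removal_reason %in% c("POP", "OTHER", "NONE")))
    stop("removal_reason must be POP, OTHER or NONE")
  dup <- duplicated(records[c("sow_id", "parity")])
  if (any(dup))
    stop("duplicate sow x parity record(s): ",
         paste(unique(records$sow_id[dup]), collapse = ", "))
  bad <- !is.na(records$farrow_date) &
    records$farrow_date < records$insem_date
  if (any(bad))
    stop("farrowing before insemination for sow(s): ",
         paste(unique(records$sow_id[bad]), collapse = ", "))
  has_rm <- !is.na(records$removal_date)
  if (any(has_rm != (records$removal_reason != "NONE")))
    stop("removal_date must be present iff removal_reason is not NONE")
  invisible(records)
}

#' Quality-control filter for sow records
#'
#' Removes whole sows that fail any enabled rule:
#' \describe{
#'   \item{missing_mortality}{died flag set but no removal date.}
#'   \item{overdue}{any parity with > \code{maxGestation} days from
#'     insemination to farrowing.}
#'   \item{pedigree}{sire or dam id equal to the sow's own id, or (when a
#'     \code{birth_date} column is present for parents via \code{birthDates})
#'     a parent born after the sow.}
#' }
#' Sows with merely missing sire/dam ids are retained: pooled-semen
#' inseminations legitimately lack a sire.
#'
#' @param records sow record data.frame.
#' @param maxGestation maximum insemination-to-farrowing interval in days
#'   (default 116).
#' @param rules character vector of enabled rules.
#' @param birthDates optional named vector (id -> Date) used by the pedigree
#'   chronology check.
#' @return list with \code{records} (retained rows) and \code{report}, a list
#'   counting removed sows per rule.
#' @export
qcFilter <- function(records,
                     maxGestation = 116,
                     rules = c("missing_mortality", "overdue", "pedigree"),
                     birthDates = NULL) {
  validateSowRecords(records)
  report <- list(n_sows_in = length(unique(records$sow_id)),
                 missing_mortality = 0L, overdue = 0L, pedigree = 0L)
  if (!nrow(records)) {
    report$n_sows_out <- 0L
    report$removed_after_parity6 <- 0L
    return(list(records = records, report = report))
  }
  drop <- character(0)
  if ("missing_mortality" %in% rules) {
    bad <- records$sow_id[records$died %in% TRUE & is.na(records$removal_date)]
    bad <- setdiff(unique(bad), drop)
    report$missing_mortality <- length(bad)
    drop <- c(drop, bad)
  }
  if ("overdue" %in% rules) {
    ivl <- as.numeric(records$farrow_date - records$insem_date)
    bad <- records$sow_id[!is.na(ivl) & ivl > maxGestation]
    bad <- setdiff(unique(bad), drop)
    report$overdue <- length(bad)
    drop <- c(drop, bad)
  }
  if ("pedigree" %in% rules) {
    self <- (!is.na(records$sire) & records$sire == records$sow_id) |
      (!is.na(records$dam) & records$dam == records$sow_id)
    bad <- records$sow_id[self]
    if (!is.null(birthDates)) {
      first <- tapply(records$insem_date, records$sow_id, min)
      for (p in c("sire", "dam")) {
        pid <- records[[p]]
        known <- !is.na(pid) & pid %in% names(birthDates)
        late <- known & as.Date(birthDates[pid], origin = "1970-01-01") >
          as.Date(first[records$sow_id], origin = "1970-01-01")
        bad <- c(bad, records$sow_id[late %in% TRUE])
      }
    }
    bad <- setdiff(unique(bad), drop)
    report$pedigree <- length(bad)
    drop <- c(drop, bad)
  }
  keep <- !(records$sow_id %in% drop)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  report$n_sows_out <- length(unique(out$sow_id))
  # informational: sows removed after parity 6 still contribute phenotype-0
  # records to the by-parity datasets of parities they completed
  report$removed_after_parity6 <-
    length(unique(out$sow_id[!is.na(out$removal_parity) &
                               out$removal_parity > 6L]))
  list(records = out, report = report)
}

#' Herd-year-quarter contemporary groups
#'
#' Builds the HYQ label (farm, year, quarter of insemination) with calendar
#' quarters (Jan-Mar = Q1).
#'
#' @param records sow record data.frame.
#' @param dateField which date column to use (default \code{"insem_date"}).
#' @return character vector of labels \code{"farm_year_Qq"}, parallel to rows.
#' @export
buildHYQ <- function(records, dateField = "insem_date") {
  d <- records[[dateField]]
  if (anyNA(d))
    stop("absent ", dateField, " for sow(s): ",
         paste(unique(records$sow_id[is.na(d)]), collapse = ", "))
  lt <- as.POSIXlt(d)
  sprintf("%s_%d_Q%d", records$farm, lt$year + 1900L, (lt$mon %/% 3L) + 1L)
}

#' Across-parity trait coding
#'
#' One row per culled/dead sow with removal parity in 2..6: phenotype 1 if
#' the sow was removed because of pelvic organ prolapse, 0 if removed for any
#' other reason.  Sows never removed contribute no record.  The HYQ group is
#' taken from the insemination of the removal parity; the removal parity is
#' kept as a fixed-effect label.
#'
#' @param records QC-passed sow record data.frame.
#' @param parityRange retained removal parities (default 2:6).
#' @return a \linkS4class{TraitData} with tag \code{"ACROSS"}.
#' @export
codeAcrossParity <- function(records, parityRange = 2:6) {
  culled <- records[records$removal_reason != "NONE" &
                      !is.na(records$removal_parity) &
                      records$removal_parity %in% parityRange, , drop = FALSE]
  # the record of the removal parity supplies the insemination date for HYQ
  rm_rec <- culled[culled$parity == culled$removal_parity, , drop = FALSE]
  new("TraitData",
      sowId = rm_rec$sow_id,
      phenotype = as.integer(rm_rec$removal_reason == "POP"),
      hyq = factor(buildHYQ(rm_rec)),
      parity = as.integer(rm_rec$removal_parity),
      tag = "ACROSS")
}

#' By-parity trait coding
#'
#' One row per sow at risk in the given parity (i.e. with a record for it):
#' phenotype 1 if removed in that parity because of prolapse, 0 if not
#' removed in that parity or removed for another reason.
#'
#' @param records QC-passed sow record data.frame.
#' @param parity analysed parity, in 2..6.
#' @return a \linkS4class{TraitData} with tag \code{"PARITY_<parity>"}.
#' @export
codeByParity <- function(records, parity) {
  if (length(parity) != 1L || !parity %in% 2:6)
    stop("parity must be a single value in 2..6")
  at_risk <- records[records$parity == parity, , drop = FALSE]
  pop_here <- at_risk$removal_reason == "POP" &
    !is.na(at_risk$removal_parity) & at_risk$removal_parity == parity
  new("TraitData",
      sowId = at_risk$sow_id,
      phenotype = as.integer(pop_here),
      hyq = factor(buildHYQ(at_risk)),
      parity = rep(as.integer(parity), nrow(at_risk)),
      tag = sprintf("PARITY_%d", parity))
}

#' Write a trait dataset as CSV
#'
#' @param dataset a \linkS4class{TraitData}.
#' @param path output CSV path.
#' @return path, invisibly.
#' @export
writeTraitData <- function(dataset, path) {
  write.csv(data.frame(sow_id = dataset@sowId, phenotype = dataset@phenotype,
                       hyq = as.character(dataset@hyq), parity = dataset@parity),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Monthly prolapse summary
#'
#' Descriptive summary: per culling month, the number of culled sows and the
#' percentage of culls that were due to prolapse.
#'
#' @param records sow record data.frame.
#' @return data.frame with columns \code{month}, \code{n_culls}, \code{pct_pop}.
#' @export
monthlyPOPSummary <- function(records) {
  culled <- records[records$removal_reason != "NONE" &
                      records$parity == records$removal_parity, , drop = FALSE]
  if (!nrow(culled))
    return(data.frame(month = character(0), n_culls = integer(0),
                      pct_pop = numeric(0)))
  mon <- format(culled$removal_date, "%Y-%m")
  agg <- aggregate(list(n_culls = culled$sow_id,
                        pct_pop = culled$removal_reason == "POP"),
                   by = list(month = mon),
                   FUN = function(x) if (is.logical(x)) 100 * mean(x) else length(x))
  agg$n_culls <- as.integer(tapply(culled$sow_id, mon, length)[agg$month])
  agg[order(agg$month), ]
}
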