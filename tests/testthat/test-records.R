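test_that("qc filter removes the right sows and counts per rule", {
  # 10 sows: 7 clean, 1 died without removal date, 1 overdue, 1 self-parent
  clean <- lapply(1:7, function(i) makeSow(sprintf("c%d", i)))
  dead <- makeSow("dead1", rmParity = 2L, reason = "OTHER", died = TRUE)
  dead$removal_date <- as.Date(NA)
  dead$removal_reason <- "NONE"
  dead$removal_parity <- NA_integer_
  dead$died[2] <- TRUE       # died flag without mortality date
  over <- makeSow("over1", overdueParity = 2L)
  selfp <- makeSow("self1", sire = "self1")
  rec <- do.call(bindSows, c(clean, list(dead, over, selfp)))

  res <- qcFilter(rec)
  expect_setequal(unique(res$records$sow_id), sprintf("c%d", 1:7))
  expect_equal(res$report$missing_mortality, 1L)
  expect_equal(res$report$overdue, 1L)
  expect_equal(res$report$pedigree, 1L)
  expect_equal(res$report$n_sows_out, 7L)

  # boundary: 116 days is retained, 117 is overdue
  ok116 <- makeSow("b116", gestation = 116L)
  expect_equal(qcFilter(bindSows(ok116))$report$overdue, 0L)
  bad117 <- makeSow("b117", gestation = 117L)
  expect_equal(qcFilter(bindSows(bad117))$report$overdue, 1L)

  # idempotence
  res2 <- qcFilter(res$records)
  expect_identical(res2$records, res$records)

  # missing sire is retained
  pooled <- makeSow("pool1", sire = NA)
  expect_equal(qcFilter(bindSows(pooled))$report$n_sows_out, 1L)

  # empty input: all counters zero
  empty <- qcFilter(rec[0, ])
  expect_equal(empty$report$missing_mortality, 0L)
  expect_equal(empty$report$overdue, 0L)
  expect_equal(nrow(empty$records), 0L)
})

test_that("record validation rejects malformed input", {
  rec <- makeSow("a1")
  dup <- bindSows(rec, rec[1, ])
  expect_error(qcFilter(dup), "duplicate")
  bad <- rec
  bad$removal_reason[1] <- "POP"   # reason without removal date
  expect_error(qcFilter(bad), "removal_date")
})

test_that("record CSV reader parses dates and flags bad ones", {
  rec <- bindSows(makeSow("a1", rmParity = 3L, reason = "POP"),
                  makeSow("a2", sire = NA))
  path <- tempfile(fileext = ".csv")
  out <- rec
  for (col in c("insem_date", "farrow_date", "removal_date"))
    out[[col]] <- ifelse(is.na(out[[col]]), "", format(out[[col]]))
  write.csv(out, path, row.names = FALSE)
  back <- readSowRecords(path)
  expect_equal(back$insem_date, rec$insem_date)
  expect_equal(back$removal_reason, rec$removal_reason)
  expect_true(is.na(back$sire[back$sow_id == "a2"][1]))

  out$insem_date[1] <- "not-a-date"
  write.csv(out, path, row.names = FALSE)
  expect_error(readSowRecords(path), "a1")
})

test_that("HYQ labels follow calendar quarters of the insemination date", {
  rec <- makeSow("q1", entry = as.Date("2015-05-10"), upTo = 1L)
  expect_equal(buildHYQ(rec), "A_2015_Q2")

  r2 <- bindSows(makeSow("qa", entry = as.Date("2015-03-31"), upTo = 1L),
                 makeSow("qb", entry = as.Date("2015-04-01"), upTo = 1L))
  labs <- buildHYQ(r2)
  expect_equal(labs, c("A_2015_Q1", "A_2015_Q2"))

  # 12 monthly dates -> exactly 4 quarters
  months <- lapply(1:12, function(m)
    makeSow(sprintf("m%02d", m),
            entry = as.Date(sprintf("2017-%02d-15", m)), upTo = 1L))
  labs <- buildHYQ(do.call(bindSows, months))
  expect_equal(length(unique(labs)), 4L)

  norm <- makeSow("nd", upTo = 1L)
  norm$insem_date <- as.Date(NA)
  expect_error(buildHYQ(norm), "nd")
})

test_that("across-parity coding keeps culled sows in parities 2-6 only", {
  rec <- bindSows(
    makeSow("p1", rmParity = 3L, reason = "POP"),
    makeSow("p2", rmParity = 3L, reason = "OTHER"),
    makeSow("p3", rmParity = 3L, reason = "OTHER"),
    makeSow("early", rmParity = 1L, reason = "POP"),   # parity 1: excluded
    makeSow("alive", upTo = 4L))                        # never removed
  ds <- codeAcrossParity(rec)
  expect_s4_class(ds, "TraitData")
  expect_setequal(ds@sowId, c("p1", "p2", "p3"))
  expect_equal(ds@phenotype[match(c("p1", "p2", "p3"), ds@sowId)],
               c(1L, 0L, 0L))
  expect_equal(unique(ds@parity), 3L)
  expect_false("early" %in% ds@sowId)
  expect_false("alive" %in% ds@sowId)
})

test_that("by-parity coding puts sows at risk with correct phenotypes", {
  rec <- bindSows(
    makeSow("pop4", rmParity = 4L, reason = "POP"),
    makeSow("oth5", rmParity = 5L, reason = "OTHER"),
    makeSow("alive", upTo = 6L))
  d4 <- codeByParity(rec, 4L)
  d5 <- codeByParity(rec, 5L)
  expect_equal(d4@phenotype[d4@sowId == "pop4"], 1L)
  expect_false("pop4" %in% d5@sowId)           # removed sows have no later record
  expect_equal(d4@phenotype[d4@sowId == "oth5"], 0L)
  expect_equal(d5@phenotype[d5@sowId == "oth5"], 0L)
  expect_equal(d5@phenotype[d5@sowId == "alive"], 0L)
  expect_error(codeByParity(rec, 7L), "2..6")
})

test_that("across-parity cases equal the union of by-parity cases", {
  set.seed(31)
  sc <- simScenario(nSows = 1500, nMarkers = 60, nChromosomes = 2,
                    nQtl = 10, seed = 31)
  g <- simulateGenotypes(sc, nInd = 1500)
  rec <- simulatePopRecords(g, sc)$records
  qc <- qcFilter(rec)
  expect_identical(qc$records, rec)  # generator emits clean data
  across <- codeAcrossParity(qc$records)
  byCases <- unlist(lapply(2:6, function(p) {
    d <- codeByParity(qc$records, p)
    d@sowId[d@phenotype == 1L]
  }))
  expect_setequal(byCases, across@sowId[across@phenotype == 1L])
  # across size = culled sows with removal parity in 2..6
  nExpected <- length(unique(rec$sow_id[!is.na(rec$removal_parity) &
                                          rec$removal_parity %in% 2:6]))
  expect_equal(length(across@sowId), nExpected)
})

test_that("synthetic cull cohort hits its prolapse fraction", {
  set.seed(77)
  n <- 500
  hyq <- factor(rep(sprintf("h%d", 1:10), length.out = n))
  ph <- rbinom(n, 1, 0.10)
  ds <- new("TraitData", sowId = sprintf("s%03d", 1:n),
            phenotype = as.integer(ph), hyq = hyq,
            parity = rep(3L, n), tag = "ACROSS")
  # binomial 99% interval around 0.10 at n = 500
  half <- qnorm(0.995) * sqrt(0.1 * 0.9 / n)
  expect_lt(abs(mean(ds@phenotype) - 0.10), half + 1e-9)
})
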