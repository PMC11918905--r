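test_that("long-format loading retains complete participants and applies the inclusion rule", {
  catalog <- defaultItemCatalog()
  a <- randomScoreArray(2, 5, catalog, seed = 11)
  path <- writeTempCsv(arrayToLong(a))
  panel <- loadPanel(path)
  expect_s4_class(panel, "SymptomPanel")
  expect_identical(length(participantIds(panel)), 2L)
  expect_identical(nrow(panel), 62L)
  expect_identical(ncol(panel), 10L)
  expect_identical(nrow(exclusionLog(panel)), 0L)

  # a third participant with only 3 complete waves is excluded and logged
  b <- randomScoreArray(3, 5, catalog, seed = 12)
  b["S03", c("W4", "W5"), ] <- NA
  path2 <- writeTempCsv(arrayToLong(b))
  expect_message(panel2 <- loadPanel(path2), "1 participant")
  expect_identical(sort(participantIds(panel2)), c("S01", "S02"))
  expect_identical(nrow(exclusionLog(panel2)), 1L)
  expect_identical(exclusionLog(panel2)$participant, "S03")
  expect_identical(exclusionLog(panel2)$nCompleteWaves, 3)

  # a wave missing a single item is dropped wholly, never imputed
  cc <- randomScoreArray(2, 5, catalog, seed = 13)
  cc["S01", "W2", 5] <- NA
  panel3 <- loadPanel(writeTempCsv(arrayToLong(cc)))
  cd <- SummarizedExperiment::colData(panel3)
  expect_identical(sum(cd$participant == "S01"), 4L)
  expect_false("W2" %in% cd$wave[cd$participant == "S01"])
})

test_that("malformed input is rejected with the offending location", {
  catalog <- makeItemCatalog(3)
  a <- randomScoreArray(2, 5, catalog, seed = 2)
  df <- arrayToLong(a)
  bad <- df
  bad$score[7] <- 4  # IDS items span 0-3
  expect_error(loadPanel(writeTempCsv(bad), config = list(catalog = catalog)),
               "out of range.*IDS.*line 8")
  dup <- rbind(df, df[3, ])
  expect_error(loadPanel(writeTempCsv(dup), config = list(catalog = catalog)),
               "duplicate")
  expect_error(loadPanel(writeTempCsv(df[, -4]),
                         config = list(catalog = catalog)),
               "missing column")
  unknown <- df
  unknown$item[1] <- "XXX9"
  expect_error(loadPanel(writeTempCsv(unknown),
                         config = list(catalog = catalog)),
               "unknown item")
  expect_error(loadPanel(tempfile(), config = list(catalog = catalog)),
               "not found")
})

test_that("write/load round trip reproduces scores, flags and covariates", {
  catalog <- makeItemCatalog(5)
  a <- randomScoreArray(3, 5, catalog, seed = 3)
  set.seed(30)
  ad <- matrix(runif(15) < 0.5, 3, 5, dimnames = dimnames(a)[1:2])
  mdd <- matrix(runif(15) < 0.5, 3, 5, dimnames = dimnames(a)[1:2])
  panel <- suppressMessages(SymptomPanel(a, catalog = catalog,
                                         covariates = tinyCovariates(dimnames(a)[[1]]),
                                         diagnosisAD = ad, diagnosisMDD = mdd))
  pPath <- tempfile(fileext = ".csv")
  cPath <- tempfile(fileext = ".csv")
  writePanel(panel, pPath)
  writeCovariates(panel, cPath)
  back <- loadPanel(pPath, cPath, config = list(catalog = catalog))
  expect_identical(scoreMatrix(back), scoreMatrix(panel))
  expect_identical(diagnosisFlags(back)$AD[, ], diagnosisFlags(panel)$AD[, ])
  expect_identical(diagnosisFlags(back)$MDD[, ], diagnosisFlags(panel)$MDD[, ])
  expect_equal(covariates(back)$age, covariates(panel)$age)
})

test_that("group-level standardization matches direct arithmetic", {
  # item 1 pooled scores {0,1,2,3} equally frequent over 2 participants x 4 waves
  catalog <- makeItemCatalog(2)
  a <- array(NA_real_, c(2, 4, 2),
             dimnames = list(c("S01", "S02"), paste0("W", 1:4),
                             catalog$itemId))
  a[1, , 1] <- 0:3; a[2, , 1] <- 3:0
  a[1, , 2] <- c(1, 2, 1, 2); a[2, , 2] <- c(2, 1, 2, 1)
  panel <- makeTinyPanel(scores = a, catalog = catalog)
  sp <- standardize(panel)
  pooled <- rep(0:3, 2)
  expect_equal(SummarizedExperiment::rowData(sp)$itemMean[1], 1.5,
               ignore_attr = TRUE)
  expect_equal(SummarizedExperiment::rowData(sp)$itemSD[1],
               stats::sd(pooled), ignore_attr = TRUE)
  expect_equal(zMatrix(sp)[1, 1], (0 - 1.5) / stats::sd(pooled))
  # raw per-participant item means are computed before standardization
  expect_equal(rawItemMeans(sp)["S01", 1], mean(0:3), ignore_attr = TRUE)
  expect_equal(rawItemMeans(sp)["S02", 2], mean(c(2, 1, 2, 1)),
               ignore_attr = TRUE)
})

test_that("pooled z-scores have mean 0 and sample SD 1 per item", {
  sp <- standardize(makeTinyPanel(n = 6, P = 5, seed = 8))
  z <- zMatrix(sp)
  expect_lt(max(abs(rowMeans(z))), 1e-8)
  expect_lt(max(abs(apply(z, 1, stats::sd) - 1)), 1e-8)
})

test_that("zero-variance items map to z = 0 with a warning, and are flagged", {
  catalog <- makeItemCatalog(3)
  a <- randomScoreArray(3, 4, catalog, seed = 4)
  a[, , 2] <- 0
  panel <- makeTinyPanel(scores = a, catalog = catalog)
  expect_warning(sp <- standardize(panel), "zero-variance")
  expect_true(all(zMatrix(sp)[2, ] == 0))
  expect_true(SummarizedExperiment::rowData(sp)$zeroVariance[2])
  expect_false(any(SummarizedExperiment::rowData(sp)$zeroVariance[-2]))
})

test_that("standardization is idempotent up to tolerance", {
  sp <- standardize(makeTinyPanel(n = 5, P = 4, seed = 5))
  sp2 <- standardize(sp)
  expect_lt(max(abs(zMatrix(sp2) - zMatrix(sp))), 1e-8)
})

test_that("the inclusion rule is order-independent", {
  catalog <- makeItemCatalog(4)
  a <- randomScoreArray(5, 5, catalog, seed = 6)
  a["S02", c("W1", "W3"), ] <- NA   # 3 complete waves -> excluded
  a["S04", "W5", 2] <- NA           # 4 complete waves -> retained
  p1 <- suppressMessages(makeTinyPanel(scores = a, catalog = catalog))
  perm <- c("S05", "S03", "S01", "S04", "S02")
  p2 <- suppressMessages(makeTinyPanel(scores = a[perm, , ],
                                       catalog = catalog))
  expect_setequal(participantIds(p1), participantIds(p2))
  expect_setequal(exclusionLog(p1)$participant, exclusionLog(p2)$participant)
})

test_that("construction rejects out-of-range scores naming the item", {
  catalog <- makeItemCatalog(3)
  a <- randomScoreArray(2, 4, catalog, seed = 7)
  a[1, 2, 3] <- 9
  expect_error(makeTinyPanel(scores = a, catalog = catalog),
               "out of range.*IDS03")
})
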