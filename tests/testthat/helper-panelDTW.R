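# shared fixture builders; everything is generated in code under fixed seeds

tinyCovariates <- function(pid) {
  data.frame(participant = pid,
             age = 30 + seq_along(pid),
             sex = rep_len(0:1, length(pid)),
             education = rep_len(1:3, length(pid)),
             stringsAsFactors = FALSE)
}

# random in-range score array [participant, wave, item] for a given catalog
randomScoreArray <- function(n, W, catalog, seed = 1) {
  set.seed(seed)
  P <- nrow(catalog)
  a <- array(NA_real_, c(n, W, P),
             dimnames = list(sprintf("S%02d", seq_len(n)),
                             paste0("W", seq_len(W)),
                             catalog$itemId))
  for (j in seq_len(P))
    a[, , j] <- sample(catalog$minScore[j]:catalog$maxScore[j], n * W,
                       replace = TRUE)
  a
}

makeTinyPanel <- function(n = 3, W = 5, P = 4, seed = 1, scores = NULL,
                          catalog = makeItemCatalog(P), ...) {
  if (is.null(scores)) scores <- randomScoreArray(n, W, catalog, seed)
  suppressMessages(SymptomPanel(
    scores, waveTimes = seq_len(dim(scores)[2]) * 2 - 2, catalog = catalog,
    covariates = tinyCovariates(dimnames(scores)[[1]]), ...))
}

# long-format data.frame from a score array (rows for observed cells only)
arrayToLong <- function(a, ad = NULL, mdd = NULL) {
  dn <- dimnames(a)
  idx <- which(!is.na(a), arr.ind = TRUE)
  out <- data.frame(participant = dn[[1]][idx[, 1]],
                    wave = dn[[2]][idx[, 2]],
                    item = dn[[3]][idx[, 3]],
                    score = a[idx], stringsAsFactors = FALSE)
  if (!is.null(ad)) {
    out$ad <- ad[cbind(idx[, 1], idx[, 2])]
    out$mdd <- mdd[cbind(idx[, 1], idx[, 2])]
  }
  out[order(out$participant, out$wave, out$item), ]
}

writeTempCsv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
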