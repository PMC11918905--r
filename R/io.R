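#' Load a symptom panel from delimited text
#'
#' Reads a long-format (\code{participant, wave, item, score} plus optional
#' \code{ad}, \code{mdd} flag columns) or wide-format (one
#' \code{<item>_<wave>} column per item and wave, optional \code{AD_<wave>} /
#' \code{MDD_<wave>} columns) delimited file together with a participant
#' covariate table, validates it against the item catalog and applies the
#' inclusion rule (at least four complete waves by default).
#'
#' @param path path to the panel file (comma- or tab-delimited; the delimiter
#'   is sniffed from the header line).
#' @param covariatesPath optional path to a covariate table with columns
#'   \code{participant, age, sex, education}.
#' @param config list of options: \code{format} ("long" or "wide"),
#'   \code{catalog} (default \code{\link{defaultItemCatalog}()}),
#'   \code{waves} (ordered wave labels; default the sorted unique waves in
#'   the file), \code{waveTimes} (numeric, default \code{c(0,2,4,6,9)} when 5
#'   waves), \code{minCompleteWaves} (default 4). May also be the path of a
#'   YAML file holding these fields.
#' @return A validated \linkS4class{SymptomPanel}; excluded participants are
#'   logged in \code{exclusionLog()}.
#' @export
loadPanel <- function(path, covariatesPath = NULL, config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  catalog <- config$catalog
  if (is.null(catalog)) catalog <- defaultItemCatalog()
  if (is.character(catalog)) catalog <- utils::read.csv(catalog)
  validateCatalog(catalog)
  format <- if (is.null(config$format)) "long" else
    match.arg(config$format, c("long", "wide"))
  if (!file.exists(path)) stop("panel file not found: ", path)
  sep <- sniffSep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)

  if (format == "long") {
    need <- c("participant", "wave", "item", "score")
    if (!all(need %in% names(raw)))
      stop("malformed long panel: missing column(s) ",
           paste(setdiff(need, names(raw)), collapse = ", "))
    raw$participant <- as.character(raw$participant)
    raw$wave <- as.character(raw$wave)
    unknown <- setdiff(unique(raw$item), catalog$itemId)
    if (length(unknown))
      stop("unknown item(s) not in catalog: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    key <- paste(raw$participant, raw$wave, raw$item, sep = "\r")
    if (anyDuplicated(key)) {
      d <- which(duplicated(key))[1L]
      stop("duplicate (participant, wave, item) record at line ", d + 1L,
           ": ", raw$participant[d], " / ", raw$wave[d], " / ", raw$item[d])
    }
    if (!is.numeric(raw$score))
      stop("malformed panel: non-numeric score at line ",
           which(is.na(suppressWarnings(as.numeric(raw$score))) &
                   !is.na(raw$score))[1L] + 1L)
    j <- match(raw$item, catalog$itemId)
    bad <- which(!is.na(raw$score) &
                   (raw$score < catalog$minScore[j] |
                      raw$score > catalog$maxScore[j]))
    if (length(bad))
      stop("score out of range for item ", raw$item[bad[1L]],
           " at line ", bad[1L] + 1L, " (value ", raw$score[bad[1L]], ")")
    waves <- config$waves
    if (is.null(waves)) waves <- sort(unique(raw$wave))
    pid <- unique(raw$participant)
    scores <- array(NA_real_, c(length(pid), length(waves), nrow(catalog)),
                    dimnames = list(pid, waves, catalog$itemId))
    scores[cbind(match(raw$participant, pid), match(raw$wave, waves), j)] <-
      raw$score
    ad <- mdd <- matrix(FALSE, length(pid), length(waves),
                        dimnames = list(pid, waves))
    if (all(c("ad", "mdd") %in% names(raw))) {
      pw <- !duplicated(paste(raw$participant, raw$wave, sep = "\r"))
      ad[cbind(match(raw$participant[pw], pid), match(raw$wave[pw], waves))] <-
        as.logical(raw$ad[pw])
      mdd[cbind(match(raw$participant[pw], pid), match(raw$wave[pw], waves))] <-
        as.logical(raw$mdd[pw])
    }
  } else {
    if (!"participant" %in% names(raw))
      stop("malformed wide panel: missing participant column")
    pid <- as.character(raw$participant)
    itemCols <- grep("^(IDS|BAI|PSWQ|IT)[0-9]+_", names(raw), value = TRUE)
    parts <- regmatches(itemCols, regexpr("_[^_]+$", itemCols))
    waves <- config$waves
    if (is.null(waves)) waves <- sort(unique(sub("^_", "", parts)))
    scores <- array(NA_real_, c(length(pid), length(waves), nrow(catalog)),
                    dimnames = list(pid, waves, catalog$itemId))
    for (cn in itemCols) {
      it <- sub("_[^_]+$", "", cn)
      wv <- sub("^.*_", "", cn)
      if (!it %in% catalog$itemId) stop("unknown item column: ", cn)
      scores[, match(wv, waves), match(it, catalog$itemId)] <- raw[[cn]]
    }
    ad <- mdd <- matrix(FALSE, length(pid), length(waves),
                        dimnames = list(pid, waves))
    for (w in waves) {
      if (paste0("AD_", w) %in% names(raw))
        ad[, w] <- as.logical(raw[[paste0("AD_", w)]])
      if (paste0("MDD_", w) %in% names(raw))
        mdd[, w] <- as.logical(raw[[paste0("MDD_", w)]])
    }
    j <- seq_len(nrow(catalog))
  }

  covTab <- NULL
  if (!is.null(covariatesPath)) {
    if (!file.exists(covariatesPath))
      stop("covariate file not found: ", covariatesPath)
    covTab <- utils::read.table(covariatesPath, header = TRUE,
                                sep = sniffSep(covariatesPath),
                                stringsAsFactors = FALSE)
    covTab$participant <- as.character(covTab$participant)
  }
  waveTimes <- config$waveTimes
  if (is.null(waveTimes))
    waveTimes <- if (dim(scores)[2L] == 5L) c(0, 2, 4, 6, 9) else
      seq_len(dim(scores)[2L]) - 1
  mcw <- if (is.null(config$minCompleteWaves)) 4L else
    as.integer(config$minCompleteWaves)
  SymptomPanel(scores, waveTimes = waveTimes, catalog = catalog,
               covariates = covTab, diagnosisAD = ad, diagnosisMDD = mdd,
               minCompleteWaves = mcw)
}

sniffSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Write a panel back to long-format delimited text
#'
#' Exports all retained assessments as one record per participant, wave and
#' item, with the diagnosis flags repeated per record. For a
#' \linkS4class{StandardizedPanel} a \code{z} column is appended, so the
#' standardized panel round-trips in the same dialect.
#'
#' @param panel a \linkS4class{SymptomPanel} or \linkS4class{StandardizedPanel}.
#' @param path output file path (comma-delimited).
#' @return Invisibly, the data.frame that was written.
#' @export
writePanel <- function(panel, path) {
  sc <- scoreMatrix(panel)
  cd <- SummarizedExperiment::colData(panel)
  fl <- diagnosisFlags(panel)
  wIdx <- match(cd$wave, waveLabels(panel))
  out <- data.frame(
    participant = rep(cd$participant, each = nrow(sc)),
    wave = rep(cd$wave, each = nrow(sc)),
    item = rep(rownames(sc), times = ncol(sc)),
    score = as.vector(sc),
    ad = rep(fl$AD[cbind(match(cd$participant, rownames(fl$AD)), wIdx)],
             each = nrow(sc)),
    mdd = rep(fl$MDD[cbind(match(cd$participant, rownames(fl$MDD)), wIdx)],
              each = nrow(sc)),
    stringsAsFactors = FALSE
  )
  if (methods::is(panel, "StandardizedPanel"))
    out$z <- as.vector(zMatrix(panel))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Write the participant covariate table
#'
#' @param panel a \linkS4class{SymptomPanel}.
#' @param path output file path (comma-delimited).
#' @return Invisibly, the covariate data.frame.
#' @export
writeCovariates <- function(panel, path) {
  utils::write.csv(covariates(panel), path, row.names = FALSE, quote = FALSE)
  invisible(covariates(panel))
}
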