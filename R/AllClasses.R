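#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors DataFrame metadata SimpleList
NULL

#' SymptomPanel: validated sparse symptom panel
#'
#' An S4 container for sparse longitudinal symptom panels, extending
#' \linkS4class{SummarizedExperiment}. Rows are questionnaire items (the item
#' catalog lives in \code{rowData}), columns are participant-by-wave
#' assessments. Only \emph{complete} waves (all items observed) of
#' \emph{retained} participants (at least \code{minCompleteWaves} complete
#' waves, four by default) are kept; excluded participants are recorded in
#' the exclusion log. Participant covariates (age, sex, education) and the
#' per-assessment anxiety/depression diagnosis flags are stored in
#' \code{metadata}.
#'
#' @slot .. inherits all slots from \code{SummarizedExperiment}.
#' @seealso \code{\link{SymptomPanel}} (constructor),
#'   \code{\link{standardize}}, \code{\link{loadPanel}}
#' @aliases SymptomPanel-class
#' @export
setClass("SymptomPanel", contains = "SummarizedExperiment")

#' StandardizedPanel: group-level standardized symptom panel
#'
#' A \linkS4class{SymptomPanel} whose scores have been group-level
#' standardized: for every item, z = (score - pooled mean) / pooled SD,
#' pooled over all participants and complete waves. Adds a \code{"z"} assay,
#' per-item pooled means/SDs in \code{rowData} and the matrix of raw
#' per-participant item means (computed \emph{before} standardization) in
#' \code{metadata}.
#'
#' @aliases StandardizedPanel-class
#' @export
setClass("StandardizedPanel", contains = "SymptomPanel")

#' SymptomNetwork: significance-filtered symptom network
#'
#' Group-level symptom network: nodes are items (with scale, centrality and
#' fixed 2-D layout coordinates), edges are the item pairs whose mean DTW
#' distance is significantly smaller than that of all remaining pairs. Edge
#' weight scale and node placement of subgroup networks are inherited from
#' the whole-group network so plots are directly comparable.
#'
#' @slot nodes data.frame: item, scale, centrality, zCentrality, isolated, x, y.
#' @slot edges data.frame of retained (significant) edges with effect sizes.
#' @slot layout numeric matrix of node coordinates (rownames = itemId).
#' @slot alpha significance level used for edge filtering.
#' @slot group group label ("all" for the whole-group network).
#' @slot effectRange numeric length-2: edge-effect range fixed for plotting.
#' @slot graph the underlying \pkg{igraph} object.
#' @aliases SymptomNetwork-class
#' @export
setClass("SymptomNetwork",
  representation(
    nodes = "data.frame",
    edges = "data.frame",
    layout = "matrix",
    alpha = "numeric",
    group = "character",
    effectRange = "numeric",
    graph = "ANY"
  )
)

setValidity("SymptomPanel", function(object) {
  msg <- character()
  if (!"scores" %in% names(SummarizedExperiment::assays(object)))
    msg <- c(msg, "assay 'scores' is required")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("itemId", "scale", "minScore", "maxScore")
  if (!all(need %in% names(rd)))
    msg <- c(msg, "rowData must contain itemId, scale, minScore, maxScore")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("participant", "wave") %in% names(cd)))
    msg <- c(msg, "colData must contain participant and wave")
  if (!length(msg) && ncol(object)) {
    sc <- SummarizedExperiment::assay(object, "scores")
    bad <- sc < rd$minScore | sc > rd$maxScore
    if (any(bad, na.rm = TRUE))
      msg <- c(msg, "scores outside the declared item ranges")
    if (anyNA(sc))
      msg <- c(msg, "retained assessments must be complete (no missing scores)")
    k <- table(cd$participant)
    mcw <- S4Vectors::metadata(object)$minCompleteWaves
    if (!is.null(mcw) && any(k < mcw))
      msg <- c(msg, sprintf("participants with fewer than %d complete waves retained", mcw))
  }
  if (length(msg)) msg else TRUE
})

setValidity("StandardizedPanel", function(object) {
  msg <- character()
  if (!"z" %in% names(SummarizedExperiment::assays(object)))
    msg <- c(msg, "assay 'z' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("itemMean", "itemSD", "zeroVariance") %in% names(rd)))
    msg <- c(msg, "rowData must contain itemMean, itemSD, zeroVariance")
  if (is.null(S4Vectors::metadata(object)$rawItemMeans))
    msg <- c(msg, "metadata must contain rawItemMeans")
  if (length(msg)) msg else TRUE
})

#' Construct a SymptomPanel from a participant x wave x item score array
#'
#' Validates scores against the item catalog, drops incomplete waves (a wave
#' is complete for a participant only if all items are observed), applies the
#' inclusion rule (at least \code{minCompleteWaves} complete waves, default
#' four) and assembles the result as a \linkS4class{SymptomPanel}.
#'
#' @param scores 3-way numeric array \code{[participant, wave, item]} with
#'   \code{NA} for missing scores. Dimnames are used when present; otherwise
#'   default participant ids \code{P0001, ...} and the catalog item ids apply.
#' @param waveTimes numeric vector of assessment times in years (metadata
#'   only; warping operates on assessment indices). Default \code{c(0,2,4,6,9)}.
#' @param catalog item catalog (see \code{\link{defaultItemCatalog}}); its
#'   rows must match the third array dimension.
#' @param covariates data.frame with columns \code{participant}, \code{age}
#'   (years), \code{sex} (0/1) and \code{education} (ordinal 1-3).
#' @param diagnosisAD,diagnosisMDD logical participant x wave matrices of
#'   diagnosis indicators; the first column is the lifetime-before-baseline
#'   flag. Default all \code{FALSE}.
#' @param minCompleteWaves inclusion threshold on complete waves (default 4).
#' @return A validated \linkS4class{SymptomPanel}. Participants failing the
#'   inclusion rule are excluded and recorded in \code{exclusionLog()}.
#' @examples
#' cfg <- cohortConfig(nPerGroup = c(control = 3, AD = 2, MDD = 2, comorbid = 3))
#' sim <- simulateCohort(cfg)
#' sim$panel
#' @export
SymptomPanel <- function(scores, waveTimes = c(0, 2, 4, 6, 9),
                         catalog = defaultItemCatalog(),
                         covariates = NULL,
                         diagnosisAD = NULL, diagnosisMDD = NULL,
                         minCompleteWaves = 4L) {
  stopifnot(is.array(scores), length(dim(scores)) == 3L)
  validateCatalog(catalog)
  n <- dim(scores)[1L]; W <- dim(scores)[2L]; P <- dim(scores)[3L]
  if (P != nrow(catalog))
    stop("third dimension of scores (", P, ") does not match catalog size (",
         nrow(catalog), ")")
  if (length(waveTimes) != W)
    stop("waveTimes length does not match the wave dimension")
  pid <- dimnames(scores)[[1L]]
  if (is.null(pid)) pid <- sprintf("P%04d", seq_len(n))
  waves <- dimnames(scores)[[2L]]
  if (is.null(waves)) waves <- paste0("W", seq_len(W))

  ## range validation (before any exclusion, so errors name the offence)
  for (j in seq_len(P)) {
    v <- scores[, , j]
    bad <- which(!is.na(v) & (v < catalog$minScore[j] | v > catalog$maxScore[j]))
    if (length(bad))
      stop("score out of range [", catalog$minScore[j], ",", catalog$maxScore[j],
           "] for item ", catalog$itemId[j])
  }

  complete <- !apply(is.na(scores), c(1L, 2L), any)      # participant x wave
  nComplete <- rowSums(complete)
  keep <- nComplete >= minCompleteWaves
  exclusionLog <- data.frame(participant = pid[!keep],
                             nCompleteWaves = nComplete[!keep],
                             stringsAsFactors = FALSE)
  if (!any(keep))
    stop("no participant has >= ", minCompleteWaves, " complete waves")
  if (nrow(exclusionLog))
    message(nrow(exclusionLog), " participant(s) excluded (< ",
            minCompleteWaves, " complete waves)")

  if (is.null(covariates)) {
    covariates <- data.frame(participant = pid, age = NA_real_,
                             sex = NA_real_, education = NA_real_,
                             stringsAsFactors = FALSE)
  }
  need <- c("participant", "age", "sex", "education")
  if (!all(need %in% names(covariates)))
    stop("covariates must contain columns: ", paste(need, collapse = ", "))
  if (!all(pid[keep] %in% covariates$participant))
    stop("covariates missing for participant(s): ",
         paste(utils::head(setdiff(pid[keep], covariates$participant), 5L),
               collapse = ", "))

  blank <- matrix(FALSE, n, W, dimnames = list(pid, waves))
  if (is.null(diagnosisAD)) diagnosisAD <- blank
  if (is.null(diagnosisMDD)) diagnosisMDD <- blank
  stopifnot(all(dim(diagnosisAD) == c(n, W)), all(dim(diagnosisMDD) == c(n, W)))
  dimnames(diagnosisAD) <- dimnames(diagnosisMDD) <- list(pid, waves)

  ## flatten retained complete waves to an item x assessment matrix
  idx <- which(complete & keep, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  m <- matrix(NA_real_, nrow = P, ncol = nrow(idx),
              dimnames = list(catalog$itemId,
                              paste(pid[idx[, 1L]], waves[idx[, 2L]], sep = ".")))
  for (r in seq_len(nrow(idx)))
    m[, r] <- scores[idx[r, 1L], idx[r, 2L], ]

  cd <- S4Vectors::DataFrame(
    participant = pid[idx[, 1L]],
    wave = waves[idx[, 2L]],
    waveTime = waveTimes[idx[, 2L]],
    row.names = colnames(m)
  )
  keepPid <- pid[keep]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(scores = m),
    rowData = S4Vectors::DataFrame(catalog, row.names = catalog$itemId),
    colData = cd,
    metadata = list(
      covariates = covariates[match(keepPid, covariates$participant), ,
                              drop = FALSE],
      diagnosisAD = diagnosisAD[keepPid, , drop = FALSE],
      diagnosisMDD = diagnosisMDD[keepPid, , drop = FALSE],
      waves = waves,
      waveTimes = waveTimes,
      minCompleteWaves = as.integer(minCompleteWaves),
      exclusionLog = exclusionLog
    )
  )
  methods::new("SymptomPanel", se)
}
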