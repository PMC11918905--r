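#' @name accessors
#' @title Accessors for SymptomPanel objects
#' @description Accessor generics for the panel containers: item catalog,
#'   participant ids, wave labels, covariates, diagnosis flags, exclusion log,
#'   raw score matrix and (for standardized panels) the z-score matrix and
#'   raw per-participant item means.
#' @param x A \linkS4class{SymptomPanel} or \linkS4class{StandardizedPanel}.
#' @return See the individual accessor descriptions.
NULL

#' @rdname accessors
#' @export
setGeneric("itemCatalog", function(x) standardGeneric("itemCatalog"))
#' @rdname accessors
#' @export
setGeneric("participantIds", function(x) standardGeneric("participantIds"))
#' @rdname accessors
#' @export
setGeneric("waveLabels", function(x) standardGeneric("waveLabels"))
#' @rdname accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))
#' @rdname accessors
#' @export
setGeneric("diagnosisFlags", function(x) standardGeneric("diagnosisFlags"))
#' @rdname accessors
#' @export
setGeneric("exclusionLog", function(x) standardGeneric("exclusionLog"))
#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))
#' @rdname accessors
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))
#' @rdname accessors
#' @export
setGeneric("rawItemMeans", function(x) standardGeneric("rawItemMeans"))

#' @rdname accessors
setMethod("itemCatalog", "SymptomPanel", function(x)
  as.data.frame(SummarizedExperiment::rowData(x))[
    , c("itemId", "scale", "minScore", "maxScore", "label"), drop = FALSE])

#' @rdname accessors
setMethod("participantIds", "SymptomPanel", function(x)
  unique(SummarizedExperiment::colData(x)$participant))

#' @rdname accessors
setMethod("waveLabels", "SymptomPanel", function(x)
  S4Vectors::metadata(x)$waves)

#' @rdname accessors
setMethod("covariates", "SymptomPanel", function(x)
  S4Vectors::metadata(x)$covariates)

#' @rdname accessors
setMethod("diagnosisFlags", "SymptomPanel", function(x)
  list(AD = S4Vectors::metadata(x)$diagnosisAD,
       MDD = S4Vectors::metadata(x)$diagnosisMDD))

#' @rdname accessors
setMethod("exclusionLog", "SymptomPanel", function(x)
  S4Vectors::metadata(x)$exclusionLog)

#' @rdname accessors
setMethod("scoreMatrix", "SymptomPanel", function(x)
  SummarizedExperiment::assay(x, "scores"))

#' @rdname accessors
setMethod("zMatrix", "StandardizedPanel", function(x)
  SummarizedExperiment::assay(x, "z"))

#' @rdname accessors
setMethod("rawItemMeans", "StandardizedPanel", function(x)
  S4Vectors::metadata(x)$rawItemMeans)

setMethod("show", "SymptomPanel", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("class:", class(object), "\n")
  cat("items:", nrow(object), " assessments:", ncol(object), "\n")
  cat("participants:", length(unique(cd$participant)),
      " (excluded:", nrow(exclusionLog(object)), ")\n")
  k <- table(table(cd$participant))
  cat("complete waves per participant:",
      paste(sprintf("%s x %s", k, names(k)), collapse = ", "), "\n")
  if (methods::is(object, "StandardizedPanel")) {
    rd <- SummarizedExperiment::rowData(object)
    nzv <- sum(rd$zeroVariance)
    cat("standardized: yes (", nzv, "zero-variance item(s) flagged )\n")
  }
})

setMethod("show", "SymptomNetwork", function(object) {
  cat("class: SymptomNetwork (group:", object@group, ")\n")
  cat("nodes:", nrow(object@nodes),
      " edges:", nrow(object@edges),
      " isolated:", sum(object@nodes$isolated), "\n")
  cat("alpha:", format(object@alpha), " effect range: [",
      paste(signif(object@effectRange, 4), collapse = ", "), "]\n")
})
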