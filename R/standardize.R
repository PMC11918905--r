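#' Group-level standardization of item scores
#'
#' Standardizes every item over the pooled sample (all retained participants
#' and all their complete waves): \eqn{z = (x - \bar x) / s} with the sample
#' (n-1) standard deviation. Items with zero pooled variance are mapped to
#' z = 0 and flagged (never dropped), so downstream warping distances remain
#' defined. Raw per-participant item means -- later used as adjustment
#' covariates -- are computed before standardization.
#'
#' Standardization is idempotent: applying it to an already standardized
#' panel leaves every value unchanged (up to numerical tolerance).
#'
#' @param x a \linkS4class{SymptomPanel} (or \linkS4class{StandardizedPanel},
#'   in which case the z-scores are re-standardized, a no-op).
#' @return A \linkS4class{StandardizedPanel} with assay \code{"z"}, per-item
#'   \code{itemMean}, \code{itemSD} and \code{zeroVariance} columns in
#'   \code{rowData}, and the participant-by-item matrix of raw means in
#'   \code{metadata(x)$rawItemMeans}.
#' @examples
#' sim <- simulateCohort(cohortConfig(nPerGroup = c(control = 3, AD = 2,
#'                                                  MDD = 2, comorbid = 3)))
#' sp <- standardize(sim$panel)
#' range(rowMeans(zMatrix(sp)))  # pooled item means ~ 0
#' @export
setGeneric("standardize", function(x) standardGeneric("standardize"))

#' @rdname standardize
setMethod("standardize", "SymptomPanel", function(x) {
  sc <- scoreMatrix(x)
  cd <- SummarizedExperiment::colData(x)

  ## raw per-participant item means, computed on the raw scores
  pf <- factor(cd$participant, levels = unique(cd$participant))
  rim <- t(rowsum(t(sc), pf) / as.vector(table(pf)))  # items x participants
  rim <- t(rim)                                       # participants x items

  mu <- rowMeans(sc)
  sdv <- apply(sc, 1L, stats::sd)
  zero <- sdv == 0 | !is.finite(sdv)
  if (any(zero))
    warning(sum(zero), " zero-variance item(s) mapped to z = 0: ",
            paste(utils::head(rownames(sc)[zero], 5L), collapse = ", "))
  denom <- ifelse(zero, 1, sdv)
  z <- (sc - mu) / denom
  z[zero, ] <- 0

  rd <- SummarizedExperiment::rowData(x)
  rd$itemMean <- mu
  rd$itemSD <- sdv
  rd$zeroVariance <- zero
  SummarizedExperiment::rowData(x) <- rd
  SummarizedExperiment::assays(x)$z <- z
  md <- S4Vectors::metadata(x)
  md$rawItemMeans <- rim
  S4Vectors::metadata(x) <- md
  methods::new("StandardizedPanel", x)
})

#' @rdname standardize
setMethod("standardize", "StandardizedPanel", function(x) {
  z <- zMatrix(x)
  mu <- rowMeans(z)
  sdv <- apply(z, 1L, stats::sd)
  zero <- sdv == 0 | !is.finite(sdv)
  denom <- ifelse(zero, 1, sdv)
  z2 <- (z - mu) / denom
  z2[zero, ] <- 0
  SummarizedExperiment::assays(x)$z <- z2
  x
})

#' Mean symptom severity covariate
#'
#' Per-participant mean symptom severity used in the density adjustment
#' models. The default is the grand mean over all standardized item scores
#' across the participant's complete waves; \code{type = "per_instrument"}
#' instead returns one mean sum score per instrument (IDS, BAI, PSWQ).
#'
#' @param x a \linkS4class{StandardizedPanel}.
#' @param type \code{"grand_z"} (default) or \code{"per_instrument"}.
#' @return A data.frame keyed by \code{participant}: column \code{severity},
#'   or one \code{severity_<scale>} column per instrument.
#' @export
meanSeverity <- function(x, type = c("grand_z", "per_instrument")) {
  type <- match.arg(type)
  stopifnot(methods::is(x, "StandardizedPanel"))
  cd <- SummarizedExperiment::colData(x)
  pf <- factor(cd$participant, levels = unique(cd$participant))
  if (type == "grand_z") {
    z <- zMatrix(x)
    sev <- rowsum(colMeans(z), pf) / as.vector(table(pf))
    return(data.frame(participant = levels(pf), severity = as.vector(sev),
                      stringsAsFactors = FALSE))
  }
  sc <- scoreMatrix(x)
  cat <- itemCatalog(x)
  out <- data.frame(participant = levels(pf), stringsAsFactors = FALSE)
  for (s in unique(cat$scale)) {
    sums <- colSums(sc[cat$scale == s, , drop = FALSE])
    out[[paste0("severity_", s)]] <-
      as.vector(rowsum(sums, pf) / as.vector(table(pf)))
  }
  out
}
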