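#' Invert mean distances to the network-density scale
#'
#' Network density is the inverse of the average DTW distance: shorter mean
#' distances mean denser, more synchronized symptom dynamics. The default is
#' the linear inversion \code{shift - meanDistance} (group contrasts and the
#' quadratic stability regression are invariant to this affine choice); the
#' reciprocal \code{1 / meanDistance} is available as an option.
#'
#' @param meanDistance numeric vector of per-participant mean distances.
#' @param invert \code{"linear"} (default) or \code{"reciprocal"}.
#' @param shift shift of the linear inversion (default 2).
#' @return Numeric vector of densities (names preserved).
#' @export
invertDistance <- function(meanDistance, invert = c("linear", "reciprocal"),
                           shift = 2) {
  invert <- match.arg(invert)
  if (invert == "linear") shift - meanDistance else 1 / meanDistance
}

#' Covariate-adjusted network density by group
#'
#' Per participant, density is the inverted mean of all pairwise item
#' distances. Group densities are adjusted for mean symptom severity, age,
#' sex and education in a linear model with the grouping factor; adjusted
#' group means with standard errors and pairwise group comparisons are
#' returned. (With one density record per participant the random-intercept
#' mixed model reduces to this fixed-effects model.)
#'
#' @param density named numeric vector of per-participant densities, e.g.
#'   \code{invertDistance(participantMeanDistances(sp))}.
#' @param grouping named character/factor vector assigning each participant
#'   to a group (e.g. diagnostic subgroup or stability category).
#' @param covariates data.frame with \code{participant}, \code{age},
#'   \code{sex}, \code{education} and \code{severity} columns.
#' @param adjust adjust for covariates (default TRUE); when FALSE, raw group
#'   means and SEs are returned (still via the same model machinery).
#' @return list of class \code{"DensityEstimate"}: \code{estimates}
#'   (data.frame \code{group}, \code{adjustedDensity}, \code{se}, \code{df},
#'   \code{n}), \code{comparisons} (pairwise contrasts with p-values) and
#'   \code{model} (the fitted \code{lm}).
#' @export
networkDensity <- function(density, grouping, covariates, adjust = TRUE) {
  ids <- names(density)
  if (is.null(ids)) stop("density must be named by participant")
  grouping <- grouping[ids]
  if (anyNA(grouping)) stop("grouping missing for some participants")
  grp <- factor(as.character(grouping))
  small <- names(table(grp))[table(grp) < 2L]
  if (length(small)) {
    warning("group(s) with < 2 participants excluded: ",
            paste(small, collapse = ", "))
    keep <- !grp %in% small
    density <- density[keep]; grp <- droplevels(grp[keep]); ids <- ids[keep]
  }
  dat <- data.frame(density = as.vector(density), group = grp,
                    participant = ids, stringsAsFactors = FALSE)
  if (adjust) {
    need <- c("participant", "age", "sex", "education", "severity")
    if (!all(need %in% names(covariates)))
      stop("covariates must contain: ", paste(need, collapse = ", "))
    m <- match(ids, covariates$participant)
    if (anyNA(m)) stop("covariates missing for some participants")
    dat <- cbind(dat, covariates[m, c("age", "sex", "education", "severity")])
    fit <- stats::lm(density ~ severity + age + sex + education + group,
                     data = dat)
  } else {
    fit <- stats::lm(density ~ group, data = dat)
  }
  emm <- emmeans::emmeans(fit, "group")
  est <- as.data.frame(emm)
  estimates <- data.frame(group = as.character(est$group),
                          adjustedDensity = est$emmean,
                          se = est$SE, df = est$df,
                          n = as.vector(table(grp)[as.character(est$group)]),
                          stringsAsFactors = FALSE)
  cmp <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"))
  structure(list(estimates = estimates, comparisons = cmp, model = fit),
            class = "DensityEstimate")
}

#' @export
print.DensityEstimate <- function(x, ...) {
  cat("Adjusted network density by group:\n")
  print(x$estimates, row.names = FALSE, digits = 4)
  cat("\nPairwise comparisons:\n")
  print(x$comparisons[, c("contrast", "estimate", "SE", "p.value")],
        row.names = FALSE, digits = 4)
  invisible(x)
}
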