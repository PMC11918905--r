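#' Disease-state stability score and diagnostic subgroup
#'
#' The stability score counts, over the five diagnostic assessments
#' (lifetime-before-baseline plus four follow-up intervals), how often an
#' anxiety and/or depressive diagnosis was present, yielding 0-5. It is a
#' count, not a sequence: reordering the assessments leaves it unchanged.
#' Score 0 identifies the controls; mid-range scores (2-3) flag unstable
#' disease states, 4-5 relatively stable disease. The diagnostic subgroup is
#' derived from the same flags: ever-AD without MDD, ever-MDD without AD,
#' both (comorbid), or neither (control).
#'
#' @param ad,mdd logical participant x assessment matrices (first column =
#'   lifetime-before-baseline flag), or a \linkS4class{SymptomPanel} as
#'   \code{ad} (flags are then taken from the panel metadata).
#' @return data.frame: \code{participant}, \code{score} (0-5),
#'   \code{subgroup} (control / AD_only / MDD_only / comorbid) and
#'   \code{category} (stable_health 0-1 / unstable 2-3 / stable_disease 4-5).
#' @examples
#' ad <- rbind(A = c(FALSE, FALSE, FALSE, FALSE, FALSE),
#'             B = c(TRUE, TRUE, FALSE, TRUE, TRUE))
#' mdd <- rbind(A = rep(FALSE, 5), B = c(TRUE, FALSE, FALSE, TRUE, TRUE))
#' stabilityScore(ad, mdd)
#' @export
stabilityScore <- function(ad, mdd = NULL) {
  if (methods::is(ad, "SymptomPanel")) {
    fl <- diagnosisFlags(ad)
    ad <- fl$AD; mdd <- fl$MDD
  }
  ad <- as.matrix(ad); mdd <- as.matrix(mdd)
  if (!identical(dim(ad), dim(mdd)))
    stop("AD and MDD flag matrices must have identical dimensions")
  if (anyNA(ad) || anyNA(mdd))
    stop("missing diagnosis flag: no partial stability scores are computed")
  score <- as.integer(rowSums(ad | mdd))
  everAD <- rowSums(ad) > 0
  everMDD <- rowSums(mdd) > 0
  subgroup <- ifelse(everAD & everMDD, "comorbid",
               ifelse(everAD, "AD_only",
                ifelse(everMDD, "MDD_only", "control")))
  pid <- rownames(ad)
  if (is.null(pid)) pid <- sprintf("P%04d", seq_len(nrow(ad)))
  data.frame(participant = pid,
             score = score,
             subgroup = factor(subgroup, levels = c("control", "AD_only",
                                                    "MDD_only", "comorbid")),
             category = stabilityCategory(score),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Map stability scores to interpretation categories
#'
#' 0-1: stable health; 2-3: unstable (alternation between health and disease
#' states); 4-5: stable disease.
#'
#' @param score integer vector of stability scores.
#' @return factor with levels stable_health, unstable, stable_disease.
#' @export
stabilityCategory <- function(score) {
  cut(score, breaks = c(-Inf, 1, 3, Inf),
      labels = c("stable_health", "unstable", "stable_disease"))
}

#' Quadratic model of network density versus disease-state stability
#'
#' Implements the two-step procedure: per-participant density is first
#' residualized on mean symptom severity, age, sex and education; the
#' residuals are then regressed on the stability score with linear and
#' quadratic terms. A negative quadratic coefficient indicates an
#' inverted-U: density peaks at the unstable mid-range scores. Adjusted mean
#' densities per score level (residual means with standard errors) are
#' returned alongside. A single joint model (density on covariates and the
#' stability polynomial together) is available via \code{twoStep = FALSE}.
#'
#' @param density named per-participant density vector.
#' @param profiles data.frame from \code{\link{stabilityScore}} (columns
#'   \code{participant}, \code{score}).
#' @param covariates data.frame with \code{participant}, \code{age},
#'   \code{sex}, \code{education}, \code{severity}.
#' @param twoStep residualize first (default, the literal procedure) or fit
#'   one joint model.
#' @return list of class \code{"QuadraticFit"}: \code{betaLinear},
#'   \code{betaQuadratic}, \code{pLinear}, \code{pQuadratic},
#'   \code{adjustedMeans} (per score level: mean residual density, SE, n),
#'   \code{model}, \code{residualModel}.
#' @export
densityVsStability <- function(density, profiles, covariates,
                               twoStep = TRUE) {
  ids <- names(density)
  if (is.null(ids)) stop("density must be named by participant")
  score <- profiles$score[match(ids, profiles$participant)]
  if (anyNA(score)) stop("stability score missing for some participants")
  if (length(unique(score)) < 3L)
    stop("need >= 3 distinct stability scores for a quadratic fit")
  m <- match(ids, covariates$participant)
  if (anyNA(m)) stop("covariates missing for some participants")
  dat <- data.frame(density = as.vector(density), score = score,
                    covariates[m, c("age", "sex", "education", "severity")])

  X <- stats::model.matrix(~ severity + age + sex + education, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("collinear covariate column(s): ", paste(dropped, collapse = ", "))
  }

  if (twoStep) {
    resFit <- stats::lm(density ~ severity + age + sex + education, dat)
    dat$resid <- stats::resid(resFit)
    fit <- stats::lm(resid ~ score + I(score^2), dat)
  } else {
    resFit <- NULL
    fit <- stats::lm(density ~ severity + age + sex + education +
                       score + I(score^2), dat)
    dat$resid <- stats::resid(stats::lm(density ~ severity + age + sex +
                                          education, dat))
  }
  co <- summary(fit)$coefficients
  am <- do.call(rbind, lapply(split(dat$resid, dat$score), function(v)
    data.frame(mean = mean(v),
               se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else
                 NA_real_,
               n = length(v))))
  am <- data.frame(score = as.integer(rownames(am)), am, row.names = NULL)
  structure(list(
    betaLinear = co["score", "Estimate"],
    betaQuadratic = co["I(score^2)", "Estimate"],
    pLinear = co["score", "Pr(>|t|)"],
    pQuadratic = co["I(score^2)", "Pr(>|t|)"],
    adjustedMeans = am,
    model = fit, residualModel = resFit),
    class = "QuadraticFit")
}

#' @export
print.QuadraticFit <- function(x, ...) {
  cat("Density ~ stability score (linear + quadratic):\n")
  cat(sprintf("  beta linear    = %8.4f (p = %.3g)\n", x$betaLinear, x$pLinear))
  cat(sprintf("  beta quadratic = %8.4f (p = %.3g)\n",
              x$betaQuadratic, x$pQuadratic))
  cat("Adjusted mean density by score:\n")
  print(x$adjustedMeans, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Mean instrument sum scores over time by group
#'
#' Per group, wave and instrument: mean sum score with standard error, the
#' tabular analog of severity-trajectory line plots. Groups of one report a
#' missing SE.
#'
#' @param panel a \linkS4class{SymptomPanel}.
#' @param grouping named character/factor vector assigning each participant
#'   to a group.
#' @return data.frame: \code{group}, \code{wave}, \code{scale},
#'   \code{meanSum}, \code{se}, \code{n}.
#' @export
severityTrajectories <- function(panel, grouping) {
  stopifnot(methods::is(panel, "SymptomPanel"))
  sc <- scoreMatrix(panel)
  cd <- SummarizedExperiment::colData(panel)
  cat <- itemCatalog(panel)
  grp <- as.character(grouping[cd$participant])
  if (anyNA(grp)) stop("grouping missing for some participants")
  out <- list()
  for (s in unique(cat$scale)) {
    sums <- colSums(sc[cat$scale == s, , drop = FALSE])
    agg <- stats::aggregate(sums,
                            by = list(group = grp, wave = cd$wave),
                            function(v) c(mean = mean(v),
                                          se = if (length(v) > 1L)
                                            stats::sd(v) / sqrt(length(v))
                                          else NA_real_,
                                          n = length(v)))
    out[[s]] <- data.frame(group = agg$group, wave = agg$wave, scale = s,
                           meanSum = agg$x[, "mean"], se = agg$x[, "se"],
                           n = as.integer(agg$x[, "n"]),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$scale, res$group, res$wave), ]
}
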