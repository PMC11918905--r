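#' Edge significance tests: is a pair's mean distance smaller than the rest?
#'
#' For every unordered item pair, contrasts that pair's per-participant DTW
#' distances against the distances of all remaining pairs, one-sided in the
#' smaller-than direction: an edge is retained when the focal pair's mean
#' distance is significantly below the rest-of-pairs reference at
#' \code{alpha} (default 1e-4, uncorrected).
#'
#' Two modes are available. \code{"ttest"} is the independent-samples Welch
#' t-test of the focal pair's distances against all remaining distances.
#' \code{"adjusted"} (default) is a linear model of distance on the
#' focal-pair indicator with participant intercepts absorbed (the
#' within-participant estimator, identical here to the fixed-effect contrast
#' of a random-intercept model because every participant contributes every
#' pair) plus an item-score adjustment: either a quadratic polynomial in
#' the pair's mean raw score (\code{edgeAdjust = "pair_mean"}, default; the
#' distance-versus-level relation is nonlinear near the response floor, and
#' the quadratic term keeps the test's size at its nominal level) or item
#' membership main effects (\code{edgeAdjust = "item_indicators"}). The
#' adjustment guards against item pairs that both stay near zero and
#' therefore have a trivially small distance. All (P^2-P)/2 models share their nuisance
#' projections, so the closed-form engine is vectorized over pairs; an
#' explicit \code{engine = "lmer"} per-pair mixed-model fit is available for
#' small problems and cross-checks.
#'
#' @param distances long distance table from \code{\link{cohortDistances}}.
#' @param alpha significance level in (0, 1); default 1e-4.
#' @param mode \code{"adjusted"} (default) or \code{"ttest"}.
#' @param edgeAdjust covariate coding for the adjusted mode.
#' @param engine \code{"closed_form"} (default) or \code{"lmer"}.
#' @param correction optional multiple-testing correction applied to the
#'   p-values before thresholding: \code{"none"} (default, the convention of
#'   the analysis this package implements), \code{"bonferroni"} or
#'   \code{"BH"}.
#' @return data.frame with one row per pair: \code{itemI}, \code{itemJ},
#'   \code{meanDistance}, \code{restMean}, \code{effect} (positive = focal
#'   pair shorter than the reference, the edge-width coefficient),
#'   \code{statistic}, \code{pValue}, \code{significant},
#'   \code{zeroVariance}. Attributes record alpha, mode and adjustment.
#' @export
testEdges <- function(distances, alpha = 1e-4,
                      mode = c("adjusted", "ttest"),
                      edgeAdjust = c("pair_mean", "item_indicators"),
                      engine = c("closed_form", "lmer"),
                      correction = c("none", "bonferroni", "BH")) {
  mode <- match.arg(mode)
  edgeAdjust <- match.arg(edgeAdjust)
  engine <- match.arg(engine)
  correction <- match.arg(correction)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  need <- c("participant", "itemI", "itemJ", "distance", "pairMeanRaw")
  if (!all(need %in% names(distances)))
    stop("distance table lacks column(s): ",
         paste(setdiff(need, names(distances)), collapse = ", "))
  if (length(unique(distances$participant)) < 2L)
    stop("edge testing requires at least 2 participants")

  pairKey <- paste(distances$itemI, distances$itemJ, sep = "~")
  pair <- factor(pairKey, levels = unique(pairKey))
  part <- factor(distances$participant, levels = unique(distances$participant))
  K <- nlevels(pair); nP <- nlevels(part); N <- nrow(distances)
  if (N != K * nP || !all(table(part) == K))
    stop("distance table must be balanced: every participant x pair once")
  y <- distances$distance

  first <- !duplicated(pair)
  out <- data.frame(itemI = distances$itemI[first],
                    itemJ = distances$itemJ[first],
                    stringsAsFactors = FALSE)
  focalSum <- as.vector(rowsum(y, pair))
  out$meanDistance <- focalSum / nP
  out$restMean <- (sum(y) - focalSum) / (N - nP)

  if (mode == "ttest") {
    sq <- as.vector(rowsum(y * y, pair))
    vF <- (sq - focalSum^2 / nP) / (nP - 1)
    nR <- N - nP
    sumR <- sum(y) - focalSum
    sqR <- sum(y * y) - sq
    vR <- (sqR - sumR^2 / nR) / (nR - 1)
    se2 <- vF / nP + vR / nR
    zero <- se2 <= 1e-14
    tstat <- ifelse(zero, 0, (out$meanDistance - out$restMean) / sqrt(se2))
    df <- ifelse(zero, 1,
                 se2^2 / ((vF / nP)^2 / (nP - 1) + (vR / nR)^2 / (nR - 1)))
    p <- ifelse(zero, 1, stats::pt(tstat, df))
    out$effect <- out$restMean - out$meanDistance
    out$statistic <- tstat
    out$pValue <- p
    out$zeroVariance <- zero
  } else if (engine == "lmer") {
    out <- edgeTestLmer(distances, pair, out, edgeAdjust)
  } else {
    ## within-participant (participant-intercepts absorbed) closed form via
    ## Frisch-Waugh: residualize y on the nuisance terms once, then for each
    ## focal-pair indicator x the slope is sum(resid over the pair's rows) /
    ## residual sum of squares of x.
    ybar <- as.vector(rowsum(y, part)) / K
    yt <- y - ybar[as.integer(part)]
    Sxx <- nP * (1 - 1 / K)
    if (edgeAdjust == "pair_mean") {
      ## quadratic polynomial in the pair mean raw score: the dependence of
      ## distance on score level is nonlinear (floor effects), and a linear
      ## term alone leaves the test slightly anti-conservative
      C <- cbind(distances$pairMeanRaw, distances$pairMeanRaw^2)
      Ct <- C - (rowsum(C, part) / K)[as.integer(part), , drop = FALSE]
      keep <- colSums(Ct * Ct) > 1e-10
      Ct <- Ct[, keep, drop = FALSE]
      if (ncol(Ct) == 2L && rcond(crossprod(Ct)) < 1e-12)
        Ct <- Ct[, 1L, drop = FALSE]
      if (ncol(Ct)) {
        G <- crossprod(Ct)
        B <- solve(G, crossprod(Ct, yt))
        ey <- as.vector(yt - Ct %*% B)
        A <- rowsum(Ct, pair)
        q <- rowSums((A %*% solve(G)) * A)
      } else {
        ey <- yt
        q <- 0
      }
      denom <- Sxx - q
      dfAdj <- nP + 1L + ncol(Ct)
    } else {
      ## item membership main effects; on the within-demeaned design the
      ## Gram matrix acts as nP * (P - 2) * I on centered coefficient
      ## vectors, giving a closed-form projection.
      P <- attr(distances, "nItems")
      if (is.null(P))
        P <- length(unique(c(out$itemI, out$itemJ)))
      if (P < 3L)
        stop("item-indicator adjustment needs at least 3 items")
      acc <- rowsum(c(yt, yt), c(distances$itemI, distances$itemJ))
      gam <- acc[, 1L] / (nP * (P - 2))          # named by itemId
      ey <- unname(yt - gam[distances$itemI] - gam[distances$itemJ])
      denom <- rep(nP * (1 - 1 / K - 2 / P), K)
      dfAdj <- nP + 1L + (P - 1L)
    }
    SSE <- sum(ey * ey)
    Sk <- as.vector(rowsum(ey, pair))
    beta <- Sk / denom
    RSS <- pmax(SSE - beta^2 * denom, 0)
    df <- N - dfAdj
    sigma2 <- RSS / df
    zero <- sigma2 <= 1e-14 | denom <= 1e-12
    se <- sqrt(ifelse(zero, 1, sigma2 / denom))
    tstat <- ifelse(zero, 0, beta / se)
    out$effect <- -beta
    out$statistic <- tstat
    out$pValue <- ifelse(zero, 1, stats::pt(tstat, df))
    out$zeroVariance <- zero
  }

  if (correction != "none")
    out$pValue <- stats::p.adjust(out$pValue,
                                  method = ifelse(correction == "BH", "BH",
                                                  "bonferroni"))
  out$significant <- out$pValue < alpha & out$meanDistance < out$restMean
  attr(out, "alpha") <- alpha
  attr(out, "mode") <- mode
  attr(out, "edgeAdjust") <- if (mode == "adjusted") edgeAdjust else NA_character_
  rownames(out) <- NULL
  out
}

## per-pair random-intercept fits; only sensible for small K
edgeTestLmer <- function(distances, pair, out, edgeAdjust) {
  K <- nlevels(pair)
  if (K > 300L)
    warning("engine = 'lmer' fits one mixed model per pair; ", K,
            " pairs will be slow")
  eff <- stat <- p <- numeric(K)
  zero <- logical(K)
  for (k in seq_len(K)) {
    dat <- data.frame(y = distances$distance,
                      x = as.integer(pair == levels(pair)[k]),
                      c = distances$pairMeanRaw,
                      id = distances$participant)
    fit <- tryCatch(
      lme4::lmer(y ~ x + c + I(c^2) + (1 | id), data = dat,
                 control = lme4::lmerControl(calc.derivs = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) { eff[k] <- 0; stat[k] <- 0; p[k] <- 1; zero[k] <- TRUE; next }
    co <- summary(fit)$coefficients
    eff[k] <- -co["x", "Estimate"]
    stat[k] <- co["x", "t value"]
    p[k] <- stats::pnorm(stat[k])      # one-sided smaller-than, normal approx
  }
  out$effect <- eff
  out$statistic <- stat
  out$pValue <- p
  out$zeroVariance <- zero
  out
}
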