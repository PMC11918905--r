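#' Default item-to-factor map for the 62-item catalog
#'
#' Schematic latent-factor assignment used by the cohort generator: sleep
#' (IDS 1-4), mood (IDS 5-17), somatic arousal (IDS 18-30 and BAI 11-21),
#' cognitive anxiety (BAI 1-10) and worry (all PSWQ items). Worry items get
#' the strongest within-factor coupling (highest loadings), emulating the
#' tight clustering of the short worry questionnaire.
#'
#' @param catalog an item catalog (default the 62-item catalog).
#' @return character vector of factor names, one per catalog row.
#' @export
defaultFactorMap <- function(catalog = defaultItemCatalog()) {
  f <- character(nrow(catalog))
  ids <- catalog$scale == "IDS"
  bai <- catalog$scale == "BAI"
  psw <- catalog$scale == "PSWQ"
  idsIdx <- cumsum(ids)
  baiIdx <- cumsum(bai)
  f[ids & idsIdx <= 4] <- "sleep"
  f[ids & idsIdx >= 5 & idsIdx <= 17] <- "mood"
  f[ids & idsIdx >= 18] <- "somatic_arousal"
  f[bai & baiIdx <= 10] <- "cognitive_anxiety"
  f[bai & baiIdx >= 11] <- "somatic_arousal"
  f[psw] <- "worry"
  f
}

#' Default item loadings
#'
#' @param catalog an item catalog.
#' @param worryLoading loading of worry (PSWQ) items (default 1.25, above
#'   the 1.0 of other items, so worry items cluster most tightly).
#' @return numeric vector of loadings, one per catalog row.
#' @export
defaultLoadings <- function(catalog = defaultItemCatalog(),
                            worryLoading = 1.25) {
  ifelse(catalog$scale == "PSWQ", worryLoading, 1)
}

#' Generator configuration for synthetic symptom-panel cohorts
#'
#' Defines the generating conditions: subgroup sizes (defaults emulate a large
#' depression-anxiety cohort: 360 controls / 158 AD / 265 MDD / 866 comorbid,
#' scaled by 1/5), five waves at years 0/2/4/6/9, the 62-item catalog with the
#' latent-factor map, per-subgroup factor coupling (controls < AD = MDD <
#' comorbid), severity offsets with an elevated baseline (producing the
#' post-baseline drop in mean scores), per-subgroup relapse/remission
#' transition probabilities for the per-wave diagnosis flags, and the
#' discretization onto each item's Likert range.
#'
#' @param nPerGroup named integer vector (control, AD, MDD, comorbid); every
#'   entry must be >= 2.
#' @param waveTimes assessment times in years.
#' @param catalog item catalog.
#' @param factorOf character vector mapping every item to a latent factor.
#' @param loading numeric item loadings.
#' @param coupling per-subgroup coupling of factors to the shared symptom
#'   state, in [0, 1); drives network density.
#' @param severityOffset per-subgroup mean offset on the latent scale.
#' @param baselineBoost extra severity at the baseline wave (post-baseline
#'   drop emulation).
#' @param arPhi,factorArPhi AR(1) coefficients of the shared state and the
#'   factor-specific states across waves.
#' @param noiseSD item-level noise SD on the latent scale (scalar or one
#'   value per item).
#' @param persistProb,relapseProb per-subgroup probabilities that a disorder
#'   present (absent) at one assessment is present at the next.
#' @param missingWaveProb probability that a participant misses one
#'   follow-up wave (yielding 4-wave participants).
#' @param seed integer seed.
#' @return list of class \code{"cohortConfig"}.
#' @export
cohortConfig <- function(nPerGroup = c(control = 72, AD = 32, MDD = 53,
                                       comorbid = 173),
                         waveTimes = c(0, 2, 4, 6, 9),
                         catalog = defaultItemCatalog(),
                         factorOf = defaultFactorMap(catalog),
                         loading = defaultLoadings(catalog),
                         coupling = c(control = 0.05, AD = 0.55,
                                      MDD = 0.60, comorbid = 0.85),
                         severityOffset = c(control = 0, AD = 0.20,
                                            MDD = 0.25, comorbid = 0.50),
                         baselineBoost = 0.35,
                         arPhi = 0.5, factorArPhi = 0.4, noiseSD = 0.8,
                         persistProb = c(control = 0, AD = 0.6,
                                         MDD = 0.6, comorbid = 0.8),
                         relapseProb = c(control = 0, AD = 0.3,
                                         MDD = 0.3, comorbid = 0.5),
                         missingWaveProb = 0.25,
                         seed = 1L) {
  validateCatalog(catalog)
  groups <- names(nPerGroup)
  if (is.null(groups) || !length(groups))
    stop("nPerGroup must be a named vector of subgroup sizes")
  if (any(nPerGroup < 2))
    stop("every subgroup needs n >= 2")
  if (length(factorOf) != nrow(catalog) || anyNA(factorOf) ||
      any(!nzchar(factorOf)))
    stop("invalid loading map: factorOf must name a factor for every item")
  if (length(loading) != nrow(catalog) || anyNA(loading))
    stop("invalid loading map: one finite loading per item required")
  for (nm in groups) {
    for (v in c("coupling", "severityOffset", "persistProb", "relapseProb")) {
      vals <- get(v)
      if (!nm %in% names(vals))
        stop(v, " missing entry for subgroup ", nm)
    }
  }
  if (any(coupling < 0 | coupling >= 1))
    stop("coupling must lie in [0, 1)")
  if (any(c(persistProb, relapseProb, missingWaveProb) < 0) ||
      any(c(persistProb, relapseProb, missingWaveProb) > 1))
    stop("probabilities must lie in [0, 1]")
  structure(list(nPerGroup = nPerGroup, waveTimes = waveTimes,
                 catalog = catalog, factorOf = factorOf, loading = loading,
                 coupling = coupling, severityOffset = severityOffset,
                 baselineBoost = baselineBoost, arPhi = arPhi,
                 factorArPhi = factorArPhi, noiseSD = noiseSD,
                 persistProb = persistProb, relapseProb = relapseProb,
                 missingWaveProb = missingWaveProb, seed = as.integer(seed)),
            class = "cohortConfig")
}

## stationary AR(1) matrix n x W, unit marginal variance
ar1Matrix <- function(n, W, phi) {
  m <- matrix(0, n, W)
  m[, 1L] <- stats::rnorm(n)
  if (W > 1L)
    for (t in 2:W)
      m[, t] <- phi * m[, t - 1L] + sqrt(1 - phi^2) * stats::rnorm(n)
  m
}

## latent-factor score simulation shared by all scenarios
simulateScoreArray <- function(n, W, catalog, factorOf, loading,
                               couplingP, offsetP, baselineBoost,
                               arPhi, factorArPhi, noiseSD) {
  P <- nrow(catalog)
  factors <- unique(factorOf)
  fIdx <- match(factorOf, factors)
  s <- ar1Matrix(n, W, arPhi)
  u <- array(0, c(n, W, length(factors)))
  for (k in seq_along(factors)) u[, , k] <- ar1Matrix(n, W, factorArPhi)
  rho <- couplingP
  noiseSD <- rep_len(noiseSD, P)                       # per-item noise allowed
  scale01 <- (catalog$maxScore - catalog$minScore) / 3  # PSWQ spans 0-4
  a <- 1.0 * scale01 + catalog$minScore
  b <- 0.9 * scale01
  scores <- array(NA_real_, c(n, W, P))
  for (t in seq_len(W)) {
    f <- rho * s[, t] +
      sqrt(1 - rho^2) * matrix(u[, t, ], n, length(factors))   # n x K
    lat <- f[, fIdx, drop = FALSE] *
      matrix(loading, n, P, byrow = TRUE) +
      matrix(stats::rnorm(n * P), n, P) *
        matrix(noiseSD, n, P, byrow = TRUE)
    mu <- offsetP + if (t == 1L) baselineBoost else 0
    raw <- matrix(a, n, P, byrow = TRUE) +
      matrix(b, n, P, byrow = TRUE) * (mu + lat)
    sc <- round(raw)
    sc <- pmax(sc, matrix(catalog$minScore, n, P, byrow = TRUE))
    sc <- pmin(sc, matrix(catalog$maxScore, n, P, byrow = TRUE))
    scores[, t, ] <- sc
  }
  scores
}

## diagnosis flag chains per disorder: baseline lifetime flag, then a
## two-state Markov chain over the four follow-up assessments
markovFlags <- function(n, W, start, persist, relapse) {
  m <- matrix(FALSE, n, W)
  m[, 1L] <- start
  if (W > 1L)
    for (t in 2:W) {
      pr <- ifelse(m[, t - 1L], persist, relapse)
      m[, t] <- stats::runif(n) < pr
    }
  m
}

drawCovariates <- function(n) {
  age <- stats::rnorm(n, 41.5, 13.2)
  age <- pmin(pmax(age, 18), 65)
  sex <- as.integer(stats::runif(n) < 0.664)
  education <- sample.int(3L, n, replace = TRUE,
                          prob = c(0.033, 0.554, 0.413))
  data.frame(age = age, sex = sex, education = education)
}

#' Generate a synthetic symptom-panel cohort with known ground truth
#'
#' Latent factor paths evolve as AR(1) processes over waves, cross-coupled
#' through a shared per-participant symptom state with subgroup-specific
#' coupling strength; item scores are the discretized (rounded and clipped)
#' loading-weighted factor values plus noise and severity offsets, with an
#' elevated baseline producing the initial post-baseline drop. Per-wave
#' diagnosis flags follow per-subgroup relapse/remission Markov chains (the
#' baseline flag is the lifetime-before-inclusion diagnosis). Covariates are
#' drawn to match typical cohort marginals (age ~ N(41.5, 13.2) truncated to
#' 18-65, 66.4\% female, education 3.3/55.4/41.3\%). Fully seeded: the same
#' config and seed regenerate the identical cohort.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param seed overrides \code{config$seed} when given.
#' @return list with \code{panel} (a \linkS4class{SymptomPanel}) and
#'   \code{truth} (per-participant subgroup, coupling, severity offset,
#'   stability score, the item-factor map and loadings).
#' @export
simulateCohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohortConfig"))
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  W <- length(config$waveTimes)
  groups <- names(config$nPerGroup)
  group <- rep(groups, config$nPerGroup)
  n <- length(group)
  pid <- sprintf("P%04d", seq_len(n))

  ad0 <- group %in% c("AD", "comorbid")
  mdd0 <- group %in% c("MDD", "comorbid")
  ad <- markovFlags(n, W, ad0, config$persistProb[group],
                    config$relapseProb[group])
  mdd <- markovFlags(n, W, mdd0, config$persistProb[group],
                     config$relapseProb[group])
  ad[!ad0, ] <- FALSE        # controls and MDD-only never receive an AD flag
  mdd[!mdd0, ] <- FALSE
  rownames(ad) <- rownames(mdd) <- pid

  scores <- simulateScoreArray(
    n, W, config$catalog, config$factorOf, config$loading,
    couplingP = config$coupling[group],
    offsetP = config$severityOffset[group],
    baselineBoost = config$baselineBoost,
    arPhi = config$arPhi, factorArPhi = config$factorArPhi,
    noiseSD = config$noiseSD)
  dimnames(scores) <- list(pid, paste0("W", seq_len(W)),
                           config$catalog$itemId)
  if (config$missingWaveProb > 0 && W > 4L) {
    miss <- stats::runif(n) < config$missingWaveProb
    dropW <- sample(2:W, n, replace = TRUE)
    for (i in which(miss)) scores[i, dropW[i], ] <- NA
  }

  cov <- cbind(participant = pid, drawCovariates(n))
  panel <- SymptomPanel(scores, waveTimes = config$waveTimes,
                        catalog = config$catalog, covariates = cov,
                        diagnosisAD = ad, diagnosisMDD = mdd)
  truth <- list(
    participant = pid, group = group,
    coupling = unname(config$coupling[group]),
    severityOffset = unname(config$severityOffset[group]),
    stability = stabilityScore(ad, mdd),
    factorOf = config$factorOf, loading = config$loading,
    config = config)
  list(panel = panel, truth = truth)
}

#' Config for a null cohort of mutually independent items
#'
#' Every item loads on its own latent factor and the shared-state coupling
#' is zero, so all item pairs are pairwise independent: the edge-test
#' false-positive rate should match its nominal alpha.
#'
#' @param n number of participants.
#' @param nItems catalog size.
#' @param seed integer seed.
#' @param ... passed to \code{\link{cohortConfig}}.
#' @return A \code{\link{cohortConfig}}.
#' @export
independentItemsConfig <- function(n = 300, nItems = 20, seed = 1L, ...) {
  catalog <- makeItemCatalog(nItems)
  cohortConfig(nPerGroup = c(control = n),
               catalog = catalog,
               factorOf = paste0("solo", seq_len(nItems)),
               loading = rep(1, nItems),
               coupling = c(control = 0),
               severityOffset = c(control = 0.3),
               persistProb = c(control = 0),
               relapseProb = c(control = 0),
               seed = seed, ...)
}

#' Config for a clustered cohort with an engineered hub item
#'
#' \code{clusterSize} items share one latent factor; all remaining items are
#' independent noise. The first cluster item is the engineered hub: its
#' item-specific noise is reduced, so its dynamics track the shared factor
#' most faithfully and its distances to the other cluster members are the
#' shortest (highest centrality), while its marginal score distribution
#' stays comparable to the members'. Within-cluster pairs are true edges;
#' every pair involving a non-cluster item is null.
#'
#' @param n participants.
#' @param nItems catalog size.
#' @param clusterSize number of items in the coupled cluster.
#' @param hubNoiseSD,noiseSD item-specific noise SD of the hub and of all
#'   other items.
#' @param seed integer seed.
#' @param ... passed to \code{\link{cohortConfig}}.
#' @return A \code{\link{cohortConfig}} whose truth is recoverable: fields
#'   \code{clusterItems} and \code{hub} record the engineered structure.
#' @export
clusterScenarioConfig <- function(n = 500, nItems = 20, clusterSize = 8,
                                  hubNoiseSD = 0.4, noiseSD = 0.8,
                                  seed = 1L, ...) {
  stopifnot(clusterSize >= 3, clusterSize <= nItems)
  catalog <- makeItemCatalog(nItems)
  factorOf <- c(rep("cluster", clusterSize),
                paste0("solo", seq_len(nItems - clusterSize)))
  cfg <- cohortConfig(nPerGroup = c(control = n),
                      catalog = catalog, factorOf = factorOf,
                      loading = rep(1, nItems),
                      coupling = c(control = 0),
                      severityOffset = c(control = 0.4),
                      noiseSD = c(hubNoiseSD, rep(noiseSD, nItems - 1L)),
                      persistProb = c(control = 0),
                      relapseProb = c(control = 0),
                      seed = seed, ...)
  cfg$clusterItems <- catalog$itemId[seq_len(clusterSize)]
  cfg$hub <- catalog$itemId[1L]
  cfg
}

#' Stability scenario: density as a prescribed function of the score
#'
#' Generates a cohort whose disease-state stability scores span 0-5 with a
#' realistic marginal distribution (overridable) and whose per-participant
#' factor coupling -- hence network density -- follows \code{targetProfile},
#' a relative density level per score. The default profile is an inverted U
#' peaking at the unstable mid scores; a flat profile yields a quadratic
#' coefficient centered on zero. Severity rises mildly with the score, so
#' the covariate adjustment is exercised.
#'
#' @param targetProfile numeric length 6 in [0, 1]: relative density for
#'   scores 0..5, mapped linearly onto \code{couplingRange}.
#' @param n participants.
#' @param scoreProbs marginal probabilities of scores 0..5 (default
#'   360/374/249/252/220/194 out of 1,649, an observed cohort marginal).
#' @param couplingRange coupling values at profile 0 and 1.
#' @param catalog item catalog (default 62 items).
#' @param severityBase,severitySlope latent severity offset: base +
#'   slope * score.
#' @param missingWaveProb as in \code{\link{cohortConfig}}.
#' @param seed integer seed.
#' @return list with \code{panel} and \code{truth} (including the realized
#'   scores, subgroups and per-participant coupling).
#' @export
makeStabilityScenario <- function(targetProfile = c(0.10, 0.35, 0.80, 1.00,
                                                    0.55, 0.35),
                                  n = 800,
                                  scoreProbs = c(360, 374, 249, 252, 220,
                                                 194) / 1649,
                                  couplingRange = c(0.08, 0.80),
                                  catalog = defaultItemCatalog(),
                                  severityBase = -0.1, severitySlope = 0.15,
                                  missingWaveProb = 0.25,
                                  seed = 1L) {
  if (length(targetProfile) != 6L || anyNA(targetProfile) ||
      any(targetProfile < 0 | targetProfile > 1))
    stop("targetProfile must give a relative density in [0,1] for scores 0..5")
  stopifnot(length(scoreProbs) == 6L, all(scoreProbs >= 0))
  set.seed(as.integer(seed))
  W <- 5L
  pid <- sprintf("P%04d", seq_len(n))
  score <- sample(0:5, n, replace = TRUE, prob = scoreProbs)

  ad <- mdd <- matrix(FALSE, n, W, dimnames = list(pid, paste0("W", 1:W)))
  kind <- rep("control", n)
  pos <- score > 0
  kind[pos] <- sample(c("AD_only", "MDD_only", "comorbid"), sum(pos),
                      replace = TRUE, prob = c(0.123, 0.206, 0.672))
  for (i in which(pos)) {
    at <- sample.int(W, score[i])
    if (kind[i] == "AD_only") ad[i, at] <- TRUE
    else if (kind[i] == "MDD_only") mdd[i, at] <- TRUE
    else {
      ad[i, at[1L]] <- mdd[i, at[1L]] <- TRUE   # comorbid: both ever present
      if (score[i] > 1L)
        for (t in at[-1L]) {
          w <- sample.int(3L, 1L)
          if (w != 2L) ad[i, t] <- TRUE
          if (w != 1L) mdd[i, t] <- TRUE
        }
    }
  }

  rho <- couplingRange[1L] +
    targetProfile[score + 1L] * diff(couplingRange)
  offset <- severityBase + severitySlope * score
  factorOf <- defaultFactorMap(catalog)
  loading <- defaultLoadings(catalog)
  scores <- simulateScoreArray(n, W, catalog, factorOf, loading,
                               couplingP = rho, offsetP = offset,
                               baselineBoost = 0.35, arPhi = 0.5,
                               factorArPhi = 0.4, noiseSD = 0.8)
  dimnames(scores) <- list(pid, paste0("W", 1:W), catalog$itemId)
  if (missingWaveProb > 0) {
    miss <- stats::runif(n) < missingWaveProb
    dropW <- sample(2:W, n, replace = TRUE)
    for (i in which(miss)) scores[i, dropW[i], ] <- NA
  }
  cov <- cbind(participant = pid, drawCovariates(n))
  panel <- SymptomPanel(scores, waveTimes = c(0, 2, 4, 6, 9),
                        catalog = catalog, covariates = cov,
                        diagnosisAD = ad, diagnosisMDD = mdd)
  truth <- list(participant = pid, score = score, kind = kind,
                coupling = rho, severityOffset = offset,
                targetProfile = targetProfile)
  list(panel = panel, truth = truth)
}
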