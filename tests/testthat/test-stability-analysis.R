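test_that("stability scores count diagnosis-positive assessments", {
  ad <- rbind(A = rep(FALSE, 5),
              B = c(TRUE, TRUE, TRUE, TRUE, TRUE),
              C = c(TRUE, FALSE, TRUE, FALSE, FALSE),
              D = rep(FALSE, 5),
              E = c(FALSE, TRUE, TRUE, FALSE, FALSE))
  mdd <- rbind(A = rep(FALSE, 5),
               B = c(TRUE, TRUE, FALSE, TRUE, TRUE),
               C = c(FALSE, FALSE, TRUE, FALSE, FALSE),
               D = c(FALSE, TRUE, FALSE, FALSE, TRUE),
               E = rep(FALSE, 5))
  prof <- stabilityScore(ad, mdd)
  expect_identical(prof$score, c(0L, 5L, 2L, 2L, 2L))
  expect_identical(as.character(prof$subgroup),
                   c("control", "comorbid", "comorbid", "MDD_only",
                     "AD_only"))
  expect_identical(as.character(prof$category),
                   c("stable_health", "stable_disease", "unstable",
                     "unstable", "unstable"))
  # an AD-and-MDD overlap at one assessment is counted once, not twice
  expect_identical(prof$score[3], 2L)
})

test_that("the attainable score set over 5 assessments is exactly 0..5", {
  pats <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 5)))
  rownames(pats) <- sprintf("P%02d", seq_len(nrow(pats)))
  blank <- pats & FALSE
  scores <- stabilityScore(pats, blank)$score
  expect_identical(sort(unique(scores)), 0:5)
  expect_identical(max(scores), 5L)
  # score 0 if and only if control
  prof <- stabilityScore(pats, blank)
  expect_identical(prof$score == 0L, prof$subgroup == "control")
})

test_that("the score is a count: reordering assessments never changes it", {
  set.seed(61)
  ad <- matrix(runif(40) < 0.4, 8, 5)
  mdd <- matrix(runif(40) < 0.4, 8, 5)
  s1 <- stabilityScore(ad, mdd)$score
  s2 <- stabilityScore(ad[, 5:1], mdd[, 5:1])$score
  expect_identical(s1, s2)
})

test_that("missing flags are an error, not a partial score", {
  ad <- matrix(c(TRUE, NA, FALSE, TRUE, FALSE), 1, 5)
  mdd <- matrix(FALSE, 1, 5)
  expect_error(stabilityScore(ad, mdd), "missing")
  expect_error(stabilityScore(matrix(FALSE, 2, 5), matrix(FALSE, 2, 4)),
               "identical dimensions")
})

test_that("category boundaries follow the 0-1 / 2-3 / 4-5 convention", {
  expect_identical(as.character(stabilityCategory(0:5)),
                   c("stable_health", "stable_health", "unstable",
                     "unstable", "stable_disease", "stable_disease"))
})

test_that("with a balanced covariate design, score-level constants are reproduced", {
  # densities exactly constant within score level; covariates identically
  # distributed in every level, so the residualization is a pure centering
  lev <- rep(0:5, each = 8)
  const <- c(1.2, 1.5, 1.9, 2.0, 1.6, 1.4)
  dens <- setNames(const[lev + 1], sprintf("P%03d", seq_along(lev)))
  covPat <- expand.grid(age = c(30, 50), sex = 0:1, severity = c(-1, 1))
  cov <- data.frame(participant = names(dens),
                    covPat[rep(1:8, times = 6), ],
                    education = 2)
  prof <- data.frame(participant = names(dens), score = lev)
  expect_error(densityVsStability(dens, prof, cov), "collinear.*education")
  cov$education <- rep(c(1, 2, 2, 1, 2, 1, 1, 2), 6)
  qf <- densityVsStability(dens, prof, cov)
  expect_equal(qf$adjustedMeans$mean + mean(dens), const, tolerance = 1e-10)
  expect_equal(qf$adjustedMeans$n, rep(8L, 6))
  expect_lt(qf$betaQuadratic, 0)    # the constants trace an inverted U
})

test_that("quadratic shape conclusions are invariant to the affine inversion", {
  sc <- makeStabilityScenario(n = 150, seed = 62)
  sp <- standardize(sc$panel)
  md <- participantMeanDistances(sp)
  cov <- merge(covariates(sc$panel), meanSeverity(sp), by = "participant")
  prof <- data.frame(participant = sc$truth$participant,
                     score = sc$truth$score)
  q1 <- densityVsStability(invertDistance(md, shift = 2), prof, cov)
  q2 <- densityVsStability(3 + 5 * invertDistance(md, shift = 2), prof, cov)
  expect_equal(q2$betaQuadratic, 5 * q1$betaQuadratic, tolerance = 1e-8)
  expect_equal(q2$pQuadratic, q1$pQuadratic, tolerance = 1e-8)
  expect_equal(q2$betaLinear, 5 * q1$betaLinear, tolerance = 1e-8)
  # joint single-model variant agrees on the shape
  q3 <- densityVsStability(invertDistance(md, shift = 2), prof, cov,
                           twoStep = FALSE)
  expect_identical(sign(q3$betaQuadratic), sign(q1$betaQuadratic))
  # fewer than three distinct score levels cannot identify a quadratic
  prof2 <- data.frame(participant = names(md)[1:20],
                      score = rep(c(0L, 1L), 10))
  expect_error(densityVsStability(md[1:20], prof2, cov), "3 distinct")
})

test_that("severity trajectories aggregate sum scores correctly", {
  sim <- simulateCohort(cohortConfig(), seed = 63)
  grp <- setNames(sim$truth$group, sim$truth$participant)
  tr <- severityTrajectories(sim$panel, grp)
  expect_setequal(unique(tr$scale), c("IDS", "BAI", "PSWQ"))
  # linearity: the mean sum score equals the sum of per-item means
  sc <- scoreMatrix(sim$panel)
  cd <- SummarizedExperiment::colData(sim$panel)
  cat <- itemCatalog(sim$panel)
  sel <- cd$participant %in% names(grp)[grp == "comorbid"] & cd$wave == "W2"
  manual <- sum(rowMeans(sc[cat$scale == "IDS", sel, drop = FALSE]))
  expect_equal(tr$meanSum[tr$group == "comorbid" & tr$wave == "W2" &
                            tr$scale == "IDS"], manual, tolerance = 1e-10)
  # the comorbid group was generated most severe: highest across waves
  top <- 0L
  for (s in unique(tr$scale)) for (w in unique(tr$wave)) {
    sub <- tr[tr$scale == s & tr$wave == w, ]
    top <- top + (sub$group[which.max(sub$meanSum)] == "comorbid")
  }
  expect_gte(top, 14L)
  # a single-participant group reports a missing SE
  grp2 <- grp; grp2[1] <- "lonely"
  tr2 <- severityTrajectories(sim$panel, grp2)
  expect_true(all(is.na(tr2$se[tr2$group == "lonely"])))
  expect_true(all(tr2$n[tr2$group == "lonely"] == 1L))
})

test_that("the post-baseline drop appears in generated severity trajectories", {
  sim <- simulateCohort(cohortConfig(), seed = 64)
  grp <- setNames(sim$truth$group, sim$truth$participant)
  tr <- severityTrajectories(sim$panel, grp)
  for (s in c("IDS", "BAI", "PSWQ")) {
    sub <- tr[tr$scale == s & tr$group == "comorbid", ]
    expect_gt(sub$meanSum[sub$wave == "W1"], sub$meanSum[sub$wave == "W2"])
  }
})
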