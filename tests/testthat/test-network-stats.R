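# the edge-test closed form is validated against explicit model fits (LSDV
# lm, per-pair t.test, lmer) on small cohorts, then exercised for power,
# calibration and its output invariants on generated structure

test_that("adjusted edge test equals the explicit participant-dummy regression", {
  sim <- simulateCohort(clusterScenarioConfig(n = 12, nItems = 6,
                                              clusterSize = 3), seed = 41)
  d <- cohortDistances(standardize(sim$panel))
  e <- testEdges(d, alpha = 0.01)
  pairKey <- paste(d$itemI, d$itemJ, sep = "~")
  for (k in c(1, 7, 15)) {
    lev <- paste(e$itemI[k], e$itemJ[k], sep = "~")
    fit <- stats::lm(distance ~ x + pairMeanRaw + I(pairMeanRaw^2) +
                       factor(participant),
                     data = transform(d, x = as.integer(pairKey == lev)))
    co <- summary(fit)$coefficients["x", ]
    expect_equal(-e$effect[k], unname(co["Estimate"]), tolerance = 1e-8)
    expect_equal(e$statistic[k], unname(co["t value"]), tolerance = 1e-8)
    expect_equal(e$pValue[k],
                 stats::pt(unname(co["t value"]), fit$df.residual),
                 tolerance = 1e-8)
  }
})

test_that("item-indicator adjustment equals the explicit membership regression", {
  sim <- simulateCohort(clusterScenarioConfig(n = 10, nItems = 5,
                                              clusterSize = 3), seed = 42)
  d <- cohortDistances(standardize(sim$panel))
  e <- testEdges(d, alpha = 0.01, edgeAdjust = "item_indicators")
  items <- sort(unique(c(d$itemI, d$itemJ)))
  Z <- sapply(items, function(it) as.integer(d$itemI == it | d$itemJ == it))
  pairKey <- paste(d$itemI, d$itemJ, sep = "~")
  for (k in c(2, 9)) {
    lev <- paste(e$itemI[k], e$itemJ[k], sep = "~")
    dat <- data.frame(y = d$distance, x = as.integer(pairKey == lev),
                      Z[, -ncol(Z)], id = d$participant)
    fit <- stats::lm(y ~ . - id + factor(id), data = dat)
    co <- summary(fit)$coefficients["x", ]
    expect_equal(-e$effect[k], unname(co["Estimate"]), tolerance = 1e-8)
    expect_equal(e$statistic[k], unname(co["t value"]), tolerance = 1e-8)
  }
})

test_that("t-test mode matches stats::t.test (one-sided Welch)", {
  sim <- simulateCohort(clusterScenarioConfig(n = 15, nItems = 5,
                                              clusterSize = 3), seed = 43)
  d <- cohortDistances(standardize(sim$panel))
  e <- testEdges(d, alpha = 0.01, mode = "ttest")
  pairKey <- paste(d$itemI, d$itemJ, sep = "~")
  for (k in c(1, 6, 10)) {
    lev <- paste(e$itemI[k], e$itemJ[k], sep = "~")
    tt <- stats::t.test(d$distance[pairKey == lev],
                        d$distance[pairKey != lev],
                        alternative = "less")
    expect_equal(e$statistic[k], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(e$pValue[k], tt$p.value, tolerance = 1e-10)
  }
})

test_that("per-pair mixed-model engine agrees with the closed form", {
  sim <- simulateCohort(clusterScenarioConfig(n = 25, nItems = 4,
                                              clusterSize = 3), seed = 44)
  d <- cohortDistances(standardize(sim$panel))
  e1 <- testEdges(d, alpha = 0.01)
  e2 <- testEdges(d, alpha = 0.01, engine = "lmer")
  # approximate: the mixed model pools some between-participant information
  # for the raw-score covariate, so the contrast is close but not identical
  expect_lt(max(abs(e1$effect - e2$effect)), 0.1)
  expect_lt(max(abs(e1$statistic - e2$statistic)), 0.5)
  expect_identical(sign(e1$statistic), sign(e2$statistic))
})

test_that("edge detection separates coupled clusters from noise items", {
  cfg <- clusterScenarioConfig(n = 200, nItems = 12, clusterSize = 4)
  sim <- simulateCohort(cfg, seed = 45)
  d <- cohortDistances(standardize(sim$panel))
  e <- testEdges(d, alpha = 1e-4)
  within <- e$itemI %in% cfg$clusterItems & e$itemJ %in% cfg$clusterItems
  expect_true(all(e$significant[within]))
  expect_lte(sum(e$significant[!within]), 1L)
  # direction invariant: every retained edge is shorter than the reference
  expect_true(all(e$meanDistance[e$significant] < e$restMean[e$significant]))
})

test_that("a pair drawn from the global distribution is not flagged", {
  sim <- simulateCohort(independentItemsConfig(n = 200, nItems = 8), seed = 46)
  e <- testEdges(cohortDistances(standardize(sim$panel)), alpha = 1e-4)
  expect_lte(sum(e$significant), 1L)
  expect_gt(min(e$pValue), 1e-6)
})

test_that("degenerate and invalid inputs are handled explicitly", {
  sim <- simulateCohort(clusterScenarioConfig(n = 6, nItems = 4,
                                              clusterSize = 3), seed = 47)
  d <- cohortDistances(standardize(sim$panel))
  expect_error(testEdges(d, alpha = 0), "alpha")
  expect_error(testEdges(d, alpha = 1), "alpha")
  expect_error(testEdges(d[d$participant == "P0001", ]), "2 participants")
  expect_error(testEdges(d[-3, ]), "balanced")
  # constant distances: flagged, p = 1, never significant
  dc <- d; dc$distance <- 0.7
  ec <- testEdges(dc, alpha = 0.5)
  expect_true(all(ec$zeroVariance))
  expect_true(all(ec$pValue == 1))
  expect_false(any(ec$significant))
})

test_that("centrality ranks the engineered hub first and flags isolates", {
  cfg <- clusterScenarioConfig(n = 300, nItems = 12, clusterSize = 5)
  sim <- simulateCohort(cfg, seed = 48)
  e <- testEdges(cohortDistances(standardize(sim$panel)), alpha = 1e-4)
  cen <- itemCentrality(e)
  expect_identical(cen$item[which.max(cen$centrality)], cfg$hub)
  iso <- cen$isolated
  expect_true(any(iso))                       # noise items have no edges
  expect_true(all(cen$centrality[iso] == 0))
  expect_true(all(cen$zCentrality[iso] <= min(cen$zCentrality[!iso])))
  # permutation invariance: shuffling edge rows changes nothing
  cen2 <- itemCentrality(e[sample(nrow(e)), ])
  expect_equal(cen, cen2)
  # reciprocal inversion preserves the ranking
  cenR <- itemCentrality(e, invert = "reciprocal")
  expect_identical(order(cen$centrality[!iso]), order(cenR$centrality[!iso]))
})

test_that("subgroup networks inherit whole-group layout and edge scale", {
  cfg <- clusterScenarioConfig(n = 60, nItems = 8, clusterSize = 4)
  sim <- simulateCohort(cfg, seed = 49)
  d <- cohortDistances(standardize(sim$panel))
  e <- testEdges(d, alpha = 0.01)
  whole <- buildNetwork(e, itemCentrality(e), seed = 5)
  whole2 <- buildNetwork(e, itemCentrality(e), seed = 5)
  expect_identical(whole@layout, whole2@layout)      # seeded determinism

  half <- unique(d$participant)[1:30]
  dHalf <- d[d$participant %in% half, ]
  attr(dHalf, "nItems") <- attr(d, "nItems")
  eHalf <- testEdges(dHalf, alpha = 0.01)
  sub <- buildNetwork(eHalf, itemCentrality(eHalf), layoutSource = whole,
                      group = "half")
  expect_identical(sub@layout, whole@layout[rownames(sub@layout), ])
  expect_identical(sub@effectRange, whole@effectRange)

  eNone <- e; eNone$significant <- FALSE
  empty <- buildNetwork(eNone, itemCentrality(eNone))
  expect_identical(nrow(empty@edges), 0L)
  expect_true(all(empty@nodes$isolated))
  files <- exportNetwork(empty, tempfile("net"))
  expect_true(all(file.exists(files)))

  small <- buildNetwork(eHalf[eHalf$itemI != "IDS01" &
                                eHalf$itemJ != "IDS01", ],
                        catalog = makeItemCatalog(8))
  expect_error(buildNetwork(e, itemCentrality(e), layoutSource = small),
               "does not cover")
})

test_that("network exports round-trip through GraphML and JSON", {
  cfg <- clusterScenarioConfig(n = 60, nItems = 6, clusterSize = 4)
  sim <- simulateCohort(cfg, seed = 50)
  e <- testEdges(cohortDistances(standardize(sim$panel)), alpha = 0.01)
  net <- buildNetwork(e, itemCentrality(e), catalog = makeItemCatalog(6))
  dir <- tempfile("export")
  files <- exportNetwork(net, dir)
  expect_true(all(file.exists(files)))
  g <- igraph::read_graph(files["graphml"], format = "graphml")
  expect_equal(igraph::vcount(g), 6)
  expect_equal(igraph::ecount(g), igraph::ecount(net@graph))
  js <- jsonlite::read_json(files["json"], simplifyVector = TRUE)
  expect_equal(nrow(js$nodes), 6L)
  expect_equal(js$alpha, attr(e, "alpha"))
})

test_that("density inversion is anti-monotone in distance", {
  md <- c(a = 0.4, b = 0.7, c = 1.1)
  for (inv in c("linear", "reciprocal")) {
    d0 <- invertDistance(md, invert = inv)
    d1 <- invertDistance(1.3 * md, invert = inv)
    expect_true(all(d1 < d0))
  }
  expect_equal(invertDistance(md), 2 - md)
  expect_equal(invertDistance(md, "reciprocal"), 1 / md)
})

test_that("adjusted density estimates respect exchangeability and location shifts", {
  sim <- simulateCohort(cohortConfig(nPerGroup = c(control = 40, AD = 40,
                                                   MDD = 2, comorbid = 2)),
                        seed = 51)
  sp <- standardize(sim$panel)
  dens <- invertDistance(participantMeanDistances(sp))
  cov <- merge(covariates(sim$panel), meanSeverity(sp), by = "participant")
  # two groups drawn from one distribution: no significant contrast
  ids <- sim$truth$participant[sim$truth$group == "control"]
  fake <- setNames(rep(c("g1", "g2"), each = 20), ids)
  nd <- networkDensity(dens[ids], fake, cov)
  expect_gt(nd$comparisons$p.value[1], 0.001)
  expect_lt(abs(diff(nd$estimates$adjustedDensity)),
            4 * max(nd$estimates$se))
  # adding a constant to age leaves adjusted group differences unchanged
  cov2 <- cov; cov2$age <- cov2$age + 100
  nd2 <- networkDensity(dens[ids], fake, cov2)
  expect_equal(diff(nd$estimates$adjustedDensity),
               diff(nd2$estimates$adjustedDensity), tolerance = 1e-8)
  # groups below two participants are dropped with a warning
  g3 <- setNames(c(rep("g1", 19), "tiny", rep("g2", 20)), ids)
  expect_warning(nd3 <- networkDensity(dens[ids], g3, cov), "excluded")
  expect_setequal(nd3$estimates$group, c("g1", "g2"))
})
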