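#' Pipeline configuration
#'
#' Resolves the full set of analysis options for \code{\link{runPipeline}}.
#' Either \code{input} (paths to a long-format panel file and a covariate
#' table) or \code{simulate} (a \code{\link{cohortConfig}} or the result of
#' \code{\link{makeStabilityScenario}}) must be supplied at run time.
#'
#' @param input optional list(panel = path, covariates = path, config = list).
#' @param simulate optional \code{\link{cohortConfig}}.
#' @param window Sakoe-Chiba band half-width (default 1).
#' @param metric DTW local cost metric ("absolute" or "squared").
#' @param alpha edge significance level (default 1e-4).
#' @param edgeMode "adjusted" or "ttest".
#' @param edgeAdjust "pair_mean" or "item_indicators".
#' @param invert density inversion, "linear" or "reciprocal".
#' @param shift linear-inversion shift.
#' @param groupBy "diagnosis", "stability" or "none".
#' @param seed integer seed (layout and any simulation).
#' @param writeDistances write the full long distance table (default TRUE;
#'   large for big cohorts).
#' @return list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(input = NULL, simulate = NULL,
                           window = 1L, metric = "absolute",
                           alpha = 1e-4, edgeMode = "adjusted",
                           edgeAdjust = "pair_mean",
                           invert = "linear", shift = 2,
                           groupBy = c("diagnosis", "stability", "none"),
                           seed = 1L, writeDistances = TRUE) {
  structure(list(input = input, simulate = simulate,
                 window = as.integer(window), metric = metric,
                 alpha = alpha, edgeMode = edgeMode,
                 edgeAdjust = edgeAdjust, invert = invert, shift = shift,
                 groupBy = match.arg(groupBy), seed = as.integer(seed),
                 writeDistances = isTRUE(writeDistances)),
            class = "pipelineConfig")
}

#' Run the full panel-to-network pipeline
#'
#' Executes load (or simulate) -> standardize -> per-participant DTW
#' distances -> edge tests, centrality and networks (whole group first, then
#' subgroups with the whole-group layout and edge scale) -> adjusted network
#' densities -> stability scoring and the quadratic density-stability
#' regression, writing all tables, network exports and a machine-readable
#' manifest (resolved config, package version, file checksums) to
#' \code{outDir}. Any stage failure aborts with the stage name. Reruns with
#' the same config and seed produce identical deterministic outputs.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory (created; default a timestamped directory
#'   under \code{tempdir()}).
#' @return Invisibly, a list with the key results (panel, edges, networks,
#'   density, stability fit) and \code{manifest} (list of files written).
#' @export
runPipeline <- function(config, outDir = file.path(tempdir(),
                          format(Sys.time(), "panelDTW_%Y%m%d_%H%M%S"))) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) message("[panelDTW] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  panel <- stage("load", {
    if (!is.null(config$simulate)) {
      log("simulating cohort (seed ", config$seed, ")")
      simulateCohort(config$simulate, seed = config$seed)$panel
    } else if (!is.null(config$input)) {
      if (!file.exists(config$input$panel %||% ""))
        stop("panel file not found: ", config$input$panel)
      if (!is.null(config$input$covariates) &&
          !file.exists(config$input$covariates))
        stop("covariate file not found: ", config$input$covariates)
      loadPanel(config$input$panel, config$input$covariates,
                config$input$config %||% list())
    } else stop("config must provide either input paths or a simulate config")
  })
  log(length(participantIds(panel)), " participants retained, ",
      nrow(exclusionLog(panel)), " excluded")

  sp <- stage("standardize", standardize(panel))
  dist <- stage("distances", cohortDistances(sp, window = config$window,
                                             metric = config$metric))
  edges <- stage("edges", testEdges(dist, alpha = config$alpha,
                                    mode = config$edgeMode,
                                    edgeAdjust = config$edgeAdjust))
  log(sum(edges$significant), " of ", nrow(edges),
      " edges significant at alpha ", config$alpha,
      " (mode ", config$edgeMode, ", inversion ", config$invert, ")")
  cent <- stage("centrality", itemCentrality(edges, invert = config$invert,
                                             shift = config$shift))
  whole <- stage("network", buildNetwork(edges, cent, itemCatalog(panel),
                                         seed = config$seed, group = "all"))

  prof <- stage("stability", stabilityScore(panel))
  grouping <- switch(config$groupBy,
    diagnosis = stats::setNames(as.character(prof$subgroup), prof$participant),
    stability = stats::setNames(as.character(prof$category), prof$participant),
    none = NULL)

  subnets <- list()
  if (!is.null(grouping)) {
    subnets <- stage("subgroup networks", {
      out <- list()
      for (g in unique(grouping)) {
        idx <- dist$participant %in% names(grouping)[grouping == g]
        if (length(unique(dist$participant[idx])) < 2L) next
        subDist <- dist[idx, , drop = FALSE]
        attr(subDist, "nItems") <- attr(dist, "nItems")
        e <- testEdges(subDist, alpha = config$alpha,
                       mode = config$edgeMode, edgeAdjust = config$edgeAdjust)
        out[[g]] <- buildNetwork(e, itemCentrality(e, invert = config$invert,
                                                   shift = config$shift),
                                 itemCatalog(panel), layoutSource = whole,
                                 group = g)
      }
      out
    })
  }

  md <- stage("density", {
    meanD <- participantMeanDistances(sp, window = config$window,
                                      metric = config$metric)
    dens <- invertDistance(meanD, invert = config$invert,
                           shift = config$shift)
    cov <- merge(covariates(panel), meanSeverity(sp), by = "participant")
    est <- if (!is.null(grouping))
      networkDensity(dens, grouping, cov) else NULL
    qf <- densityVsStability(dens, prof, cov)
    list(density = dens, covariates = cov, estimate = est, quadratic = qf)
  })

  traj <- stage("trajectories", severityTrajectories(
    panel, stats::setNames(as.character(prof$subgroup), prof$participant)))

  manifest <- stage("write", {
    files <- character()
    wp <- file.path(outDir, "panel_long.csv")
    writePanel(sp, wp); files["panel"] <- wp
    wc <- file.path(outDir, "covariates.csv")
    writeCovariates(panel, wc); files["covariates"] <- wc
    if (config$writeDistances) {
      wd <- file.path(outDir, "distances.csv")
      utils::write.csv(dist, wd, row.names = FALSE); files["distances"] <- wd
    }
    we <- file.path(outDir, "edges.csv")
    utils::write.csv(edges, we, row.names = FALSE); files["edges"] <- we
    files <- c(files, exportNetwork(whole, outDir, prefix = "all"))
    for (g in names(subnets))
      files <- c(files, exportNetwork(subnets[[g]], outDir, prefix = g))
    ws <- file.path(outDir, "stability.csv")
    utils::write.csv(prof, ws, row.names = FALSE); files["stability"] <- ws
    wt <- file.path(outDir, "trajectories.csv")
    utils::write.csv(traj, wt, row.names = FALSE); files["trajectories"] <- wt
    if (!is.null(md$estimate)) {
      wde <- file.path(outDir, "density_by_group.csv")
      utils::write.csv(md$estimate$estimates, wde, row.names = FALSE)
      files["density"] <- wde
    }
    wq <- file.path(outDir, "quadratic_fit.json")
    jsonlite::write_json(list(betaLinear = md$quadratic$betaLinear,
                              betaQuadratic = md$quadratic$betaQuadratic,
                              pLinear = md$quadratic$pLinear,
                              pQuadratic = md$quadratic$pQuadratic,
                              adjustedMeans = md$quadratic$adjustedMeans),
                         wq, auto_unbox = TRUE, digits = NA)
    files["quadratic"] <- wq
    mf <- file.path(outDir, "manifest.json")
    cfgOut <- config
    cfgOut$simulate <- if (!is.null(config$simulate)) "embedded" else NULL
    jsonlite::write_json(list(
      package = "panelDTW",
      version = as.character(utils::packageVersion("panelDTW")),
      config = cfgOut[setdiff(names(cfgOut), c("input", "simulate"))],
      nParticipants = length(participantIds(panel)),
      nExcluded = nrow(exclusionLog(panel)),
      files = lapply(as.list(files), function(f)
        list(path = basename(f), md5 = unname(tools::md5sum(f))))),
      mf, auto_unbox = TRUE, digits = NA)
    files["manifest"] <- mf
    files
  })
  log("pipeline complete: ", length(manifest), " files in ", outDir)
  invisible(list(panel = panel, standardized = sp, edges = edges,
                 network = whole, subgroupNetworks = subnets,
                 density = md, stability = prof, trajectories = traj,
                 manifest = manifest, outDir = outDir))
}
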