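#' Per-participant item-pair DTW distance matrix
#'
#' Computes the symmetric P x P matrix of normalized symmetric2 DTW distances
#' between all item pairs for one participant, using that participant's
#' complete waves at their native length (4 or 5); path-length normalization
#' makes the two directly comparable. For the default 62-item catalog this
#' yields (62^2 - 62) / 2 = 1,891 unique distances.
#'
#' @param x a \linkS4class{StandardizedPanel}.
#' @param participant a participant id present in the panel.
#' @param window Sakoe-Chiba band half-width (default 1).
#' @param metric local cost metric, \code{"absolute"} or \code{"squared"}.
#' @return A P x P symmetric matrix with zero diagonal, item ids as dimnames,
#'   and attributes \code{participant} and \code{nWaves}.
#' @export
participantDistances <- function(x, participant, window = 1L,
                                 metric = c("absolute", "squared")) {
  metric <- match.arg(metric)
  stopifnot(methods::is(x, "StandardizedPanel"))
  cd <- SummarizedExperiment::colData(x)
  sel <- which(cd$participant == participant)
  if (!length(sel)) stop("participant not in panel: ", participant)
  sel <- sel[order(match(cd$wave[sel], waveLabels(x)))]
  z <- t(zMatrix(x)[, sel, drop = FALSE])         # T x P
  D <- dtwPairwiseCpp(z, window = as.integer(window),
                      squared = metric == "squared")
  dimnames(D) <- list(colnames(z), colnames(z))
  attr(D, "participant") <- participant
  attr(D, "nWaves") <- nrow(z)
  D
}

#' Cohort-wide long table of item-pair DTW distances
#'
#' Stacks all per-participant distance matrices into one long table, the unit
#' of analysis for edge testing and density models: one row per participant
#' and unordered item pair (i < j), with the pair-mean raw score covariate
#' (mean of the two items' per-participant raw means) attached. The result is
#' a pure function of the panel: participant processing order does not affect
#' it, and re-running is bit-identical.
#'
#' @inheritParams participantDistances
#' @return A data.frame with columns \code{participant}, \code{itemI},
#'   \code{itemJ}, \code{distance}, \code{pairMeanRaw}, \code{nWaves};
#'   \code{nParticipants * (P^2 - P) / 2} rows. The item catalog size is
#'   attached as attribute \code{nItems}.
#' @export
cohortDistances <- function(x, window = 1L,
                            metric = c("absolute", "squared")) {
  metric <- match.arg(metric)
  stopifnot(methods::is(x, "StandardizedPanel"))
  pids <- participantIds(x)
  if (!length(pids)) stop("empty cohort")
  items <- rownames(x)
  P <- length(items)
  ut <- which(upper.tri(matrix(0, P, P)))           # column-major upper triangle
  iIdx <- row(matrix(0, P, P))[ut]
  jIdx <- col(matrix(0, P, P))[ut]
  rim <- rawItemMeans(x)                            # participants x items
  K <- length(ut)

  cd <- SummarizedExperiment::colData(x)
  z <- zMatrix(x)
  wl <- waveLabels(x)
  sq <- metric == "squared"
  splitIdx <- split(seq_len(ncol(z)), cd$participant)
  nPid <- length(pids)
  dist <- matrix(NA_real_, K, nPid)
  nW <- integer(nPid)
  for (k in seq_len(nPid)) {
    sel <- splitIdx[[pids[k]]]
    sel <- sel[order(match(cd$wave[sel], wl))]
    D <- dtwPairwiseCpp(t(z[, sel, drop = FALSE]),
                        window = as.integer(window), squared = sq)
    dist[, k] <- D[ut]
    nW[k] <- length(sel)
  }
  pm <- (rim[, iIdx, drop = FALSE] + rim[, jIdx, drop = FALSE]) / 2  # pid x K
  out <- data.frame(
    participant = rep(pids, each = K),
    itemI = rep(items[iIdx], times = nPid),
    itemJ = rep(items[jIdx], times = nPid),
    distance = as.vector(dist),
    pairMeanRaw = as.vector(t(pm[pids, , drop = FALSE])),
    nWaves = rep(nW, each = K),
    stringsAsFactors = FALSE
  )
  attr(out, "nItems") <- P
  out
}

#' Per-participant mean DTW distance (fast path)
#'
#' Mean of the (P^2 - P)/2 unique pairwise distances per participant, the
#' quantity that network density inverts. Skips materializing the long table,
#' which matters for large simulation studies.
#'
#' @inheritParams participantDistances
#' @return Named numeric vector of mean distances, one per participant.
#' @export
participantMeanDistances <- function(x, window = 1L,
                                     metric = c("absolute", "squared")) {
  metric <- match.arg(metric)
  stopifnot(methods::is(x, "StandardizedPanel"))
  cd <- SummarizedExperiment::colData(x)
  z <- zMatrix(x)
  pids <- participantIds(x)
  P <- nrow(z)
  out <- numeric(length(pids))
  names(out) <- pids
  wl <- waveLabels(x)
  sq <- metric == "squared"
  split_idx <- split(seq_len(ncol(z)), cd$participant)
  for (p in pids) {
    sel <- split_idx[[p]]
    sel <- sel[order(match(cd$wave[sel], wl))]
    D <- dtwPairwiseCpp(t(z[, sel, drop = FALSE]), window = as.integer(window),
                        squared = sq)
    out[p] <- sum(D) / (P * (P - 1))    # symmetric, zero diagonal
  }
  out
}
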