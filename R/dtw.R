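#' Local cost matrix of two equal-length series
#'
#' @param a,b equal-length finite numeric vectors (standardized item scores
#'   of two items for one participant).
#' @param metric \code{"absolute"} (default) or \code{"squared"} local cost.
#' @return The T x T matrix \code{lcm[i, j] = |a_i - b_j|} (or its square).
#' @examples
#' localCost(c(1, 2), c(3, 0))
#' @export
localCost <- function(a, b, metric = c("absolute", "squared")) {
  metric <- match.arg(metric)
  if (length(a) != length(b))
    stop("series must have equal length (same participant, same waves)")
  if (anyNA(a) || anyNA(b) || !all(is.finite(c(a, b))))
    stop("series must be finite with no missing values")
  d <- abs(outer(a, b, "-"))
  if (metric == "squared") d <- d * d
  d
}

#' Dynamic time warping distance for short series (symmetric2, banded)
#'
#' Computes the DTW alignment of two equal-length series under the
#' \code{symmetric2} step pattern restricted to a Sakoe-Chiba band
#' \eqn{|i - j| \le w}: the accumulated cost satisfies
#' \deqn{D(i,j) = \min\{D(i-1,j) + c_{ij},\; D(i-1,j-1) + 2 c_{ij},\;
#'   D(i,j-1) + c_{ij}\}} with \eqn{D(1,1) = 2 c_{11}}. The reported
#' normalized distance divides the cumulative cost by \eqn{T_a + T_b}, which
#' makes distances comparable between participants with four and with five
#' assessments. The optimal path is recovered by backtracking; ties between
#' equal-cost predecessors are broken deterministically (diagonal, then
#' vertical, then horizontal), which affects only the reported path, never
#' the distance.
#'
#' @param a,b equal-length finite numeric vectors.
#' @param window Sakoe-Chiba band half-width in assessment indices
#'   (default 1; \code{window >= length(a) - 1} is unconstrained).
#' @param stepPattern only \code{"symmetric2"} is implemented (the normalizable,
#'   symmetric default of the DTW literature).
#' @param metric local cost metric, see \code{\link{localCost}}.
#' @return An object of class \code{"WarpingResult"}: list with \code{lcm},
#'   \code{acm} (band-infeasible cells are \code{Inf}), \code{path} (m x 2
#'   index matrix from (1,1) to (T,T)), \code{cumulativeCost} and
#'   \code{normalizedDistance}.
#' @examples
#' dtwDistance(c(0, 0, 0), c(1, 1, 1))$normalizedDistance  # 1
#' @export
dtwDistance <- function(a, b, window = 1L,
                        stepPattern = "symmetric2",
                        metric = c("absolute", "squared")) {
  metric <- match.arg(metric)
  if (!identical(stepPattern, "symmetric2"))
    stop("unknown step pattern: ", stepPattern)
  if (length(window) != 1L || is.na(window) || window < 0)
    stop("window must be a non-negative integer")
  lcm <- localCost(a, b, metric)
  T <- length(a)
  acm <- matrix(Inf, T, T)
  for (i in seq_len(T)) {
    jr <- max(1L, i - window):min(T, i + window)
    for (j in jr) {
      c_ij <- lcm[i, j]
      if (i == 1L && j == 1L) {
        acm[1L, 1L] <- 2 * c_ij
        next
      }
      cand <- Inf
      if (i > 1L && j > 1L) cand <- min(cand, acm[i - 1L, j - 1L] + 2 * c_ij)
      if (i > 1L) cand <- min(cand, acm[i - 1L, j] + c_ij)
      if (j > 1L) cand <- min(cand, acm[i, j - 1L] + c_ij)
      acm[i, j] <- cand
    }
  }
  cost <- acm[T, T]

  ## backtrack; tie preference: diagonal, vertical, horizontal
  path <- matrix(c(T, T), 1L, 2L)
  i <- T; j <- T
  tol <- 1e-9
  while (i > 1L || j > 1L) {
    c_ij <- lcm[i, j]
    if (i > 1L && j > 1L &&
        abs(acm[i - 1L, j - 1L] + 2 * c_ij - acm[i, j]) <= tol) {
      i <- i - 1L; j <- j - 1L
    } else if (i > 1L && is.finite(acm[i - 1L, j]) &&
               abs(acm[i - 1L, j] + c_ij - acm[i, j]) <= tol) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
    path <- rbind(c(i, j), path)
  }
  structure(
    list(lcm = lcm, acm = acm, path = path,
         cumulativeCost = cost,
         normalizedDistance = cost / (2 * T)),
    class = "WarpingResult"
  )
}

#' @export
print.WarpingResult <- function(x, ...) {
  cat("WarpingResult: T =", nrow(x$lcm),
      " cumulative cost =", format(x$cumulativeCost),
      " normalized =", format(x$normalizedDistance), "\n")
  cat("path:", paste(sprintf("(%d,%d)", x$path[, 1], x$path[, 2]),
                     collapse = " -> "), "\n")
  invisible(x)
}

#' Brute-force DTW by exhaustive path enumeration (test oracle)
#'
#' Enumerates every monotone warping path from (1,1) to (T,T) with steps
#' from \{(1,0), (0,1), (1,1)\} inside the Sakoe-Chiba band, scores each with
#' symmetric2 weights (diagonal steps count the local cost twice, the (1,1)
#' anchor counts twice) and returns the minimum. Exponential in T; restricted
#' to very short series and used as an independent oracle for
#' \code{\link{dtwDistance}}.
#'
#' @inheritParams dtwDistance
#' @return A list with \code{cumulativeCost}, \code{normalizedDistance},
#'   \code{path} (one optimal path) and \code{nPaths} (number of admissible
#'   paths enumerated).
#' @export
bruteForceDTW <- function(a, b, window = 1L,
                          stepPattern = "symmetric2",
                          metric = c("absolute", "squared")) {
  metric <- match.arg(metric)
  if (!identical(stepPattern, "symmetric2"))
    stop("unknown step pattern: ", stepPattern)
  T <- length(a)
  if (T > 6L) stop("brute-force enumeration is limited to T <= 6")
  lcm <- localCost(a, b, metric)
  best <- list(cost = Inf, path = NULL)
  nPaths <- 0L
  recurse <- function(i, j, cost, path) {
    if (abs(i - j) > window) return(invisible())
    if (i > T || j > T) return(invisible())
    if (i == T && j == T) {
      nPaths <<- nPaths + 1L
      if (cost < best$cost) best <<- list(cost = cost, path = path)
      return(invisible())
    }
    recurse(i + 1L, j + 1L, cost + 2 * lcm[i + 1L, j + 1L],
            rbind(path, c(i + 1L, j + 1L)))
    recurse(i + 1L, j, cost + lcm[i + 1L, j], rbind(path, c(i + 1L, j)))
    recurse(i, j + 1L, cost + lcm[i, j + 1L], rbind(path, c(i, j + 1L)))
  }
  recurse(1L, 1L, 2 * lcm[1L, 1L], matrix(c(1L, 1L), 1L, 2L))
  list(cumulativeCost = best$cost,
       normalizedDistance = best$cost / (2 * T),
       path = best$path, nPaths = nPaths)
}
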