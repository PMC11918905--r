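#' Default 62-item symptom catalog
#'
#' The instrument catalog used throughout the package: 30 depressive-symptom
#' items (IDS, scored 0-3), 21 anxiety items (BAI, scored 0-3) and the 11-item
#' short worry questionnaire (PSWQ, scored 0-4), 62 items in total.
#'
#' @return A \code{data.frame} with columns \code{itemId}, \code{scale}
#'   (one of \code{"IDS"}, \code{"BAI"}, \code{"PSWQ"}), \code{minScore},
#'   \code{maxScore} and \code{label}, one row per item.
#' @examples
#' cat62 <- defaultItemCatalog()
#' table(cat62$scale)
#' @export
defaultItemCatalog <- function() {
  ids <- sprintf("IDS%02d", 1:30)
  bai <- sprintf("BAI%02d", 1:21)
  psw <- sprintf("PSWQ%02d", 1:11)
  data.frame(
    itemId   = c(ids, bai, psw),
    scale    = rep(c("IDS", "BAI", "PSWQ"), c(30L, 21L, 11L)),
    minScore = 0L,
    maxScore = rep(c(3L, 3L, 4L), c(30L, 21L, 11L)),
    label    = c(paste("IDS item", 1:30),
                 paste("BAI item", 1:21),
                 paste("PSWQ item", 1:11)),
    stringsAsFactors = FALSE
  )
}

#' Build a reduced generic item catalog
#'
#' Convenience constructor for simulation studies that do not need the full
#' 62-item instrument set. Items are generic 0-3 Likert items on a single
#' nominal scale.
#'
#' @param nItems Number of items.
#' @param scale Scale label attached to every item (must be IDS, BAI or PSWQ;
#'   defaults to IDS so 0-3 scoring applies).
#' @return An item catalog \code{data.frame} as in
#'   \code{\link{defaultItemCatalog}}.
#' @export
makeItemCatalog <- function(nItems, scale = "IDS") {
  scale <- match.arg(scale, c("IDS", "BAI", "PSWQ"))
  maxScore <- if (scale == "PSWQ") 4L else 3L
  data.frame(
    itemId   = sprintf("%s%02d", scale, seq_len(nItems)),
    scale    = scale,
    minScore = 0L,
    maxScore = maxScore,
    label    = paste(scale, "item", seq_len(nItems)),
    stringsAsFactors = FALSE
  )
}

validateCatalog <- function(catalog) {
  required <- c("itemId", "scale", "minScore", "maxScore", "label")
  missing <- setdiff(required, names(catalog))
  if (length(missing))
    stop("item catalog lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(catalog$itemId))
    stop("duplicate itemId in catalog: ",
         paste(unique(catalog$itemId[duplicated(catalog$itemId)]), collapse = ", "))
  if (!all(catalog$scale %in% c("IDS", "BAI", "PSWQ")))
    stop("catalog scale must be one of IDS, BAI, PSWQ")
  if (!all(catalog$minScore < catalog$maxScore))
    stop("catalog requires minScore < maxScore for every item")
  invisible(catalog)
}
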