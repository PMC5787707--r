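#' @importFrom stats cor cov ecdf hclust as.dist mahalanobis medpolish
#'   p.adjust phyper prcomp quantile rbinom rnorm rpois runif sd var predict
#'   setNames ks.test
#' @importFrom utils head modifyList packageVersion
NULL

#' Normalize a well identifier
#'
#' Converts well identifiers such as `"B2"` to the canonical
#' letter + zero-padded two-digit column form (`"B02"`), matching common
#' plate-reader exports.
#'
#' @param well_id Character vector of well identifiers (row letter followed
#'   by column number, e.g. `"B2"`, `"b02"`, `"P24"`).
#' @return Character vector of normalized well identifiers.
#' @examples
#' normalize_well_id(c("B2", "b02", "A10"))
#' @export
normalize_well_id <- function(well_id) {
  well_id <- toupper(trimws(as.character(well_id)))
  ok <- grepl("^[A-P][0-9]{1,2}$", well_id)
  if (any(!ok)) {
    stop("malformed well id(s): ", paste(unique(well_id[!ok]), collapse = ", "))
  }
  row <- substr(well_id, 1L, 1L)
  col <- as.integer(substr(well_id, 2L, nchar(well_id)))
  sprintf("%s%02d", row, col)
}

#' Plate-grid coordinates of a well
#'
#' @param well_id Character vector of (normalized or raw) well ids.
#' @return Integer matrix with columns `row` (A = 1) and `col`.
#' @export
well_coordinates <- function(well_id) {
  well_id <- normalize_well_id(well_id)
  cbind(
    row = match(substr(well_id, 1L, 1L), LETTERS),
    col = as.integer(substr(well_id, 2L, 3L))
  )
}

# Deterministic 31-bit substream seed for a (screen seed, plate, well) key.
# Plain polynomial rolling hash; doubles stay exact (< 2^53) throughout.
well_seed <- function(seed, plate_id, well_id) {
  key <- paste(plate_id, well_id, sep = ":")
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2038074743
  as.integer((h + (seed %% 2038074743) * 7919) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
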