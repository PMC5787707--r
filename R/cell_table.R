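#' Construct a single-cell feature table
#'
#' The central container of the package: one row per segmented cell, keyed by
#' `(plate_id, well_id, cell_id)`, with a logical `transfected` flag
#' (T(+) versus T(-)) and one numeric column per image-derived feature.
#' T(-) cells act as the in-well wild-type reference for standardization and
#' as the negative class for the within-well classifier.
#'
#' @param df A data.frame with columns `plate_id`, `well_id`, `cell_id`,
#'   `transfected`, plus the feature columns.
#' @param features Character vector naming the feature columns. If `NULL`,
#'   every column other than the four identity columns is taken as a feature.
#' @return A `cell_table`: a data.frame carrying a `features` attribute.
#' @examples
#' df <- data.frame(plate_id = "P1", well_id = "B02", cell_id = 1:2,
#'                  transfected = c(TRUE, FALSE), f1 = c(0.5, -0.2))
#' ct <- cell_table(df)
#' features(ct)
#' @export
cell_table <- function(df, features = NULL) {
  df <- as.data.frame(df)
  mandatory <- c("plate_id", "well_id", "cell_id", "transfected")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    stop("cell table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(features)) {
    features <- setdiff(names(df), mandatory)
  }
  if (!length(features)) stop("cell table has no feature columns")
  if (anyDuplicated(features)) stop("feature names must be unique")
  absent <- setdiff(features, names(df))
  if (length(absent)) {
    stop("declared feature(s) absent from table: ",
         paste(absent, collapse = ", "))
  }
  df$plate_id <- as.character(df$plate_id)
  df$well_id <- normalize_well_id(df$well_id)
  df$cell_id <- as.integer(df$cell_id)
  df$transfected <- as.logical(df$transfected)
  if (anyNA(df$transfected)) stop("transfected flag contains missing values")
  for (f in features) {
    v <- df[[f]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      stop("feature '", f, "' is non-numeric",
           if (length(bad)) paste0(" (first offending row: ", bad[1], ")"))
    }
    if (anyNA(v)) {
      stop("feature '", f, "' has missing value(s); first offending row: ",
           which(is.na(v))[1])
    }
  }
  key <- paste(df$plate_id, df$well_id, df$cell_id)
  if (anyDuplicated(key)) {
    stop("duplicate (plate_id, well_id, cell_id) key: ",
         key[anyDuplicated(key)])
  }
  df <- df[, c(mandatory, features)]
  attr(df, "features") <- features
  class(df) <- c("cell_table", "data.frame")
  df
}

#' Feature names of a cell table
#' @param x A `cell_table`.
#' @return Character vector of feature column names.
#' @export
features <- function(x) attr(x, "features")

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("cell_table: %d cells, %d wells, %d features%s\n",
              nrow(x), length(unique(paste(x$plate_id, x$well_id))),
              length(features(x)),
              if (isTRUE(attr(x, "standardized"))) " (standardized)" else ""))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Construct a plate map
#'
#' Maps each well to its perturbation: the plasmid/guide identity, the target
#' gene and whether the well carries a non-targeting control. Control wells
#' define the null distribution for the PV gate and every Tukey-fence hit
#' threshold.
#'
#' @param df A data.frame with columns `plate_id`, `well_id`,
#'   `perturbation_id`, `gene`, `guide_id`, `is_control`.
#' @return A `plate_map` data.frame.
#' @export
plate_map <- function(df) {
  df <- as.data.frame(df)
  mandatory <- c("plate_id", "well_id", "perturbation_id", "gene",
                 "guide_id", "is_control")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    stop("plate map schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  df$plate_id <- as.character(df$plate_id)
  if (nrow(df)) df$well_id <- normalize_well_id(df$well_id)
  for (col in c("perturbation_id", "gene", "guide_id")) {
    df[[col]] <- as.character(df[[col]])
  }
  df$is_control <- as.logical(df$is_control)
  key <- paste(df$plate_id, df$well_id)
  if (anyDuplicated(key)) {
    stop("duplicate (plate_id, well_id) in plate map: ",
         key[anyDuplicated(key)])
  }
  df <- df[, mandatory]
  class(df) <- c("plate_map", "data.frame")
  df
}

#' Read a single-cell feature table from CSV
#'
#' Expects one header row with `plate_id`, `well_id`, `cell_id`,
#' `transfected` and one column per feature; feature columns are
#' auto-detected when `feature_names` is not given.
#'
#' @param path Path to a CSV file.
#' @param feature_names Optional character vector restricting which columns
#'   are treated as features.
#' @return A [cell_table()].
#' @export
read_cell_table <- function(path, feature_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- data.table::fread(path, data.table = FALSE, na.strings = "NA")
  cell_table(df, features = feature_names)
}

#' Write a single-cell feature table to CSV
#'
#' Numeric values are serialized with full precision so that a
#' write/read round trip is lossless.
#'
#' @param x A [cell_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path)
  invisible(path)
}

#' Read a plate map from CSV
#' @param path Path to a CSV file with the [plate_map()] schema.
#' @return A [plate_map()].
#' @export
read_plate_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- data.table::fread(path, data.table = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0) {
    stop("plate map schema error: file has no header")
  }
  plate_map(df)
}

#' Write a plate map to CSV
#' @param x A [plate_map()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_map <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path)
  invisible(path)
}

#' Cross-validate a cell table against a plate map
#'
#' Report-only consistency check: lists wells present in the cell table but
#' absent from the plate map and vice versa, and verifies that at least one
#' non-targeting control well exists (required by gate and fence
#' computations downstream). Inputs are not modified.
#'
#' @param cells A [cell_table()].
#' @param map A [plate_map()].
#' @return A list with elements `pass` (logical), `missing_from_map`,
#'   `missing_from_cells` (character vectors of `plate:well` keys) and
#'   `has_control` (logical).
#' @export
validate_screen <- function(cells, map) {
  cw <- unique(paste(cells$plate_id, cells$well_id, sep = ":"))
  mw <- unique(paste(map$plate_id, map$well_id, sep = ":"))
  missing_from_map <- setdiff(cw, mw)
  missing_from_cells <- setdiff(mw, cw)
  has_control <- any(map$is_control)
  structure(
    list(
      pass = !length(missing_from_map) && !length(missing_from_cells) &&
        has_control,
      missing_from_map = missing_from_map,
      missing_from_cells = missing_from_cells,
      has_control = has_control
    ),
    class = "screen_validation"
  )
}

#' @export
print.screen_validation <- function(x, ...) {
  cat("screen validation:", if (x$pass) "PASS" else "FAIL", "\n")
  if (length(x$missing_from_map)) {
    cat(" wells missing from plate map:",
        paste(x$missing_from_map, collapse = ", "), "\n")
  }
  if (length(x$missing_from_cells)) {
    cat(" wells missing from cell table:",
        paste(x$missing_from_cells, collapse = ", "), "\n")
  }
  if (!x$has_control) cat(" no non-targeting control wells in plate map\n")
  invisible(x)
}
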