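#' Well-level quality control
#'
#' Drops wells with too few transfected cells to train a classifier
#' (default 300) or too few non-transfected cells to estimate the in-well
#' wild-type reference (default 100).
#'
#' @param cells A [cell_table()].
#' @param min_tpos Minimum number of T(+) cells per well.
#' @param min_tneg Minimum number of T(-) cells per well.
#' @return A list with `cells` (retained [cell_table()]) and `exclusions`
#'   (data.frame: plate_id, well_id, n_tpos, n_tneg, reason).
#' @export
qc_wells <- function(cells, min_tpos = 300, min_tneg = 100) {
  key <- paste(cells$plate_id, cells$well_id, sep = ":")
  n_tpos <- tapply(cells$transfected, key, sum)
  n_tneg <- tapply(!cells$transfected, key, sum)
  wells <- names(n_tpos)
  bad_pos <- n_tpos < min_tpos
  bad_neg <- n_tneg < min_tneg
  bad <- bad_pos | bad_neg
  reason <- ifelse(bad_pos & bad_neg, "too few T(+) and T(-) cells",
                   ifelse(bad_pos, "too few T(+) cells",
                          "too few T(-) cells"))
  exclusions <- data.frame(
    plate_id = sub(":.*$", "", wells[bad]),
    well_id = sub("^.*:", "", wells[bad]),
    n_tpos = as.integer(n_tpos[bad]),
    n_tneg = as.integer(n_tneg[bad]),
    reason = reason[bad],
    row.names = NULL
  )
  retained <- cells[!key %in% wells[bad], , drop = FALSE]
  attr(retained, "features") <- features(cells)
  class(retained) <- class(cells)
  list(cells = retained, exclusions = exclusions)
}

#' Standardize features against the in-well T(-) population
#'
#' Every feature value in a well is z-scored by the mean and sample SD
#' (n - 1 denominator) of that well's T(-) cells, the in-well wild-type
#' reference. This removes well-to-well technical offsets before any
#' cross-well comparison. Features whose T(-) SD falls at or below
#' `sd_epsilon` in any well are dropped screen-wide (with a warning) so
#' that all wells share one feature space for the pooled PCA.
#'
#' @param cells A [cell_table()] (post-QC).
#' @param feature_names Features to standardize; default all.
#' @param sd_epsilon Smallest admissible T(-) SD.
#' @return A standardized `cell_table` carrying a `standardization`
#'   attribute (data.frame of per-well T(-) means/SDs) and
#'   `standardized = TRUE`.
#' @export
standardize_within_well <- function(cells, feature_names = NULL,
                                    sd_epsilon = 1e-8) {
  feats <- feature_names %||% features(cells)
  key <- paste(cells$plate_id, cells$well_id, sep = ":")
  wells <- unique(key)

  n_tneg <- tapply(!cells$transfected, key, sum)
  deficient <- names(n_tneg)[n_tneg < 2]
  if (length(deficient)) {
    stop("standardization requires >= 2 T(-) cells per well; offending ",
         "well(s): ", paste(deficient, collapse = ", "))
  }

  X <- as.matrix(cells[, feats, drop = FALSE])
  tneg <- !cells$transfected
  g <- match(key, wells)
  mu <- rowsum(X[tneg, , drop = FALSE], group = g[tneg]) /
    as.vector(table(g[tneg]))
  # sample SD with n-1 denominator, per well x feature
  cnt <- as.vector(table(g[tneg]))
  ss <- rowsum(X[tneg, , drop = FALSE]^2, group = g[tneg])
  v <- (ss - cnt * mu^2) / (cnt - 1)
  v[v < 0] <- 0
  sdw <- sqrt(v)

  degenerate <- apply(sdw <= sd_epsilon, 2, any)
  if (any(degenerate)) {
    warning("dropping feature(s) with degenerate T(-) SD in >= 1 well: ",
            paste(feats[degenerate], collapse = ", "))
    feats <- feats[!degenerate]
    if (!length(feats)) stop("no features survive the SD check")
    X <- X[, feats, drop = FALSE]
    mu <- mu[, feats, drop = FALSE]
    sdw <- sdw[, feats, drop = FALSE]
  }

  Z <- (X - mu[g, , drop = FALSE]) / sdw[g, , drop = FALSE]

  out <- as.data.frame(cells)[, c("plate_id", "well_id", "cell_id",
                                  "transfected")]
  out <- cbind(out, as.data.frame(Z, check.names = FALSE))
  prov <- data.frame(
    plate_id = rep(sub(":.*$", "", wells), each = length(feats)),
    well_id = rep(sub("^.*:", "", wells), each = length(feats)),
    feature = rep(feats, times = length(wells)),
    tneg_mean = as.vector(t(mu)),
    tneg_sd = as.vector(t(sdw)),
    row.names = NULL
  )
  out <- cell_table(out, features = feats)
  attr(out, "standardization") <- prov
  attr(out, "standardized") <- TRUE
  out
}

#' Mean feature profiles per well and population
#'
#' Averages features over the T(+) and T(-) cells of each well, the input
#' to the between-well (profile-comparison) branch of the analysis. Plate
#' grid coordinates are attached for B-score correction.
#'
#' @param cells A [cell_table()] (raw or standardized).
#' @param feature_names Features to average; default all.
#' @return A `well_profiles` data.frame: plate_id, well_id, population
#'   (`"Tpos"`/`"Tneg"`), row_index, col_index, one column per feature.
#' @export
well_mean_profiles <- function(cells, feature_names = NULL) {
  feats <- feature_names %||% features(cells)
  X <- as.matrix(cells[, feats, drop = FALSE])
  pop <- ifelse(cells$transfected, "Tpos", "Tneg")
  key <- paste(cells$plate_id, cells$well_id, pop, sep = ":")
  counts <- table(key)  # sorted by key, matching rowsum() group order
  means <- rowsum(X, group = key) / as.vector(counts)

  parts <- do.call(rbind, strsplit(rownames(means), ":", fixed = TRUE))
  coords <- well_coordinates(parts[, 2])
  out <- data.frame(
    plate_id = parts[, 1], well_id = parts[, 2], population = parts[, 3],
    row_index = coords[, "row"], col_index = coords[, "col"],
    n_cells = as.integer(counts[rownames(means)]),
    as.data.frame(means, check.names = FALSE),
    row.names = NULL, check.names = FALSE
  )
  out <- out[order(out$plate_id, out$well_id, out$population), ]
  rownames(out) <- NULL
  attr(out, "features") <- feats
  class(out) <- c("well_profiles", "data.frame")
  out
}

#' B-score correction of well profiles
#'
#' Removes plate positional effects from well-level profiles: per plate,
#' population and feature, a two-way Tukey median polish is run on the well
#' grid (iterated row- and column-median sweeps) and the residuals are
#' scaled by 1.4826 x the median absolute residual of that plate, yielding
#' robust z-score-like B-scores. A constant plate yields all-zero scores
#' rather than NaN.
#'
#' @param profiles A `well_profiles` table from [well_mean_profiles()].
#' @param max_iter Maximum polish sweeps.
#' @param tol Convergence tolerance on the polish.
#' @return A `well_profiles` table with feature values replaced by B-scores.
#' @export
bscore <- function(profiles, max_iter = 10, tol = 1e-6) {
  feats <- attr(profiles, "features")
  out <- profiles
  for (plate in unique(profiles$plate_id)) {
    for (pop in unique(profiles$population)) {
      sel <- profiles$plate_id == plate & profiles$population == pop
      if (!any(sel)) next
      if (sum(sel) < 2) {
        stop("B-score undefined for plate ", plate,
             " (single well in population ", pop, ")")
      }
      sub <- profiles[sel, ]
      rows <- sort(unique(sub$row_index))
      cols <- sort(unique(sub$col_index))
      ri <- match(sub$row_index, rows)
      ci <- match(sub$col_index, cols)
      for (f in feats) {
        m <- matrix(NA_real_, length(rows), length(cols))
        m[cbind(ri, ci)] <- sub[[f]]
        if (length(rows) == 1 || length(cols) == 1) {
          # degenerate grid: a single median sweep absorbs the one margin
          resid <- m[cbind(ri, ci)] -
            stats::median(m[cbind(ri, ci)], na.rm = TRUE)
        } else {
          mp <- stats::medpolish(m, eps = tol, maxiter = max_iter,
                                 trace.iter = FALSE, na.rm = TRUE)
          resid <- mp$residuals[cbind(ri, ci)]
        }
        scale <- 1.4826 * stats::median(abs(resid), na.rm = TRUE)
        out[sel, f] <- if (is.na(scale) || scale < 1e-12) 0 else resid / scale
      }
    }
  }
  attr(out, "features") <- feats
  class(out) <- c("well_profiles", "data.frame")
  out
}
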