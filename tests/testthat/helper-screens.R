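# Shared fixture builders. Everything is generated in code at test time;
# heavier screens are cached per session so several tests can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A hand-built cell table: explicit per-well T(+)/T(-) counts and constant
# or supplied feature values, for boundary tests.
tiny_cells <- function(wells, plate = "PL01") {
  rows <- lapply(seq_along(wells), function(i) {
    w <- wells[[i]]
    n <- w$n_tpos + w$n_tneg
    vals <- w$values %||% stats::rnorm(n)
    data.frame(plate_id = plate, well_id = names(wells)[i],
               cell_id = seq_len(n),
               transfected = rep(c(TRUE, FALSE), c(w$n_tpos, w$n_tneg)),
               f1 = vals)
  })
  cell_table(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Merge several generated screens, renaming plates so well keys stay
# unique, and optionally overriding the target gene per screen.
# Perturbation and guide ids are regenerated from the new plate/well key
# so they stay unique across the merged screen.
merge_screens <- function(screens, plates, genes = NULL) {
  stopifnot(length(screens) == length(plates))
  for (i in seq_along(screens)) {
    for (tab in c("cells", "map", "truth")) {
      screens[[i]][[tab]]$plate_id <- plates[i]
    }
    m <- screens[[i]]$map
    m$perturbation_id <- sprintf("%s_%s_%s",
                                 ifelse(m$is_control, "CTRL", "PERT"),
                                 m$plate_id, m$well_id)
    m$guide_id <- paste0(m$perturbation_id, "_g1")
    screens[[i]]$map <- m
    if (!is.null(genes) && !is.na(genes[i])) {
      tgt <- !screens[[i]]$map$is_control
      screens[[i]]$map$gene[tgt] <- genes[i]
    }
  }
  feats <- features(screens[[1]]$cells)
  list(
    cells = cell_table(do.call(rbind, lapply(screens, function(s)
      as.data.frame(s$cells))), features = feats),
    map = plate_map(do.call(rbind, lapply(screens, function(s)
      as.data.frame(s$map)))),
    truth = do.call(rbind, lapply(screens, `[[`, "truth"))
  )
}

# Move a screen's wells to new grid positions on one plate (applied
# consistently to cells, map and truth), e.g. to interleave effect and
# control wells for plate-correction comparisons.
relocate_wells <- function(scr, plate, new_ids) {
  old <- unique(paste(scr$map$plate_id, scr$map$well_id, sep = ":"))
  stopifnot(length(old) == length(new_ids))
  for (tab in c("cells", "map", "truth")) {
    key <- paste(scr[[tab]]$plate_id, scr[[tab]]$well_id, sep = ":")
    idx <- match(key, old)
    scr[[tab]]$well_id <- new_ids[idx]
    scr[[tab]]$plate_id <- plate
  }
  scr
}

# Rank-based AUC (Mann-Whitney) of score separating positives from
# negatives; used as an independent well-level ranking metric.
rank_auc <- function(score_pos, score_neg) {
  r <- rank(c(score_pos, score_neg))
  (sum(r[seq_along(score_pos)]) -
      length(score_pos) * (length(score_pos) + 1) / 2) /
    (length(score_pos) * length(score_neg))
}

# Brute-force two-sample KS statistic: evaluate both ECDFs at every pooled
# point by counting.
ks_brute <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, numeric(1)))
}

# Brute-force type-7 quantile: linear interpolation between order
# statistics, written independently of stats::quantile.
quantile7_brute <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Brute-force Tukey median polish on a complete matrix.
medpolish_brute <- function(m, max_iter = 50, tol = 1e-9) {
  overall <- 0
  row_eff <- rep(0, nrow(m))
  col_eff <- rep(0, ncol(m))
  r <- m
  for (i in seq_len(max_iter)) {
    rm <- apply(r, 1, median)
    r <- sweep(r, 1, rm)
    row_eff <- row_eff + rm
    cm_delta <- median(col_eff)
    col_eff <- col_eff - cm_delta
    overall <- overall + cm_delta
    cm <- apply(r, 2, median)
    r <- sweep(r, 2, cm)
    col_eff <- col_eff + cm
    rm_delta <- median(row_eff)
    row_eff <- row_eff - rm_delta
    overall <- overall + rm_delta
    if (max(abs(rm)) < tol && max(abs(cm)) < tol) break
  }
  list(residuals = r, overall = overall, row = row_eff, col = col_eff)
}
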