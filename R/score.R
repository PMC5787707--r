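#' Compute the PV gate from non-targeting control cells
#'
#' Pools the predicted values (PVs) of all T(+) cells in non-targeting
#' control wells — each scored by its own well's classifiers — and sets the
#' single-cell gate at `mean + multiplier x sample SD` of that pool. T(+)
#' cells above the gate are called phenotypically perturbed and enter
#' profiling. The pool is screen-wide, matching the single printed gate of
#' the original screen.
#'
#' @param pv Per-cell PV table (`plate_id`, `well_id`, `cell_id`,
#'   `transfected`, `pv`), e.g. `classify_screen()$pv`.
#' @param map A [plate_map()].
#' @param multiplier SD multiplier (default 3).
#' @return A `pv_gate` list: `threshold`, `control_mean`, `control_sd`,
#'   `multiplier`, `n_control_cells`.
#' @export
compute_pv_gate <- function(pv, map, multiplier = 3) {
  ctrl <- map[map$is_control, c("plate_id", "well_id")]
  key <- paste(pv$plate_id, pv$well_id)
  sel <- key %in% paste(ctrl$plate_id, ctrl$well_id) & pv$transfected
  pool <- pv$pv[sel]
  if (!length(pool)) stop("no T(+) cells found in non-targeting control wells")
  m <- mean(pool)
  s <- if (length(pool) > 1) sd(pool) else 0
  structure(
    list(threshold = m + multiplier * s, control_mean = m, control_sd = s,
         multiplier = multiplier, n_control_cells = length(pool)),
    class = "pv_gate"
  )
}

#' @export
print.pv_gate <- function(x, ...) {
  cat(sprintf("PV gate: %.4f (control mean %.4f + %g x SD %.4f, n = %d)\n",
              x$threshold, x$control_mean, x$multiplier, x$control_sd,
              x$n_control_cells))
  invisible(x)
}

#' Gate phenotypically perturbed cells
#'
#' Returns the T(+) cells whose PV strictly exceeds the gate threshold.
#' T(-) cells are never returned, whatever their PV.
#'
#' @param pv Per-cell PV table (see [compute_pv_gate()]).
#' @param gate A `pv_gate`.
#' @return The gated subset of `pv` rows.
#' @export
gate_cells <- function(pv, gate) {
  stopifnot(inherits(gate, "pv_gate"))
  out <- pv[pv$transfected & pv$pv > gate$threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Phenotypic score: two-sample Kolmogorov-Smirnov statistic
#'
#' \eqn{D = \sup_x |F_{target}(x) - F_{control}(x)|} between the PV
#' distributions of transfected cells in a perturbation well versus
#' non-targeting control wells. 0 means indistinguishable populations,
#' 1 disjoint supports. Only the statistic is returned; no p-value.
#'
#' @param target_pv Numeric PVs of T(+) cells in the target population.
#' @param control_pv Numeric PVs of T(+) cells in control populations.
#' @return The KS statistic in `[0, 1]`.
#' @export
phenotypic_score <- function(target_pv, control_pv) {
  if (!length(target_pv) || !length(control_pv)) {
    stop("both samples must be non-empty")
  }
  v <- sort(unique(c(target_pv, control_pv)))
  max(abs(ecdf(target_pv)(v) - ecdf(control_pv)(v)))
}

#' Call hits from classification scores
#'
#' A perturbation is a hit when its classification score strictly exceeds
#' the Tukey fence `Q3 + multiplier x IQR` of the classification scores of
#' non-targeting control wells (quantiles by linear interpolation between
#' order statistics). The fence is conservative: it selects classifiers
#' that perform better than classifiers trained on control populations.
#'
#' @param wells Per-well score table (`plate_id`, `well_id`,
#'   `classification_score`), e.g. `classify_screen()$wells`.
#' @param map A [plate_map()].
#' @param multiplier IQR multiplier (default 1.5).
#' @return A list: `threshold` (a `hit_threshold` with `value`, `q3`,
#'   `iqr`, `multiplier`, `n_control`) and `wells` (input with `is_hit`
#'   added).
#' @export
call_hits <- function(wells, map, multiplier = 1.5) {
  key <- paste(wells$plate_id, wells$well_id)
  ctrl_key <- paste(map$plate_id[map$is_control], map$well_id[map$is_control])
  ctrl_scores <- wells$classification_score[key %in% ctrl_key]
  if (length(ctrl_scores) < 4) {
    stop("hit calling requires >= 4 control wells (found ",
         length(ctrl_scores), ")")
  }
  q3 <- unname(quantile(ctrl_scores, 0.75, type = 7))
  iqr <- unname(quantile(ctrl_scores, 0.75, type = 7) -
                  quantile(ctrl_scores, 0.25, type = 7))
  thr <- q3 + multiplier * iqr
  wells$is_hit <- wells$classification_score > thr
  list(
    threshold = structure(
      list(value = thr, q3 = q3, iqr = iqr, multiplier = multiplier,
           n_control = length(ctrl_scores)),
      class = "hit_threshold"
    ),
    wells = wells
  )
}

#' @export
print.hit_threshold <- function(x, ...) {
  cat(sprintf("hit threshold: %.4f (Q3 %.4f + %g x IQR %.4f, %d controls)\n",
              x$value, x$q3, x$multiplier, x$iqr, x$n_control))
  invisible(x)
}

#' Assemble the per-perturbation screen result
#'
#' Joins per-well classifier output, PV gating and hit calls into one table:
#' cell counts, mean misclassification, classification score, KS phenotypic
#' score against the pooled control T(+) PVs, gated-cell count, and hit flag.
#'
#' @param classification A `screen_classification` from [classify_screen()].
#' @param map A [plate_map()].
#' @param gate_multiplier SD multiplier for the PV gate (default 3).
#' @param hit_multiplier IQR multiplier for the hit fence (default 1.5).
#' @return A list: `screen` (the per-well result data.frame), `gate`
#'   (`pv_gate`), `hit_threshold`, `gated` (gated-cell table).
#' @export
score_screen <- function(classification, map, gate_multiplier = 3,
                         hit_multiplier = 1.5) {
  wells <- classification$wells
  pv <- classification$pv
  gate <- compute_pv_gate(pv, map, multiplier = gate_multiplier)
  gated <- gate_cells(pv, gate)
  hits <- call_hits(wells, map, multiplier = hit_multiplier)

  ctrl_key <- paste(map$plate_id[map$is_control], map$well_id[map$is_control])
  pv_key <- paste(pv$plate_id, pv$well_id)
  ctrl_pool <- pv$pv[pv_key %in% ctrl_key & pv$transfected]

  wells <- hits$wells
  wk <- paste(wells$plate_id, wells$well_id)
  gk <- paste(gated$plate_id, gated$well_id)
  wells$phenotypic_score <- vapply(seq_len(nrow(wells)), function(i) {
    tpv <- pv$pv[pv_key == wk[i] & pv$transfected]
    phenotypic_score(tpv, ctrl_pool)
  }, numeric(1))
  wells$n_gated <- as.integer(table(factor(gk, levels = wk)))

  mk <- paste(map$plate_id, map$well_id)
  idx <- match(wk, mk)
  wells$perturbation_id <- map$perturbation_id[idx]
  wells$gene <- map$gene[idx]
  wells$is_control <- map$is_control[idx]
  wells <- wells[, c("plate_id", "well_id", "perturbation_id", "gene",
                     "is_control", "n_tpos", "n_tneg",
                     "mean_misclassification", "classification_score",
                     "phenotypic_score", "n_gated", "is_hit")]
  list(screen = wells, gate = gate, hit_threshold = hits$threshold,
       gated = gated)
}
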