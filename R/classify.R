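#' Pooled principal component analysis of standardized features
#'
#' PCA is fitted once on cells pooled across all QC-retained wells of the
#' screen (per feature set), so that component scores — and hence classifier
#' predicted values — live in a common space across wells. Components are
#' ordered by decreasing explained variance; each component's sign is fixed
#' so that its largest-magnitude loading is positive.
#'
#' @param cells A standardized [cell_table()].
#' @param k Number of components to retain (<= number of features). The
#'   screen defaults are 50 for cell-morphology features and 30 for
#'   nuclear-pore-staining features.
#' @param feature_names Features to use; default all.
#' @return A `pc_model` list: `features`, `feature_means`, `loadings`
#'   (features x k, orthonormal columns), `explained_variance`, `k`.
#' @export
fit_pca <- function(cells, k, feature_names = NULL) {
  feats <- feature_names %||% features(cells)
  if (k > length(feats)) {
    stop("k (", k, ") exceeds the number of features (", length(feats), ")")
  }
  X <- as.matrix(as.data.frame(cells)[, feats, drop = FALSE])
  if (nrow(X) < k + 1) stop("need at least k + 1 cells to fit a ", k,
                            "-component PCA")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  structure(
    list(features = feats,
         feature_means = pc$center,
         loadings = load,
         explained_variance = pc$sdev[seq_len(k)]^2,
         k = as.integer(k)),
    class = "pc_model"
  )
}

#' Project cells onto a fitted PC model
#'
#' @param cells A [cell_table()] in the model's feature space.
#' @param model A `pc_model` from [fit_pca()].
#' @return A data.frame: plate_id, well_id, cell_id, transfected,
#'   `PC1..PCk` component scores.
#' @export
project_cells <- function(cells, model) {
  stopifnot(inherits(model, "pc_model"))
  absent <- setdiff(model$features, names(cells))
  if (length(absent)) {
    stop("cells lack model feature(s): ", paste(absent, collapse = ", "))
  }
  X <- as.matrix(as.data.frame(cells)[, model$features, drop = FALSE])
  S <- sweep(X, 2, model$feature_means) %*% model$loadings
  colnames(S) <- paste0("PC", seq_len(model$k))
  cbind(as.data.frame(cells)[, c("plate_id", "well_id", "cell_id",
                                 "transfected")],
        as.data.frame(S))
}

#' Reconstruct feature values from component scores
#'
#' Inverse of [project_cells()] (exact when `k` equals the number of
#' features). Mostly useful for diagnostics.
#'
#' @param scores Numeric matrix of component scores (cells x k).
#' @param model A `pc_model`.
#' @return Matrix of reconstructed feature values.
#' @export
reconstruct_cells <- function(scores, model) {
  sweep(as.matrix(scores) %*% t(model$loadings), 2, model$feature_means, "+")
}

#' Within-well bootstrapped classifier of T(+) versus T(-) cells
#'
#' The scoring engine: for one well, repeatedly (`n_boot` times) draw
#' `n_per_class` T(+) and `n_per_class` T(-) cells with replacement, fit an
#' L1-penalized (LASSO) logistic regression over a penalty path with
#' `n_folds`-fold cross-validation (folds stratified by class), pick the
#' penalty minimizing CV misclassification error, and record that error.
#' Each bootstrap's refitted model assigns every cell in the well a
#' predicted value (PV): the linear predictor (log-odds of being T(+)), so
#' PV > 0 places a cell on the phenotypically perturbed side of the
#' decision boundary. PVs and misclassification errors are averaged over
#' bootstraps, and
#'
#' \deqn{\mathrm{classification\ score} = 0.5 - \overline{\mathrm{CV\
#' misclassification}}}
#'
#' so 0 means the classifier cannot tell the populations apart (no
#' phenotype) and 0.5 means perfect separation.
#'
#' @param scores Data.frame for one well: `cell_id`, `transfected`, and
#'   numeric component-score columns (e.g. from [project_cells()]).
#' @param n_boot Number of bootstraps (screen default 100).
#' @param n_per_class Cells drawn per class per bootstrap (default 500),
#'   with replacement, regardless of the true class imbalance.
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Integer seed for this well's resampling stream.
#' @param nlambda Length of the glmnet penalty path.
#' @return A `well_classifier_result` list: `n_bootstraps`,
#'   `mean_misclassification`, `classification_score`, `pv` (data.frame
#'   cell_id, transfected, pv), `selected_feature_frequency`.
#' @export
fit_well_classifier <- function(scores, n_boot = 100, n_per_class = 500,
                                n_folds = 10, seed = 1, nlambda = 30) {
  if (n_folds < 2) stop("n_folds must be >= 2")
  id_cols <- intersect(c("plate_id", "well_id", "cell_id", "transfected"),
                       names(scores))
  comp <- setdiff(names(scores), id_cols)
  if (!length(comp)) stop("no component-score columns found")
  X <- as.matrix(scores[, comp, drop = FALSE])
  y <- scores$transfected
  pos <- which(y)
  neg <- which(!y)
  if (!length(pos) || !length(neg)) {
    stop("both T(+) and T(-) cells are required to train a classifier")
  }

  withr::with_seed(as.integer(seed), {
    miscl <- numeric(n_boot)
    pv_sum <- numeric(nrow(X))
    nz <- numeric(length(comp))
    for (b in seq_len(n_boot)) {
      i_pos <- sample(pos, n_per_class, replace = TRUE)
      i_neg <- sample(neg, n_per_class, replace = TRUE)
      idx <- c(i_pos, i_neg)
      yb <- c(rep(1, n_per_class), rep(0, n_per_class))
      # class-stratified folds: every fold sees both classes
      foldid <- c(sample(rep(seq_len(n_folds), length.out = n_per_class)),
                  sample(rep(seq_len(n_folds), length.out = n_per_class)))
      cv <- suppressWarnings(glmnet::cv.glmnet(
        X[idx, , drop = FALSE], yb, family = "binomial",
        type.measure = "class", foldid = foldid, nlambda = nlambda,
        standardize = FALSE
      ))
      sel <- which(cv$lambda == cv$lambda.min)[1]
      miscl[b] <- cv$cvm[sel]
      pv_sum <- pv_sum + as.vector(suppressWarnings(
        predict(cv, newx = X, s = "lambda.min", type = "link")))
      beta <- as.vector(stats::coef(cv, s = "lambda.min"))[-1]
      nz <- nz + (beta != 0)
    }
  })

  mean_miscl <- mean(miscl)
  structure(
    list(
      n_bootstraps = as.integer(n_boot),
      mean_misclassification = mean_miscl,
      classification_score = 0.5 - mean_miscl,
      pv = data.frame(cell_id = scores$cell_id,
                      transfected = scores$transfected,
                      pv = pv_sum / n_boot),
      selected_feature_frequency = setNames(nz / n_boot, comp)
    ),
    class = "well_classifier_result"
  )
}

#' @export
print.well_classifier_result <- function(x, ...) {
  cat(sprintf(paste0("well classifier: %d bootstraps, mean ",
                     "misclassification %.3f, score %.3f\n"),
              x$n_bootstraps, x$mean_misclassification,
              x$classification_score))
  invisible(x)
}

#' Classify every well of a screen
#'
#' Fits the pooled PCA once, then runs [fit_well_classifier()] in every
#' well. Each well uses a deterministic seed substream derived from
#' `(seed, plate_id, well_id)`, so results are independent of well order.
#'
#' @param cells A standardized [cell_table()] (post-QC).
#' @param pca_k Retained components for the pooled PCA.
#' @param n_boot,n_per_class,n_folds,nlambda Passed to
#'   [fit_well_classifier()].
#' @param seed Screen-level seed.
#' @param feature_names Features for the PCA; default all.
#' @return A `screen_classification` list: `wells` (data.frame per well:
#'   plate_id, well_id, n_tpos, n_tneg, mean_misclassification,
#'   classification_score), `pv` (data.frame per cell: plate_id, well_id,
#'   cell_id, transfected, pv), `pca` (the `pc_model`).
#' @export
classify_screen <- function(cells, pca_k = 30, n_boot = 100,
                            n_per_class = 500, n_folds = 10, seed = 1,
                            nlambda = 30, feature_names = NULL) {
  model <- fit_pca(cells, k = pca_k, feature_names = feature_names)
  proj <- project_cells(cells, model)
  key <- paste(proj$plate_id, proj$well_id, sep = ":")
  wells <- unique(key)

  well_rows <- vector("list", length(wells))
  pv_rows <- vector("list", length(wells))
  for (i in seq_along(wells)) {
    sub <- proj[key == wells[i], , drop = FALSE]
    fit <- fit_well_classifier(
      sub, n_boot = n_boot, n_per_class = n_per_class, n_folds = n_folds,
      seed = well_seed(seed, sub$plate_id[1], sub$well_id[1]),
      nlambda = nlambda
    )
    well_rows[[i]] <- data.frame(
      plate_id = sub$plate_id[1], well_id = sub$well_id[1],
      n_tpos = sum(sub$transfected), n_tneg = sum(!sub$transfected),
      mean_misclassification = fit$mean_misclassification,
      classification_score = fit$classification_score
    )
    pv_rows[[i]] <- cbind(sub[, c("plate_id", "well_id")], fit$pv)
  }
  out <- list(
    wells = do.call(rbind, well_rows),
    pv = do.call(rbind, pv_rows),
    pca = model
  )
  rownames(out$wells) <- rownames(out$pv) <- NULL
  class(out) <- "screen_classification"
  out
}
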