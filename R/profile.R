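#' Mean feature profiles of gated (phenotypically perturbed) cells
#'
#' For each perturbation, averages the standardized features of its
#' PV-gated cells and references the result to the mean over control T(+)
#' cells, so a profile of zeros means "looks like a control transfected
#' population". Perturbations with fewer than `min_gated` gated cells are
#' withheld (reported, not returned) to guard against single-cell noise.
#'
#' @param cells A standardized [cell_table()].
#' @param gated Gated-cell table from [gate_cells()] (`plate_id`,
#'   `well_id`, `cell_id`).
#' @param map A [plate_map()].
#' @param feature_names Features to profile; default all.
#' @param min_gated Minimum gated cells to report a profile (default 20).
#' @return A list: `profiles` (data.frame: perturbation_id, gene, n_gated,
#'   one column per feature) and `withheld` (data.frame with reasons).
#' @export
perturbation_profiles <- function(cells, gated, map, feature_names = NULL,
                                  min_gated = 20) {
  feats <- feature_names %||% features(cells)
  ck <- paste(cells$plate_id, cells$well_id, cells$cell_id)
  gk <- paste(gated$plate_id, gated$well_id, gated$cell_id)
  wk <- paste(cells$plate_id, cells$well_id)
  mk <- paste(map$plate_id, map$well_id)
  ctrl <- cells$transfected & (map$is_control[match(wk, mk)] %in% TRUE)
  if (!any(ctrl)) stop("no control T(+) cells available as reference")
  ref <- colMeans(as.matrix(as.data.frame(cells)[ctrl, feats, drop = FALSE]))

  sel <- cells[ck %in% gk, , drop = FALSE]
  pert <- map$perturbation_id[match(paste(sel$plate_id, sel$well_id), mk)]
  X <- as.matrix(as.data.frame(sel)[, feats, drop = FALSE])

  counts <- table(pert)
  profiles <- list()
  withheld <- list()
  for (p in names(counts)) {
    n <- as.integer(counts[[p]])
    gene <- map$gene[match(p, map$perturbation_id)]
    if (n < min_gated) {
      withheld[[p]] <- data.frame(
        perturbation_id = p, gene = gene, n_gated = n,
        reason = sprintf("fewer than %d gated cells", min_gated)
      )
      next
    }
    prof <- colMeans(X[pert == p, , drop = FALSE]) - ref
    profiles[[p]] <- data.frame(perturbation_id = p, gene = gene,
                                n_gated = n, t(prof), check.names = FALSE)
  }
  out <- list(
    profiles = if (length(profiles)) do.call(rbind, profiles) else
      data.frame(),
    withheld = if (length(withheld)) do.call(rbind, withheld) else
      data.frame()
  )
  rownames(out$profiles) <- rownames(out$withheld) <- NULL
  attr(out$profiles, "features") <- feats
  out
}

#' Pearson correlations between perturbation profiles
#'
#' Computes the correlation between every pair of profiles and labels each
#' pair as within-gene (independent guides targeting the same gene — the
#' replicate-consistency readout) or between-gene. Pairs involving a
#' constant profile have undefined correlation and are flagged.
#'
#' @param profiles Profile table from [perturbation_profiles()] (columns
#'   `perturbation_id`, `gene`, features).
#' @param feature_names Features to correlate; default the table's
#'   `features` attribute.
#' @return A data.frame: id_a, id_b, gene_a, gene_b, within_gene, r,
#'   undefined.
#' @export
replicate_correlation <- function(profiles, feature_names = NULL) {
  feats <- feature_names %||% attr(profiles, "features")
  n <- nrow(profiles)
  if (n < 2) stop("need >= 2 profiles")
  X <- as.matrix(profiles[, feats, drop = FALSE])
  const <- apply(X, 1, function(r) sd(r) == 0)
  pairs <- utils::combn(n, 2)
  r <- rep(NA_real_, ncol(pairs))
  ok <- !(const[pairs[1, ]] | const[pairs[2, ]])
  r[ok] <- vapply(which(ok), function(j) {
    cor(X[pairs[1, j], ], X[pairs[2, j], ])
  }, numeric(1))
  data.frame(
    id_a = profiles$perturbation_id[pairs[1, ]],
    id_b = profiles$perturbation_id[pairs[2, ]],
    gene_a = profiles$gene[pairs[1, ]],
    gene_b = profiles$gene[pairs[2, ]],
    within_gene = profiles$gene[pairs[1, ]] == profiles$gene[pairs[2, ]],
    r = r,
    undefined = !ok
  )
}

#' Hierarchical clustering of perturbation profiles
#'
#' Average-linkage agglomerative clustering under correlation distance
#' (1 - Pearson r). Rows are ordered by perturbation id before clustering
#' so that ties in merge height resolve deterministically by id order.
#'
#' @param profiles Profile table from [perturbation_profiles()].
#' @param feature_names Features to use; default the table's attribute.
#' @return An `hclust` object with perturbation ids as labels.
#' @export
cluster_profiles <- function(profiles, feature_names = NULL) {
  feats <- feature_names %||% attr(profiles, "features")
  if (nrow(profiles) < 2) stop("need >= 2 profiles to cluster")
  ord <- order(profiles$perturbation_id)
  X <- as.matrix(profiles[ord, feats, drop = FALSE])
  rownames(X) <- profiles$perturbation_id[ord]
  d <- as.dist(1 - cor(t(X)))
  hclust(d, method = "average")
}

#' Export a profile dendrogram as Newick text
#'
#' Serializes the tree from [cluster_profiles()] (merge heights become
#' branch lengths) for use with standard tree viewers.
#'
#' @param hc An `hclust` object.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to `path`.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the 'ape' package is required for Newick export")
  }
  txt <- ape::write.tree(ape::as.phylo(hc))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Diagonal-shrinkage covariance estimate
#'
#' Sample covariance with the off-diagonal correlations shrunk toward zero
#' by an analytically chosen intensity (the variance-of-correlations rule),
#' keeping the estimate well conditioned when profiles are few relative to
#' features.
#'
#' @param X Numeric matrix (observations x variables).
#' @return A list: `sigma` (shrunk covariance), `lambda` (intensity used).
#' @export
cov_shrink_diag <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need >= 2 observations")
  s <- apply(X, 2, sd)
  s[s == 0] <- 1  # constant columns: zero correlation with everything
  Z <- scale(X, center = TRUE, scale = s)
  R <- crossprod(Z) / (n - 1)
  diag(R) <- 1
  # var of each r_ij from the standardized cross products
  var_r <- matrix(0, ncol(X), ncol(X))
  for (j in seq_len(ncol(X))) {
    w <- Z * Z[, j]
    var_r[, j] <- n / ((n - 1)^3) * colSums((w - rep(colMeans(w),
                                                     each = n))^2)
  }
  off <- row(R) != col(R)
  denom <- sum(R[off]^2)
  lambda <- if (denom > 0) min(1, max(0, sum(var_r[off]) / denom)) else 1
  R_shrunk <- (1 - lambda) * R
  diag(R_shrunk) <- 1
  sigma <- R_shrunk * tcrossprod(s)
  list(sigma = sigma, lambda = lambda)
}

#' Between-well Mahalanobis profiling
#'
#' The between-well baseline: the distance of each well-population profile
#' from the centre of the distribution of all profiles, under a
#' shrinkage-regularized covariance of the profiles (pseudo-inverse
#' fallback if still singular). A T(+) profile is a hit when its distance
#' strictly exceeds `Q3 + multiplier x IQR` of the distances of
#' non-targeting control T(+) profiles.
#'
#' @param profiles A `well_profiles` table, normally after [bscore()].
#' @param map A [plate_map()], needed for the control fence; with
#'   `map = NULL` only the distances are returned (no threshold, no hit
#'   flags).
#' @param multiplier IQR multiplier for the fence (default 3).
#' @param shrinkage `"auto"` (analytic shrinkage; the default) or `"none"`
#'   (plain sample covariance — affine-equivariant, for diagnostics and
#'   well-conditioned inputs).
#' @return A list: `distances` (profile table with `mahalanobis_distance`
#'   and, for T(+) rows, `is_hit`), `threshold` (a `hit_threshold`),
#'   `lambda` (shrinkage intensity).
#' @export
mahalanobis_profiles <- function(profiles, map = NULL, multiplier = 3,
                                 shrinkage = c("auto", "none")) {
  shrinkage <- match.arg(shrinkage)
  feats <- attr(profiles, "features")
  X <- as.matrix(profiles[, feats, drop = FALSE])
  mu <- colMeans(X)
  if (shrinkage == "auto") {
    cs <- cov_shrink_diag(X)
    sigma <- cs$sigma
    lambda <- cs$lambda
  } else {
    sigma <- cov(X)
    lambda <- 0
  }
  d2 <- tryCatch(
    mahalanobis(X, mu, sigma),
    error = function(e) {
      inv <- MASS::ginv(sigma)
      rowSums((sweep(X, 2, mu) %*% inv) * sweep(X, 2, mu))
    }
  )
  out <- profiles[, c("plate_id", "well_id", "population")]
  out$mahalanobis_distance <- sqrt(pmax(0, d2))
  if (is.null(map)) {
    return(list(distances = out, threshold = NULL, lambda = lambda))
  }

  ctrl_key <- paste(map$plate_id[map$is_control], map$well_id[map$is_control])
  key <- paste(out$plate_id, out$well_id)
  ctrl_d <- out$mahalanobis_distance[key %in% ctrl_key &
                                       out$population == "Tpos"]
  if (length(ctrl_d) < 4) {
    stop("between-well fence requires >= 4 control T(+) profiles (found ",
         length(ctrl_d), ")")
  }
  q3 <- unname(quantile(ctrl_d, 0.75, type = 7))
  iqr <- unname(q3 - quantile(ctrl_d, 0.25, type = 7))
  thr <- q3 + multiplier * iqr
  out$is_hit <- out$population == "Tpos" & out$mahalanobis_distance > thr
  list(
    distances = out,
    threshold = structure(
      list(value = thr, q3 = q3, iqr = iqr, multiplier = multiplier,
           n_control = length(ctrl_d)),
      class = "hit_threshold"
    ),
    lambda = lambda
  )
}
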