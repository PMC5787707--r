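profile_df <- function(ids, genes, X) {
  df <- data.frame(perturbation_id = ids, gene = genes, n_gated = 50L,
                   X, check.names = FALSE)
  attr(df, "features") <- colnames(X)
  df
}

test_that("gated-cell profiles are control-referenced means", {
  set.seed(61)
  # control well cells at baseline; perturbation cells shifted by +2 on f1
  n <- 60
  df <- data.frame(
    plate_id = "P",
    well_id = rep(c("A01", "A02"), each = n),
    cell_id = rep(seq_len(n), 2),
    transfected = TRUE,
    f1 = c(rnorm(n), rnorm(n) + 2),
    f2 = rnorm(2 * n)
  )
  cells <- cell_table(df)
  map <- plate_map(data.frame(
    plate_id = "P", well_id = c("A01", "A02"),
    perturbation_id = c("ctrl", "pert"), gene = c("nt", "G1"),
    guide_id = c("g0", "g1"), is_control = c(TRUE, FALSE)
  ))
  gated <- df[df$well_id == "A02", c("plate_id", "well_id", "cell_id")]
  prof <- perturbation_profiles(cells, gated, map, min_gated = 10)
  expect_equal(nrow(prof$profiles), 1L)
  expect_equal(prof$profiles$f1, 2, tolerance = 0.5)
  expect_equal(prof$profiles$f2, 0, tolerance = 0.5)

  # gating the control population itself gives a near-zero profile
  gated_ctrl <- df[df$well_id == "A01", c("plate_id", "well_id", "cell_id")]
  prof0 <- perturbation_profiles(cells, gated_ctrl, map, min_gated = 10)
  expect_equal(prof0$profiles$f1, 0, tolerance = 1e-10)
  expect_equal(prof0$profiles$f2, 0, tolerance = 1e-10)

  # single gated cell with min_gated 1: profile equals that cell minus ref
  one <- gated[1, ]
  p1 <- perturbation_profiles(cells, one, map, min_gated = 1)
  ref <- colMeans(df[df$well_id == "A01", c("f1", "f2")])
  cell_vals <- unlist(df[df$well_id == "A02" & df$cell_id == one$cell_id,
                         c("f1", "f2")])
  expect_equal(unlist(p1$profiles[, c("f1", "f2")]),
               cell_vals - ref, ignore_attr = TRUE)

  # below min_gated: withheld with a reason, not returned
  few <- perturbation_profiles(cells, gated[1:5, ], map, min_gated = 20)
  expect_equal(nrow(few$profiles), 0L)
  expect_match(few$withheld$reason, "fewer than 20")
})

test_that("replicate correlations label and compute pairs correctly", {
  v <- c(1, -2, 3, 0.5)
  X <- rbind(a1 = v, a2 = v, b1 = -v, flat = rep(1, 4))
  colnames(X) <- paste0("f", 1:4)
  prof <- profile_df(c("a1", "a2", "b1", "flat"),
                     c("GA", "GA", "GB", "GC"), X)
  rc <- replicate_correlation(prof)
  pair <- function(i, j) rc[rc$id_a == i & rc$id_b == j, ]
  expect_equal(pair("a1", "a2")$r, 1)
  expect_true(pair("a1", "a2")$within_gene)
  expect_equal(pair("a1", "b1")$r, -1)
  expect_false(pair("a1", "b1")$within_gene)
  expect_true(pair("a1", "flat")$undefined)
  expect_true(is.na(pair("a1", "flat")$r))
})

test_that("clustering merges identical profiles first, invariant to order", {
  set.seed(62)
  v <- rnorm(6)
  X <- rbind(p1 = v + rnorm(6, sd = 1e-4), p2 = v + rnorm(6, sd = 1e-4),
             p3 = -v)
  colnames(X) <- paste0("f", 1:6)
  prof <- profile_df(c("p1", "p2", "p3"), c("GA", "GA", "GB"), X)
  hc <- cluster_profiles(prof)
  # first merge joins the near-identical pair p1, p2
  first <- sort(abs(hc$merge[1, ]))
  expect_equal(hc$labels[first], c("p1", "p2"))

  shuffled <- prof[c(3, 1, 2), ]
  attr(shuffled, "features") <- attr(prof, "features")
  hc2 <- cluster_profiles(shuffled)
  expect_equal(hc$height, hc2$height)
  expect_equal(stats::cophenetic(hc), stats::cophenetic(hc2))

  expect_error(cluster_profiles(prof[1, , drop = FALSE]), ">= 2")

  nwk <- dendrogram_newick(hc)
  expect_match(nwk, "^\\(.*\\);$")
  expect_true(all(vapply(hc$labels, grepl, logical(1), x = nwk,
                         fixed = TRUE)))
})

test_that("Mahalanobis distances match the quadratic-form oracle", {
  # three profiles in 2D with a hand-checkable covariance
  X <- rbind(c(0, 0), c(2, 1), c(4, 5))
  colnames(X) <- c("f1", "f2")
  prof <- data.frame(plate_id = "P",
                     well_id = c("A01", "A02", "A03"),
                     population = "Tpos", row_index = 1L,
                     col_index = 1:3, n_cells = 10L, X,
                     check.names = FALSE)
  attr(prof, "features") <- c("f1", "f2")
  class(prof) <- c("well_profiles", "data.frame")
  res <- mahalanobis_profiles(prof, map = NULL, shrinkage = "none")
  S <- cov(X)
  mu <- colMeans(X)
  oracle <- apply(X, 1, function(r) {
    sqrt(drop(t(r - mu) %*% solve(S) %*% (r - mu)))
  })
  expect_equal(res$distances$mahalanobis_distance, unname(oracle),
               tolerance = 1e-6)
})

test_that("shrinkage distances approach Euclidean for identity covariance", {
  set.seed(63)
  X <- matrix(rnorm(500 * 5), 500, 5)
  colnames(X) <- paste0("f", 1:5)
  prof <- data.frame(plate_id = "P",
                     well_id = sprintf("%s%02d",
                                       rep(LETTERS[1:16], each = 20),
                                       rep(3:22, 16))[1:500],
                     population = "Tpos", row_index = 1L, col_index = 1L,
                     n_cells = 10L, X, check.names = FALSE)
  attr(prof, "features") <- paste0("f", 1:5)
  class(prof) <- c("well_profiles", "data.frame")
  res <- mahalanobis_profiles(prof, map = NULL, shrinkage = "auto")
  eu <- sqrt(rowSums(scale(X, scale = FALSE)^2))
  rel <- abs(res$distances$mahalanobis_distance - eu) / eu
  expect_lt(stats::median(rel), 0.05)
})

test_that("unregularized distances are affine invariant", {
  set.seed(64)
  X <- matrix(rnorm(40 * 3), 40, 3)
  colnames(X) <- paste0("f", 1:3)
  mk <- function(M) {
    prof <- data.frame(plate_id = "P",
                       well_id = sprintf("A%02d", 1:40),
                       population = "Tpos", row_index = 1L, col_index = 1L,
                       n_cells = 10L, M, check.names = FALSE)
    attr(prof, "features") <- colnames(M)
    class(prof) <- c("well_profiles", "data.frame")
    prof
  }
  A <- matrix(c(2, 0.5, 0, 1, 3, 0.2, 0, 0, 1.5), 3, 3)
  Y <- X %*% A
  colnames(Y) <- colnames(X)
  d1 <- mahalanobis_profiles(mk(X), map = NULL, shrinkage = "none")
  d2 <- mahalanobis_profiles(mk(Y), map = NULL, shrinkage = "none")
  expect_equal(d1$distances$mahalanobis_distance,
               d2$distances$mahalanobis_distance, tolerance = 1e-6)
})

test_that("the grand-mean profile has distance zero and the fence flags", {
  set.seed(65)
  m <- c(1, 2)
  V <- matrix(rnorm(10 * 2), 10, 2)
  X <- rbind(sweep(V, 2, m, "+"), sweep(-V, 2, m, "+"), m)
  colnames(X) <- c("f1", "f2")
  wells <- sprintf("A%02d", seq_len(nrow(X)))
  prof <- data.frame(plate_id = "P", well_id = wells,
                     population = "Tpos", row_index = 1L, col_index = 1L,
                     n_cells = 10L, X, check.names = FALSE)
  attr(prof, "features") <- c("f1", "f2")
  class(prof) <- c("well_profiles", "data.frame")
  res <- mahalanobis_profiles(prof, map = NULL, shrinkage = "none")
  expect_equal(res$distances$mahalanobis_distance[nrow(X)], 0,
               tolerance = 1e-8)

  map <- plate_map(data.frame(
    plate_id = "P", well_id = wells,
    perturbation_id = paste0("p", seq_along(wells)),
    gene = "nt", guide_id = "g",
    is_control = rep(c(TRUE, FALSE), length.out = length(wells))
  ))
  fen <- mahalanobis_profiles(prof, map = map, shrinkage = "none")
  expect_true(all(fen$distances$mahalanobis_distance >= 0))
  expect_equal(fen$threshold$multiplier, 3)
  expect_true(all(fen$distances$is_hit ==
                    (fen$distances$mahalanobis_distance >
                       fen$threshold$value &
                       fen$distances$population == "Tpos")))
})
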