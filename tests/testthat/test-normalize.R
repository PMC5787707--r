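test_that("well QC excludes at the documented cell-count boundaries", {
  set.seed(21)
  cells <- tiny_cells(list(
    A01 = list(n_tpos = 299, n_tneg = 150),
    A02 = list(n_tpos = 300, n_tneg = 150),
    A03 = list(n_tpos = 400, n_tneg = 99),
    A04 = list(n_tpos = 400, n_tneg = 100)
  ))
  qc <- qc_wells(cells)
  expect_setequal(unique(qc$cells$well_id), c("A02", "A04"))
  expect_setequal(qc$exclusions$well_id, c("A01", "A03"))
  expect_match(qc$exclusions$reason[qc$exclusions$well_id == "A01"], "T\\(\\+\\)")
  expect_match(qc$exclusions$reason[qc$exclusions$well_id == "A03"], "T\\(-\\)")

  # no thresholds, no exclusions; output equals input
  all_in <- qc_wells(cells, min_tpos = 0, min_tneg = 0)
  expect_equal(nrow(all_in$exclusions), 0L)
  expect_equal(as.data.frame(all_in$cells), as.data.frame(cells))
})

test_that("raising QC minima never retains a previously excluded well", {
  set.seed(22)
  counts <- data.frame(tp = sample(250:350, 12, TRUE),
                       tn = sample(80:120, 12, TRUE))
  wells <- lapply(seq_len(12), function(i) {
    list(n_tpos = counts$tp[i], n_tneg = counts$tn[i])
  })
  names(wells) <- sprintf("A%02d", seq_len(12))
  cells <- tiny_cells(wells)
  prev <- unique(qc_wells(cells, min_tpos = 280)$cells$well_id)
  for (m in c(300, 320, 340)) {
    cur <- unique(qc_wells(cells, min_tpos = m)$cells$well_id)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("standardization matches the hand oracle and is idempotent", {
  cells <- cell_table(data.frame(
    plate_id = "P", well_id = "A01", cell_id = 1:4,
    transfected = c(FALSE, FALSE, FALSE, TRUE),
    f1 = c(1, 2, 3, 4)
  ))
  std <- standardize_within_well(cells)
  # T(-) {1,2,3}: mean 2, sample SD 1; the T(+) value 4 maps to 2.0
  expect_equal(std$f1, c(-1, 0, 1, 2))
  prov <- attr(std, "standardization")
  expect_equal(prov$tneg_mean, 2)
  expect_equal(prov$tneg_sd, 1)

  scr <- generate_screen(sim_config(wells_per_plate = 4,
                                    cells_per_well = 300, seed = 31))
  s1 <- standardize_within_well(scr$cells)
  s2 <- standardize_within_well(s1)
  for (f in features(s1)) expect_equal(s2[[f]], s1[[f]], tolerance = 1e-9)
  # every well's T(-) population sits at mean 0, SD 1
  for (w in unique(s1$well_id)) {
    x <- s1$f01[!s1$transfected & s1$well_id == w]
    expect_equal(mean(x), 0, tolerance = 1e-9)
    expect_equal(sd(x), 1, tolerance = 1e-9)
  }
})

test_that("degenerate features are dropped screen-wide with a warning", {
  set.seed(23)
  df <- data.frame(
    plate_id = "P", well_id = rep(c("A01", "A02"), each = 6),
    cell_id = rep(1:6, 2), transfected = rep(c(TRUE, FALSE), 6),
    ok = rnorm(12),
    flat = c(rnorm(6), rep(5, 6))  # constant in well A02
  )
  cells <- cell_table(df)
  expect_warning(std <- standardize_within_well(cells), "flat")
  expect_equal(features(std), "ok")

  solo <- cell_table(data.frame(plate_id = "P", well_id = "A01",
                                cell_id = 1:3,
                                transfected = c(TRUE, TRUE, FALSE),
                                f1 = rnorm(3)))
  expect_error(standardize_within_well(solo), "A01")
})

test_that("well mean profiles are arithmetic means with plate geometry", {
  cells <- cell_table(data.frame(
    plate_id = "P", well_id = "B04", cell_id = 1:4,
    transfected = c(TRUE, TRUE, FALSE, FALSE),
    f1 = c(1, 3, 10, 30)
  ))
  prof <- well_mean_profiles(cells)
  expect_equal(prof$f1[prof$population == "Tpos"], 2)
  expect_equal(prof$f1[prof$population == "Tneg"], 20)
  expect_equal(prof$row_index, c(2L, 2L))
  expect_equal(prof$col_index, c(4L, 4L))

  shuffled <- cell_table(as.data.frame(cells)[c(3, 1, 4, 2), ])
  expect_equal(well_mean_profiles(shuffled), prof)
})

test_that("B-score zeroes exactly additive plates and guards constants", {
  grid <- expand.grid(row = 1:4, col = 3:8)
  vals <- 5 + 0.7 * grid$row - 0.3 * grid$col
  prof <- data.frame(
    plate_id = "P", well_id = sprintf("%s%02d", LETTERS[grid$row], grid$col),
    population = "Tpos", row_index = grid$row, col_index = grid$col,
    n_cells = 10L, f1 = vals
  )
  attr(prof, "features") <- "f1"
  class(prof) <- c("well_profiles", "data.frame")
  bs <- bscore(prof)
  expect_equal(bs$f1, rep(0, nrow(prof)), tolerance = 1e-9)

  const <- prof
  const$f1 <- 2
  expect_equal(bscore(const)$f1, rep(0, nrow(prof)))
  expect_false(anyNA(bscore(const)$f1))

  single <- prof[1, ]
  attr(single, "features") <- "f1"
  class(single) <- c("well_profiles", "data.frame")
  expect_error(bscore(single), "single well")
})

test_that("B-score matches a brute-force median polish on a 3x3 grid", {
  grid <- expand.grid(row = 1:3, col = 3:5)
  m <- matrix(c(0.1, -0.2, 0.05,
                0.0, 0.15, -0.1,
                4.0, 0.05, -0.05), nrow = 3, byrow = TRUE)
  prof <- data.frame(
    plate_id = "P", well_id = sprintf("%s%02d", LETTERS[grid$row], grid$col),
    population = "Tpos", row_index = grid$row, col_index = grid$col,
    n_cells = 10L,
    f1 = m[cbind(grid$row, grid$col - 2)]
  )
  attr(prof, "features") <- "f1"
  class(prof) <- c("well_profiles", "data.frame")
  bs <- bscore(prof, max_iter = 50, tol = 1e-9)

  oracle <- medpolish_brute(m)
  scale <- 1.4826 * median(abs(oracle$residuals))
  expected <- (oracle$residuals / scale)[cbind(grid$row, grid$col - 2)]
  expect_equal(bs$f1, expected, tolerance = 1e-6)
  # the outlier well carries the plate's largest |B-score|
  expect_equal(which.max(abs(bs$f1)), which(prof$well_id == "C03"))
})

test_that("B-scores are invariant to additive row and column structure", {
  set.seed(24)
  grid <- expand.grid(row = 1:5, col = 3:9)
  prof <- data.frame(
    plate_id = "P", well_id = sprintf("%s%02d", LETTERS[grid$row], grid$col),
    population = "Tpos", row_index = grid$row, col_index = grid$col,
    n_cells = 10L, f1 = rnorm(nrow(grid))
  )
  attr(prof, "features") <- "f1"
  class(prof) <- c("well_profiles", "data.frame")
  base <- bscore(prof, max_iter = 200, tol = 1e-12)

  # a constant added to one whole row is absorbed exactly by the first
  # row-median sweep; adding it to every row (a plate-wide offset)
  # likewise cancels
  row_shift <- prof
  row_shift$f1[row_shift$row_index == 2] <-
    row_shift$f1[row_shift$row_index == 2] + 7
  expect_equal(bscore(row_shift, max_iter = 200, tol = 1e-12)$f1, base$f1,
               tolerance = 1e-9)
  offset <- prof
  offset$f1 <- offset$f1 + 11
  expect_equal(bscore(offset, max_iter = 200, tol = 1e-12)$f1, base$f1,
               tolerance = 1e-9)
})
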