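#' Configuration for a synthetic arrayed screen
#'
#' Encodes the generative assumptions of an arrayed transient-transfection
#' CRISPR screen: each well receives one perturbation; a fraction
#' `transfection_rate` of its cells are transfected (T(+)); of those, a
#' fraction `penetrance` is truly genetically perturbed (editing is
#' incomplete, so T(+) populations are phenotypic mixtures). Wild-type cell
#' features are independent standard normal; a perturbed cell's features are
#' additionally shifted by `effect_vector` (in units of the wild-type SD).
#' Technical structure is additive: a per-well offset with SD `well_sigma`
#' plus linear plate row/column gradients.
#'
#' Wells are laid out on a 16 x 24 grid with the outer two columns on each
#' side left unused (columns 3-22), mirroring common plate handling.
#'
#' @param n_plates Number of plates.
#' @param wells_per_plate Wells used per plate (<= 320 on the default grid).
#' @param cells_per_well Mean of the Poisson cell count per well.
#' @param transfection_rate Probability a cell is T(+).
#' @param penetrance Probability a T(+) cell in a targeting well is truly
#'   perturbed.
#' @param n_features Number of features.
#' @param effect_vector Per-feature mean shift (wild-type SD units) applied
#'   to perturbed cells in targeting wells; recycled checks against
#'   `n_features`. Default: a 3-SD shift on the first feature.
#' @param well_sigma SD of the additive well-level technical offset.
#' @param row_effect,col_effect Additive gradient per plate row / column step.
#' @param control_fraction Fraction of wells carrying a non-targeting
#'   control (effect identically zero).
#' @param seed Integer screen-level seed; per-well substreams are derived
#'   from it so results do not depend on well order.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_plates = 1,
                       wells_per_plate = 96,
                       cells_per_well = 2000,
                       transfection_rate = 0.5,
                       penetrance = 0.6,
                       n_features = 20,
                       effect_vector = c(3, rep(0, n_features - 1)),
                       well_sigma = 0.2,
                       row_effect = 0,
                       col_effect = 0,
                       control_fraction = 0.25,
                       seed = 1) {
  cfg <- list(n_plates = as.integer(n_plates),
              wells_per_plate = as.integer(wells_per_plate),
              cells_per_well = cells_per_well,
              transfection_rate = transfection_rate,
              penetrance = penetrance,
              n_features = as.integer(n_features),
              effect_vector = as.numeric(effect_vector),
              well_sigma = well_sigma,
              row_effect = row_effect,
              col_effect = col_effect,
              control_fraction = control_fraction,
              seed = as.integer(seed))
  probs <- c(cfg$transfection_rate, cfg$penetrance, cfg$control_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (length(cfg$effect_vector) != cfg$n_features) {
    stop("effect_vector length must equal n_features")
  }
  if (cfg$cells_per_well < 1) stop("cells_per_well must be >= 1")
  if (cfg$well_sigma < 0) stop("well_sigma must be >= 0")
  if (cfg$wells_per_plate > 16 * 20) {
    stop("at most 320 usable wells per plate (outer two columns unused)")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Row-major fill of the usable 16 x 20 interior of a 16 x 24 plate.
plate_layout <- function(wells_per_plate) {
  rows <- rep(LETTERS[1:16], each = 20)
  cols <- rep(3:22, times = 16)
  sprintf("%s%02d", rows, cols)[seq_len(wells_per_plate)]
}

#' Generate a synthetic screen
#'
#' Draws a full arrayed screen under [sim_config()] assumptions and returns
#' the single-cell table, plate map, and a per-cell truth table with the
#' latent perturbed status (which real screens never observe) for use in
#' recovery tests.
#'
#' Identical configurations yield byte-identical outputs. Each well uses a
#' deterministic random substream keyed by `(seed, plate_id, well_id)`, so
#' adding wells to a config leaves existing wells unchanged. The caller's
#' RNG state is untouched.
#'
#' @param cfg A [sim_config()].
#' @return A list with `cells` ([cell_table()]), `map` ([plate_map()]) and
#'   `truth` (data.frame: plate_id, well_id, cell_id, transfected,
#'   perturbed).
#' @export
generate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  feats <- sprintf("f%02d", seq_len(cfg$n_features))
  wells <- plate_layout(cfg$wells_per_plate)

  # deterministic striped control layout: every stride-th well is a
  # non-targeting control, spreading controls across any plate gradient
  n_ctrl <- round(cfg$control_fraction * cfg$wells_per_plate)
  is_ctrl <- rep(FALSE, cfg$wells_per_plate)
  if (n_ctrl > 0) {
    is_ctrl[round(seq(1, cfg$wells_per_plate, length.out = n_ctrl))] <- TRUE
  }

  map_rows <- list()
  cell_rows <- list()
  truth_rows <- list()
  for (p in seq_len(cfg$n_plates)) {
    plate <- sprintf("PL%02d", p)
    for (i in seq_along(wells)) {
      w <- wells[i]
      res <- withr::with_seed(
        well_seed(cfg$seed, plate, w),
        simulate_well(cfg, plate, w, i, feats, is_ctrl[i])
      )
      map_rows[[length(map_rows) + 1L]] <- res$map
      cell_rows[[length(cell_rows) + 1L]] <- res$cells
      truth_rows[[length(truth_rows) + 1L]] <- res$truth
    }
  }
  cells <- do.call(rbind, cell_rows)
  truth <- do.call(rbind, truth_rows)
  rownames(cells) <- rownames(truth) <- NULL
  list(
    cells = cell_table(cells, features = feats),
    map = plate_map(do.call(rbind, map_rows)),
    truth = truth
  )
}

simulate_well <- function(cfg, plate, w, well_index, feats, is_control) {
  coords <- well_coordinates(w)
  n <- max(1L, rpois(1, cfg$cells_per_well))
  transfected <- runif(n) < cfg$transfection_rate
  perturbed <- transfected & !is_control & (runif(n) < cfg$penetrance)

  x <- matrix(rnorm(n * cfg$n_features), n, cfg$n_features)
  offset <- rnorm(cfg$n_features, 0, cfg$well_sigma) +
    cfg$row_effect * (coords[1, "row"] - 1) +
    cfg$col_effect * (coords[1, "col"] - 1)
  x <- sweep(x, 2, offset, "+")
  if (any(perturbed)) {
    x[perturbed, ] <- sweep(x[perturbed, , drop = FALSE], 2,
                            cfg$effect_vector, "+")
  }
  colnames(x) <- feats

  cells <- data.frame(plate_id = plate, well_id = w, cell_id = seq_len(n),
                      transfected = transfected, x, check.names = FALSE)
  pid <- if (is_control) sprintf("CTRL_%s_%s", plate, w) else
    sprintf("PERT_%s_%s", plate, w)
  map <- data.frame(
    plate_id = plate, well_id = w,
    perturbation_id = pid,
    gene = if (is_control) "non-targeting" else sprintf("GENE%03d", well_index),
    guide_id = paste0(pid, "_g1"),
    is_control = is_control
  )
  truth <- data.frame(plate_id = plate, well_id = w, cell_id = seq_len(n),
                      transfected = transfected, perturbed = perturbed)
  list(cells = cells, map = map, truth = truth)
}

#' Generate a toy gene-model / guide-candidate fixture
#'
#' Emits a small set of genes, each with 2-6 transcripts built from a shared
#' pool of exon regions, plus candidate guides with on-target scores on a
#' fixed 0.05 grid. By construction every gene has internal exon regions,
#' and candidates span scores strictly below and at/above any threshold in
#' (0, 1), so selection-rule boundaries are exercised.
#'
#' @param seed Integer seed.
#' @param n_genes Number of toy genes.
#' @return A list with `gene_models` (data.frame: gene, transcript_id,
#'   exon_rank, exon_region_id) and `candidates` (data.frame: guide_id,
#'   gene, exon_region_id, on_target_score).
#' @export
generate_guide_fixture <- function(seed = 1, n_genes = 4) {
  withr::with_seed(as.integer(seed), {
    gm <- list()
    cand <- list()
    for (g in seq_len(n_genes)) {
      gene <- sprintf("G%02d", g)
      n_regions <- sample(5:8, 1)
      regions <- sprintf("%s_E%02d", gene, seq_len(n_regions))
      n_tx <- sample(2:6, 1)
      covered <- character(0)
      for (t in seq_len(n_tx)) {
        # contiguous exon run keeps 5'->3' order; length >= 2 guarantees
        # distinct first/last exons
        len <- sample(2:n_regions, 1)
        start <- sample(seq_len(n_regions - len + 1), 1)
        idx <- start:(start + len - 1)
        covered <- union(covered, regions[idx])
        gm[[length(gm) + 1L]] <- data.frame(
          gene = gene, transcript_id = sprintf("%s_T%d", gene, t),
          exon_rank = seq_along(idx), exon_region_id = regions[idx]
        )
      }
      # candidates only in regions some transcript actually contains
      covered <- regions[regions %in% covered]
      scores <- seq(0.05, 0.95, by = 0.05)
      for (r in covered) {
        k <- sample(1:3, 1)
        cand[[length(cand) + 1L]] <- data.frame(
          guide_id = sprintf("%s_gd%d", r, seq_len(k)),
          gene = gene, exon_region_id = r,
          on_target_score = sample(scores, k, replace = TRUE)
        )
      }
      # force score-boundary coverage: one guide strictly below and one at
      # or above every threshold on the open unit interval
      cand[[length(cand) + 1L]] <- data.frame(
        guide_id = paste0(gene, "_lo"), gene = gene,
        exon_region_id = covered[1], on_target_score = 0.05
      )
      cand[[length(cand) + 1L]] <- data.frame(
        guide_id = paste0(gene, "_hi"), gene = gene,
        exon_region_id = covered[length(covered)], on_target_score = 0.95
      )
    }
    gm <- do.call(rbind, gm)
    cand <- do.call(rbind, cand)
    rownames(gm) <- rownames(cand) <- NULL
    list(gene_models = gm, candidates = cand)
  })
}
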