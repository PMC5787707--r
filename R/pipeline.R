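#' Pipeline configuration
#'
#' Collects every tunable of the analysis with defaults matching the
#' published screen: 50 (morphology) / 30 (marker staining) principal
#' components, 100 bootstraps of 500 + 500 cells with 10-fold CV, a
#' mean + 3 SD PV gate, a Q3 + 1.5 IQR within-well hit fence, a
#' Q3 + 3 IQR between-well fence, and a 300-T(+)-cell well QC minimum.
#'
#' @param ... Named overrides of the defaults below.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    pca_k = 30,
    n_boot = 100,
    n_per_class = 500,
    n_folds = 10,
    nlambda = 30,
    gate_multiplier = 3,
    hit_multiplier = 1.5,
    between_multiplier = 3,
    min_tpos = 300,
    min_tneg = 100,
    min_gated = 20,
    sd_epsilon = 1e-8,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(cfg, over)
  counts <- c("pca_k", "n_boot", "n_per_class", "n_folds", "min_gated")
  if (any(unlist(cfg[counts]) < 1)) stop("counts must be positive")
  mults <- c("gate_multiplier", "hit_multiplier", "between_multiplier")
  if (any(unlist(cfg[mults]) < 0)) stop("multipliers must be >= 0")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [pipeline_config()] fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

write_manifest <- function(out_dir, config, stage) {
  manifest <- list(
    stage = stage,
    config = unclass(config),
    package_version = as.character(packageVersion("hetscore")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the within-well analysis end to end
#'
#' QC -> in-well standardization -> pooled PCA -> per-well bootstrapped
#' classification -> PV gate -> hit calling + KS phenotypic scores ->
#' gated-cell profiles. All randomness derives from `config$seed` through
#' per-well substreams, so reruns reproduce every table exactly.
#'
#' @param cells A [cell_table()].
#' @param map A [plate_map()].
#' @param config A [pipeline_config()].
#' @param feature_names Feature subset to analyse; default all.
#' @param out_dir Optional directory; when given, writes screen_result.csv,
#'   pv.csv, gated_cells.csv, profiles.csv, exclusions.csv and
#'   manifest.json.
#' @return A list: `screen`, `gate`, `hit_threshold`, `gated`, `profiles`,
#'   `exclusions`, `pv`, `classification`.
#' @export
run_within_well <- function(cells, map, config = pipeline_config(),
                            feature_names = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  val <- validate_screen(cells, map)
  if (!val$has_control) stop("pipeline requires >= 1 control well")

  qc <- qc_wells(cells, min_tpos = config$min_tpos,
                 min_tneg = config$min_tneg)
  if (!nrow(qc$cells)) stop("no wells survive QC")
  std <- standardize_within_well(qc$cells, feature_names = feature_names,
                                 sd_epsilon = config$sd_epsilon)
  cls <- classify_screen(
    std, pca_k = min(config$pca_k, length(features(std))),
    n_boot = config$n_boot, n_per_class = config$n_per_class,
    n_folds = config$n_folds, seed = config$seed, nlambda = config$nlambda
  )
  sc <- score_screen(cls, map, gate_multiplier = config$gate_multiplier,
                     hit_multiplier = config$hit_multiplier)
  prof <- perturbation_profiles(std, sc$gated, map,
                                min_gated = config$min_gated)
  out <- list(screen = sc$screen, gate = sc$gate,
              hit_threshold = sc$hit_threshold, gated = sc$gated,
              profiles = prof$profiles, withheld_profiles = prof$withheld,
              exclusions = qc$exclusions, pv = cls$pv, classification = cls)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(out$screen, file.path(out_dir, "screen_result.csv"))
    data.table::fwrite(out$pv, file.path(out_dir, "pv.csv"))
    data.table::fwrite(out$gated, file.path(out_dir, "gated_cells.csv"))
    if (nrow(out$profiles)) {
      data.table::fwrite(out$profiles, file.path(out_dir, "profiles.csv"))
    }
    data.table::fwrite(out$exclusions, file.path(out_dir, "exclusions.csv"))
    write_manifest(out_dir, config, "within_well")
  }
  out
}

#' Run the between-well analysis end to end
#'
#' QC -> per-well mean feature profiles of the T(+) and T(-) populations ->
#' B-score plate correction -> Mahalanobis distance of each profile from
#' the distribution of all profiles -> Q3 + 3 IQR control fence.
#'
#' @inheritParams run_within_well
#' @return A list: `distances`, `threshold`, `lambda`, `profiles`
#'   (B-scored), `exclusions`.
#' @export
run_between_well <- function(cells, map, config = pipeline_config(),
                             feature_names = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  qc <- qc_wells(cells, min_tpos = config$min_tpos,
                 min_tneg = config$min_tneg)
  if (!nrow(qc$cells)) stop("no wells survive QC")
  prof <- well_mean_profiles(qc$cells, feature_names = feature_names)
  bs <- bscore(prof)
  mh <- mahalanobis_profiles(bs, map, multiplier = config$between_multiplier)
  out <- list(distances = mh$distances, threshold = mh$threshold,
              lambda = mh$lambda, profiles = bs, exclusions = qc$exclusions)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(out$distances, file.path(out_dir, "distances.csv"))
    data.table::fwrite(out$profiles, file.path(out_dir,
                                               "well_profiles_bscore.csv"))
    write_manifest(out_dir, config, "between_well")
  }
  out
}
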