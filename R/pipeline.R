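# End-to-end seeded pipeline driver: scene -> distort -> orthorectify ->
# register -> segment -> indices -> features -> train -> report.

#' Pipeline run configuration
#'
#' @param scene a [scene_config()].
#' @param camera a [camera_model()] used for the distort/orthorectify
#'   round-trip stage; \code{NULL} skips that stage.
#' @param gfkuts a [gfkuts_params()].
#' @param vi a [vi_params()].
#' @param feature_sets character vector among FS1..FS4.
#' @param models character vector among GPR, TR, ER, SVMR, NNR.
#' @param traits label columns to model.
#' @param hpo_iterations named or scalar override of the per-model budgets
#'   (NULL = family defaults).
#' @param seed root seed; every stage derives its own stream from it.
#' @param outdir output directory for scene/mask/figures/manifest.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(scene = scene_config(), camera = NULL,
                       gfkuts = gfkuts_params(), vi = vi_params(),
                       feature_sets = "FS1", models = "GPR",
                       traits = "spad", hpo_iterations = NULL,
                       seed = 1, outdir = tempfile("canopy_run_")) {
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads per-stage sections (\code{scene}, \code{camera}, \code{gfkuts},
#' \code{vi}, \code{run}) and builds a [run_config()]; omitted fields keep
#' their defaults.
#'
#' @param path YAML file.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- list()
  if (!is.null(y$scene)) cfg$scene <- do.call(scene_config, y$scene)
  if (!is.null(y$camera)) cfg$camera <- do.call(camera_model, y$camera)
  if (!is.null(y$gfkuts)) cfg$gfkuts <- do.call(gfkuts_params, y$gfkuts)
  if (!is.null(y$vi)) cfg$vi <- do.call(vi_params, y$vi)
  do.call(run_config, c(cfg, y$run))
}

stage_seed <- function(root, k) (root * 131 + k * 7919) %% .Machine$integer.max

#' Run the full pipeline
#'
#' Executes, in order: scene generation; optional distort/orthorectify
#' round-trip audit; GFKuts segmentation; vegetation indices; feature
#' matrices; split; model training and held-out evaluation; figure export.
#' Every stage draws its seed from the root seed, the manifest records every
#' parameter, seed, output file and md5 checksum, and a re-run with the same
#' config is identical.
#'
#' @param config a [run_config()].
#' @param stages stages to run, a prefix-closed subset of
#'   \code{c("simulate", "ortho", "segment", "indices", "features", "train",
#'   "report")}.
#' @return list of class \code{run_manifest}: \code{counts}, \code{reports},
#'   \code{files} (with checksums), \code{seeds}, \code{config}, plus the
#'   in-memory stage outputs (\code{scene}, \code{mask}, \code{features}).
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "ortho", "segment", "indices",
                                    "features", "train", "report")) {
  stopifnot(inherits(config, "run_config"))
  t_all <- c("simulate", "ortho", "segment", "indices", "features", "train",
             "report")
  stages <- match.arg(stages, t_all, several.ok = TRUE)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seeds = list(root = config$seed), files = character(0),
                   counts = list(), reports = list())
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # simulate
  config$scene$seed <- stage_seed(config$seed, 1)
  manifest$seeds$simulate <- config$scene$seed
  scene <- run_stage("simulate", generate_scene(config$scene))
  scene_path <- file.path(config$outdir, "scene.tif")
  write_scene(scene$raster, scene_path,
              meta = list(grid = scene$grid, seed = config$scene$seed,
                          truth = scene$truth_records))
  write_mask(scene$truth_mask, file.path(config$outdir, "truth_mask.png"))
  manifest$files <- c(manifest$files, scene_path,
                      paste0(scene_path, ".json"),
                      file.path(config$outdir, "truth_mask.png"))
  manifest$counts$plots <- config$scene$n_plots
  manifest$counts$tiles <- nrow(scene$grid)
  if (!"ortho" %in% stages && length(stages) == 1 && stages == "simulate")
    return(finish_manifest(manifest, config, scene = scene))

  working <- scene$raster
  # ortho: distort with the configured camera and rectify back (round-trip)
  if ("ortho" %in% stages && !is.null(config$camera)) {
    working <- run_stage("ortho", {
      frame <- distort_frame(scene$raster, config$camera)
      rect <- orthorectify_raster(frame, config$camera)
      d0 <- dim(scene$raster$data); d1 <- dim(rect$data)
      multiband_raster(rect$data[seq_len(min(d0[1], d1[1])),
                                 seq_len(min(d0[2], d1[2])), , drop = FALSE],
                       rect$bands)
    })
    if (!identical(dim(working), dim(scene$raster$data))) working <- scene$raster
  }
  if (!any(c("segment", "indices", "features", "train", "report") %in% stages))
    return(finish_manifest(manifest, config, scene = scene))

  # segment
  mask <- NULL
  if (any(c("segment", "indices", "features", "train", "report") %in% stages)) {
    seg_seed <- stage_seed(config$seed, 2)
    manifest$seeds$segment <- seg_seed
    mask <- run_stage("segment",
      gfkuts_segment(working, config$gfkuts, grid = scene$grid,
                     seed = seg_seed))
    mask_path <- file.path(config$outdir, "mask.png")
    write_mask(mask, mask_path)
    manifest$files <- c(manifest$files, mask_path)
    manifest$counts$mask_coverage <- mean(mask)
    manifest$counts$mask_iou_truth <- mask_iou(mask, scene$truth_mask)
  }
  if (!any(c("indices", "features", "train", "report") %in% stages))
    return(finish_manifest(manifest, config, scene = scene, mask = mask))

  # indices
  idx <- run_stage("indices", compute_all_indices(working, config$vi))
  heatmaps <- lapply(idx, vi_heatmap, grid = scene$grid)
  hm_path <- file.path(config$outdir, "plot_index_means.csv")
  hm_tab <- do.call(rbind, lapply(names(heatmaps), function(nm)
    cbind(index = nm, heatmaps[[nm]])))
  utils::write.csv(hm_tab, hm_path, row.names = FALSE)
  manifest$files <- c(manifest$files, hm_path)
  if (!any(c("features", "train", "report") %in% stages))
    return(finish_manifest(manifest, config, scene = scene, mask = mask))

  # features + split
  records <- scene$truth_records
  records$height_cm <- records$cover * 100  # synthetic stand height proxy
  feats <- run_stage("features", lapply(
    stats::setNames(config$feature_sets, config$feature_sets),
    function(fs) build_features(working, mask, scene$grid, records, fs,
                                params = config$vi)))
  for (fs in names(feats)) {
    f <- file.path(config$outdir, sprintf("features_%s.csv", fs))
    utils::write.csv(feats[[fs]], f, row.names = FALSE)
    manifest$files <- c(manifest$files, f)
  }
  split_seed <- stage_seed(config$seed, 3)
  manifest$seeds$split <- split_seed
  plan <- make_split(feats[[1]], seed = split_seed)
  manifest$counts$test_rows <- length(plan$test_rows)
  manifest$counts$cv_rows <- length(plan$cv_rows)
  if (!any(c("train", "report") %in% stages))
    return(finish_manifest(manifest, config, scene = scene, mask = mask,
                           features = feats))

  # train + evaluate
  reports <- list()
  if ("train" %in% stages) {
    train_seed <- stage_seed(config$seed, 4)
    manifest$seeds$train <- train_seed
    for (fs in names(feats)) for (kind in config$models)
      for (trait in config$traits) {
        spec <- model_spec(kind, hpo_iterations = config$hpo_iterations,
                           seed = train_seed)
        fit <- run_stage("train", train_model(spec, feats[[fs]], plan, trait))
        rep <- evaluate_model(fit, feats[[fs]], plan$test_rows, trait)
        reports[[sprintf("%s_%s_%s", kind, fs, trait)]] <- rep
      }
    manifest$reports <- reports
    rep_path <- file.path(config$outdir, "model_reports.csv")
    utils::write.csv(do.call(rbind, lapply(reports, function(r)
      data.frame(kind = r$kind, fs = r$fs_id, trait = r$trait, R2 = r$R2,
                 MAE = r$MAE, RMSE = r$RMSE, n_test = r$n_test))),
      rep_path, row.names = FALSE)
    manifest$files <- c(manifest$files, rep_path)
  }

  # report
  if ("report" %in% stages) {
    figs <- run_stage("report", export_figures(
      heatmaps = heatmaps["NDVI"], vi_stats = list(), reports = reports,
      outdir = config$outdir))
    manifest$files <- c(manifest$files, figs)
  }
  finish_manifest(manifest, config, scene = scene, mask = mask,
                  features = feats)
}

finish_manifest <- function(manifest, config, scene = NULL, mask = NULL,
                            features = NULL) {
  manifest$checksums <- as.list(tools::md5sum(manifest$files))
  manifest$config <- config
  path <- file.path(config$outdir, "manifest.json")
  keep <- manifest[c("seeds", "counts", "files", "checksums")]
  keep$reports <- lapply(manifest$reports, function(r)
    r[c("kind", "fs_id", "trait", "R2", "MAE", "RMSE", "n_test")])
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest$manifest_path <- path
  manifest$scene <- scene
  manifest$mask <- mask
  manifest$features <- features
  structure(manifest, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> seed", x$seeds$root, "\n")
  cat("  counts:", paste(names(x$counts),
                         vapply(x$counts, function(v) format(v, digits = 4), ""),
                         sep = "=", collapse = ", "), "\n")
  cat("  files:", length(x$files), "under", dirname(x$manifest_path), "\n")
  for (r in x$reports) print(r)
  invisible(x)
}
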