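# Pipeline orchestration: simulate -> train-seg -> segment -> featurize ->
# classify -> report, as one configured, logged, seeded run.  Each stage
# reads its predecessor's on-disk artifacts, so any stage can be resumed.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    phantom = list(),            # phantom_spec() overrides
    train = list(),              # train_config() overrides
    hog = list(),                # hog_config() overrides
    lbp = list(),                # lbp_config() overrides
    classifiers = default_classifier_bank(),
    k_folds = 10L,
    featurize_source = "predicted",  # or "truth"
    include_geometric = TRUE,
    crop_size = 64L,
    min_area = 9L,
    log_level = "info"
  )
}

#' Validate and complete a pipeline configuration
#'
#' Accepts a JSON config file path or a plain list; unknown keys are
#' rejected, missing keys are filled with documented defaults, and nested
#' sections are validated by their own constructors
#' ([phantom_spec()], [train_config()], [hog_config()], [lbp_config()]).
#'
#' @param config path to a JSON file, or a named list.
#' @return Object of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: '%s'", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stopf("config must be a list or a JSON file path")
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s): %s (valid: %s)",
          paste(unknown, collapse = ", "),
          paste(names(defaults), collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  check_number(cfg$seed, "seed", integer = TRUE)
  check_number(cfg$k_folds, "k_folds", min = 2, integer = TRUE)
  if (!cfg$featurize_source %in% c("predicted", "truth"))
    stopf("field 'featurize_source' must be 'predicted' or 'truth'")
  # cross-validate the nested sections by constructing them
  cfg$phantom <- do.call(phantom_spec,
                         utils::modifyList(list(seed = cfg$seed),
                                           as.list(cfg$phantom)))
  cfg$train <- do.call(train_config,
                       utils::modifyList(list(seed = derive_seed(cfg$seed, 2L)),
                                         as.list(cfg$train)))
  cfg$hog <- do.call(hog_config, as.list(cfg$hog))
  cfg$lbp <- do.call(lbp_config, as.list(cfg$lbp))
  presets <- names(classifier_presets())
  bad <- setdiff(cfg$classifiers, presets)
  if (length(bad))
    stopf("unknown classifier(s) in config: %s", paste(bad, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

plog <- function(cfg, level, fmt, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] < levels[[cfg$log_level %||% "info"]]) return(invisible())
  msg <- sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                 sprintf(fmt, ...))
  message(msg)
  lf <- attr(cfg, "log_file")
  if (!is.null(lf)) cat(msg, "\n", file = lf, append = TRUE)
  invisible()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_manifest <- function(run_dir) {
  path <- file.path(run_dir, "data", "manifest.csv")
  if (!file.exists(path)) stopf("manifest not found at '%s'; run the simulate stage first", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

load_labeled_slices <- function(run_dir, image_size) {
  manifest <- read_manifest(run_dir)
  ids <- unique(manifest$slice_id)
  lapply(ids, function(sid) {
    img <- load_slice(file.path(run_dir, "data", paste0(sid, ".png")),
                      target_size = image_size)$image
    msk <- load_mask(file.path(run_dir, "data", paste0(sid, "_mask.png")),
                     expected_dim = dim(img)[1:2])
    structure(list(image = img, mask = msk,
                   nodules = manifest[manifest$slice_id == sid, ],
                   slice_id = sid),
              class = "labeled_slice")
  })
}

stage_simulate <- function(cfg, run_dir) {
  plog(cfg, "info", "simulate: %d slice(s) at %dx%d",
       cfg$phantom$n_slices, cfg$phantom$image_size, cfg$phantom$image_size)
  generate_dataset(cfg$phantom, file.path(run_dir, "data"))
}

stage_train_seg <- function(cfg, run_dir) {
  slices <- load_labeled_slices(run_dir, cfg$phantom$image_size)
  plog(cfg, "info", "train-seg: %d slice(s), %d epoch(s)", length(slices),
       cfg$train$epochs)
  net <- build_network(seg_net_config(c(rep(cfg$phantom$image_size, 2), 3L)),
                       seed = cfg$train$seed)
  fit <- train_segnet(net, slices, cfg$train)
  dir.create(file.path(run_dir, "model"), recursive = TRUE, showWarnings = FALSE)
  save_network(fit$network, file.path(run_dir, "model", "segnet.ckpt"))
  utils::write.csv(fit$history, file.path(run_dir, "model", "history.csv"),
                   row.names = FALSE)
  if (!is.null(fit$metrics))
    jsonlite::write_json(fit$metrics[c("global_accuracy", "mean_accuracy",
                                       "mean_iou", "weighted_iou",
                                       "mean_bf_score")],
                         file.path(run_dir, "model", "heldout_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

stage_segment <- function(cfg, run_dir) {
  ckpt <- file.path(run_dir, "model", "segnet.ckpt")
  if (!file.exists(ckpt))
    stopf("model checkpoint not found at '%s'; run the train-seg stage first", ckpt)
  net <- load_network(ckpt)
  manifest <- read_manifest(run_dir)
  ids <- unique(manifest$slice_id)
  out <- file.path(run_dir, "masks_pred")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  plog(cfg, "info", "segment: predicting %d mask(s)", length(ids))
  for (sid in ids) {
    img <- load_slice(file.path(run_dir, "data", paste0(sid, ".png")),
                      target_size = cfg$phantom$image_size)$image
    pm <- predict_mask(net, img)
    write_mask_png(pm, file.path(out, paste0(sid, "_pred.png")))
  }
  invisible(ids)
}

# assign each extracted region the manifest nodule whose recorded centroid
# is nearest to the region centroid (must fall within the region's
# bounding-box diagonal); unmatched regions are dropped with a log line
stage_featurize <- function(cfg, run_dir) {
  manifest <- read_manifest(run_dir)
  ids <- unique(manifest$slice_id)
  use_pred <- cfg$featurize_source == "predicted"
  if (use_pred && !dir.exists(file.path(run_dir, "masks_pred")))
    stopf("predicted masks not found under '%s'; run the segment stage first",
          file.path(run_dir, "masks_pred"))
  rows <- list(); feats <- list()
  for (sid in ids) {
    img <- load_slice(file.path(run_dir, "data", paste0(sid, ".png")),
                      target_size = cfg$phantom$image_size)$image
    mask_path <- if (use_pred)
      file.path(run_dir, "masks_pred", paste0(sid, "_pred.png"))
    else file.path(run_dir, "data", paste0(sid, "_mask.png"))
    msk <- load_mask(mask_path, expected_dim = dim(img)[1:2])
    regions <- extract_nodule_regions(img, msk, min_area = cfg$min_area,
                                      crop_size = cfg$crop_size)
    nods <- manifest[manifest$slice_id == sid, ]
    for (rg in regions) {
      d <- sqrt((nods$centroid_row - rg$centroid[1])^2 +
                  (nods$centroid_col - rg$centroid[2])^2)
      if (length(d) == 0) next
      j <- which.min(d)
      diag_len <- sqrt(sum((rg$bounding_box[3:4] - rg$bounding_box[1:2])^2))
      if (d[j] > max(diag_len, 10)) {
        plog(cfg, "debug", "featurize: dropped unmatched region in %s", sid)
        next
      }
      fv <- featurize_region(rg, cfg$hog, cfg$lbp,
                             include_geometric = cfg$include_geometric)
      nid <- paste0(sid, "_n", nods$nodule_id[j])
      rows[[length(rows) + 1L]] <- data.frame(nodule_id = nid,
                                              label = nods$class[j])
      feats[[length(feats) + 1L]] <- fv$fused
    }
  }
  if (!length(rows)) stopf("featurize produced no labeled regions")
  fm <- do.call(rbind, lapply(feats, rbind))
  colnames(fm) <- paste0("f_", seq_len(ncol(fm)) - 1L)
  df <- cbind(do.call(rbind, rows), as.data.frame(fm))
  utils::write.csv(df, file.path(run_dir, "features.csv"), row.names = FALSE)
  fv1 <- featurize_region(list(crop = matrix(0, cfg$crop_size, cfg$crop_size),
                               crop_mask = {
                                 m <- matrix(0L, cfg$crop_size, cfg$crop_size)
                                 m[2:4, 2:4] <- 1L; m
                               }),
                          cfg$hog, cfg$lbp,
                          include_geometric = cfg$include_geometric)
  schema <- list(hog_length = length(fv1$hog),
                 lbp_length = length(fv1$lbp_hist),
                 geometric_length = length(fv1$geometric),
                 order = c("hog", "lbp", "geometric"),
                 hog = unclass(cfg$hog), lbp = unclass(cfg$lbp))
  jsonlite::write_json(schema, file.path(run_dir, "features_schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  plog(cfg, "info", "featurize: %d nodule(s) x %d feature(s)", nrow(df),
       ncol(fm))
  invisible(df)
}

stage_classify <- function(cfg, run_dir) {
  fpath <- file.path(run_dir, "features.csv")
  if (!file.exists(fpath))
    stopf("features not found at '%s'; run the featurize stage first", fpath)
  df <- utils::read.csv(fpath, stringsAsFactors = FALSE)
  X <- as.matrix(df[, grep("^f_", names(df)), drop = FALSE])
  plog(cfg, "info", "classify: %d sample(s), %d classifier(s), %d folds",
       nrow(X), length(cfg$classifiers), cfg$k_folds)
  report <- cross_validate(X, df$label, specs = cfg$classifiers,
                           k_folds = cfg$k_folds,
                           seed = derive_seed(cfg$seed, 5L))
  rank_and_report(report, file.path(run_dir, "report"))
  invisible(report)
}

#' Run the full pipeline
#'
#' Executes the requested stages in order inside `out_dir`, writing each
#' stage's artifacts plus a `run.json` capturing the configuration, seed and
#' package version.  A failing stage aborts with the stage named; partial
#' outputs are retained so the run can be resumed with a subset of stages.
#'
#' @param config a [validate_config()] result, config list, or JSON path.
#' @param out_dir run directory (created if needed).
#' @param stages subset of
#'   `c("simulate", "train-seg", "segment", "featurize", "classify")`.
#' @return Invisibly, the run directory.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "train-seg", "segment",
                                    "featurize", "classify")) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  all_stages <- c("simulate", "train-seg", "segment", "featurize", "classify")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- all_stages[all_stages %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create run directory '%s'", out_dir)
  attr(cfg, "log_file") <- file.path(out_dir, "run.log")

  # fail fast on missing prerequisites before any compute
  if (!"simulate" %in% stages && any(stages %in% c("train-seg", "segment", "featurize")))
    read_manifest(out_dir)
  if (!"segment" %in% stages && "featurize" %in% stages &&
      cfg$featurize_source == "predicted" &&
      !dir.exists(file.path(out_dir, "masks_pred")))
    stopf("featurize (source = 'predicted') requires the masks_pred directory; run the segment stage first")

  cfg_plain <- unclass(cfg)
  cfg_plain$phantom <- unclass(cfg_plain$phantom)
  cfg_plain$train <- unclass(cfg_plain$train)
  cfg_plain$hog <- unclass(cfg_plain$hog)
  cfg_plain$lbp <- unclass(cfg_plain$lbp)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg_plain, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  run_info <- list(
    package = "focalseg",
    version = as.character(utils::packageVersion("focalseg")),
    seed = cfg$seed,
    stage_seeds = list(train = cfg$train$seed,
                       classify = derive_seed(cfg$seed, 5L)),
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages = stages,
    started = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
  jsonlite::write_json(run_info, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  runners <- list("simulate" = stage_simulate, "train-seg" = stage_train_seg,
                  "segment" = stage_segment, "featurize" = stage_featurize,
                  "classify" = stage_classify)
  for (st in stages) {
    plog(cfg, "info", "stage '%s' starting", st)
    ok <- tryCatch({ runners[[st]](cfg, out_dir); TRUE },
                   error = function(e) {
                     plog(cfg, "error", "stage '%s' failed: %s", st,
                          conditionMessage(e))
                     stopf("pipeline aborted at stage '%s': %s", st,
                           conditionMessage(e))
                   })
  }
  plog(cfg, "info", "pipeline complete: %s", out_dir)
  invisible(out_dir)
}
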