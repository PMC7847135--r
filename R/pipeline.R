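#' Pipeline configuration
#'
#' Builds and validates the configuration for [run_pipeline()]. `images` and
#' `rois` name directories of PNG/TIFF images and matching ROI JSON files
#' (same basename); `labels` a CSV with specimen_id and group columns.
#'
#' @param images,rois input directories.
#' @param labels labels CSV path.
#' @param out output directory.
#' @param ref_width canonical abdomen width (pixels).
#' @param segmentation [segmentation_params()].
#' @param central_band central-spot band as a fraction of body width.
#' @param expected_spots QC: expected spot count per specimen (NA disables
#'   the check).
#' @param f_enter,f_remove stepwise LDA thresholds.
#' @param hidden_grid MLP topology grid; a single value skips the search.
#' @param train_frac training fraction for the network split.
#' @param seed master seed (split, network init, importance).
#' @param importance_reps permutations per variable for the importance
#'   report.
#' @param low_q,high_q level-stretch quantiles.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(images, rois = images, labels, out,
                            ref_width = 400,
                            segmentation = segmentation_params(),
                            central_band = 0.15,
                            expected_spots = 14L,
                            f_enter = 4.0, f_remove = 3.9,
                            hidden_grid = 20L,
                            train_frac = 0.6,
                            seed = 1L,
                            importance_reps = 50L,
                            low_q = 0.25, high_q = 0.75) {
  cfg <- as.list(environment())
  stopifnot(ref_width > 0, central_band > 0, central_band < 0.5,
            inherits(segmentation, "segmentation_params"))
  structure(cfg, class = "pipeline_config")
}

#' Run the full spot-pattern pipeline
#'
#' Executes standardize, segment, features, heatmap, stats and classify in
#' order, persisting each stage's artifacts under `config$out` and a run
#' manifest (versions, seeds, parameters, per-stage QC counts). Specimens
#' that fail a stage (missing ROI, no spots, ambiguous central spots, QC
#' spot-count deviation) are excluded and listed in the QC report; the
#' pipeline completes on the rest.
#'
#' @param config a [pipeline_config()].
#' @param resume skip stages whose outputs already exist.
#' @return invisibly, a list with the feature table, stats, LDA and MLP
#'   results, importance report and the manifest.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (d in c("standardized", "masks", "features", "heatmaps", "stats",
              "classify"))
    dir.create(file.path(out, d), showWarnings = FALSE)
  labels <- utils::read.csv(config$labels, stringsAsFactors = FALSE)
  qc <- list(excluded = list())
  manifest <- list(package_version = as.character(utils::packageVersion("spotmorph")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = config$seed,
                   parameters = config[setdiff(names(config), "segmentation")],
                   segmentation = unclass(config$segmentation))

  img_files <- list.files(config$images, pattern = "\\.(png|tif|tiff)$",
                          ignore.case = TRUE, full.names = TRUE)
  specimens <- list()
  masks <- list()
  groups <- character(0)
  feat_csv <- file.path(out, "features", "features.csv")
  if (resume && file.exists(feat_csv)) {
    message("resume: reusing ", feat_csv, " and skipping the image stages")
    img_files <- character(0)
  }

  for (f in img_files) {
    id <- tools::file_path_sans_ext(basename(f))
    grp <- labels$group[match(id, labels$specimen_id)]
    if (is.na(grp)) next
    roi_path <- file.path(config$rois, paste0(id, ".json"))
    warnings_seen <- character(0)
    res <- tryCatch(withCallingHandlers({
      if (!file.exists(roi_path)) stop("missing ROI annotation")
      gray <- desaturate(read_image(f))
      gray <- stretch_levels(gray, config$low_q, config$high_q)
      std <- standardize_geometry(gray, read_roi(roi_path), config$ref_width)
      thr <- if (config$segmentation$threshold_method == "fixed")
        config$segmentation$fixed_threshold
      else minimum_auto_threshold(std$pixels, std$roi_mask)
      m <- binarize_spots(std$pixels, thr, std$roi_mask)
      m <- clean_mask(m, config$segmentation$outlier_radius,
                      config$segmentation$outlier_threshold)
      m <- fill_holes(m)
      spots <- label_spots(m, config$segmentation)
      if (!is.na(config$expected_spots) &&
          nrow(spots$components) != config$expected_spots)
        stop("QC: found ", nrow(spots$components), " spots, expected ",
             config$expected_spots)
      recs <- measure_spots(spots, std, config$central_band)
      list(id = id, group = grp, std = std, mask = m, spots = spots,
           records = recs, threshold = thr, warnings = warnings_seen)
    }, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    }), error = function(e) e)
    if (inherits(res, "condition")) {
      qc$excluded[[id]] <- conditionMessage(res)
      next
    }
    write_image(res$std$pixels, file.path(out, "standardized",
                                          paste0(id, ".png")))
    jsonlite::write_json(res$std$transform,
                         file.path(out, "standardized", paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA)
    write_image(res$mask$grid * 255, file.path(out, "masks",
                                               paste0(id, ".png")))
    write_image(res$spots$labels, file.path(out, "masks",
                                            paste0(id, "_labels.png")),
                bits = 16L)
    specimens[[id]] <- list(specimen_id = id, group = res$group,
                            records = res$records, Ta = res$spots$Ta)
    masks[[id]] <- res$mask
    groups[id] <- res$group
  }
  if (length(specimens) > 0L) {
    per_spot <- do.call(rbind, lapply(specimens, function(s) {
      cbind(specimen_id = s$specimen_id, s$records)
    }))
    utils::write.csv(per_spot, file.path(out, "features", "spots.csv"),
                     row.names = FALSE)
    features <- build_feature_table(specimens)
    utils::write.csv(features, feat_csv, row.names = FALSE)
    jsonlite::write_json(as.list(attr(features, "units")),
                         file.path(out, "features", "units.json"),
                         auto_unbox = TRUE)
    for (grp in unique(groups)) {
      hm <- accumulate_heatmap(masks[groups == grp], group = grp)
      utils::write.csv(hm$grid, file.path(out, "heatmaps",
                                          paste0(grp, ".csv")),
                       row.names = FALSE)
      render_heatmap(hm, file.path(out, "heatmaps", paste0(grp, ".png")))
    }
  } else if (resume && file.exists(feat_csv)) {
    features <- utils::read.csv(feat_csv, stringsAsFactors = FALSE)
  } else {
    stop("no specimen survived the pipeline")
  }

  st <- compare_groups(features)
  utils::write.csv(st$descriptives,
                   file.path(out, "stats", "descriptives.csv"),
                   row.names = FALSE)
  utils::write.csv(st$tests, file.path(out, "stats", "kruskal_wallis.csv"),
                   row.names = FALSE)

  lda_fit <- stepwise_lda(features, features$group,
                          f_enter = config$f_enter, f_remove = config$f_remove)
  utils::write.csv(lda_fit$step_trace,
                   file.path(out, "classify", "lda_steps.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(lda_fit$confusion_resub),
                   file.path(out, "classify", "lda_confusion.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(specimen_id = features$specimen_id,
                              group = features$group, lda_fit$scores),
                   file.path(out, "classify", "lda_scores.csv"),
                   row.names = FALSE)

  forced <- features$specimen_id[lda_fit$misclassified_resub]
  split <- make_split(features$group, ids = seq_len(nrow(features)),
                      train_frac = config$train_frac,
                      forced_validation_ids = match(forced,
                                                    features$specimen_id),
                      seed = config$seed)
  if (length(config$hidden_grid) > 1L) {
    srch <- search_topology(features, features$group, split,
                            hidden_grid = config$hidden_grid,
                            seed = config$seed)
    mlp <- srch$best
    utils::write.csv(srch$leaderboard,
                     file.path(out, "classify", "mlp_leaderboard.csv"),
                     row.names = FALSE)
  } else {
    mlp <- train_mlp(features, features$group, split,
                     mlp_config(hidden_units = config$hidden_grid,
                                seed = config$seed))
  }
  utils::write.csv(as.data.frame(mlp$confusion_validation),
                   file.path(out, "classify", "mlp_confusion_validation.csv"),
                   row.names = FALSE)
  imp <- permutation_importance(mlp, features, features$group,
                                reps = config$importance_reps,
                                seed = config$seed)
  utils::write.csv(imp, file.path(out, "classify", "importance.csv"),
                   row.names = FALSE)

  manifest$qc <- list(n_input = length(img_files),
                      n_analyzed = length(specimens),
                      excluded = qc$excluded)
  manifest$results <- list(
    lda_accuracy_resub = lda_fit$accuracy_resub,
    lda_accuracy_loo = lda_fit$accuracy_loo,
    wilks_lambda = lda_fit$wilks_lambda,
    mlp_accuracy_train = mlp$accuracy_train,
    mlp_accuracy_validation = mlp$accuracy_validation)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(features = features, stats = st, lda = lda_fit, mlp = mlp,
                 importance = imp, manifest = manifest,
                 qc = manifest$qc))
}
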