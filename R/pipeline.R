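#' Write a volumetric phantom subject to disk
#'
#' Writes the intensity volume as NIfTI, the endpoint annotations as JSON,
#' and (optionally) the ground truth (dense polyline, radius profile, true
#' features) as a JSON sidecar.
#'
#' @param subj A [simulate_volumetric_subject()] result.
#' @param id Subject identifier used for file names.
#' @param volumes_dir,annotations_dir,truth_dir Output directories
#'   (created if needed; `truth_dir = NULL` skips truth output).
#' @return The subject id, invisibly.
#' @export
write_phantom_subject <- function(subj, id, volumes_dir, annotations_dir,
                                  truth_dir = NULL) {
  dir.create(volumes_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(annotations_dir, recursive = TRUE, showWarnings = FALSE)
  write_nifti(subj$volume, file.path(volumes_dir, paste0(id, ".nii.gz")))
  ann <- lapply(subj$segments, function(s)
    list(label = s$label, endpoint_a = as.integer(s$endpoints[1, ]),
         endpoint_b = as.integer(s$endpoints[2, ])))
  write_annotations(ann, file.path(annotations_dir, paste0(id, ".json")))
  if (!is.null(truth_dir)) {
    dir.create(truth_dir, recursive = TRUE, showWarnings = FALSE)
    truth <- lapply(subj$segments, function(s)
      list(label = s$label,
           polyline_mm = s$ground_truth$polyline,
           radii_mm = s$ground_truth$radius_profile,
           true_features = as.list(s$ground_truth$true_features)))
    jsonlite::write_json(list(age = subj$age, segments = unname(truth)),
                         file.path(truth_dir, paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(id)
}

.pipeline_defaults <- function() {
  list(threshold = NULL, threshold_percentile = 99, connectivity = 26,
       step = 0.5, df_frac = 0.5, qc_max_ratio = 1, qc_max_snap_mm = 5,
       pad_definition = "soam_over_rl",
       models = c("random_forest", "linear", "adaboost",
                  "gradient_boosting", "bayesian_ridge",
                  "xgb_style_boosting"),
       k = 4, seed = 1L, tune = FALSE, n_iter = 10, save_masks = FALSE)
}

.load_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- utils::modifyList(.pipeline_defaults(), config)
  for (f in c("volumes_dir", "annotations_dir", "ages_csv", "out_dir"))
    if (is.null(cfg[[f]])) vm_stop("pipeline config is missing '", f, "'")
  for (f in c("volumes_dir", "annotations_dir", "ages_csv"))
    if (!file.exists(cfg[[f]]))
      vm_stop("pipeline config path does not resolve: ", f, " = ", cfg[[f]])
  cfg
}

# centerline + features for every annotated segment of one subject;
# errors propagate to the caller, which turns them into exclusions
.process_subject <- function(id, vol_path, ann_path, age, cfg) {
  vol <- read_nifti(vol_path)
  ann <- read_annotations(ann_path)
  eps <- do.call(rbind, lapply(ann, function(a) rbind(a$endpoint_a,
                                                      a$endpoint_b)))
  sspec <- seed_spec(eps, threshold = cfg$threshold,
                     percentile = if (is.null(cfg$threshold))
                       cfg$threshold_percentile else NULL,
                     connectivity = cfg$connectivity)
  mask <- region_growing(vol, sspec)
  skel <- skeletonize(mask, anchors = eps)
  g <- build_skeleton_graph(skel)
  segments <- list()
  qc <- list()
  polys <- list()
  for (a in ann) {
    sa <- snap_endpoint(a$endpoint_a, g)
    sb <- snap_endpoint(a$endpoint_b, g)
    path <- shortest_centerline_path(g, sa$node, sb$node)
    poly <- smooth_resample(path, step = cfg$step, df_frac = cfg$df_frac)
    qc[[a$label]] <- path_qc(path, c(sa$distance_mm, sb$distance_mm),
                             max_ratio = cfg$qc_max_ratio,
                             max_snap_mm = cfg$qc_max_snap_mm)
    segments[[a$label]] <- segment_features(poly, mask, a$label,
                                            pad_definition = cfg$pad_definition)
    polys[[a$label]] <- unclass(poly)
  }
  list(record = subject_record(id, age, segments, qc = qc),
       polylines = polys, mask = mask)
}

#' Run the full pipeline on a directory cohort
#'
#' Orchestrates segmentation, skeletonization, per-segment Dijkstra paths,
#' smoothing, feature extraction, exclusion logic, table assembly and
#' cross-validated modeling. Inputs: a directory of NIfTI volumes named
#' `<subject_id>.nii[.gz]`, a directory of matching `<subject_id>.json`
#' endpoint annotations, and a CSV with columns `subject_id, age`.
#' Every intermediate is persisted under `out_dir`; `manifest.json` records
#' the configuration, seeds, package version and per-subject outcomes.
#' Subject-level data problems (unreadable annotations, failed paths)
#' become logged exclusions; infrastructural failures halt.
#'
#' @param config Named list or path to a JSON file. Required fields:
#'   `volumes_dir`, `annotations_dir`, `ages_csv`, `out_dir`. Optional:
#'   `threshold` or `threshold_percentile` (default percentile 99),
#'   `connectivity`, `step`, `df_frac`, `qc_max_ratio`, `qc_max_snap_mm`,
#'   `pad_definition`, `models`, `k`, `seed`, `tune`, `n_iter`,
#'   `save_masks`.
#' @return The output directory path, invisibly; see its `manifest.json`,
#'   `cohort.csv`, `metrics_*.csv`, `importances_*.csv` and `plots/`.
#' @export
run_pipeline <- function(config) {
  cfg <- .load_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  ages <- read.csv(cfg$ages_csv, check.names = FALSE)
  if (!all(c("subject_id", "age") %in% names(ages)))
    vm_stop("ages_csv must have columns subject_id, age")
  vols <- list.files(cfg$volumes_dir, pattern = "\\.nii(\\.gz)?$",
                     full.names = TRUE)
  ids <- sub("\\.nii(\\.gz)?$", "", basename(vols))
  records <- list()
  outcomes <- list()
  dir.create(file.path(cfg$out_dir, "centerlines"), showWarnings = FALSE)
  if (cfg$save_masks)
    dir.create(file.path(cfg$out_dir, "masks"), showWarnings = FALSE)
  for (i in seq_along(ids)) {
    id <- ids[i]
    age <- ages$age[match(id, ages$subject_id)]
    ann_path <- file.path(cfg$annotations_dir, paste0(id, ".json"))
    res <- tryCatch({
      if (is.na(age)) vm_stop("no age for subject ", id)
      if (!file.exists(ann_path)) vm_stop("no annotations for subject ", id)
      .process_subject(id, vols[i], ann_path, age, cfg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      records[[i]] <- subject_record(id, if (is.na(age)) 999 else age,
                                     segments = list(), quality_ok = TRUE)
      outcomes[[i]] <- list(subject_id = id, status = "failed",
                            message = conditionMessage(res))
      next
    }
    records[[i]] <- res$record
    outcomes[[i]] <- list(subject_id = id, status = "processed")
    write_polylines(res$polylines,
                    file.path(cfg$out_dir, "centerlines",
                              paste0(id, ".json")))
    if (cfg$save_masks)
      write_nifti(res$mask, file.path(cfg$out_dir, "masks",
                                      paste0(id, "_mask.nii.gz")))
  }
  excl <- apply_exclusions(records)
  write.csv(excl$log, file.path(cfg$out_dir, "exclusions.csv"),
            row.names = FALSE)
  tab <- assemble_table(excl$retained)
  write_feature_table(tab, file.path(cfg$out_dir, "cohort.csv"))
  cv <- NULL
  if (nrow(tab) >= cfg$k * 2) {
    specs <- setNames(lapply(cfg$models, model_spec), cfg$models)
    cv <- run_cv(tab, specs, k = cfg$k, seed = cfg$seed, tune = cfg$tune,
                 n_iter = cfg$n_iter)
    write.csv(cv$fold_metrics, file.path(cfg$out_dir, "metrics_folds.csv"),
              row.names = FALSE)
    write.csv(cv$aggregated, file.path(cfg$out_dir,
                                       "metrics_aggregated.csv"),
              row.names = FALSE)
    dir.create(file.path(cfg$out_dir, "plots"), showWarnings = FALSE)
    for (mn in names(cv$importances))
      write.csv(cv$importances[[mn]],
                file.path(cfg$out_dir, sprintf("importances_%s.csv", mn)),
                row.names = FALSE)
    for (mn in unique(cv$predictions$model)) {
      pv <- cv$predictions[cv$predictions$model == mn &
                             cv$predictions$set == "validation", ]
      scatter_plot(pv$age, pv$predicted,
                   file.path(cfg$out_dir, "plots",
                             sprintf("scatter_%s.pdf", mn)),
                   title = paste(mn, "(validation)"))
    }
  }
  manifest <- list(
    package = "vesselmorph",
    version = as.character(utils::packageVersion("vesselmorph")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "timestamp")],
    subjects = outcomes,
    n_retained = nrow(tab),
    exclusions = nrow(excl$log))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cfg$out_dir)
}

#' Generate and analyze a demonstration phantom cohort
#'
#' Simulates `n_subjects` volumetric phantom subjects with ages drawn
#' uniformly in 20-80 years (diameters increase with age by construction),
#' writes them to disk, runs the full pipeline, and prints the aggregated
#' metrics table (model x RMSE, R2, MAPE, r).
#'
#' @param seed Global seed.
#' @param n_subjects Number of subjects (default 12).
#' @param dir Working directory (default: fresh temporary directory).
#' @param grid Phantom [grid_spec()].
#' @param models Model families to evaluate.
#' @return The run output directory, invisibly.
#' @export
vm_demo <- function(seed = 1L, n_subjects = 12,
                    dir = tempfile("vmdemo"),
                    grid = grid_spec(c(64, 64, 48), c(0.5, 0.5, 0.5)),
                    models = c("random_forest", "linear", "adaboost",
                               "gradient_boosting", "bayesian_ridge",
                               "xgb_style_boosting")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ages <- withr::with_seed(as.integer(seed),
                           round(runif(n_subjects, 20, 80), 1))
  ids <- sprintf("P%03d", seq_len(n_subjects))
  for (i in seq_len(n_subjects)) {
    subj <- simulate_volumetric_subject(ages[i], grid = grid,
                                        seed = .child_seed(seed, i))
    write_phantom_subject(subj, ids[i], file.path(dir, "volumes"),
                          file.path(dir, "annotations"),
                          truth_dir = file.path(dir, "truth"))
  }
  write.csv(data.frame(subject_id = ids, age = ages),
            file.path(dir, "ages.csv"), row.names = FALSE)
  out <- run_pipeline(list(volumes_dir = file.path(dir, "volumes"),
                           annotations_dir = file.path(dir, "annotations"),
                           ages_csv = file.path(dir, "ages.csv"),
                           out_dir = file.path(dir, "run"),
                           threshold = 120, models = models,
                           seed = as.integer(seed)))
  met <- file.path(out, "metrics_aggregated.csv")
  if (file.exists(met)) {
    a <- read.csv(met)
    cat(sprintf("%-22s %-16s %-16s %-16s %-16s\n", "Model", "RMSE", "R2",
                "MAPE", "Pearson r"))
    for (i in seq_len(nrow(a)))
      cat(sprintf("%-22s %6.3f +/- %-6.3f %6.3f +/- %-6.3f %6.3f +/- %-6.3f %6.3f +/- %-6.3f\n",
                  a$model[i], a$rmse_mean[i], a$rmse_sd[i], a$r2_mean[i],
                  a$r2_sd[i], a$mape_mean[i], a$mape_sd[i], a$r_mean[i],
                  a$r_sd[i]))
  }
  invisible(out)
}
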