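# Plain-text and NIfTI export of pipeline artifacts.

#' Write a feature table and its labels as CSV
#'
#' @param table a [feature_table()].
#' @param features_path,labels_path output CSV paths.
#' @return invisibly, the feature path.
#' @export
write_feature_table <- function(table, features_path,
                                labels_path = NULL) {
  df <- as.data.frame(table)
  utils::write.csv(df, features_path, row.names = TRUE)
  if (!is.null(labels_path))
    utils::write.csv(attr(table, "labels"), labels_path, row.names = FALSE)
  invisible(features_path)
}

#' Read a feature table from CSV
#'
#' @param features_path CSV written by [write_feature_table()].
#' @param labels_path CSV with columns vessel_id, tcfa, mc, tcfa_mc.
#' @param range_kind `"LOI"` or `"Vessel"`.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(features_path, labels_path,
                               range_kind = c("LOI", "Vessel")) {
  df <- utils::read.csv(features_path, row.names = 1, check.names = FALSE)
  labs <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  labs$tcfa <- as.logical(labs$tcfa)
  labs$mc <- as.logical(labs$mc)
  labs$tcfa_mc <- as.logical(labs$tcfa_mc)
  feature_table(df, labs, match.arg(range_kind))
}

# JSON-serializable view of a selection trace / model result.
trace_as_list <- function(tr) {
  list(target = tr$target, range_kind = tr$range_kind,
       surviving_after_correlation = tr$surviving_after_correlation,
       univariate_auc = as.list(tr$univariate_auc),
       top105 = tr$top105, mrmr50 = tr$mrmr50,
       candidate10 = tr$candidate10, final_set = tr$final_set)
}

model_as_list <- function(md) {
  list(target = md$target, range_kind = md$range_kind,
       feature_set = md$feature_set, mean_auc = md$mean_auc,
       sd_auc = md$sd_auc, n_repeats = md$cv$n_repeats,
       per_repeat_auc = md$per_repeat_auc)
}

#' Write all pipeline artifacts to a directory
#'
#' Feature tables as CSV, selection traces and model results as JSON, mean
#' ROC curves as CSV, and a manifest JSON naming every file together with
#' the config hash and seeds.
#'
#' @param result a `pcat_pipeline_result` from [run_pipeline()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (rk in names(result$tables)) {
    fp <- file.path(out_dir, paste0("features_", rk, ".csv"))
    lp <- file.path(out_dir, paste0("labels.csv"))
    write_feature_table(result$tables[[rk]], fp, lp)
    files[[paste0("features_", rk)]] <- basename(fp)
  }
  for (key in names(result$traces)) {
    tp <- file.path(out_dir, paste0("trace_", key, ".json"))
    jsonlite::write_json(trace_as_list(result$traces[[key]]), tp,
                         auto_unbox = TRUE, digits = NA)
    files[[paste0("trace_", key)]] <- basename(tp)
  }
  for (key in names(result$models)) {
    mp <- file.path(out_dir, paste0("model_", key, ".json"))
    jsonlite::write_json(model_as_list(result$models[[key]]), mp,
                         auto_unbox = TRUE, digits = NA)
    rp <- file.path(out_dir, paste0("roc_", key, ".csv"))
    utils::write.csv(result$models[[key]]$mean_roc, rp, row.names = FALSE)
    files[[paste0("model_", key)]] <- basename(mp)
  }
  manifest <- c(result$manifest, list(files = files))
  mpth <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpth, auto_unbox = TRUE, digits = NA)
  invisible(mpth)
}

#' Write a phantom cohort to disk
#'
#' Volumes and wall masks as NIfTI (requires the RNifti package), labels as
#' CSV and a cohort manifest as JSON.
#'
#' @param cohort result of [generate_cohort()].
#' @param out_dir output directory.
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("writing NIfTI volumes requires the RNifti package")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$vessels)) {
    v <- cohort$vessels[[i]]$volume
    w <- cohort$vessels[[i]]$walls
    pix <- v$spacing_mm[c(2, 3, 1)]
    img <- RNifti::asNifti(v$voxels)
    RNifti::pixdim(img) <- pix
    RNifti::writeNifti(img, file.path(out_dir, paste0(v$vessel_id, ".nii.gz")))
    wall_arr <- array(0L, dim(v$voxels))
    for (s in seq_along(w$outer_wall_masks)) {
      wall_arr[, , s] <- w$outer_wall_masks[[s]] + w$lumen_masks[[s]]
    }
    wimg <- RNifti::asNifti(wall_arr)
    RNifti::pixdim(wimg) <- pix
    RNifti::writeNifti(wimg,
                       file.path(out_dir, paste0(v$vessel_id, "_walls.nii.gz")))
  }
  utils::write.csv(cohort$labels, file.path(out_dir, "labels.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n_vessels = length(cohort$vessels),
         vessel_ids = cohort$labels$vessel_id),
    file.path(out_dir, "cohort_manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
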