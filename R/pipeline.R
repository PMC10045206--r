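# End-to-end orchestration: phantom cohort -> PCAT segmentation -> radiomic
# feature tables -> selection cascade -> cross-validated model evaluation,
# for every requested (target, range) pair, from a single config object.

#' Pipeline configuration
#'
#' One auditable object holding every pipeline constant: the adipose HU
#' window (-190, -30), the three discretizations (8, 16, 32 bins), the
#' correlation threshold 0.95, 15 features per family (105 candidates), mRMR
#' subset of 50, at most 10 final features, and stratified 3-fold CV with
#' 1000 repeats.
#'
#' @param phantom a [phantom_config()] describing the cohort to simulate.
#' @param bins gray-level discretizations.
#' @param correlation_threshold `|r|` pruning threshold.
#' @param k_per_family univariate screen survivors per family.
#' @param mrmr_k mRMR subset size.
#' @param max_final_features final model size cap.
#' @param cv a [cv_protocol()].
#' @param targets subset of `c("tcfa", "mc", "tcfa_mc")`.
#' @param ranges subset of `c("LOI", "Vessel")`.
#' @param min_fat_voxels minimum fat voxels for a slice to enter aggregation.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(),
                            bins = RADIOMIC_BINS,
                            correlation_threshold = 0.95,
                            k_per_family = 15L,
                            mrmr_k = 50L,
                            max_final_features = 10L,
                            cv = cv_protocol(),
                            targets = c("tcfa", "mc", "tcfa_mc"),
                            ranges = c("LOI", "Vessel"),
                            min_fat_voxels = 10L) {
  targets <- match.arg(targets, c("tcfa", "mc", "tcfa_mc"),
                       several.ok = TRUE)
  ranges <- match.arg(ranges, c("LOI", "Vessel"), several.ok = TRUE)
  stopifnot(inherits(phantom, "phantom_config"), inherits(cv, "cv_protocol"),
            correlation_threshold > 0, k_per_family >= 1, mrmr_k >= 1,
            max_final_features >= 1)
  structure(list(phantom = phantom, bins = as.integer(bins),
                 correlation_threshold = correlation_threshold,
                 k_per_family = as.integer(k_per_family),
                 mrmr_k = as.integer(mrmr_k),
                 max_final_features = as.integer(max_final_features),
                 cv = cv, targets = targets, ranges = ranges,
                 min_fat_voxels = as.integer(min_fat_voxels)),
            class = "pipeline_config")
}

# FNV-1a hash of the JSON-serialized config, for manifest provenance.
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass_recursive(config), auto_unbox = TRUE,
                        digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

#' Run the full PCAT radiomics pipeline
#'
#' Generates (or accepts) a cohort, builds the feature tables for the
#' requested ranges, and runs the selection cascade plus the final model
#' evaluation for every (target, range) pair. When `out_dir` is given,
#' feature tables (CSV), selection traces and model results (JSON) and a
#' manifest linking them to the config hash and seed are written there.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-generated cohort (default: generate from
#'   `config$phantom`).
#' @param out_dir optional output directory.
#' @return an object of class `pcat_pipeline_result`: list with `tables`,
#'   `traces`, `models`, `summary` (a [compare_ranges()] table), `manifest`.
#' @export
run_pipeline <- function(config, cohort = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) cohort <- generate_cohort(config$phantom)

  tables <- list()
  for (rk in config$ranges) {
    msg("extracting ", rk, " features")
    tables[[rk]] <- tryCatch(
      build_feature_table(cohort, rk, config$bins, config$min_fat_voxels),
      error = function(e) stop("feature extraction failed (", rk, "): ",
                               conditionMessage(e)))
  }

  traces <- list(); models <- list()
  for (rk in config$ranges) {
    for (tg in config$targets) {
      key <- paste(tg, rk, sep = "_")
      msg("selection + evaluation: ", key)
      tr <- tryCatch(
        select_features(tables[[rk]], tg, config$cv,
                        config$correlation_threshold, config$k_per_family,
                        config$mrmr_k, config$max_final_features),
        error = function(e) stop("selection failed (", key, "): ",
                                 conditionMessage(e)))
      md <- evaluate_model(tables[[rk]], tr$final_set, tg, config$cv)
      traces[[key]] <- tr
      models[[key]] <- md
    }
  }

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$phantom$rng_seed,
    cv_seed = config$cv$rng_seed,
    n_vessels = config$phantom$n_vessels,
    ranges = config$ranges, targets = config$targets,
    n_features = vapply(tables, ncol, integer(1)),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  result <- structure(list(tables = tables, traces = traces, models = models,
                           summary = compare_ranges(models),
                           labels = cohort$labels, manifest = manifest),
                      class = "pcat_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pcat_pipeline_result <- function(x, ...) {
  cat("PCAT radiomics pipeline result (config", x$manifest$config_hash,
      ")\n")
  cat(sprintf("  %d vessels; feature tables: %s\n", x$manifest$n_vessels,
              paste(names(x$tables), vapply(x$tables, ncol, integer(1)),
                    sep = "=", collapse = ", ")))
  print(x$summary)
  invisible(x)
}
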