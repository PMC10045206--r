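# Nested cross-validation: the full selection cascade is re-run inside every
# training fold, so the evaluated features never see the held-out samples.
# This is the protocol to use when an unbiased performance estimate is
# needed (e.g. null calibration); the plain pipeline mirrors the common
# radiomics practice of screening on the full table, which is optimistic.

#' Nested cross-validated evaluation of the selection cascade
#'
#' Per outer repeat and fold, the complete cascade (correlation pruning,
#' univariate screen, per-family pooling, mRMR, recursive elimination) is
#' run on the training folds only, using an inner CV protocol with
#' `inner_repeats` repeats and a seed derived from the outer one; a
#' ridge-logistic model on the selected features then scores the held-out
#' fold. Pooled out-of-fold scores give one AUC per repeat.
#'
#' @inheritParams select_features
#' @param inner_repeats CV repeats used by the inner selection (default 10;
#'   kept small because selection runs once per outer fold).
#' @return an object of class `pcat_model` with an additional
#'   `selected_sets` element (list of per-fold selections of the last
#'   repeat).
#' @export
evaluate_nested <- function(table, target, cv, inner_repeats = 10L,
                            correlation_threshold = 0.95,
                            k_per_family = 15L, mrmr_k = 50L,
                            max_final = 10L) {
  df <- as.data.frame(table)
  labs <- attr(table, "labels")
  y <- ft_target(table, target)
  if (min(sum(y == 1), sum(y == 0)) < 2 * cv$n_folds)
    stop("nested evaluation needs at least 2 * n_folds members per class")
  fpr_grid <- seq(0, 1, length.out = 101L)
  with_seed(cv$rng_seed, {
    aucs <- numeric(cv$n_repeats)
    tpr_sum <- numeric(length(fpr_grid))
    sets <- NULL
    for (rep_i in seq_len(cv$n_repeats)) {
      folds <- make_folds(y, cv)
      scores <- numeric(length(y))
      sets <- vector("list", cv$n_folds)
      for (f in seq_len(cv$n_folds)) {
        te <- folds == f
        train_tab <- feature_table(df[!te, , drop = FALSE],
                                   labs[!te, , drop = FALSE],
                                   attr(table, "range_kind"))
        inner_cv <- cv_protocol(cv$n_folds, inner_repeats, TRUE,
                                derive_seed(cv$rng_seed,
                                            rep_i * cv$n_folds + f))
        trace <- suppressWarnings(suppressMessages(
          select_features(train_tab, target, inner_cv,
                          correlation_threshold, k_per_family, mrmr_k,
                          max_final)))
        sets[[f]] <- trace$final_set
        Xtr <- as.matrix(df[!te, trace$final_set, drop = FALSE])
        Xte <- as.matrix(df[te, trace$final_set, drop = FALSE])
        sp <- standardize_pair(Xtr, Xte)
        beta <- ridge_logistic(sp$tr, y[!te])
        scores[te] <- stats::plogis(drop(cbind(1, sp$te) %*% beta))
      }
      aucs[rep_i] <- auc_mw(scores, y)
      tpr_sum <- tpr_sum + roc_on_grid(scores, y, fpr_grid)
    }
    structure(list(target = target,
                   range_kind = attr(table, "range_kind"),
                   feature_set = unique(unlist(sets)),
                   selected_sets = sets,
                   per_repeat_auc = aucs,
                   mean_auc = mean(aucs),
                   sd_auc = sd0(aucs),
                   mean_roc = data.frame(fpr = fpr_grid,
                                         tpr = tpr_sum / cv$n_repeats),
                   cv = cv, n = length(y), n_pos = sum(y)),
              class = "pcat_model")
  })
}
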