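# Repeated stratified k-fold cross-validation of logistic radiomics models.
# AUCs are computed on the pooled out-of-fold scores of each repeat; the
# reported model performance is the mean +/- SD over repeats, with a mean ROC
# curve obtained by vertical averaging on a fixed FPR grid.

# Ridge penalty applied to all logistic fits (on standardized features,
# intercept unpenalized). Guards against quasi-separation at small n.
RIDGE_LAMBDA <- 0.01

#' Cross-validation protocol
#'
#' @param n_folds number of folds (default 3).
#' @param n_repeats number of repeated shuffles (default 1000).
#' @param stratified stratify folds by class (default TRUE).
#' @param rng_seed integer seed for the fold shuffles.
#' @return an object of class `cv_protocol`.
#' @export
cv_protocol <- function(n_folds = 3L, n_repeats = 1000L, stratified = TRUE,
                        rng_seed = 1L) {
  stopifnot(n_folds >= 2L, n_repeats >= 1L)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 stratified = isTRUE(stratified),
                 rng_seed = as.integer(rng_seed)),
            class = "cv_protocol")
}

#' Mann-Whitney AUC of scores against binary labels
#'
#' `U / (n_pos * n_neg)` with midrank tie handling; identical to the area
#' under the empirical ROC curve with trapezoidal tie treatment.
#'
#' @param scores numeric vector.
#' @param y 0/1 labels (both classes present).
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  stopifnot(n1 > 0L, n0 > 0L)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment; every fold receives >= 1 member of each class
# when each class has >= n_folds members. Non-stratified draws are redrawn
# (up to 100 times) until no fold is single-class.
make_folds <- function(y, cv) {
  n <- length(y)
  if (cv$stratified) {
    if (min(sum(y == 1), sum(y == 0)) < cv$n_folds)
      stop("class count smaller than the number of folds")
    folds <- integer(n)
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(cv$n_folds), length(idx))
    }
    return(folds)
  }
  for (try in 1:100) {
    folds <- sample(rep_len(seq_len(cv$n_folds), n))
    ok <- all(vapply(seq_len(cv$n_folds), function(f)
      length(unique(y[folds == f])) == 2L, logical(1)))
    if (ok) return(folds)
  }
  stop("could not draw folds with both classes in every fold")
}

# Center/scale columns by training statistics; zero-variance columns map to 0.
standardize_pair <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- Inf   # constant -> all zeros
  list(tr = sweep(sweep(Xtr, 2, mu), 2, sdv, "/"),
       te = sweep(sweep(Xte, 2, mu), 2, sdv, "/"))
}

#' Ridge-penalized logistic regression (IRLS)
#'
#' Newton iterations on the penalized binomial log-likelihood with penalty
#' `lambda/2 * sum(beta^2)` on the non-intercept coefficients. Intended for
#' standardized design matrices.
#'
#' @param X numeric matrix (no intercept column).
#' @param y 0/1 labels.
#' @param lambda ridge penalty, default `RIDGE_LAMBDA` (0.01).
#' @param max_iter,tol Newton iteration controls.
#' @return numeric vector of coefficients `(intercept, beta_1..beta_p)`.
#' @export
ridge_logistic <- function(X, y, lambda = RIDGE_LAMBDA, max_iter = 50L,
                           tol = 1e-8) {
  X1 <- cbind(1, as.matrix(X))
  p1 <- ncol(X1)
  D <- diag(c(0, rep(lambda, p1 - 1L)), p1)
  beta <- numeric(p1)
  beta[1] <- stats::qlogis(pmin(pmax(mean(y), 0.02), 0.98))
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X1, y - mu)) - drop(D %*% beta)
    H <- crossprod(X1 * w, X1) + D
    step <- tryCatch(solve(H, grad),
                     error = function(e) solve(H + diag(1e-8, p1), grad))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Univariate logistic screening, vectorized across features: fits
# score = plogis(a_j + b_j x_j) per column with a 2-parameter Newton solver
# shared across all columns. Returns the test-set score matrix.
univariate_scores <- function(Xtr, ytr, Xte, lambda = RIDGE_LAMBDA,
                              max_iter = 25L) {
  n <- nrow(Xtr); p <- ncol(Xtr)
  a <- rep(stats::qlogis(pmin(pmax(mean(ytr), 0.02), 0.98)), p)
  b <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- matrix(a, n, p, byrow = TRUE) + Xtr * matrix(b, n, p, byrow = TRUE)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    r <- ytr - mu
    ga <- colSums(r)
    gb <- colSums(Xtr * r) - lambda * b
    h11 <- colSums(w)
    h12 <- colSums(w * Xtr)
    h22 <- colSums(w * Xtr^2) + lambda
    det <- h11 * h22 - h12^2
    ok <- is.finite(det) & det > 1e-12
    da <- ifelse(ok, (h22 * ga - h12 * gb) / det, 0)
    db <- ifelse(ok, (-h12 * ga + h11 * gb) / det, 0)
    a <- a + da
    b <- b + db
    if (max(abs(da), abs(db)) < 1e-8) break
  }
  stats::plogis(matrix(a, nrow(Xte), p, byrow = TRUE) +
                  Xte * matrix(b, nrow(Xte), p, byrow = TRUE))
}

# One CV repeat of the univariate screen: pooled out-of-fold score matrix.
univariate_oof_scores <- function(X, y, cv) {
  folds <- make_folds(y, cv)
  scores <- matrix(NA_real_, nrow(X), ncol(X))
  for (f in seq_len(cv$n_folds)) {
    te <- folds == f
    sp <- standardize_pair(X[!te, , drop = FALSE], X[te, , drop = FALSE])
    scores[te, ] <- univariate_scores(sp$tr, y[!te], sp$te)
  }
  scores
}

#' Mean cross-validated AUC of every feature (univariate screen)
#'
#' For each repeat, a stratified fold split is drawn; a single-feature
#' ridge-logistic model (feature standardized on the training folds) is fit
#' per feature and fold, out-of-fold scores are pooled, and one AUC per
#' feature is recorded. Returns the mean over repeats.
#'
#' @param table a [feature_table()].
#' @param target `"tcfa"`, `"mc"` or `"tcfa_mc"`.
#' @param cv a [cv_protocol()].
#' @param features optional subset of column names (default all).
#' @return named numeric vector of mean AUCs.
#' @export
screen_univariate <- function(table, target, cv, features = NULL) {
  X <- as.matrix(as.data.frame(table))
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  y <- ft_target(table, target)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  with_seed(cv$rng_seed, {
    acc <- numeric(ncol(X))
    ypos <- y == 1L
    n1 <- sum(ypos); n0 <- sum(!ypos)
    for (rep_i in seq_len(cv$n_repeats)) {
      sc <- univariate_oof_scores(X, y, cv)
      rk <- apply(sc, 2, rank)
      acc <- acc + (colSums(rk[ypos, , drop = FALSE]) - n1 * (n1 + 1) / 2) /
        (n1 * n0)
    }
    stats::setNames(acc / cv$n_repeats, colnames(X))
  })
}

#' Mean cross-validated AUC of one feature
#'
#' @inheritParams screen_univariate
#' @param feature one column name.
#' @return mean AUC over repeats.
#' @export
univariate_auc <- function(table, feature, target, cv) {
  stopifnot(feature %in% colnames(table))
  unname(screen_univariate(table, target, cv, features = feature))
}

# Interpolate one ROC curve (from pooled scores) on a fixed FPR grid.
roc_on_grid <- function(scores, y, fpr_grid) {
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  tp <- cumsum(ys == 1L)
  fp <- cumsum(ys == 0L)
  # collapse threshold ties: keep the last point of each tied score block
  last <- c(diff(scores[ord]) != 0, TRUE)
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  # at a repeated FPR keep the highest TPR (the ROC step value there)
  keep <- !duplicated(fpr, fromLast = TRUE)
  stats::approx(fpr[keep], tpr[keep], xout = fpr_grid, method = "linear",
                rule = 2)$y
}

#' Evaluate a radiomics model by repeated stratified cross-validation
#'
#' Per repeat: a stratified fold split is drawn (degenerate non-stratified
#' shuffles are redrawn so the number of repeats is preserved); a
#' ridge-logistic model on the selected features (standardized on the
#' training folds) scores each held-out fold; the pooled out-of-fold scores
#' give one AUC. Reports mean and sample SD over repeats and the vertically
#' averaged ROC curve on a 101-point FPR grid.
#'
#' @param table a [feature_table()].
#' @param feature_set character vector of column names (the model features).
#' @param target `"tcfa"`, `"mc"` or `"tcfa_mc"`.
#' @param cv a [cv_protocol()].
#' @return an object of class `pcat_model`.
#' @export
evaluate_model <- function(table, feature_set, target, cv) {
  stopifnot(all(feature_set %in% colnames(table)))
  X <- as.matrix(as.data.frame(table)[, feature_set, drop = FALSE])
  y <- ft_target(table, target)
  if (min(sum(y == 1), sum(y == 0)) < cv$n_folds)
    stop("each class needs at least n_folds members")
  fpr_grid <- seq(0, 1, length.out = 101L)
  with_seed(cv$rng_seed, {
    aucs <- numeric(cv$n_repeats)
    tpr_sum <- numeric(length(fpr_grid))
    for (rep_i in seq_len(cv$n_repeats)) {
      folds <- make_folds(y, cv)
      scores <- numeric(length(y))
      for (f in seq_len(cv$n_folds)) {
        te <- folds == f
        sp <- standardize_pair(X[!te, , drop = FALSE], X[te, , drop = FALSE])
        beta <- ridge_logistic(sp$tr, y[!te])
        scores[te] <- stats::plogis(drop(cbind(1, sp$te) %*% beta))
      }
      aucs[rep_i] <- auc_mw(scores, y)
      tpr_sum <- tpr_sum + roc_on_grid(scores, y, fpr_grid)
    }
    structure(list(target = target,
                   range_kind = attr(table, "range_kind"),
                   feature_set = feature_set,
                   per_repeat_auc = aucs,
                   mean_auc = mean(aucs),
                   sd_auc = sd0(aucs),
                   mean_roc = data.frame(fpr = fpr_grid,
                                         tpr = tpr_sum / cv$n_repeats),
                   cv = cv, n = length(y), n_pos = sum(y)),
              class = "pcat_model")
  })
}

#' @export
print.pcat_model <- function(x, ...) {
  cat(sprintf("PCAT radiomics model (%s, %s range): %d features, n = %d (%d positive)\n",
              toupper(x$target), x$range_kind %||% "?",
              length(x$feature_set), x$n, x$n_pos))
  cat(sprintf("  mean AUC %.3f (SD = %.3f) over %d x %d-fold stratified CV\n",
              x$mean_auc, x$sd_auc, x$cv$n_repeats, x$cv$n_folds))
  invisible(x)
}

#' @export
summary.pcat_model <- function(object, ...) {
  print(object)
  cat("  features:\n")
  for (f in object$feature_set) cat("    -", f, "\n")
  cat(sprintf("  per-repeat AUC quartiles: %.3f / %.3f / %.3f\n",
              stats::quantile(object$per_repeat_auc, 0.25),
              stats::median(object$per_repeat_auc),
              stats::quantile(object$per_repeat_auc, 0.75)))
  invisible(object)
}

#' @export
plot.pcat_model <- function(x, add = FALSE, col = "steelblue", ...) {
  if (!add) {
    graphics::plot(x$mean_roc$fpr, x$mean_roc$tpr, type = "l", col = col,
                   xlab = "False positive rate", ylab = "True positive rate",
                   main = sprintf("%s (%s): mean AUC %.3f (SD %.3f)",
                                  toupper(x$target), x$range_kind,
                                  x$mean_auc, x$sd_auc), ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  } else {
    graphics::lines(x$mean_roc$fpr, x$mean_roc$tpr, col = col, ...)
  }
  invisible(x)
}

#' Tabulate LOI vs whole-vessel model performance
#'
#' Collects mean AUC +/- SD of any number of fitted models into one summary
#' table, with the mean ROC curves attached for overlay plotting.
#'
#' @param ... `pcat_model` objects (or one list of them).
#' @return data.frame with columns target, range, n_features, mean_auc,
#'   sd_auc; attribute `roc` holds the named list of mean ROC curves.
#' @export
compare_ranges <- function(...) {
  models <- list(...)
  if (length(models) == 1L && !inherits(models[[1]], "pcat_model"))
    models <- models[[1]]
  stopifnot(all(vapply(models, inherits, logical(1), "pcat_model")))
  tab <- do.call(rbind, lapply(models, function(m)
    data.frame(target = toupper(m$target), range = m$range_kind,
               n_features = length(m$feature_set),
               mean_auc = m$mean_auc, sd_auc = m$sd_auc,
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  attr(tab, "roc") <- stats::setNames(
    lapply(models, `[[`, "mean_roc"),
    vapply(models, function(m) paste(toupper(m$target), m$range_kind,
                                     sep = "_"), character(1)))
  tab
}
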