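# Cascade feature selection: correlation pruning -> univariate CV-AUC screen
# -> top-15 per feature family (<= 105 candidates) -> mRMR to 50 -> mRMR to
# <= 10 -> coefficient-based recursive elimination.

# Canonical column order used by the correlation pruning: aggregation
# statistic (min, max, mean, sd), then family, then feature name, then bin
# count. Non-standard names fall back to their given order.
canonical_feature_order <- function(names) {
  parts <- strsplit(names, "_", fixed = TRUE)
  stat <- vapply(parts, `[`, character(1), 1)
  fam <- feature_family(names)
  bins <- suppressWarnings(as.integer(sub("b$", "", vapply(parts, function(p)
    p[length(p)], character(1)))))
  feat <- vapply(parts, function(p)
    paste(p[-c(1, 2, length(p))], collapse = "_"), character(1))
  standard <- stat %in% RADIOMIC_STATS & !is.na(fam) & !is.na(bins)
  if (!all(standard)) return(seq_along(names))
  order(match(stat, RADIOMIC_STATS), match(fam, FEATURE_FAMILIES), feat, bins)
}

#' Prune highly correlated features
#'
#' Greedy scan of the columns in canonical order: a column is kept only if
#' its absolute Pearson correlation with every previously kept column is at
#' most `threshold`; otherwise the later column of the offending pair is
#' dropped. Constant columns (undefined correlation) are kept with a
#' warning. Deterministic; dropped names are reported in a message.
#'
#' @param table a [feature_table()] with at least 2 rows.
#' @param threshold correlation threshold, default 0.95 (`|r| > 0.95` drops).
#' @return the pruned `feature_table` (columns in canonical order).
#' @export
prune_correlated <- function(table, threshold = 0.95) {
  df <- as.data.frame(table)
  stopifnot(nrow(df) >= 2L)
  ord <- canonical_feature_order(colnames(df))
  X <- as.matrix(df)[, ord, drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    warning(sum(sds == 0), " constant column(s): correlation undefined, kept")
  cm <- suppressWarnings(abs(stats::cor(X)))
  cm[!is.finite(cm)] <- 0   # constant columns correlate with nothing
  p <- ncol(X)
  kept <- logical(p)
  for (j in seq_len(p)) {
    kept[j] <- !any(cm[j, kept] > threshold)
  }
  msg("correlation pruning: ", sum(kept), " of ", p, " features survive ",
      "(|r| > ", threshold, " dropped)")
  ft_subset(table, colnames(X)[kept])
}

#' Top-k features per family by univariate AUC
#'
#' Selects, within each of the seven feature families present, the `k`
#' features with the highest mean univariate AUC (ties broken by name
#' order). Families with fewer than `k` survivors contribute all of them.
#'
#' @param auc_map named numeric vector of mean AUCs (names carry the family
#'   tag, see [feature_family()]).
#' @param k features per family, default 15.
#' @return character vector of at most `7 * k` names, ordered by family then
#'   descending AUC.
#' @export
top_k_per_family <- function(auc_map, k = 15L) {
  fam <- feature_family(names(auc_map))
  out <- character(0)
  for (f in FEATURE_FAMILIES) {
    in_fam <- which(fam == f)
    if (length(in_fam) == 0L) next
    nm <- names(auc_map)[in_fam]
    o <- order(-auc_map[in_fam], nm)
    out <- c(out, nm[o][seq_len(min(k, length(in_fam)))])
  }
  out
}

# Mutual information (bits) between two vectors of positive integer codes.
mutual_information <- function(a, b) {
  na <- max(a); nb <- max(b)
  n <- length(a)
  p <- tabulate(a + na * (b - 1L), na * nb) / n
  pa <- tabulate(a, na) / n
  pb <- tabulate(b, nb) / n
  e <- as.vector(outer(pa, pb))
  pos <- p > 0
  sum(p[pos] * log2(p[pos] / e[pos]))
}

# Three-level discretization at mean +/- SD for MI estimation.
discretize3 <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(1L, length(x)))
  findInterval(x, c(m - s, m + s)) + 1L
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy mRMR with the mutual-information difference (MID) criterion: the
#' first feature maximizes relevance `I(f; y)`; each subsequent feature
#' maximizes `I(f; y) - mean(I(f; s))` over the already selected set `S`.
#' Mutual information is estimated after discretizing each feature into 3
#' levels at mean +/- SD. Ties break on candidate order, so the result is
#' deterministic.
#'
#' @param table a [feature_table()] restricted to the candidate columns.
#' @param target `"tcfa"`, `"mc"` or `"tcfa_mc"`.
#' @param k number of features to select (`0 < k <=` number of candidates).
#' @return character vector of `k` selected names, in selection order.
#' @export
mrmr_select <- function(table, target, k) {
  df <- as.data.frame(table)
  p <- ncol(df)
  if (k <= 0) stop("k must be positive")
  if (k > p) stop("k exceeds the number of candidate features")
  y <- ft_target(table, target) + 1L
  D <- vapply(df, discretize3, integer(nrow(df)))
  relevance <- vapply(seq_len(p), function(j) mutual_information(D[, j], y),
                      numeric(1))
  selected <- integer(0)
  remaining <- seq_len(p)
  red <- matrix(NA_real_, p, p)   # pairwise MI rows, filled when selected
  for (step in seq_len(k)) {
    if (length(selected) == 0L) {
      crit <- relevance[remaining]
    } else {
      red_mean <- colMeans(red[selected, remaining, drop = FALSE])
      crit <- relevance[remaining] - red_mean
    }
    pick <- remaining[which.max(crit)]
    red[pick, ] <- vapply(seq_len(p), function(j)
      mutual_information(D[, pick], D[, j]), numeric(1))
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  colnames(df)[selected]
}

#' Coefficient-based recursive feature elimination
#'
#' Repeatedly fits a ridge-logistic model on the standardized candidate
#' features using the full table, drops the feature with the smallest
#' absolute coefficient, and records the mean cross-validated AUC of every
#' visited subset size. Returns the subset with maximal mean CV AUC, ties
#' resolved toward the smaller subset.
#'
#' @param table a [feature_table()] restricted to the candidates (<= 10 in
#'   the standard cascade).
#' @param target `"tcfa"`, `"mc"` or `"tcfa_mc"`.
#' @param cv a [cv_protocol()].
#' @return list with `final_set` (character), `auc_by_size` (data.frame of
#'   size, mean_auc, features).
#' @export
recursive_elimination <- function(table, target, cv) {
  df <- as.data.frame(table)
  y <- ft_target(table, target)
  current <- colnames(df)
  sizes <- list(); aucs <- numeric(0)
  while (length(current) >= 1L) {
    res <- evaluate_model(table, current, target, cv)
    sizes[[length(sizes) + 1L]] <- current
    aucs <- c(aucs, res$mean_auc)
    if (length(current) == 1L) break
    X <- scale(as.matrix(df[, current, drop = FALSE]))
    X[!is.finite(X)] <- 0
    beta <- ridge_logistic(X, y)[-1]
    drop_j <- which.min(abs(beta))
    current <- current[-drop_j]
  }
  # maximal mean AUC; ties (within numerical noise) toward the smaller set
  best <- which(aucs >= max(aucs) - 1e-12)
  best <- best[which.min(lengths(sizes)[best])]
  list(final_set = sizes[[best]],
       auc_by_size = data.frame(
         size = lengths(sizes),
         mean_auc = aucs,
         features = vapply(sizes, paste, character(1), collapse = ";"),
         stringsAsFactors = FALSE))
}

#' Run the full feature-selection cascade
#'
#' Correlation pruning (`|r| > correlation_threshold` dropped), univariate
#' CV-AUC screening, top-`k_per_family` pooling across the seven feature
#' families (at most 105 candidates), mRMR to `mrmr_k` (at most 50), a
#' second mRMR refinement to at most `max_final` features, and
#' coefficient-based recursive elimination.
#'
#' @param table a [feature_table()].
#' @param target `"tcfa"`, `"mc"` or `"tcfa_mc"`.
#' @param cv a [cv_protocol()].
#' @param correlation_threshold default 0.95.
#' @param k_per_family default 15.
#' @param mrmr_k default 50.
#' @param max_final default 10.
#' @return an object of class `selection_trace` with elements
#'   `surviving_after_correlation`, `univariate_auc`, `top105`, `mrmr50`,
#'   `candidate10`, `final_set`, `auc_by_size`.
#' @export
select_features <- function(table, target, cv,
                            correlation_threshold = 0.95,
                            k_per_family = 15L, mrmr_k = 50L,
                            max_final = 10L) {
  pruned <- prune_correlated(table, correlation_threshold)
  auc_map <- screen_univariate(pruned, target, cv)
  top105 <- top_k_per_family(auc_map, k_per_family)
  t105 <- ft_subset(pruned, top105)
  mrmr50 <- mrmr_select(t105, target, min(mrmr_k, length(top105)))
  t50 <- ft_subset(pruned, mrmr50)
  candidate10 <- mrmr_select(t50, target, min(max_final, length(mrmr50)))
  rec <- recursive_elimination(ft_subset(pruned, candidate10), target, cv)
  structure(list(
    target = target,
    range_kind = attr(table, "range_kind"),
    surviving_after_correlation = colnames(pruned),
    univariate_auc = auc_map,
    top105 = top105,
    mrmr50 = mrmr50,
    candidate10 = candidate10,
    final_set = rec$final_set,
    auc_by_size = rec$auc_by_size,
    cv = cv), class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("Selection trace (%s, %s range):\n", toupper(x$target),
              x$range_kind %||% "?"))
  cat(sprintf("  after |r| pruning : %d features\n",
              length(x$surviving_after_correlation)))
  cat(sprintf("  top per family    : %d\n", length(x$top105)))
  cat(sprintf("  after mRMR        : %d\n", length(x$mrmr50)))
  cat(sprintf("  refinement pool   : %d\n", length(x$candidate10)))
  cat(sprintf("  final model       : %d feature(s)\n", length(x$final_set)))
  for (f in x$final_set) cat("    -", f, "\n")
  invisible(x)
}

#' Manhattan-plot data of a univariate screen
#'
#' @param auc_map named mean-AUC vector from [screen_univariate()].
#' @return data.frame with columns name, family, mean_auc, ordered by family.
#' @export
manhattan_data <- function(auc_map) {
  d <- data.frame(name = names(auc_map),
                  family = feature_family(names(auc_map)),
                  mean_auc = unname(auc_map), stringsAsFactors = FALSE)
  d[order(match(d$family, FEATURE_FAMILIES), d$name), ]
}
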