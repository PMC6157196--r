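#' Rank pathway features by t-tests of activity
#'
#' Two-tailed Welch t-test of each pathway's activity between the good and
#' poor groups; features are ordered by ascending p-value, ties broken
#' lexicographically by pathway id.
#'
#' @param activity pathways x samples matrix.
#' @param groups named good/poor labels.
#' @return a `feature_ranking` data.frame (pathway_id, score = p-value, rank)
#'   with `attr(, "method") == "ttest"`.
#' @export
rank_by_ttest <- function(activity, groups) {
  groups <- as_survival_groups(groups)
  common <- intersect(colnames(activity), names(groups))
  g <- groups[common]
  if (any(table(g) < 2L)) stop("need at least 2 samples per group")
  poor <- g == "poor"
  vals <- as.matrix(activity)[, common, drop = FALSE]
  p <- apply(vals, 1L, function(v) welch_row(v, poor)[["p"]])
  ids <- rownames(vals)
  ord <- order(p, ids)
  out <- data.frame(pathway_id = ids[ord], score = p[ord],
                    rank = seq_along(ids), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- "ttest"
  class(out) <- c("feature_ranking", class(out))
  out
}

# fit logistic regression on selected activity rows; returns the fitted model
fit_logistic <- function(activity, ids, groups) {
  df <- as.data.frame(t(as.matrix(activity)[ids, , drop = FALSE]))
  names(df) <- make.names(ids)
  df$.y <- as.integer(groups == "poor")
  suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
}

predict_logistic <- function(fit, activity, ids) {
  df <- as.data.frame(t(as.matrix(activity)[ids, , drop = FALSE]))
  names(df) <- make.names(ids)
  suppressWarnings(stats::predict(fit, newdata = df, type = "response"))
}

# mean AUC of logistic regression over an inner stratified CV; folds fixed
inner_cv_auc <- function(activity, ids, groups, fold) {
  aucs <- vapply(sort(unique(fold)), function(k) {
    tr <- fold != k
    fit <- fit_logistic(activity[, tr, drop = FALSE], ids, groups[tr])
    sc <- predict_logistic(fit, activity[, !tr, drop = FALSE], ids)
    auc_score(sc, groups[!tr] == "poor")
  }, numeric(1))
  mean(aucs)
}

#' Greedy forward selection of ranked pathway features
#'
#' Walks the ranking from the top; each feature is tentatively added and kept
#' only if it strictly improves the mean AUC of a logistic regression under an
#' inner stratified cross-validation on the training samples. Stops when
#' `max_n` features have been accepted or the ranking is exhausted.
#'
#' @param ranking a `feature_ranking`.
#' @param activity pathways x samples matrix (training samples only).
#' @param groups named good/poor labels for those samples.
#' @param max_n maximum number of selected features; default 10.
#' @param inner_folds folds of the inner CV used as the acceptance criterion;
#'   default 3.
#' @param seed seed for the inner fold assignment (fixed across candidate
#'   evaluations so AUCs are comparable).
#' @return character vector of selected pathway ids, in acceptance order.
#' @export
greedy_select <- function(ranking, activity, groups, max_n = 10L,
                          inner_folds = 3L, seed = NULL) {
  groups <- as_survival_groups(groups)[colnames(activity)]
  fold <- with_seed(seed, stratified_folds(groups, inner_folds))
  selected <- character(0)
  best <- -Inf
  for (id in ranking$pathway_id) {
    if (!id %in% rownames(activity)) next
    cand <- c(selected, id)
    auc <- inner_cv_auc(activity, cand, groups, fold)
    if (auc > best) {
      selected <- cand
      best <- auc
    }
    if (length(selected) >= max_n) break
  }
  selected
}

#' Repeated stratified cross-validated evaluation of a pathway profile
#'
#' For each of `repeats` random stratified partitions into `folds` folds:
#' rank the features on the training samples (t-test ranker) or take the fixed
#' autoencoder ranking, greedily select features on the training fold, fit a
#' logistic regression, and record AUC and accuracy (threshold 0.5, positive
#' class poor) on the held-out fold.
#'
#' @param activity pathways x samples matrix.
#' @param groups named good/poor labels.
#' @param ranker `"ttest"` (re-ranked per training fold) or `"da"` (fixed
#'   ranking supplied via `ranking`).
#' @param ranking a `feature_ranking`, required when `ranker = "da"`.
#' @param repeats,folds default 10 repeats of 5-fold CV.
#' @param max_n greedy selection cap per fold.
#' @param seed seed for all fold assignments.
#' @return a `cv_result`: list with `metrics` (data.frame repeat_id, fold,
#'   auc, accuracy), `feature_sets` (list of selected-id vectors, one per
#'   fold), and `summary` (means and standard errors).
#' @export
cross_validate <- function(activity, groups, ranker = c("ttest", "da"),
                           ranking = NULL, repeats = 10L, folds = 5L,
                           max_n = 10L, seed = 1L) {
  ranker <- match.arg(ranker)
  if (ranker == "da" && is.null(ranking)) {
    stop("ranker = 'da' requires a precomputed ranking")
  }
  groups <- as_survival_groups(groups)
  common <- intersect(colnames(activity), names(groups))
  act <- as.matrix(activity)[, common, drop = FALSE]
  g <- groups[common]
  metrics <- list()
  feature_sets <- list()
  with_seed(seed, {
    for (rep_i in seq_len(repeats)) {
      fold <- stratified_folds(g, folds)
      inner_seed <- sample.int(1e8, 1L)
      for (k in seq_len(folds)) {
        tr <- fold != k
        act_tr <- act[, tr, drop = FALSE]
        rk <- if (ranker == "ttest") rank_by_ttest(act_tr, g[tr]) else ranking
        sel <- greedy_select(rk, act_tr, g[tr], max_n = max_n,
                             seed = inner_seed + k)
        fit <- fit_logistic(act_tr, sel, g[tr])
        sc <- predict_logistic(fit, act[, !tr, drop = FALSE], sel)
        truth <- g[!tr] == "poor"
        metrics[[length(metrics) + 1L]] <- data.frame(
          repeat_id = rep_i, fold = k,
          auc = auc_score(sc, truth),
          accuracy = mean((sc > 0.5) == truth))
        feature_sets[[length(feature_sets) + 1L]] <- sel
      }
    }
  })
  metrics <- do.call(rbind, metrics)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  structure(list(
    metrics = metrics,
    feature_sets = feature_sets,
    summary = list(auc_mean = mean(metrics$auc), auc_se = se(metrics$auc),
                   accuracy_mean = mean(metrics$accuracy),
                   accuracy_se = se(metrics$accuracy)),
    ranker = ranker, repeats = repeats, folds = folds, seed = seed
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d repeats x %d folds (%s ranker): AUC %.3f +/- %.3f, accuracy %.3f +/- %.3f\n",
              x$repeats, x$folds, x$ranker,
              x$summary$auc_mean, x$summary$auc_se,
              x$summary$accuracy_mean, x$summary$accuracy_se))
  invisible(x)
}

#' Consolidate per-fold feature sets
#'
#' Keeps the features selected in at least `min_count` of the per-fold feature
#' sets (default 4, i.e. "more than 3 of 50" for 10 repeats of 5-fold CV) and
#' reports each feature's selection frequency.
#'
#' @param cv a `cv_result` (or a plain list of character vectors).
#' @param min_count minimum number of fold-sets a feature must appear in.
#' @return data.frame (pathway_id, count, n_sets) sorted by decreasing count.
#' @export
consolidate_features <- function(cv, min_count = 4L) {
  sets <- if (inherits(cv, "cv_result")) cv$feature_sets else cv
  n_sets <- length(sets)
  counts <- table(unlist(lapply(sets, unique)))
  keep <- counts[counts >= min_count]
  out <- data.frame(
    pathway_id = as.character(names(keep)),
    count = as.integer(keep),
    n_sets = rep(n_sets, length(keep)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out[order(-out$count, out$pathway_id), , drop = FALSE]
}

#' Mean / median pathway-summary baselines
#'
#' Pathway activity as the per-sample mean or median of the z-scored values of
#' the pathway's significant member (gene, layer) pairs — no graph and no walk
#' weights.
#'
#' @param pathways named list of gene sets.
#' @param gene_stats combined per-(gene, layer) statistics.
#' @param expr_z,meth_z z-scored `omics_matrix` objects.
#' @param stat `"mean"` or `"median"`.
#' @param alpha significance threshold for membership.
#' @return pathways x samples matrix (pathways without significant members are
#'   dropped).
#' @export
baseline_activity <- function(pathways, gene_stats, expr_z, meth_z,
                              stat = c("mean", "median"), alpha = 0.05) {
  stat <- match.arg(stat)
  samples <- intersect(colnames(expr_z), colnames(meth_z))
  sig <- gene_stats[gene_stats$p_value < alpha, , drop = FALSE]
  fn <- if (stat == "mean") colMeans else function(m) apply(m, 2L, stats::median)
  rows <- list()
  for (id in names(pathways)) {
    members <- sig[sig$gene %in% pathways[[id]], , drop = FALSE]
    is_e <- members$layer == "expression"
    keep_e <- members$gene[is_e][members$gene[is_e] %in% rownames(expr_z)]
    keep_m <- members$gene[!is_e][members$gene[!is_e] %in% rownames(meth_z)]
    if (!length(keep_e) && !length(keep_m)) next
    z <- rbind(
      if (length(keep_e)) unclass(expr_z)[keep_e, samples, drop = FALSE],
      if (length(keep_m)) unclass(meth_z)[keep_m, samples, drop = FALSE]
    )
    rows[[id]] <- fn(z)
  }
  if (!length(rows)) stop("no pathway has significant members")
  out <- do.call(rbind, rows)
  colnames(out) <- samples
  out
}

#' Concatenate two single-layer pathway profiles
#'
#' Row-binds two activity matrices computed independently per layer, suffixing
#' pathway ids so they stay unique. Errors if the sample sets differ; columns
#' are aligned by sample id.
#'
#' @param expr_activity,meth_activity pathways x samples matrices.
#' @param suffixes id suffixes; default `c("_expr", "_meth")`.
#' @return concatenated matrix.
#' @export
drw_concat <- function(expr_activity, meth_activity,
                       suffixes = c("_expr", "_meth")) {
  a <- as.matrix(expr_activity)
  b <- as.matrix(meth_activity)
  if (!setequal(colnames(a), colnames(b))) {
    stop("sample sets differ between the two profiles")
  }
  b <- b[, colnames(a), drop = FALSE]
  rownames(a) <- paste0(rownames(a), suffixes[1L])
  rownames(b) <- paste0(rownames(b), suffixes[2L])
  rbind(a, b)
}

#' Simpson overlap coefficient of two sets
#'
#' |A intersect B| / min(|A|, |B|); defined as 0 when either set is empty.
#'
#' @param a,b vectors treated as sets.
#' @return overlap in \[0, 1\].
#' @export
simpson_coefficient <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (!length(a) || !length(b)) return(0)
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Pairwise Simpson similarity between two collections of gene sets
#'
#' @param sets_a,sets_b named lists of gene sets.
#' @return matrix of Simpson coefficients, rows = `sets_a`, cols = `sets_b`.
#' @export
simpson_matrix <- function(sets_a, sets_b) {
  out <- matrix(0, length(sets_a), length(sets_b),
                dimnames = list(names(sets_a), names(sets_b)))
  for (i in seq_along(sets_a)) {
    for (j in seq_along(sets_b)) {
      out[i, j] <- simpson_coefficient(sets_a[[i]], sets_b[[j]])
    }
  }
  out
}
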