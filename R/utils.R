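#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the previous RNG state so
#' package functions do not perturb the caller's random stream. A `NULL` seed
#' leaves the RNG untouched.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Area under the ROC curve from decision scores
#'
#' Rank-statistic AUC: the Mann-Whitney U of the positive-class scores divided
#' by `n_pos * n_neg`, with average ranks for ties.
#'
#' @param scores numeric decision scores (higher = more likely positive).
#' @param positive logical vector, `TRUE` for the positive class.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Normalise survival-group labels
#'
#' Accepts a named factor/character vector (names = sample ids) or the
#' data.frame produced by [derive_groups()] and returns a named factor with
#' levels `c("good", "poor")`.
#' @keywords internal
as_survival_groups <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("sample_id", "group") %in% names(groups)))
    out <- as.character(groups$group)
    names(out) <- as.character(groups$sample_id)
    groups <- out
  }
  if (is.null(names(groups))) stop("groups must be named by sample id")
  bad <- setdiff(unique(as.character(groups)), c("good", "poor"))
  if (length(bad)) stop("unknown group labels: ", paste(bad, collapse = ", "))
  factor(as.character(groups), levels = c("good", "poor"),
         labels = c("good", "poor")) |> stats::setNames(names(groups))
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds so that both groups are spread as
#' evenly as possible across folds. Uses the current RNG stream.
#' @keywords internal
stratified_folds <- function(groups, k) {
  groups <- as.factor(groups)
  fold <- integer(length(groups))
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    if (length(idx) < k) stop("class '", lev, "' has fewer samples than folds")
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
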