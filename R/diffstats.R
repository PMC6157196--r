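#' Per-gene Welch t-tests between survival groups
#'
#' Two-tailed Welch (unequal-variance) t-test of each gene between the poor and
#' good groups. The effect column is the t statistic, oriented as poor minus
#' good. Genes that are constant in both groups get t = 0, p = 1; a constant
#' gene with unequal group means gets a near-zero p with a warning (the Welch
#' statistic degenerates).
#'
#' @param x `omics_matrix` (any continuous values).
#' @param groups named good/poor labels (see [derive_groups()]).
#' @return data.frame with columns gene, layer, p_value, effect, test.
#' @export
welch_t_test <- function(x, groups) {
  groups <- as_survival_groups(groups)
  common <- intersect(colnames(x), names(groups))
  if (length(common) < 4L) stop("need at least 2 samples per group")
  g <- groups[common]
  if (any(table(g) < 2L)) stop("need at least 2 samples per group")
  vals <- unclass(x)[, common, drop = FALSE]
  poor <- g == "poor"
  res <- t(apply(vals, 1L, welch_row, poor = poor))
  data.frame(
    gene = rownames(vals),
    layer = omics_layer(x),
    p_value = res[, "p"],
    effect = res[, "t"],
    test = "welch_t",
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# one-gene Welch test; falls back to a closed-form degenerate answer when
# stats::t.test refuses (essentially constant data)
welch_row <- function(v, poor) {
  x1 <- v[poor]
  x0 <- v[!poor]
  out <- tryCatch(
    {
      tt <- stats::t.test(x1, x0, alternative = "two.sided", var.equal = FALSE)
      c(t = unname(tt$statistic), p = tt$p.value)
    },
    error = function(e) NULL
  )
  if (is.null(out)) {
    d <- mean(x1) - mean(x0)
    if (isTRUE(all.equal(d, 0)) || d == 0) {
      out <- c(t = 0, p = 1)
    } else {
      warning("zero within-group variance with unequal means; p set to 0",
              call. = FALSE)
      out <- c(t = sign(d) * sqrt(.Machine$double.xmax), p = 0)
    }
  }
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors: the median, over genes with a positive
#' geometric mean, of the ratio of the sample's count to that geometric mean.
#'
#' @param counts non-negative count matrix, genes x samples.
#' @return numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  logg <- rowMeans(log(counts))
  use <- is.finite(logg)
  if (!any(use)) stop("no gene has all-positive counts; cannot estimate size factors")
  sf <- apply(counts[use, , drop = FALSE], 2L, function(cnt) {
    stats::median(exp(log(cnt[cnt > 0]) - logg[use][cnt > 0]))
  })
  sf
}

#' Negative-binomial Wald test for differential expression
#'
#' Count-based two-group test: counts are normalised by median-of-ratios size
#' factors, a per-gene NB dispersion is estimated by method of moments from
#' the within-group residual variance (floored at `dispersion_floor`), and a
#' Wald test is applied to the log2 ratio of group means (poor over good).
#' All-zero genes are excluded with a warning. When a group mean is zero a
#' pseudo-mean of `pseudocount` normalised counts is added to both groups to
#' keep the fold change finite.
#'
#' @param counts expression `omics_matrix` of raw counts (or plain matrix).
#' @param groups named good/poor labels.
#' @param dispersion_floor lower bound for the NB dispersion estimate.
#' @param pseudocount added to both group means only when one of them is zero.
#' @return data.frame with columns gene, layer, p_value, effect (log2 fold
#'   change poor vs good), test.
#' @export
nb_wald_test <- function(counts, groups, dispersion_floor = 1e-8,
                         pseudocount = 0.5) {
  groups <- as_survival_groups(groups)
  common <- intersect(colnames(counts), names(groups))
  if (length(common) < 4L) stop("need at least 2 samples per group")
  g <- groups[common]
  if (any(table(g) < 2L)) stop("need at least 2 samples per group")
  vals <- unclass(counts)[, common, drop = FALSE]
  if (any(vals < 0) || any(vals != floor(vals))) {
    stop("nb_wald_test requires non-negative integer counts")
  }
  zero <- rowSums(vals) == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero gene(s) excluded", call. = FALSE)
    vals <- vals[!zero, , drop = FALSE]
  }
  if (!nrow(vals)) stop("no genes left after removing all-zero rows")
  sf <- size_factors(vals)
  q <- sweep(vals, 2L, sf, "/")
  poor <- g == "poor"
  n1 <- sum(poor)
  n0 <- sum(!poor)
  phi <- mean(1 / sf) # Poisson part of Var(count/sf) at dispersion 0

  m1 <- rowMeans(q[, poor, drop = FALSE])
  m0 <- rowMeans(q[, !poor, drop = FALSE])
  resid2 <- rowSums((q[, poor, drop = FALSE] - m1)^2) +
    rowSums((q[, !poor, drop = FALSE] - m0)^2)
  v_within <- resid2 / (n1 + n0 - 2L)
  m_all <- (n1 * m1 + n0 * m0) / (n1 + n0)
  alpha <- pmax((v_within - m_all * phi) / m_all^2, dispersion_floor)

  zero_mean <- m1 == 0 | m0 == 0
  a1 <- ifelse(zero_mean, m1 + pseudocount, m1)
  a0 <- ifelse(zero_mean, m0 + pseudocount, m0)
  lfc <- log2(a1 / a0)
  # Var(log mu_hat_g) = (1/n_g^2) * sum_i (1/(mu_g * sf_i) + alpha)
  var_log1 <- (sum(1 / sf[poor]) / a1 + n1 * alpha) / n1^2
  var_log0 <- (sum(1 / sf[!poor]) / a0 + n0 * alpha) / n0^2
  se_lfc <- sqrt(var_log1 + var_log0) / log(2)
  z <- lfc / se_lfc
  p <- 2 * stats::pnorm(-abs(z))

  data.frame(
    gene = rownames(vals),
    layer = "expression",
    p_value = p,
    effect = lfc,
    test = "nb_wald",
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Load externally computed differential statistics
#'
#' Accepts a results table in the common differential-expression layout with
#' columns `gene`, `log2FoldChange` and `pvalue` (extra columns ignored), so
#' statistics from a dedicated count-model package can replace the built-in
#' Wald surrogate.
#'
#' @param path TSV file.
#' @param layer which omics layer the statistics describe.
#' @return data.frame in the [nb_wald_test()] layout with `test = "external"`.
#' @export
load_external_stats <- function(path, layer = c("expression", "methylation")) {
  layer <- match.arg(layer)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           na.strings = c("NA", ""))
  need <- c("gene", "log2FoldChange", "pvalue")
  missing <- setdiff(need, names(tab))
  if (length(missing)) stop("stats table missing column(s): ",
                            paste(missing, collapse = ", "))
  bad <- is.na(tab$pvalue)
  if (any(bad)) {
    warning(sum(bad), " gene(s) with missing p-value skipped", call. = FALSE)
    tab <- tab[!bad, , drop = FALSE]
  }
  data.frame(
    gene = as.character(tab$gene),
    layer = layer,
    p_value = as.numeric(tab$pvalue),
    effect = as.numeric(tab$log2FoldChange),
    test = "external",
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Write differential statistics in the external-results layout
#'
#' @param stats data.frame from one of the differential tests.
#' @param path output TSV.
#' @export
write_gene_stats <- function(stats, path) {
  out <- data.frame(gene = stats$gene, log2FoldChange = stats$effect,
                    pvalue = stats$p_value)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
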