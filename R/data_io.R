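#' Construct an omics matrix
#'
#' Lightweight container for one omics layer: a numeric genes-by-samples
#' matrix carrying its layer of origin and the kind of values it holds.
#'
#' @param values numeric matrix, rows = genes (unique symbols), columns =
#'   samples; dimnames mandatory.
#' @param layer `"expression"` or `"methylation"`.
#' @param value_kind `"raw_counts"`, `"continuous"` or `"zscored"`.
#' @return an `omics_matrix` (a classed numeric matrix).
#' @export
omics_matrix <- function(values,
                         layer = c("expression", "methylation"),
                         value_kind = c("raw_counts", "continuous", "zscored")) {
  layer <- match.arg(layer)
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry gene rownames and sample colnames")
  }
  rownames(values) <- trimws(rownames(values))
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))]
    stop("duplicate gene ids: ", paste(unique(dup), collapse = ", "))
  }
  structure(values, layer = layer, value_kind = value_kind,
            class = c("omics_matrix", class(values)))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> layer=%s kind=%s: %d genes x %d samples\n",
              attr(x, "layer"), attr(x, "value_kind"), nrow(x), ncol(x)))
  if (anyNA(x)) cat(sprintf("  %d missing values\n", sum(is.na(x))))
  invisible(x)
}

#' @export
`[.omics_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    omics_matrix(out, attr(x, "layer"), attr(x, "value_kind"))
  } else {
    out
  }
}

omics_layer <- function(x) attr(x, "layer")
omics_kind <- function(x) attr(x, "value_kind")

#' Read a genes-by-samples TSV matrix
#'
#' Expects a header row of sample ids and gene symbols in the first column.
#' Tokens in `na` are read as missing; any other non-numeric cell is an error.
#'
#' @param path TSV file.
#' @inheritParams omics_matrix
#' @param na character tokens treated as missing.
#' @return an [omics_matrix()].
#' @export
read_omics <- function(path, layer = c("expression", "methylation"),
                       value_kind = NULL, na = c("NA", "NaN", "")) {
  layer <- match.arg(layer)
  if (is.null(value_kind)) {
    value_kind <- if (layer == "expression") "raw_counts" else "continuous"
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, na.strings = na,
                           colClasses = "character", quote = "")
  if (ncol(tab) < 2L) stop("malformed header: need a gene column plus >=1 sample")
  genes <- trimws(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- is.na(num) & !is.na(vals)
  if (any(bad)) {
    stop("non-numeric cell(s) at gene(s): ",
         paste(unique(genes[which(rowSums(bad) > 0)]), collapse = ", "))
  }
  dimnames(num) <- list(genes, colnames(tab)[-1L])
  n_missing <- sum(is.na(num))
  if (n_missing > 0L) {
    message(sprintf("read_omics: %d missing value(s) in %s", n_missing, path))
  }
  omics_matrix(num, layer, value_kind)
}

#' Write an omics matrix as TSV
#'
#' Inverse of [read_omics()]; values round-trip within numeric print precision.
#' @param x an `omics_matrix`.
#' @param path output file.
#' @export
write_omics <- function(x, path) {
  df <- data.frame(gene = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one tab-separated line per set — id, description, then
#' member genes. Empty member tokens are dropped with a warning; duplicate set
#' ids and lines with fewer than three fields are errors.
#'
#' @param path GMT file.
#' @return named list of character vectors (member genes), with set
#'   descriptions in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(which(nf < 3L), collapse = ", "))
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate pathway id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) {
    members <- trimws(p[-(1:2)])
    if (any(!nzchar(members))) {
      warning("empty member gene token(s) dropped", call. = FALSE)
      members <- members[nzchar(members)]
    }
    members
  })
  if (any(lengths(sets) == 0L)) stop("pathway with no member genes")
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(desc, ids)
  sets
}

#' Read a directed gene-gene edge list
#'
#' Two tab-separated columns, source and target gene symbol; an optional third
#' column is ignored. Duplicate edges are collapsed (simple graph); self-loops
#' are kept but reported.
#'
#' @param path edge-list TSV (no header).
#' @return a directed [igraph::igraph] graph.
#' @export
read_edge_list <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character", quote = "")
  if (ncol(tab) < 2L) stop("edge list needs two columns (source, target)")
  edges <- data.frame(from = trimws(tab[[1L]]), to = trimws(tab[[2L]]))
  n_loops <- sum(edges$from == edges$to)
  if (n_loops > 0L) {
    message(sprintf("read_edge_list: %d self-loop(s) in %s", n_loops, path))
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE)
}

#' Read a clinical table
#'
#' @param path TSV with columns `sample_id`, `vital_status` (1 = alive,
#'   0 = deceased) and `survival_days`.
#' @return data.frame with those columns.
#' @export
read_clinical <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           na.strings = c("NA", ""))
  need <- c("sample_id", "vital_status", "survival_days")
  missing <- setdiff(need, names(tab))
  if (length(missing)) stop("clinical table missing column(s): ",
                            paste(missing, collapse = ", "))
  tab[need]
}

#' Derive good/poor survival groups from clinical data
#'
#' Samples with missing or negative survival days are removed, as are living
#' patients whose follow-up is shorter than the threshold (their eventual group
#' is unknown). The remainder split into `good` (> threshold days) and `poor`
#' (<= threshold days).
#'
#' @param clinical data.frame as from [read_clinical()].
#' @param threshold_days group boundary; default 1095 days (3 years).
#' @return data.frame with columns `sample_id`, `group` (factor good/poor).
#' @export
derive_groups <- function(clinical, threshold_days = 1095) {
  need <- c("sample_id", "vital_status", "survival_days")
  stopifnot(all(need %in% names(clinical)))
  days <- as.numeric(clinical$survival_days)
  alive <- as.integer(clinical$vital_status) == 1L
  keep <- !is.na(days) & days >= 0 & !(alive & days < threshold_days)
  out <- clinical[keep, , drop = FALSE]
  if (!nrow(out)) stop("no samples remain after survival filtering")
  data.frame(
    sample_id = as.character(out$sample_id),
    group = factor(ifelse(as.numeric(out$survival_days) > threshold_days,
                          "good", "poor"),
                   levels = c("good", "poor")),
    stringsAsFactors = FALSE
  )
}

#' Drop genes that are mostly unexpressed
#'
#' A gene is removed iff strictly more than half of its samples have a zero
#' count; a gene with exactly half zeros is kept.
#'
#' @param x expression `omics_matrix` of raw counts.
#' @return filtered `omics_matrix`.
#' @export
filter_low_expression <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  if (omics_layer(x) != "expression") stop("filter applies to the expression layer")
  keep <- rowSums(unclass(x) == 0, na.rm = TRUE) <= ncol(x) / 2
  x[keep, , drop = FALSE]
}

#' Impute missing values with per-sample medians
#'
#' Each missing cell is replaced by the median of the observed values of the
#' same sample (column); `margin = "gene"` switches to row-wise medians.
#'
#' @param x `omics_matrix` possibly containing `NA`s.
#' @param margin `"sample"` (default, column-wise) or `"gene"`.
#' @return complete `omics_matrix`.
#' @export
impute_median <- function(x, margin = c("sample", "gene")) {
  margin <- match.arg(margin)
  stopifnot(inherits(x, "omics_matrix"))
  vals <- unclass(x)
  n_missing <- sum(is.na(vals))
  if (n_missing == 0L) return(x)
  if (margin == "sample") {
    for (j in seq_len(ncol(vals))) {
      miss <- is.na(vals[, j])
      if (!any(miss)) next
      if (all(miss)) stop("sample '", colnames(vals)[j], "' is entirely missing")
      vals[miss, j] <- stats::median(vals[!miss, j])
    }
  } else {
    for (i in seq_len(nrow(vals))) {
      miss <- is.na(vals[i, ])
      if (!any(miss)) next
      if (all(miss)) stop("gene '", rownames(vals)[i], "' is entirely missing")
      vals[i, miss] <- stats::median(vals[i, !miss])
    }
  }
  message(sprintf("impute_median: imputed %d cell(s)", n_missing))
  omics_matrix(vals, omics_layer(x), omics_kind(x))
}

#' Standardise each gene across samples
#'
#' Per-gene centring and scaling so that every row has mean 0 and standard
#' deviation 1 across samples.
#'
#' @param x complete `omics_matrix`.
#' @param sd_method `"n-1"` (sample sd, default) or `"n"` (population sd).
#' @return `omics_matrix` with `value_kind = "zscored"`.
#' @export
zscore_genes <- function(x, sd_method = c("n-1", "n")) {
  sd_method <- match.arg(sd_method)
  stopifnot(inherits(x, "omics_matrix"))
  vals <- unclass(x)
  if (anyNA(vals)) stop("zscore_genes requires a complete matrix; impute first")
  m <- rowMeans(vals)
  centred <- vals - m
  ss <- rowSums(centred^2)
  denom <- if (sd_method == "n-1") ncol(vals) - 1L else ncol(vals)
  s <- sqrt(ss / denom)
  if (any(s == 0)) {
    stop("zero-variance gene(s): ",
         paste(rownames(vals)[s == 0], collapse = ", "))
  }
  omics_matrix(centred / s, omics_layer(x), "zscored")
}
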