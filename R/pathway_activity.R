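#' Differential member nodes of a pathway
#'
#' A graph node (gene, layer) qualifies as a differential member of a pathway
#' iff the gene belongs to the pathway's gene set, the node exists in the
#' integrated graph, and its layer-specific p-value is below `alpha`. A gene
#' differential in both layers contributes both nodes.
#'
#' @param genes character vector, the pathway's member gene set.
#' @param gene_stats combined per-(gene, layer) statistics data.frame.
#' @param graph an `integrated_graph`.
#' @param alpha significance threshold on w_g; default 0.05.
#' @return data.frame with columns node, gene, layer (possibly 0 rows).
#' @export
select_differential_members <- function(genes, gene_stats, graph, alpha = 0.05) {
  stopifnot(inherits(graph, "integrated_graph"))
  nodes <- graph$nodes
  key <- paste(gene_stats$gene, gene_stats$layer, sep = "@")
  p <- stats::setNames(gene_stats$p_value, key)
  sel <- nodes$gene %in% genes & nodes$node %in% names(p) & p[nodes$node] < alpha
  sel[is.na(sel)] <- FALSE
  nodes[sel, , drop = FALSE]
}

#' Effect score of a differential gene node
#'
#' Expression nodes score by their log2 fold change; methylation nodes only by
#' the direction of change, sign(t) in \{-1, 0, +1\}.
#'
#' @param gene_stats data.frame with columns layer and effect.
#' @return numeric vector of scores, one per row.
#' @export
gene_score <- function(gene_stats) {
  ifelse(gene_stats$layer == "expression",
         gene_stats$effect,
         sign(gene_stats$effect))
}

# layer-matched z-score rows for a set of member nodes, columns = samples
member_z <- function(members, expr_z, meth_z, samples) {
  z <- matrix(NA_real_, nrow(members), length(samples),
              dimnames = list(members$node, samples))
  is_e <- members$layer == "expression"
  if (any(is_e)) z[is_e, ] <- unclass(expr_z)[members$gene[is_e], samples, drop = FALSE]
  if (any(!is_e)) z[!is_e, ] <- unclass(meth_z)[members$gene[!is_e], samples, drop = FALSE]
  z
}

#' Per-sample activity of one pathway
#'
#' a(P) = sum_i Winf(g_i) * score(g_i) * z(g_i, s) / sqrt(sum_i Winf(g_i)^2),
#' summed over the pathway's differential member nodes, with z drawn from each
#' member's own layer. Degree-0 homogeneous in the walk weights and linear in
#' the z-profiles.
#'
#' @param members data.frame from [select_differential_members()].
#' @param w_inf stationary node weights ([random_walk()]).
#' @param gene_stats combined statistics (for the effect scores).
#' @param expr_z,meth_z z-scored `omics_matrix` objects.
#' @return named numeric vector over samples, or `NULL` (with a warning) if
#'   all member weights are zero.
#' @export
pathway_activity <- function(members, w_inf, gene_stats, expr_z, meth_z) {
  if (!nrow(members)) stop("pathway has no differential members")
  samples <- intersect(colnames(expr_z), colnames(meth_z))
  w <- as.numeric(w_inf[members$node])
  if (anyNA(w)) stop("member node missing from walk weights")
  denom <- sqrt(sum(w^2))
  if (denom == 0) {
    warning("all member walk weights are zero; pathway dropped", call. = FALSE)
    return(NULL)
  }
  key <- paste(gene_stats$gene, gene_stats$layer, sep = "@")
  s <- gene_score(gene_stats)[match(members$node, key)]
  z <- member_z(members, expr_z, meth_z, samples)
  a <- as.numeric(crossprod(z, w * s)) / denom
  stats::setNames(a, samples)
}

#' Pathway-activity profile matrix
#'
#' Applies [select_differential_members()] and [pathway_activity()] to every
#' pathway, keeping one row per pathway that has at least one differential
#' member node with non-zero walk weight.
#'
#' @param pathways named list of gene sets ([read_gmt()]).
#' @param gene_stats combined per-(gene, layer) statistics.
#' @param w_inf stationary node weights.
#' @param expr_z,meth_z z-scored `omics_matrix` objects (shared sample set).
#' @param alpha significance threshold for membership; default 0.05.
#' @return pathways x samples matrix with a per-pathway metadata data.frame in
#'   `attr(, "meta")` (pathway_id, n_total, n_de, n_dm) and the member tables
#'   in `attr(, "members")`.
#' @export
build_activity_matrix <- function(pathways, gene_stats, w_inf, expr_z, meth_z,
                                  alpha = 0.05) {
  samples <- intersect(colnames(expr_z), colnames(meth_z))
  if (!length(samples)) stop("expression and methylation share no samples")
  graph_nodes <- data.frame(node = names(w_inf),
                            gene = sub("@.*$", "", names(w_inf)),
                            layer = sub("^.*@", "", names(w_inf)))
  fake_graph <- structure(list(nodes = graph_nodes,
                               edges = data.frame(), mode = "all"),
                          class = "integrated_graph")
  rows <- list()
  meta <- list()
  members_kept <- list()
  for (id in names(pathways)) {
    members <- select_differential_members(pathways[[id]], gene_stats,
                                           fake_graph, alpha)
    if (!nrow(members)) next
    a <- suppressWarnings(
      pathway_activity(members, w_inf, gene_stats, expr_z, meth_z)
    )
    if (is.null(a)) next
    rows[[id]] <- a[samples]
    meta[[id]] <- data.frame(pathway_id = id,
                             n_total = length(pathways[[id]]),
                             n_de = sum(members$layer == "expression"),
                             n_dm = sum(members$layer == "methylation"))
    members_kept[[id]] <- members
  }
  if (!length(rows)) stop("no pathway has differential members")
  act <- do.call(rbind, rows)
  colnames(act) <- samples
  attr(act, "meta") <- do.call(rbind, c(meta, list(make.row.names = FALSE)))
  attr(act, "members") <- members_kept
  class(act) <- c("pathway_activity", class(act))
  act
}

#' @export
print.pathway_activity <- function(x, ...) {
  cat(sprintf("<pathway_activity> %d pathways x %d samples\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Write a pathway-activity matrix and its metadata
#'
#' @param activity matrix from [build_activity_matrix()].
#' @param path activity TSV; the metadata table goes to `meta_path` when given.
#' @param meta_path optional TSV for (pathway_id, n_total, n_de, n_dm).
#' @export
write_activity <- function(activity, path, meta_path = NULL) {
  df <- data.frame(pathway_id = rownames(activity),
                   as.matrix(activity)[, , drop = FALSE], check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- attr(activity, "meta")
  if (!is.null(meta_path) && !is.null(meta)) {
    utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
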