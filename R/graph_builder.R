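node_id <- function(gene, layer) paste0(gene, "@", layer)

#' Test whether a gene's methylation anti-correlates with its expression
#'
#' Pearson correlation with the two-sided significance test based on
#' t = r * sqrt((n - 2) / (1 - r^2)); the gene-pair is kept (eligible for a
#' cross-layer edge) iff r < 0 and p < alpha.
#'
#' @param x,y equal-length numeric vectors (n >= 3), e.g. one gene's
#'   expression and methylation values across samples.
#' @param alpha significance level; default 0.05.
#' @return list with elements `r`, `p`, `keep`.
#' @export
anticorrelation_test <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: correlation undefined, keep = FALSE", call. = FALSE)
    return(list(r = NA_real_, p = NA_real_, keep = FALSE))
  }
  n <- length(x)
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, keep = r < 0 && p < alpha)
}

#' Build the two-layer integrated gene-gene graph
#'
#' Nodes are (gene, layer) pairs: every base-graph gene present in the
#' expression matrix contributes an expression node, and likewise for
#' methylation. The base graph's directed edges are copied into each layer
#' (restricted to genes present in that layer). Cross-layer edges link the two
#' nodes of the same gene, in both directions: with `mode = "all"` every gene
#' present in both layers is linked; with `mode = "anti"` only genes whose
#' expression and methylation profiles are significantly anti-correlated
#' ([anticorrelation_test()]).
#'
#' @param base_graph directed [igraph::igraph] of gene-gene interactions.
#' @param expr,meth `omics_matrix` objects sharing sample ids.
#' @param mode `"all"` or `"anti"`.
#' @param alpha significance level for the anti-correlation gate.
#' @return an `integrated_graph`: list with `nodes` (data.frame node, gene,
#'   layer) and `edges` (data.frame from, to, type).
#' @export
build_integrated_graph <- function(base_graph, expr, meth,
                                   mode = c("all", "anti"), alpha = 0.05) {
  mode <- match.arg(mode)
  base_genes <- igraph::V(base_graph)$name
  ge <- intersect(base_genes, rownames(expr))
  gm <- intersect(base_genes, rownames(meth))
  if (!length(ge)) stop("no base-graph gene found in the expression layer")
  if (!length(gm)) stop("no base-graph gene found in the methylation layer")

  base_edges <- igraph::as_data_frame(base_graph, what = "edges")[, 1:2]
  names(base_edges) <- c("from", "to")

  e_expr <- base_edges[base_edges$from %in% ge & base_edges$to %in% ge, , drop = FALSE]
  e_meth <- base_edges[base_edges$from %in% gm & base_edges$to %in% gm, , drop = FALSE]

  overlap <- intersect(ge, gm)
  if (mode == "anti" && length(overlap)) {
    common <- intersect(colnames(expr), colnames(meth))
    if (length(common) < 3L) stop("need >= 3 shared samples for correlation gating")
    keep <- vapply(overlap, function(g) {
      suppressWarnings(
        anticorrelation_test(unclass(expr)[g, common],
                             unclass(meth)[g, common], alpha)$keep
      )
    }, logical(1))
    overlap <- overlap[keep]
  }

  edges <- rbind(
    if (nrow(e_expr)) data.frame(from = node_id(e_expr$from, "expression"),
                                 to = node_id(e_expr$to, "expression"),
                                 type = "within_expr"),
    if (nrow(e_meth)) data.frame(from = node_id(e_meth$from, "methylation"),
                                 to = node_id(e_meth$to, "methylation"),
                                 type = "within_meth"),
    if (length(overlap)) data.frame(
      from = c(node_id(overlap, "expression"), node_id(overlap, "methylation")),
      to = c(node_id(overlap, "methylation"), node_id(overlap, "expression")),
      type = "cross")
  )
  if (is.null(edges)) edges <- data.frame(from = character(), to = character(),
                                          type = character())

  nodes <- rbind(
    data.frame(node = node_id(ge, "expression"), gene = ge, layer = "expression"),
    data.frame(node = node_id(gm, "methylation"), gene = gm, layer = "methylation")
  )
  structure(list(nodes = nodes, edges = edges, mode = mode),
            class = "integrated_graph")
}

#' @export
print.integrated_graph <- function(x, ...) {
  cat(sprintf("<integrated_graph> %d nodes (%d expression, %d methylation), %d edges (%d cross), mode=%s\n",
              nrow(x$nodes), sum(x$nodes$layer == "expression"),
              sum(x$nodes$layer == "methylation"), nrow(x$edges),
              sum(x$edges$type == "cross"), x$mode))
  invisible(x)
}

#' Row-normalised transition matrix of an integrated graph
#'
#' M\[i, j\] = 1 / outdegree(i) for each edge i -> j. Rows of nodes with no
#' outgoing edge (dangling nodes) are left all-zero; the walk re-injects their
#' mass through the restart vector (see [random_walk()]).
#'
#' @param graph an `integrated_graph`.
#' @return sparse [Matrix::dgCMatrix-class] with node dimnames.
#' @export
transition_matrix <- function(graph) {
  stopifnot(inherits(graph, "integrated_graph"))
  nodes <- graph$nodes$node
  n <- length(nodes)
  if (!n) stop("graph has no nodes")
  idx <- stats::setNames(seq_len(n), nodes)
  i <- idx[graph$edges$from]
  j <- idx[graph$edges$to]
  if (anyNA(i) || anyNA(j)) stop("edge endpoint not in node set")
  outdeg <- tabulate(i, nbins = n)
  M <- Matrix::sparseMatrix(i = i, j = j, x = 1 / outdeg[i], dims = c(n, n),
                            dimnames = list(nodes, nodes))
  M
}

#' Export an integrated graph as a 3-column TSV
#'
#' Columns: source node (gene@layer), target node, edge type
#' (within_expr / within_meth / cross).
#' @param graph an `integrated_graph`.
#' @param path output file.
#' @export
write_integrated_graph <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE,
                     col.names = c("source_node", "target_node", "edge_type"))
  invisible(path)
}
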