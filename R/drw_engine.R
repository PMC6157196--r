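#' Initial node weights from differential p-values
#'
#' Each node's p-value w_g is transformed to -log(w_g + eps), min-max scaled to
#' \[0, 1\] separately within each layer, then the whole vector is L1-normalised
#' to a probability distribution W0. Nodes without a statistic get p = 1
#' (weight at the layer minimum); a layer whose transformed weights are all
#' equal is set to the constant 0.5 before the global L1 step, which makes it
#' uniform.
#'
#' @param gene_stats data.frame with columns gene, layer, p_value (rows from
#'   [welch_t_test()], [nb_wald_test()] or [load_external_stats()], possibly
#'   concatenated across layers).
#' @param graph an `integrated_graph`.
#' @param eps additive offset inside the log; default 2.2e-16.
#' @param minmax_scope `"layer"` (default) scales each layer separately;
#'   `"global"` scales all nodes together.
#' @return named numeric vector over graph nodes, summing to 1, with
#'   `attr(, "stage") == "initial"`.
#' @export
initial_weights <- function(gene_stats, graph, eps = 2.2e-16,
                            minmax_scope = c("layer", "global")) {
  minmax_scope <- match.arg(minmax_scope)
  stopifnot(inherits(graph, "integrated_graph"))
  nodes <- graph$nodes
  key <- paste(gene_stats$gene, gene_stats$layer, sep = "@")
  if (anyDuplicated(key)) stop("duplicate (gene, layer) rows in gene_stats")
  p <- stats::setNames(gene_stats$p_value, key)[nodes$node]
  n_missing <- sum(is.na(p))
  if (n_missing > 0L) {
    message(sprintf("initial_weights: %d node(s) without a statistic; p set to 1",
                    n_missing))
    p[is.na(p)] <- 1
  }
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  v <- -log(p + eps)
  scale_group <- if (minmax_scope == "layer") nodes$layer else rep("all", nrow(nodes))
  for (lev in unique(scale_group)) {
    sel <- scale_group == lev
    rng <- range(v[sel])
    if (rng[1] == rng[2]) {
      warning("all weights equal within scope '", lev,
              "'; set to uniform", call. = FALSE)
      v[sel] <- 0.5
    } else {
      v[sel] <- (v[sel] - rng[1]) / (rng[2] - rng[1])
    }
  }
  total <- sum(v)
  w0 <- if (total == 0) rep(1 / nrow(nodes), nrow(nodes)) else v / total
  names(w0) <- nodes$node
  attr(w0, "stage") <- "initial"
  w0
}

#' Directed random walk with restart
#'
#' Power iteration of W_{t+1} = (1 - r) M^T W_t + r W0 until the L1 change
#' drops below `tol`. Probability mass sitting on dangling nodes (all-zero
#' rows of M) would leak out of the system; it is re-injected proportionally
#' to W0 at every step, so the iterates remain probability distributions.
#'
#' @param M row-normalised transition matrix ([transition_matrix()]).
#' @param w0 initial distribution ([initial_weights()]), L1-normalised.
#' @param restart_prob restart probability r in (0, 1\]; default 0.7.
#' @param tol L1 convergence threshold; default 1e-10.
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   residual.
#' @param trace if `TRUE`, attach per-iteration L1 residuals and vector sums
#'   as attributes `"residuals"` and `"sums"`.
#' @return stationary weight vector W_inf (named, sums to 1), with
#'   `attr(, "stage") == "stationary"` and `attr(, "iterations")`.
#' @export
random_walk <- function(M, w0, restart_prob = 0.7, tol = 1e-10,
                        max_iter = 10000L, trace = FALSE) {
  r <- restart_prob
  stopifnot(r > 0, r <= 1)
  if (abs(sum(w0) - 1) > 1e-8) stop("w0 must be L1-normalised")
  w0 <- as.numeric(w0) |> stats::setNames(rownames(M))
  if (r == 1) {
    out <- w0
    attr(out, "stage") <- "stationary"
    attr(out, "iterations") <- 0L
    return(out)
  }
  Mt <- Matrix::t(M)
  dangling <- Matrix::rowSums(M) == 0
  w <- w0
  resids <- numeric(0)
  sums <- numeric(0)
  for (it in seq_len(max_iter)) {
    w_new <- (1 - r) * as.numeric(Mt %*% w) + r * w0 +
      (1 - r) * sum(w[dangling]) * w0
    resid <- sum(abs(w_new - w))
    w <- stats::setNames(w_new, names(w0))
    if (trace) {
      resids <- c(resids, resid)
      sums <- c(sums, sum(w))
    }
    if (resid < tol) {
      attr(w, "stage") <- "stationary"
      attr(w, "iterations") <- it
      if (trace) {
        attr(w, "residuals") <- resids
        attr(w, "sums") <- sums
      }
      return(w)
    }
  }
  stop(sprintf("random walk did not converge in %d iterations (residual %.3e)",
               max_iter, resid))
}

#' Closed-form stationary distribution of the restart walk
#'
#' Solves (I - (1 - r) M^T - (1 - r) W0 d^T) W = r W0 directly, where d
#' indicates dangling rows of M (their mass is folded into the restart term
#' exactly as [random_walk()] does iteratively). Intended as an exact
#' reference for the power iteration on small graphs.
#'
#' @inheritParams random_walk
#' @return named stationary weight vector.
#' @export
stationary_solve <- function(M, w0, restart_prob = 0.7) {
  r <- restart_prob
  stopifnot(r > 0, r <= 1)
  w0 <- as.numeric(w0) |> stats::setNames(rownames(M))
  if (r == 1) {
    attr(w0, "stage") <- "stationary"
    return(w0)
  }
  n <- length(w0)
  dangling <- as.numeric(Matrix::rowSums(M) == 0)
  A <- diag(n) - (1 - r) * as.matrix(Matrix::t(M)) -
    (1 - r) * outer(as.numeric(w0), dangling)
  w <- tryCatch(solve(A, r * as.numeric(w0)),
                error = function(e) stop("singular stationary system: ",
                                         conditionMessage(e)))
  w <- stats::setNames(w, names(w0))
  attr(w, "stage") <- "stationary"
  w
}

#' Write node weights as a two-column TSV
#'
#' @param w named weight vector.
#' @param path output file.
#' @export
write_node_weights <- function(w, path) {
  utils::write.table(data.frame(node = names(w), weight = as.numeric(w)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
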