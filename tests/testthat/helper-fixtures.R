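# fixture builders shared across test files; everything is generated in code

toy_omics <- function(values, layer = "expression", kind = NULL,
                      genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  if (is.null(kind)) kind <- if (layer == "expression") "raw_counts" else "continuous"
  omics_matrix(values, layer, kind)
}

toy_groups <- function(samples, poor) {
  stats::setNames(ifelse(poor, "poor", "good"), samples)
}

# integrated_graph built directly from node/edge tables (bypasses omics input)
make_integrated_graph <- function(genes, edges,
                                  layers = rep("expression", length(genes))) {
  nodes <- data.frame(node = paste0(genes, "@", layers),
                      gene = genes, layer = layers)
  structure(list(nodes = nodes, edges = edges, mode = "all"),
            class = "integrated_graph")
}

# random single-layer graph + normalised w0, for walk tests
random_walk_instance <- function(n, p_edge = 0.2, seed = 1) {
  set.seed(seed)
  genes <- sprintf("n%03d", seq_len(n))
  ids <- paste0(genes, "@expression")
  pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  edges <- pairs[runif(nrow(pairs)) < p_edge, , drop = FALSE]
  edges$type <- "within_expr"
  g <- make_integrated_graph(genes, edges)
  w0 <- runif(n)
  w0 <- w0 / sum(w0)
  names(w0) <- g$nodes$node
  list(graph = g, M = transition_matrix(g), w0 = w0)
}

# independent closed-form Welch t-test (oracle; the package wraps stats::t.test)
welch_oracle <- function(x1, x0) {
  n1 <- length(x1); n0 <- length(x0)
  v1 <- var(x1); v0 <- var(x0)
  se2 <- v1 / n1 + v0 / n0
  t <- (mean(x1) - mean(x0)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# naive dense power iteration written independently of random_walk()
naive_walk <- function(M, w0, r, iters = 5000) {
  Md <- as.matrix(M)
  dang <- rowSums(Md) == 0
  w <- as.numeric(w0)
  for (i in seq_len(iters)) {
    w <- (1 - r) * as.numeric(t(Md) %*% w) + r * as.numeric(w0) +
      (1 - r) * sum(w[dang]) * as.numeric(w0)
  }
  w
}
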