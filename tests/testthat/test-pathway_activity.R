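# shared toy universe: 3 genes in both layers, hand-set stats and weights
toy_universe <- function(n_samples = 4, seed = 51) {
  set.seed(seed)
  genes <- c("A", "B", "C")
  layers <- rep(c("expression", "methylation"), each = 3)
  g <- make_integrated_graph(rep(genes, 2),
                             data.frame(from = character(), to = character(),
                                        type = character()),
                             layers = layers)
  st <- data.frame(
    gene = rep(genes, 2), layer = layers,
    p_value = c(0.01, 0.20, 0.30, 0.20, 0.01, 0.04),
    effect = c(1.7, -0.5, 0.8, -3.2, 2.5, -1.1),
    test = rep(c("nb_wald", "welch_t"), each = 3))
  ez <- toy_omics(matrix(rnorm(3 * n_samples), 3, n_samples), "expression",
                  kind = "zscored", genes = genes)
  mz <- toy_omics(matrix(rnorm(3 * n_samples), 3, n_samples), "methylation",
                  kind = "zscored", genes = genes)
  w <- setNames(runif(6, 0.05, 0.3), g$nodes$node)
  list(graph = g, stats = st, expr_z = ez, meth_z = mz, w = w)
}

test_that("differential membership needs pathway, graph node and p < alpha", {
  u <- toy_universe()
  # pathway {A, B}: A qualifies in expression (p=.01), B in methylation (p=.01)
  m <- select_differential_members(c("A", "B"), u$stats, u$graph)
  expect_setequal(m$node, c("A@expression", "B@methylation"))
  # all members above alpha -> empty
  m2 <- select_differential_members("C", u$stats, u$graph, alpha = 0.01)
  expect_equal(nrow(m2), 0)
  # gene differential in both layers contributes two nodes
  m3 <- select_differential_members("C", u$stats, u$graph, alpha = 0.5)
  expect_setequal(m3$node, c("C@expression", "C@methylation"))

  # brute-force triple filter on a randomised instance
  set.seed(52)
  st <- u$stats
  st$p_value <- runif(6)
  pw <- sample(c("A", "B", "C"), 2)
  got <- select_differential_members(pw, st, u$graph, 0.3)$node
  oracle <- character(0)
  for (i in seq_len(nrow(st))) {
    node <- paste0(st$gene[i], "@", st$layer[i])
    if (st$gene[i] %in% pw && node %in% u$graph$nodes$node &&
        st$p_value[i] < 0.3) {
      oracle <- c(oracle, node)
    }
  }
  expect_setequal(got, oracle)
})

test_that("gene scores are log2FC for expression and sign(t) for methylation", {
  st <- data.frame(layer = c("expression", "methylation", "methylation",
                             "methylation"),
                   effect = c(1.7, -3.2, 0, 4.1))
  expect_equal(gene_score(st), c(1.7, -1, 0, 1))
})

test_that("single-member activity reduces to score * z", {
  u <- toy_universe()
  m <- select_differential_members("A", u$stats, u$graph) # A@expression only
  a <- pathway_activity(m, u$w, u$stats, u$expr_z, u$meth_z)
  expect_equal(unname(a), 1.7 * unname(unclass(u$expr_z)["A", ]),
               tolerance = 1e-12)
})

test_that("activity matches a direct summation oracle and its algebra", {
  u <- toy_universe()
  m <- select_differential_members(c("A", "B", "C"), u$stats, u$graph,
                                   alpha = 0.25)
  expect_gte(nrow(m), 3)
  a <- pathway_activity(m, u$w, u$stats, u$expr_z, u$meth_z)

  # independent loop implementation
  oracle <- numeric(ncol(u$expr_z))
  for (i in seq_len(nrow(m))) {
    row <- u$stats[u$stats$gene == m$gene[i] & u$stats$layer == m$layer[i], ]
    s <- if (row$layer == "expression") row$effect else sign(row$effect)
    z <- if (row$layer == "expression") unclass(u$expr_z)[row$gene, ] else
      unclass(u$meth_z)[row$gene, ]
    oracle <- oracle + u$w[m$node[i]] * s * z
  }
  oracle <- oracle / sqrt(sum(u$w[m$node]^2))
  expect_equal(unname(a), unname(oracle), tolerance = 1e-12)

  # degree-0 homogeneity in the walk weights
  a2 <- pathway_activity(m, u$w * 7.3, u$stats, u$expr_z, u$meth_z)
  expect_equal(a, a2, tolerance = 1e-12)

  # linearity in z
  u2 <- u
  ez_b <- toy_omics(matrix(rnorm(12), 3, 4), "expression", kind = "zscored",
                    genes = c("A", "B", "C"))
  mz_b <- toy_omics(matrix(rnorm(12), 3, 4), "methylation", kind = "zscored",
                    genes = c("A", "B", "C"))
  sum_e <- toy_omics(unclass(u$expr_z) + unclass(ez_b), "expression",
                     kind = "zscored", genes = c("A", "B", "C"))
  sum_m <- toy_omics(unclass(u$meth_z) + unclass(mz_b), "methylation",
                     kind = "zscored", genes = c("A", "B", "C"))
  expect_equal(pathway_activity(m, u$w, u$stats, sum_e, sum_m),
               pathway_activity(m, u$w, u$stats, u$expr_z, u$meth_z) +
                 pathway_activity(m, u$w, u$stats, ez_b, mz_b),
               tolerance = 1e-12)

  # flipping all member scores flips the activity sign exactly
  st_flip <- u$stats
  st_flip$effect <- -st_flip$effect
  expect_equal(pathway_activity(m, u$w, st_flip, u$expr_z, u$meth_z), -a,
               tolerance = 1e-12)

  # all-zero member weights drop the pathway
  w0 <- u$w
  w0[m$node] <- 0
  expect_warning(res <- pathway_activity(m, w0, u$stats, u$expr_z, u$meth_z),
                 "zero")
  expect_null(res)
})

test_that("activity matrix composes the per-pathway operations", {
  u <- toy_universe()
  pdb <- list(PW1 = c("A", "B"), PW2 = "C", PW_empty = "Z")
  act <- build_activity_matrix(pdb, u$stats, u$w, u$expr_z, u$meth_z,
                               alpha = 0.05)
  expect_setequal(rownames(act), c("PW1", "PW2"))
  m1 <- select_differential_members(pdb$PW1, u$stats, u$graph)
  expect_equal(unname(act["PW1", ]),
               unname(pathway_activity(m1, u$w, u$stats, u$expr_z, u$meth_z)),
               tolerance = 1e-12)
  meta <- attr(act, "meta")
  expect_equal(meta$n_de[meta$pathway_id == "PW1"], 1)
  expect_equal(meta$n_dm[meta$pathway_id == "PW1"], 1)
  expect_equal(meta$n_total[meta$pathway_id == "PW1"], 2)

  # permuting sample columns permutes activities identically
  perm <- c(3, 1, 4, 2)
  act_p <- build_activity_matrix(pdb, u$stats, u$w,
                                 u$expr_z[, perm], u$meth_z[, perm])
  expect_equal(act_p[, colnames(act)], act[, colnames(act)],
               ignore_attr = TRUE, tolerance = 1e-12)

  # a pathway set with no differential members at all is an error
  expect_error(build_activity_matrix(list(P = "Z"), u$stats, u$w,
                                     u$expr_z, u$meth_z), "no pathway")
})

test_that("activity matrices serialise with their metadata", {
  u <- toy_universe()
  act <- build_activity_matrix(list(PW1 = c("A", "B")), u$stats, u$w,
                               u$expr_z, u$meth_z)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_activity(act, p1, p2)
  tab <- read.delim(p1, check.names = FALSE)
  expect_equal(as.numeric(tab[1, -1]), unname(act["PW1", ]), tolerance = 1e-6)
  meta <- read.delim(p2)
  expect_identical(names(meta), c("pathway_id", "n_total", "n_de", "n_dm"))
})
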