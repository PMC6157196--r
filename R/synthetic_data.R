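#' Simulate overlapping pathways and a directed base gene-gene graph
#'
#' Draws `n_pathways` gene sets (sizes uniform in `size_range`) from a pool of
#' `n_genes` genes, so sets overlap by chance, then wires directed edges:
#' each ordered within-pathway gene pair becomes an edge with probability
#' `edge_density`, and sparse inter-pathway edges are added at
#' `edge_density * inter_factor`. The construction mimics the shape of a
#' curated pathway-derived interaction graph: dense locally, sparse globally.
#'
#' @param n_genes size of the gene pool (symbols `g0001`...).
#' @param n_pathways number of gene sets.
#' @param size_range integer range of pathway sizes; default c(10, 20).
#' @param edge_density within-pathway directed edge probability; default 0.15.
#' @param inter_factor multiplier for cross-pathway edge density; default 0.02.
#' @param seed RNG seed.
#' @return list with `pathways` (named list of gene vectors) and `graph`
#'   (directed [igraph::igraph] over all pool genes).
#' @export
simulate_pathways <- function(n_genes = 500L, n_pathways = 50L,
                              size_range = c(10L, 20L), edge_density = 0.15,
                              inter_factor = 0.02, seed = 1L) {
  stopifnot(n_genes >= max(size_range), n_pathways >= 1L)
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    sizes <- sample(size_range[1L]:size_range[2L], n_pathways, replace = TRUE)
    pathways <- lapply(sizes, function(s) sample(genes, s))
    names(pathways) <- sprintf("P%03d", seq_len(n_pathways))
    edges <- list()
    for (pw in pathways) {
      pairs <- expand.grid(from = pw, to = pw, stringsAsFactors = FALSE)
      pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
      keep <- stats::runif(nrow(pairs)) < edge_density
      if (any(keep)) edges[[length(edges) + 1L]] <- pairs[keep, , drop = FALSE]
    }
    n_inter <- round(edge_density * inter_factor * n_genes^2 / 100)
    if (n_inter > 0L) {
      edges[[length(edges) + 1L]] <- data.frame(
        from = sample(genes, n_inter, replace = TRUE),
        to = sample(genes, n_inter, replace = TRUE))
    }
    edf <- if (length(edges)) do.call(rbind, edges) else
      data.frame(from = character(), to = character())
    edf <- edf[edf$from != edf$to, , drop = FALSE]
    g <- igraph::graph_from_data_frame(edf, directed = TRUE,
                                       vertices = data.frame(name = genes))
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
    list(pathways = pathways, graph = g)
  })
}

#' Simulate a paired expression/methylation cohort with planted pathways
#'
#' Expression counts are negative binomial with log-normal baseline means; a
#' per-gene latent factor perturbs the NB mean so that, for the `anti_frac`
#' fraction of genes, the continuous methylation value can load on the same
#' latent with a negative coefficient (anti-correlation between the layers).
#' Genes belonging to the planted pathways have their NB mean multiplied by
#' `2^expr_lfc` and their methylation mean shifted by `meth_shift` in the poor
#' group. Labels are balanced Bernoulli draws.
#'
#' @param pathways named list of gene sets ([simulate_pathways()]).
#' @param n_samples cohort size; default 300.
#' @param planted character vector of planted pathway ids (default: first 5).
#' @param expr_lfc log2 fold change of planted genes' expression (poor vs
#'   good); default 1.5.
#' @param meth_shift additive methylation shift of planted genes in the poor
#'   group; default 1.0.
#' @param anti_frac fraction of genes whose methylation anti-correlates with
#'   their expression; default 0.5.
#' @param dispersion NB dispersion; default 0.1.
#' @param latent_sd log2-scale SD of the shared latent factor; default 0.5.
#' @param seed RNG seed.
#' @return list with `expr` (counts `omics_matrix`), `meth` (continuous
#'   `omics_matrix`), `groups` (data.frame sample_id, group) and `truth`
#'   (planted pathways, per-gene effects, anti-correlated gene set,
#'   parameters).
#' @export
simulate_cohort <- function(pathways, n_samples = 300L,
                            planted = head(names(pathways), 5L),
                            expr_lfc = 1.5, meth_shift = 1.0,
                            anti_frac = 0.5, dispersion = 0.1,
                            latent_sd = 0.5, seed = 1L) {
  stopifnot(all(planted %in% names(pathways)))
  genes <- sort(unique(unlist(pathways)))
  # the graph's full gene pool may exceed the pathway union; callers pass
  # pathway genes plus any extras via `pathways` itself
  with_seed(seed, {
    n_g <- length(genes)
    samples <- sprintf("s%04d", seq_len(n_samples))
    poor <- stats::rbinom(n_samples, 1L, 0.5) == 1L
    if (all(poor) || !any(poor)) {
      poor[1:2] <- c(TRUE, FALSE) # guard degenerate tiny cohorts
    }
    planted_genes <- unique(unlist(pathways[planted]))
    is_planted <- genes %in% planted_genes
    anti <- genes[stats::runif(n_g) < anti_frac]
    is_anti <- genes %in% anti

    base_mu <- stats::rlnorm(n_g, meanlog = log(100), sdlog = 1)
    latent <- matrix(stats::rnorm(n_g * n_samples), n_g, n_samples)
    lfc_vec <- ifelse(is_planted, expr_lfc, 0)
    mu <- base_mu * 2^(latent_sd * latent +
                         outer(lfc_vec, as.numeric(poor)))
    expr <- matrix(stats::rnbinom(n_g * n_samples, mu = mu,
                                  size = 1 / dispersion),
                   n_g, n_samples, dimnames = list(genes, samples))

    shift_vec <- ifelse(is_planted, meth_shift, 0)
    noise <- matrix(stats::rnorm(n_g * n_samples, sd = 0.6), n_g, n_samples)
    loading <- ifelse(is_anti, -0.8, 0)
    meth <- outer(shift_vec, as.numeric(poor)) + loading * latent + noise
    dimnames(meth) <- list(genes, samples)

    list(
      expr = omics_matrix(expr, "expression", "raw_counts"),
      meth = omics_matrix(meth, "methylation", "continuous"),
      groups = data.frame(sample_id = samples,
                          group = factor(ifelse(poor, "poor", "good"),
                                         levels = c("good", "poor"))),
      truth = list(planted = planted, planted_genes = planted_genes,
                   expr_lfc = stats::setNames(lfc_vec, genes),
                   meth_shift = stats::setNames(shift_vec, genes),
                   anti_genes = anti, seed = seed,
                   params = list(n_samples = n_samples, expr_lfc = expr_lfc,
                                 meth_shift = meth_shift,
                                 anti_frac = anti_frac,
                                 dispersion = dispersion,
                                 latent_sd = latent_sd))
    )
  })
}

#' Inject missing values into a matrix
#'
#' Sets each cell to `NA` independently with probability `rate`; reproducible
#' from `seed`.
#'
#' @param x an `omics_matrix`.
#' @param rate missingness probability.
#' @param seed RNG seed.
#' @return `omics_matrix` with `NA`s.
#' @export
inject_missing <- function(x, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(x)
  vals <- unclass(x)
  with_seed(seed, {
    mask <- stats::runif(length(vals)) < rate
    vals[mask] <- NA_real_
  })
  omics_matrix(vals, omics_layer(x), omics_kind(x))
}

#' Write a simulated cohort to disk in the package's file formats
#'
#' Produces expression and methylation TSVs, a clinical-style labels TSV, a
#' GMT of pathways, the base-graph edge list, and a JSON ground-truth record.
#'
#' @param sim list from [simulate_cohort()].
#' @param pathway_graph list from [simulate_pathways()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, pathway_graph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_omics(sim$expr, file.path(dir, "expression.tsv"))
  write_omics(sim$meth, file.path(dir, "methylation.tsv"))
  # encode groups as a clinical table: poor = deceased at 2y, good = alive 4y
  clin <- data.frame(
    sample_id = sim$groups$sample_id,
    vital_status = ifelse(sim$groups$group == "poor", 0L, 1L),
    survival_days = ifelse(sim$groups$group == "poor", 730L, 1460L))
  utils::write.table(clin, file.path(dir, "clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gmt <- vapply(names(pathway_graph$pathways), function(id) {
    paste(c(id, "synthetic", pathway_graph$pathways[[id]]), collapse = "\t")
  }, character(1))
  writeLines(gmt, file.path(dir, "pathways.gmt"))
  edges <- igraph::as_data_frame(pathway_graph$graph, what = "edges")
  utils::write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}
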