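#' Run the integrative random-walk pipeline in memory
#'
#' Orchestrates the full method: preprocessing (low-expression filter, median
#' imputation, z-scoring), per-layer differential statistics (NB Wald for
#' counts, Welch t for methylation), integrated-graph construction, the
#' restart walk, pathway-activity inference, feature ranking and (optionally)
#' repeated cross-validated evaluation with feature consolidation.
#'
#' @param expr expression `omics_matrix` of raw counts.
#' @param meth methylation `omics_matrix` (continuous; may contain `NA`s,
#'   which are median-imputed per sample).
#' @param groups good/poor labels (named vector or [derive_groups()] output).
#' @param base_graph directed [igraph::igraph] gene-gene graph.
#' @param pathways named list of gene sets ([read_gmt()]).
#' @param mode graph mode: `"all"` or `"anti"` cross-layer edges.
#' @param ranker `"ttest"` or `"da"`.
#' @param restart_prob,tol,alpha walk and significance parameters (defaults
#'   0.7, 1e-10, 0.05).
#' @param hidden,corruption,epochs,batch,lr autoencoder hyperparameters (used
#'   when `ranker = "da"`).
#' @param cv run [cross_validate()]? Default `TRUE`.
#' @param repeats,folds,max_n cross-validation parameters.
#' @param min_count consolidation threshold; default 4 ("> 3 of 50").
#' @param seed master seed for the stochastic stages.
#' @return list with elements `gene_stats`, `graph`, `w0`, `w_inf`,
#'   `activity`, `ranking`, and when `cv` is on, `cv` and `consolidated`.
#' @export
run_idrw <- function(expr, meth, groups, base_graph, pathways,
                     mode = c("all", "anti"), ranker = c("ttest", "da"),
                     restart_prob = 0.7, tol = 1e-10, alpha = 0.05,
                     hidden = 200L, corruption = 0.1, epochs = 200L,
                     batch = 32L, lr = 0.01,
                     cv = TRUE, repeats = 10L, folds = 5L, max_n = 10L,
                     min_count = 4L, seed = 1L) {
  mode <- match.arg(mode)
  ranker <- match.arg(ranker)
  groups <- as_survival_groups(groups)

  samples <- Reduce(intersect, list(colnames(expr), colnames(meth),
                                    names(groups)))
  if (length(samples) < 2 * folds) stop("too few labelled samples shared by the two layers")
  groups <- groups[samples]

  expr <- filter_low_expression(expr[, samples, drop = FALSE])
  meth <- meth[, samples, drop = FALSE]
  if (anyNA(meth)) meth <- impute_median(meth)

  stats_e <- nb_wald_test(expr, groups)
  stats_m <- welch_t_test(meth, groups)
  gene_stats <- rbind(stats_e, stats_m)

  expr_z <- zscore_genes(strip_constant(expr))
  meth_z <- zscore_genes(strip_constant(meth))

  graph <- build_integrated_graph(base_graph, expr_z, meth_z, mode = mode,
                                  alpha = alpha)
  M <- transition_matrix(graph)
  w0 <- initial_weights(gene_stats, graph)
  w_inf <- random_walk(M, w0, restart_prob = restart_prob, tol = tol)

  activity <- build_activity_matrix(pathways, gene_stats, w_inf,
                                    expr_z, meth_z, alpha = alpha)

  ranking <- if (ranker == "da") {
    model <- da_train(activity, hidden = hidden, corruption = corruption,
                      lr = lr, epochs = epochs, batch = batch, seed = seed)
    rank_by_da(model)
  } else {
    rank_by_ttest(activity, groups)
  }

  out <- list(gene_stats = gene_stats, graph = graph, w0 = w0, w_inf = w_inf,
              expr_z = expr_z, meth_z = meth_z,
              activity = activity, ranking = ranking, groups = groups)
  if (cv) {
    out$cv <- cross_validate(activity, groups, ranker = ranker,
                             ranking = if (ranker == "da") ranking,
                             repeats = repeats, folds = folds,
                             max_n = max_n, seed = seed)
    out$consolidated <- consolidate_features(out$cv, min_count = min_count)
  }
  out
}

# drop zero-variance genes (z-scoring would fail on them)
strip_constant <- function(x) {
  vals <- unclass(x)
  s <- apply(vals, 1L, stats::sd)
  x[s > 0, , drop = FALSE]
}

#' File-driven pipeline runner
#'
#' Reads all inputs named in `config`, executes [run_idrw()] (or one of the
#' baseline profiles) and writes the artifacts plus a JSON provenance record
#' into `config$out_dir`.
#'
#' `config` is a named list, or the path of a YAML file holding one, with
#' entries: `expression`, `methylation`, `clinical`, `edges`, `gmt`,
#' `out_dir`, and optionally `mode` (idrw / idrw_anti / drw_concat / mean /
#' median / gene_profile), `ranker`, `seed` and any numeric parameter of
#' [run_idrw()].
#'
#' @param config named list or YAML path.
#' @return the [run_idrw()] result list (invisibly), with `cv` metrics written
#'   to disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  need <- c("expression", "methylation", "clinical", "edges", "gmt", "out_dir")
  missing <- setdiff(need, names(config))
  if (length(missing)) stop("config missing entries: ",
                            paste(missing, collapse = ", "))
  mode <- config$mode %||% "idrw"
  ranker <- config$ranker %||% "ttest"
  seed <- config$seed %||% 1L

  expr <- read_omics(config$expression, "expression")
  meth <- read_omics(config$methylation, "methylation")
  groups <- derive_groups(read_clinical(config$clinical))
  base_graph <- read_edge_list(config$edges)
  pathways <- read_gmt(config$gmt)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  graph_mode <- if (mode == "idrw_anti") "anti" else "all"
  res <- run_profile(mode, expr, meth, groups, base_graph, pathways,
                     graph_mode, ranker, seed, config)

  out_dir <- config$out_dir
  if (!is.null(res$activity)) {
    write_activity(res$activity, file.path(out_dir, "activity.tsv"),
                   file.path(out_dir, "activity_meta.tsv"))
  }
  if (!is.null(res$w_inf)) {
    write_node_weights(res$w_inf, file.path(out_dir, "walk_weights.tsv"))
  }
  if (!is.null(res$ranking)) {
    utils::write.table(res$ranking, file.path(out_dir, "ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$cv)) {
    utils::write.table(res$cv$metrics, file.path(out_dir, "cv_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$consolidated,
                       file.path(out_dir, "consolidated_features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  prov <- list(package_version = as.character(utils::packageVersion("idrw")),
               r_version = R.version.string,
               mode = mode, ranker = ranker, seed = seed,
               config_hash = digest_config(config),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

digest_config <- function(config) {
  keys <- sort(names(config))
  flat <- paste(keys, vapply(config[keys], function(v)
    paste(format(v), collapse = ","), character(1)), sep = "=", collapse = ";")
  # small stable polynomial hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(flat)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

run_profile <- function(mode, expr, meth, groups, base_graph, pathways,
                        graph_mode, ranker, seed, config) {
  if (mode %in% c("idrw", "idrw_anti")) {
    return(run_idrw(expr, meth, groups, base_graph, pathways,
                    mode = graph_mode, ranker = ranker, seed = seed,
                    repeats = config$repeats %||% 10L,
                    folds = config$folds %||% 5L,
                    max_n = config$max_n %||% 10L,
                    restart_prob = config$restart_prob %||% 0.7,
                    alpha = config$alpha %||% 0.05))
  }
  # baseline profiles share the preprocessing + diffstats front end
  groups <- as_survival_groups(groups)
  samples <- Reduce(intersect, list(colnames(expr), colnames(meth),
                                    names(groups)))
  groups <- groups[samples]
  expr <- filter_low_expression(expr[, samples, drop = FALSE])
  meth <- meth[, samples, drop = FALSE]
  if (anyNA(meth)) meth <- impute_median(meth)
  gene_stats <- rbind(nb_wald_test(expr, groups), welch_t_test(meth, groups))
  expr_z <- zscore_genes(strip_constant(expr))
  meth_z <- zscore_genes(strip_constant(meth))
  alpha <- config$alpha %||% 0.05

  profile <- switch(
    mode,
    mean = baseline_activity(pathways, gene_stats, expr_z, meth_z, "mean", alpha),
    median = baseline_activity(pathways, gene_stats, expr_z, meth_z, "median", alpha),
    gene_profile = rbind(unclass(expr_z), unclass(meth_z) + 0)[, samples, drop = FALSE],
    drw_concat = {
      act <- lapply(c("expression", "methylation"), function(ly) {
        om <- if (ly == "expression") expr_z else meth_z
        st <- gene_stats[gene_stats$layer == ly, , drop = FALSE]
        g1 <- build_single_layer_graph(base_graph, om, ly)
        w0 <- initial_weights(st, g1)
        wi <- random_walk(transition_matrix(g1), w0)
        build_activity_matrix(pathways, st, wi, expr_z, meth_z, alpha)
      })
      drw_concat(act[[1L]], act[[2L]])
    },
    stop("unknown mode: ", mode)
  )
  if (mode == "gene_profile") {
    rownames(profile) <- make.unique(rownames(profile))
  }
  cv <- cross_validate(profile, groups, ranker = "ttest",
                       repeats = config$repeats %||% 10L,
                       folds = config$folds %||% 5L,
                       max_n = config$max_n %||% 10L, seed = seed)
  list(activity = profile, cv = cv,
       consolidated = consolidate_features(cv),
       gene_stats = gene_stats, groups = groups)
}

#' Single-layer integrated graph (one omics layer, no cross edges)
#'
#' Restricts the base graph to the genes present in one layer; used for the
#' concatenation baseline in which each layer is walked independently.
#'
#' @param base_graph directed [igraph::igraph].
#' @param omics `omics_matrix` of that layer.
#' @param layer `"expression"` or `"methylation"`.
#' @return an `integrated_graph` with a single layer.
#' @export
build_single_layer_graph <- function(base_graph, omics,
                                     layer = c("expression", "methylation")) {
  layer <- match.arg(layer)
  base_genes <- igraph::V(base_graph)$name
  g <- intersect(base_genes, rownames(omics))
  if (!length(g)) stop("no base-graph gene found in the layer")
  be <- igraph::as_data_frame(base_graph, what = "edges")[, 1:2]
  names(be) <- c("from", "to")
  be <- be[be$from %in% g & be$to %in% g, , drop = FALSE]
  type <- if (layer == "expression") "within_expr" else "within_meth"
  edges <- if (nrow(be)) {
    data.frame(from = node_id(be$from, layer), to = node_id(be$to, layer),
               type = type)
  } else {
    data.frame(from = character(), to = character(), type = character())
  }
  structure(list(nodes = data.frame(node = node_id(g, layer), gene = g,
                                    layer = layer),
                 edges = edges, mode = "single"),
            class = "integrated_graph")
}
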