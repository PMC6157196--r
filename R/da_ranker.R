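#' Masking corruption of an input vector or matrix
#'
#' Each coordinate is independently set to zero with probability `rate`
#' (binomial masking noise). Uses the current RNG stream unless `seed` is
#' given.
#'
#' @param x numeric vector or matrix.
#' @param rate corruption probability in \[0, 1\].
#' @param seed optional seed for reproducible masks.
#' @return object of the same shape with a random subset of entries zeroed.
#' @export
da_corrupt <- function(x, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(x)
  with_seed(seed, {
    mask <- stats::rbinom(length(x), 1L, 1 - rate)
    x * mask
  })
}

new_da_model <- function(W, b, b_dec, corruption, trace = numeric(0),
                         hyper = list()) {
  structure(list(W = W, b = b, b_dec = b_dec, corruption = corruption,
                 trace = trace, hyper = hyper),
            class = "da_model")
}

#' Initialise a tied-weight denoising autoencoder
#'
#' Glorot-uniform encoder weights (p hidden x d input), zero biases.
#'
#' @param d number of input features.
#' @param hidden number of hidden units p.
#' @param corruption masking rate stored with the model.
#' @param seed RNG seed for the initialisation.
#' @return a `da_model`.
#' @export
da_init <- function(d, hidden, corruption = 0.1, seed = 1L) {
  lim <- sqrt(6 / (d + hidden))
  W <- with_seed(seed, matrix(stats::runif(hidden * d, -lim, lim), hidden, d))
  new_da_model(W, b = numeric(hidden), b_dec = numeric(d), corruption)
}

#' Forward pass of the tied-weight autoencoder
#'
#' y = sigmoid(W x + b) encodes; z = sigmoid(W^T y + b_dec) reconstructs with
#' the transposed encoder weights and an independent decoder bias.
#'
#' @param model a `da_model`.
#' @param x input matrix, samples x features (a vector is treated as one
#'   sample).
#' @return list with `y` (samples x hidden) and `z` (samples x features).
#' @export
da_forward <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  stopifnot(ncol(x) == ncol(model$W))
  y <- sigmoid(sweep(tcrossprod(x, model$W), 2L, model$b, "+"))
  z <- sigmoid(sweep(y %*% model$W, 2L, model$b_dec, "+"))
  list(y = y, z = z)
}

#' Reconstruction loss and analytic gradients
#'
#' Mean over the batch of L(x, z) = ||x - z||^2 / 2 with z the reconstruction
#' of the corrupted input, plus its exact gradients with respect to the tied
#' weight matrix and the two biases (the encoder weights receive both the
#' decoder-path and encoder-path terms).
#'
#' @param model a `da_model`.
#' @param x clean inputs, samples x features.
#' @param x_tilde corrupted inputs of the same shape.
#' @return list with `loss`, `W`, `b`, `b_dec` (gradients of the mean loss).
#' @export
da_gradients <- function(model, x, x_tilde) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (is.vector(x_tilde)) x_tilde <- matrix(x_tilde, nrow = 1L)
  m <- nrow(x)
  fwd <- da_forward(model, x_tilde)
  y <- fwd$y
  z <- fwd$z
  loss <- sum((x - z)^2) / 2 / m
  delta_z <- (z - x) * z * (1 - z)                 # m x d
  delta_y <- (delta_z %*% t(model$W)) * y * (1 - y) # m x p
  grad_W <- (crossprod(y, delta_z) + crossprod(delta_y, x_tilde)) / m
  list(loss = loss,
       W = grad_W,
       b = colSums(delta_y) / m,
       b_dec = colSums(delta_z) / m)
}

#' Train a denoising autoencoder on a pathway-activity profile
#'
#' Samples are training instances and pathways are input features, so the
#' profile matrix (pathways x samples) is transposed internally. Minibatch
#' gradient descent on the mean squared reconstruction error of masked inputs;
#' deterministic given `seed`.
#'
#' @param activity pathways x samples matrix ([build_activity_matrix()]), or
#'   any features x samples numeric matrix.
#' @param hidden hidden-layer width; default 200.
#' @param corruption masking rate; default 0.1.
#' @param lr learning rate; default 0.01.
#' @param epochs full passes over the data; default 500.
#' @param batch minibatch size; default 32.
#' @param seed RNG seed controlling initialisation, corruption and shuffling.
#' @return trained `da_model`; `$trace` holds the mean minibatch loss per
#'   epoch and `$feature_ids` the pathway ids.
#' @export
da_train <- function(activity, hidden = 200L, corruption = 0.1, lr = 0.01,
                     epochs = 500L, batch = 32L, seed = 1L) {
  X <- t(as.matrix(activity)) # samples x features
  n <- nrow(X)
  d <- ncol(X)
  if (!n || !d) stop("empty training matrix")
  model <- da_init(d, hidden, corruption, seed = seed)
  if (epochs == 0L) {
    model$feature_ids <- rownames(activity)
    return(model)
  }
  with_seed(seed + 1L, {
    trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1L, n)]
        xb <- X[idx, , drop = FALSE]
        xt <- da_corrupt(xb, corruption)
        g <- da_gradients(model, xb, xt)
        if (!is.finite(g$loss)) {
          stop(sprintf("non-finite loss at epoch %d", ep))
        }
        model$W <- model$W - lr * g$W
        model$b <- model$b - lr * g$b
        model$b_dec <- model$b_dec - lr * g$b_dec
        losses <- c(losses, g$loss)
      }
      trace[ep] <- mean(losses)
    }
    model$trace <- trace
  })
  model$hyper <- list(hidden = hidden, corruption = corruption, lr = lr,
                      epochs = epochs, batch = batch, seed = seed)
  model$feature_ids <- rownames(activity)
  model
}

#' @export
print.da_model <- function(x, ...) {
  cat(sprintf("<da_model> %d hidden x %d input; corruption %.2f; %d epochs trained\n",
              nrow(x$W), ncol(x$W), x$corruption, length(x$trace)))
  invisible(x)
}

#' Rank pathway features by autoencoder weights
#'
#' Each input feature is scored by the mean of its encoder weight column (its
#' connection weights to all hidden units). Ranking is by decreasing absolute
#' score by default (the signed score is retained in the output); ties break
#' lexicographically by pathway id.
#'
#' @param model trained `da_model`.
#' @param feature_ids pathway ids matching the model's input features; taken
#'   from the model when omitted.
#' @param signed if `TRUE`, rank by the signed mean weight instead of its
#'   absolute value.
#' @return a `feature_ranking`: data.frame (pathway_id, score, rank) ordered
#'   by rank, with `attr(, "method") == "da"`.
#' @export
rank_by_da <- function(model, feature_ids = NULL, signed = FALSE) {
  if (is.null(feature_ids)) feature_ids <- model$feature_ids
  d <- ncol(model$W)
  if (length(feature_ids) != d) stop("feature_ids length must match model input size")
  score <- colMeans(model$W)
  key <- if (signed) -score else -abs(score)
  ord <- order(key, feature_ids)
  out <- data.frame(pathway_id = feature_ids[ord], score = score[ord],
                    rank = seq_len(d), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- "da"
  class(out) <- c("feature_ranking", class(out))
  out
}

#' Save / load a DA model as flat text
#'
#' Writes the weight matrix and biases as TSVs next to a JSON sidecar of
#' hyperparameters.
#' @param model trained `da_model`.
#' @param prefix path prefix; files `<prefix>_W.tsv`, `<prefix>_b.tsv`,
#'   `<prefix>_bdec.tsv`, `<prefix>_hyper.json` are produced.
#' @export
write_da_model <- function(model, prefix) {
  utils::write.table(model$W, paste0(prefix, "_W.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(b = model$b), paste0(prefix, "_b.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(b_dec = model$b_dec), paste0(prefix, "_bdec.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(model$hyper, paste0(prefix, "_hyper.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(prefix)
}
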