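# Biased matrix factorization trained by SGD on present links plus selected
# negatives. The score of pair (i, j) is mu + b_i + b_j + p_i . q_j; the
# training objective is the regularized squared error over the training
# samples. The per-epoch update loop is implemented in C++ (src/sgd.cpp);
# sgd_update() is the reference single-sample update in R and the test suite
# asserts the two agree.

#' Matrix-factorization hyperparameters
#'
#' @param k latent dimension (far smaller than min(N, M)).
#' @param lam regularization weight (lambda >= 0).
#' @param gamma SGD learning rate (> 0).
#' @param max_iters number of epochs; every training sample is updated once
#'   per epoch, so this is the minimum number of updates per sample.
#' @param init_scale standard deviation of the Gaussian factor initialization.
#' @param seed integer seed (initialization and epoch shuffles).
#' @param threshold decision cutoff for hard link predictions (AUC/AUPR do
#'   not use it).
#' @export
mf_params <- function(k = 16L, lam = 0.05, gamma = 0.01, max_iters = 30L,
                      init_scale = 0.1, seed = 1L, threshold = 0.5) {
  k <- as.integer(k); max_iters <- as.integer(max_iters)
  stopifnot(k >= 1L, lam >= 0, gamma > 0, max_iters >= 1L, init_scale >= 0)
  structure(list(k = k, lam = lam, gamma = gamma, max_iters = max_iters,
                 init_scale = init_scale, seed = as.integer(seed),
                 threshold = threshold),
            class = "mf_params")
}

#' Build a training set from a network and selected negatives
#'
#' Positives are the network's present edges (value 1); negatives are the
#' selected pairs (value 0). Indices are positions in the network's node
#' lists.
#'
#' @param net a [bipartite_network()].
#' @param negatives data.frame of pairs to use as value-0 samples.
#' @return object of class `training_set`: list with `i`, `j` (integer
#'   indices), `a` (0/1 values), `n_rows`, `n_cols`.
#' @export
training_set <- function(net, negatives) {
  neg <- as_edge_df(negatives)
  i <- c(match(net$present$left, net$left), match(neg$left, net$left))
  j <- c(match(net$present$right, net$right), match(neg$right, net$right))
  if (anyNA(i) || anyNA(j)) stop("training pair outside the network's node lists")
  a <- c(rep(1, nrow(net$present)), rep(0, nrow(neg)))
  key <- paste(i, j)
  if (anyDuplicated(key)) stop("duplicate (i, j) training sample")
  structure(list(i = as.integer(i), j = as.integer(j), a = as.numeric(a),
                 n_rows = n_left(net), n_cols = n_right(net)),
            class = "training_set")
}

#' @rdname training_set
#' @description `raw_training_set()` builds the raw-MF comparator's training
#'   set: every unobserved pair is treated as a value-0 sample.
#' @export
raw_training_set <- function(net) {
  training_set(net, unobserved_pairs(net))
}

new_factor_model <- function(P, Q, b_row, b_col, mu, params = NULL) {
  structure(list(P = P, Q = Q, b_row = b_row, b_col = b_col, mu = mu,
                 params = params),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor_model: %d x %d, k = %d, mu = %.4g\n",
              nrow(x$P), ncol(x$Q), ncol(x$P), x$mu))
  invisible(x)
}

init_factors <- function(n_rows, n_cols, params) {
  k <- params$k
  new_factor_model(
    P = matrix(stats::rnorm(n_rows * k, 0, params$init_scale), n_rows, k),
    Q = matrix(stats::rnorm(k * n_cols, 0, params$init_scale), k, n_cols),
    b_row = numeric(n_rows), b_col = numeric(n_cols), mu = 0, params = params)
}

#' Initialize a factor model
#'
#' Factor entries are i.i.d. normal with standard deviation
#' `params$init_scale`; biases start at 0 and `mu` at 0 (it is set to the
#' training-value mean when training starts). Deterministic per seed.
#'
#' @param n_rows,n_cols network dimensions (N, M).
#' @param params an [mf_params()].
#' @return object of class `factor_model` with fields `P` (N x k), `Q`
#'   (k x M), `b_row`, `b_col`, `mu`.
#' @export
init_model <- function(n_rows, n_cols, params) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  with_seed(params$seed, init_factors(n_rows, n_cols, params))
}

#' Confidence score of a node pair
#'
#' `mu + b_i + b_j + p_i . q_j`, vectorized over pairs.
#'
#' @param model a `factor_model`.
#' @param i,j integer row/column indices (recycled together).
#' @export
predict_score <- function(model, i, j) {
  i <- as.integer(i); j <- as.integer(j)
  if (any(i < 1 | i > nrow(model$P)) || any(j < 1 | j > ncol(model$Q))) {
    stop("index out of range")
  }
  dots <- rowSums(model$P[i, , drop = FALSE] * t(model$Q)[j, , drop = FALSE])
  model$mu + model$b_row[i] + model$b_col[j] + dots
}

#' Single-sample SGD update (reference implementation)
#'
#' Computes the residual `e = a - (mu + b_i + b_j + p_i . q_j)` and applies
#' the four updates, using pre-update values of `p_i` and `q_j` on the
#' right-hand sides:
#' `b_i <- b_i + gamma (e - lam b_i)`, `b_j <- b_j + gamma (e - lam b_j)`,
#' `p_i <- p_i + gamma (e q_j - lam p_i)`, `q_j <- q_j + gamma (e p_i - lam q_j)`.
#'
#' @param model a `factor_model`.
#' @param sample list or vector with elements `i`, `j`, `a`.
#' @param params an [mf_params()] (only `gamma` and `lam` are used).
#' @return the updated model.
#' @export
sgd_update <- function(model, sample, params) {
  i <- as.integer(sample$i); j <- as.integer(sample$j); a <- sample$a
  p <- model$P[i, ]; q <- model$Q[, j]
  e <- a - (model$mu + model$b_row[i] + model$b_col[j] + sum(p * q))
  if (!is.finite(e)) stop("non-finite residual in SGD update (i=", i, ", j=", j, ")")
  g <- params$gamma; lam <- params$lam
  model$b_row[i] <- model$b_row[i] + g * (e - lam * model$b_row[i])
  model$b_col[j] <- model$b_col[j] + g * (e - lam * model$b_col[j])
  model$P[i, ] <- p + g * (e * q - lam * p)
  model$Q[, j] <- q + g * (e * p - lam * q)
  model
}

#' Regularized training objective
#'
#' `sum over samples of (a_ij - p_i.q_j - b_ij)^2 +
#' lam (b_i^2 + b_j^2 + ||p_i||^2 + ||q_j||^2)`.
#'
#' @param model a `factor_model`.
#' @param ts a [training_set()].
#' @param lam regularization weight.
#' @export
mf_objective <- function(model, ts, lam) {
  pred <- predict_score(model, ts$i, ts$j)
  reg <- model$b_row[ts$i]^2 + model$b_col[ts$j]^2 +
    rowSums(model$P[ts$i, , drop = FALSE]^2) +
    colSums(model$Q^2)[ts$j]
  sum((ts$a - pred)^2 + lam * reg)
}

#' Train a biased-MF model by epoch-wise SGD
#'
#' Sets `mu` to the mean of the training values, then runs
#' `params$max_iters` epochs; each epoch applies one [sgd_update()] per
#' sample in a fresh uniformly shuffled order. The regularized objective is
#' logged after every epoch (`attr(model, "objective_trace")`). Deterministic
#' per seed (initialization and all shuffles derive from `params$seed`).
#'
#' @param ts a non-empty [training_set()].
#' @param params an [mf_params()].
#' @return a trained `factor_model`.
#' @export
train_mf <- function(ts, params) {
  n <- length(ts$i)
  if (n == 0) stop("empty training set")
  trace <- numeric(params$max_iters)
  model <- with_seed(params$seed, {
    mod <- init_factors(ts$n_rows, ts$n_cols, params)
    mod$mu <- mean(ts$a)
    # C++ kernel mutates P/Q/biases in place; we own these copies
    for (ep in seq_len(params$max_iters)) {
      ord <- sample.int(n)
      sgd_epoch(mod$P, mod$Q, mod$b_row, mod$b_col, mod$mu,
                ts$i, ts$j, ts$a, ord, params$gamma, params$lam)
      trace[ep] <- mf_objective(mod, ts, params$lam)
      if (!is.finite(trace[ep])) {
        stop("non-finite objective at epoch ", ep,
             "; reduce gamma or check the training data")
      }
    }
    mod
  })
  attr(model, "objective_trace") <- trace
  model
}

#' Score all unobserved pairs of a network
#'
#' @param model a trained `factor_model` whose shapes match the network.
#' @param net a [bipartite_network()].
#' @param exclude optional data.frame of extra pairs to skip.
#' @return data.frame with columns `left`, `right`, `score`.
#' @export
score_all_unobserved <- function(model, net, exclude = NULL) {
  if (nrow(model$P) != n_left(net) || ncol(model$Q) != n_right(net)) {
    stop(sprintf("model shape (%d x %d) does not match network (%d x %d)",
                 nrow(model$P), ncol(model$Q), n_left(net), n_right(net)))
  }
  pairs <- unobserved_pairs(net, exclude)
  if (!nrow(pairs)) return(cbind(pairs, score = numeric(0)))
  i <- match(pairs$left, net$left); j <- match(pairs$right, net$right)
  pairs$score <- predict_score(model, i, j)
  pairs
}

#' Hard link predictions at a threshold
#' @param scores data.frame with a `score` column.
#' @param threshold decision cutoff; pairs scoring above it are predicted links.
#' @export
predict_links <- function(scores, threshold) {
  scores[scores$score > threshold, , drop = FALSE]
}

#' Serialize / restore a factor model as versioned JSON
#' @param model a `factor_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  payload <- list(
    format = "fcalink-factor-model", version = 1L,
    n_rows = nrow(model$P), n_cols = ncol(model$Q), k = ncol(model$P),
    mu = model$mu, b_row = model$b_row, b_col = model$b_col,
    P = as.vector(model$P), Q = as.vector(model$Q),
    params = unclass(model$params))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "fcalink-factor-model")) stop("not a fcalink model file")
  params <- if (!is.null(x$params)) do.call(mf_params, as.list(x$params)) else NULL
  new_factor_model(
    P = matrix(x$P, x$n_rows, x$k), Q = matrix(x$Q, x$k, x$n_cols),
    b_row = as.numeric(x$b_row), b_col = as.numeric(x$b_col),
    mu = x$mu, params = params)
}
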