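#' Feed-forward network architecture with a deep/shallow split
#'
#' The federated object is a small multilayer perceptron: tanh hidden
#' layers, a single sigmoid output unit, cross-entropy loss, full-batch
#' gradient descent. Its parameter tensors (weight matrix and bias vector
#' per layer, in input-to-output order) are partitioned into a *shallow*
#' group near the input and a *deep* group near the output; the deep
#' fraction `alpha` of tensors (rounded up, taken from the output end) is
#' the part exchanged only every `Delta`-th iteration of the asynchronous
#' protocol.
#'
#' @param layer_sizes Integer vector of widths, input first, output last;
#'   the output width must be 1 (binary decision).
#' @param activation Hidden nonlinearity; only `"tanh"` is provided.
#' @param alpha Deep parameter exchange ratio in `[0, 1]`.
#' @return An `architecture` object.
#' @export
architecture <- function(layer_sizes, activation = "tanh", alpha = 0.5) {
  if (length(layer_sizes) < 2L)
    stop("architecture error: need at least input and output widths",
         call. = FALSE)
  if (utils::tail(layer_sizes, 1L) != 1L)
    stop("architecture error: output width must be 1", call. = FALSE)
  if (alpha < 0 || alpha > 1)
    stop("architecture error: alpha must lie in [0, 1]", call. = FALSE)
  activation <- match.arg(activation, "tanh")
  structure(list(layer_sizes = as.integer(layer_sizes),
                 activation = activation, alpha = alpha),
            class = "architecture")
}

#' Ordered parameter tensors with a deep/shallow partition
#'
#' @param tensors List of numeric arrays in input-to-output order.
#' @param partition_index Number of *shallow* tensors: tensors
#'   `1..partition_index` are shallow, the rest are deep. Must lie in
#'   `[0, length(tensors)]`.
#' @return A `model_parameters` object.
#' @export
model_parameters <- function(tensors, partition_index) {
  k <- length(tensors)
  if (partition_index < 0 || partition_index > k)
    stop("partition_index must lie in [0, ", k, "]", call. = FALSE)
  structure(list(tensors = tensors, partition_index = as.integer(partition_index)),
            class = "model_parameters")
}

#' Tensor indices of the deep / shallow groups
#' @param params A [model_parameters()].
#' @return Integer vector of tensor indices.
#' @export
deep_indices <- function(params) {
  k <- length(params$tensors)
  if (params$partition_index >= k) integer(0)
  else (params$partition_index + 1L):k
}

#' @rdname deep_indices
#' @export
shallow_indices <- function(params) {
  seq_len(params$partition_index)
}

#' Number of scalar parameters in a tensor group
#' @param params A [model_parameters()].
#' @param which `"all"`, `"deep"` or `"shallow"`.
#' @return Integer count of scalar parameters.
#' @export
parameter_count <- function(params, which = c("all", "deep", "shallow")) {
  which <- match.arg(which)
  idx <- switch(which, all = seq_along(params$tensors),
                deep = deep_indices(params), shallow = shallow_indices(params))
  sum(vapply(params$tensors[idx], length, integer(1)))
}

#' Initialise model parameters for an architecture
#'
#' Weights are drawn i.i.d. from `N(0, 0.1^2)` under the given seed; biases
#' start at zero. The deep group holds the last `ceiling(alpha * k)` of the
#' `k` tensors.
#'
#' @param arch An [architecture()].
#' @param seed Integer seed.
#' @return A [model_parameters()] object.
#' @export
init_model <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "architecture"))
  ls <- arch$layer_sizes
  with_seed(seed, {
    tensors <- list()
    for (i in seq_len(length(ls) - 1L)) {
      tensors[[2L * i - 1L]] <- matrix(stats::rnorm(ls[i] * ls[i + 1L],
                                                    sd = 0.1),
                                       ls[i], ls[i + 1L])
      tensors[[2L * i]] <- numeric(ls[i + 1L])
    }
    k <- length(tensors)
    n_deep <- ceiling(arch$alpha * k)
    model_parameters(tensors, partition_index = k - n_deep)
  })
}

# forward pass; returns activations for backprop
.forward <- function(params, X) {
  ts <- params$tensors
  n_layers <- length(ts) / 2L
  A <- list(X)
  H <- X
  for (i in seq_len(n_layers)) {
    Zl <- sweep(H %*% ts[[2L * i - 1L]], 2L, ts[[2L * i]], `+`)
    H <- if (i < n_layers) tanh(Zl) else stats::plogis(Zl)
    A[[i + 1L]] <- H
  }
  A
}

# mean binary cross-entropy with clipped probabilities
.bce <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Predict disease probability with the network
#'
#' @param params A [model_parameters()].
#' @param X Numeric matrix of encoded features (records in rows).
#' @return Numeric vector of probabilities in `(0, 1)`.
#' @export
mlp_predict <- function(params, X) {
  A <- .forward(params, as.matrix(X))
  as.vector(A[[length(A)]])
}

#' Cross-entropy loss of the network on a dataset
#' @param params A [model_parameters()].
#' @param dataset A `heart_dataset`.
#' @return Mean binary cross-entropy.
#' @export
mlp_loss <- function(params, dataset) {
  .bce(mlp_predict(params, dataset$features), dataset$labels)
}

#' Train the local model by full-batch gradient descent
#'
#' Runs `epochs` deterministic full-batch gradient-descent steps on the
#' mean cross-entropy; with the loss fixed and no minibatching the result
#' is bit-reproducible for a given input. The deep/shallow partition is
#' untouched by training.
#'
#' @param params A [model_parameters()].
#' @param dataset A non-empty `heart_dataset`.
#' @param epochs Number of gradient steps (`>= 0`).
#' @param learning_rate Step size (`>= 0`; 0 leaves parameters unchanged).
#' @param seed Integer seed (reserved for stochastic variants; full-batch
#'   descent does not consume randomness).
#' @return List with `params` (updated [model_parameters()]) and `loss`
#'   (mean cross-entropy after the final step).
#' @export
train_local <- function(params, dataset, epochs = 1L, learning_rate = 0.3,
                        seed = 1L) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(dataset, "heart_dataset"))
  if (nrow(dataset$features) == 0L)
    stop("training error: empty dataset", call. = FALSE)
  if (learning_rate < 0)
    stop("training error: learning_rate must be >= 0", call. = FALSE)
  X <- unname(dataset$features)
  y <- dataset$labels
  n <- nrow(X)
  ts <- params$tensors
  n_layers <- length(ts) / 2L
  for (ep in seq_len(epochs)) {
    A <- .forward(model_parameters(ts, params$partition_index), X)
    # output delta for sigmoid + cross-entropy: (p - y) / n
    delta <- (A[[n_layers + 1L]] - y) / n
    for (i in rev(seq_len(n_layers))) {
      gW <- t(A[[i]]) %*% delta
      gb <- colSums(delta)
      if (i > 1L)
        delta <- (delta %*% t(ts[[2L * i - 1L]])) * (1 - A[[i]]^2)
      ts[[2L * i - 1L]] <- ts[[2L * i - 1L]] - learning_rate * gW
      ts[[2L * i]] <- ts[[2L * i]] - learning_rate * gb
    }
  }
  out <- model_parameters(ts, params$partition_index)
  list(params = out, loss = mlp_loss(out, dataset))
}

#' Size-weighted global federated loss
#'
#' The server-side objective: the convex combination of per-node local
#' losses weighted by each node's share of the federation's data,
#' `sum_i (A_i / A) f_i`, where `A = sum_i A_i`. This is the quantity the
#' server compares against its stopping threshold `E`.
#'
#' @param client_sizes Numeric vector of per-node record counts `A_i`
#'   (all `>= 0`, total `> 0`).
#' @param client_losses Numeric vector of per-node local losses `f_i`.
#' @return The weighted loss, a single number bounded by
#'   `range(client_losses)`.
#' @examples
#' global_loss(c(1, 3), c(0.4, 0.8))  # 0.25*0.4 + 0.75*0.8 = 0.7
#' @export
global_loss <- function(client_sizes, client_losses) {
  stopifnot(length(client_sizes) == length(client_losses))
  if (any(client_sizes < 0))
    stop("client sizes must be non-negative", call. = FALSE)
  A <- sum(client_sizes)
  if (A <= 0)
    stop("undefined loss: total data size is zero", call. = FALSE)
  sum(client_sizes / A * client_losses)
}
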