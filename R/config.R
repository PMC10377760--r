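#' Protocol constants for a federated run
#'
#' Collects every knob of the federation in one validated object. Symbols
#' follow the field's convention for this protocol family: `Z` nodes run
#' `L` local iterations each; the deep fraction `alpha` of parameter
#' tensors is uploaded only on iterations divisible by `Delta`, the shallow
#' remainder on every other iteration; a node participates only if it holds
#' at least `beta` records; the server stops once the size-weighted global
#' loss falls to `E` or below.
#'
#' @param Z Number of client nodes (`>= 1`).
#' @param Delta Deep-exchange period in iterations (`>= 1`).
#' @param L Total local iterations per client (`>= 1`).
#' @param alpha Deep parameter exchange ratio in `[0, 1]`.
#' @param beta Minimum acceptable local data size (records, `>= 0`).
#' @param E Server loss threshold (`>= 0`); the run stops early once the
#'   weighted global loss is `<= E`.
#' @param seed Master seed; every stream (split, partition, init, schedule)
#'   derives its own sub-seed from it.
#' @param learning_rate Local gradient-descent step size.
#' @param epochs Local gradient steps per iteration.
#' @param hidden Integer vector of hidden-layer widths.
#' @param test_fraction Held-out fraction for evaluation.
#' @param weighting Staleness weighting scheme: `"temporal"` for
#'   `(e/2)^(-s)` or `"exponential"` for `exp(-lambda * s)`.
#' @param lambda Decay rate for the `"exponential"` scheme.
#' @param blend Aggregation blend used by the experiments: `"global"`
#'   (default — fold each batch into the current global tensors with
#'   weights `size * staleness_weight / total size`, which equals the pure
#'   convex combination whenever a full fresh batch arrives and otherwise
#'   moves the global by the arrivals' data share) or `"contributors"`
#'   (pure convex combination over the contributing nodes only; the
#'   natural choice when every aggregation sees the whole federation).
#' @param max_updates Safety cap on server aggregation events.
#' @return A `federation_config` object.
#' @export
federation_config <- function(Z = 5L, Delta = 5L, L = 50L, alpha = 0.5,
                              beta = 1L, E = 0.02, seed = 1L,
                              learning_rate = 0.3, epochs = 5L,
                              hidden = c(16L, 8L), test_fraction = 0.33,
                              weighting = c("temporal", "exponential"),
                              lambda = 0.5,
                              blend = c("global", "contributors"),
                              max_updates = 500L) {
  weighting <- match.arg(weighting)
  blend <- match.arg(blend)
  stopifnot(Z >= 1, Delta >= 1, L >= 1, alpha >= 0, alpha <= 1, beta >= 0,
            E >= 0, learning_rate >= 0, epochs >= 0, max_updates >= 0,
            test_fraction >= 0, test_fraction < 1)
  structure(list(Z = as.integer(Z), Delta = as.integer(Delta),
                 L = as.integer(L), alpha = alpha, beta = beta, E = E,
                 seed = as.integer(seed), learning_rate = learning_rate,
                 epochs = as.integer(epochs), hidden = as.integer(hidden),
                 test_fraction = test_fraction, weighting = weighting,
                 lambda = lambda, blend = blend,
                 max_updates = as.integer(max_updates)),
            class = "federation_config")
}

#' Read a federation config from a YAML file
#'
#' Keys mirror the arguments of [federation_config()]; absent keys keep
#' their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `federation_config` object.
#' @export
read_federation_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(federation_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(federation_config, vals)
}

# staleness weight under the configured scheme
.staleness_weight <- function(staleness, config) {
  switch(config$weighting,
         temporal = temporal_weight(staleness, 0),
         exponential = exp(-config$lambda * staleness))
}
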