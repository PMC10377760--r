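#' Server-side global state
#'
#' Holds the global model, an integer clock counting aggregation events,
#' the latest size-weighted global loss, and an append-only history of
#' aggregation events (the aggregation trace).
#'
#' @param model A [model_parameters()] object (the initial global model).
#' @return A `global_state` object.
#' @export
global_state <- function(model) {
  stopifnot(inherits(model, "model_parameters"))
  structure(list(model = model, round_clock = 0L, current_loss = Inf,
                 history = list(), stop_reason = NA_character_),
            class = "global_state")
}

#' Staleness weight of a client update
#'
#' An update whose sender last synchronised with the server `s = now -
#' timestep` events ago is down-weighted by `(e/2)^(-s)`: weight 1 at zero
#' staleness, strictly decreasing as the update grows stale.
#'
#' @param now Current server time (aggregation-event count).
#' @param timestep Server time at which the sender was last synchronised;
#'   must not exceed `now`.
#' @return The weight in `(0, 1]`.
#' @examples
#' temporal_weight(5, 5)  # 1
#' temporal_weight(5, 4)  # (e/2)^-1, about 0.7358
#' @export
temporal_weight <- function(now, timestep) {
  if (any(timestep > now))
    stop("causality error: timestep exceeds server time", call. = FALSE)
  (exp(1) / 2)^(-(now - timestep))
}

#' Temporally weighted aggregation of client updates
#'
#' Each arriving update carries a subset of parameter tensors. For every
#' tensor index present in at least one update, the global tensor is
#' replaced by the convex combination of the contributed tensors with
#' coefficients proportional to `data_size * staleness_weight`, normalised
#' to sum to one over the contributors; tensors no update carries are left
#' untouched (so shallow-only batches never move the deep group). The
#' server clock advances by one event and the global loss is recomputed
#' from the contributors' reported local losses via the size-weighted
#' global objective.
#'
#' @param updates Non-empty list of [update_message()]s.
#' @param global A [global_state()].
#' @param staleness Optional numeric vector, one staleness per update
#'   (server-time events since the sender was last synchronised). When
#'   absent, an update's server-time `timestep` field is used if present,
#'   else staleness 0.
#' @param config A [federation_config()]; supplies the weighting scheme
#'   and blend policy. Under `blend = "contributors"` (the op-level
#'   default) each updated tensor becomes a pure convex combination of
#'   the contributed tensors. Under `blend = "global"` the combination is
#'   folded into the current global tensor:
#'   `new = (1 - sum(w)) * old + sum(w_i * update_i)` with weights
#'   `w_i = size_i * staleness_weight_i / total_size`, so a lone fresh
#'   arrival moves the global by its data share rather than replacing it
#'   — the policy a per-arrival asynchronous server needs.
#' @param total_size Denominator for the `"global"` blend: the
#'   federation's total data size. Default is the contributors' summed
#'   sizes (which makes a full fresh batch a pure convex combination
#'   under either policy).
#' @return The updated [global_state()].
#' @export
aggregate_updates <- function(updates, global, staleness = NULL,
                              config = federation_config(blend = "contributors"),
                              total_size = NULL) {
  stopifnot(inherits(global, "global_state"))
  if (length(updates) == 0L)
    stop("aggregation error: no updates to aggregate", call. = FALSE)
  now <- global$round_clock
  if (is.null(staleness)) {
    staleness <- vapply(updates, function(u) {
      if (is.null(u$timestep)) 0 else as.numeric(now - u$timestep)
    }, numeric(1))
  }
  if (any(staleness < 0))
    stop("causality error: negative staleness", call. = FALSE)
  sizes <- vapply(updates, `[[`, integer(1), "data_size")
  w <- sizes * .staleness_weight(staleness, config)
  if (sum(w) <= 0)
    stop("aggregation error: total weight is zero", call. = FALSE)
  total <- total_size %||% sum(sizes)
  if (total < sum(sizes) - 1e-9)
    stop("aggregation error: total_size smaller than contributed sizes",
         call. = FALSE)

  tensors <- global$model$tensors
  all_idx <- sort(unique(unlist(lapply(updates, `[[`, "tensor_indices"))))
  coeff_log <- list()
  for (j in all_idx) {
    contrib <- which(vapply(updates, function(u) j %in% u$tensor_indices,
                            logical(1)))
    pieces <- lapply(updates[contrib], function(u)
      u$weights[[match(j, u$tensor_indices)]])
    ref <- tensors[[j]]
    for (p in pieces)
      if (!identical(dim(p) %||% length(p), dim(ref) %||% length(ref)))
        stop("shape error: tensor ", j, " in update does not match global",
             call. = FALSE)
    if (config$blend == "global") {
      cj <- w[contrib] / total
      residual <- 1 - sum(cj)
      if (abs(residual) < 1e-12) residual <- 0  # full fresh batch
      mixed <- residual * tensors[[j]] +
        Reduce(`+`, Map(function(p, cc) p * cc, pieces, as.list(cj)))
    } else {
      cj <- w[contrib] / sum(w[contrib])
      mixed <- Reduce(`+`, Map(function(p, cc) p * cc, pieces, as.list(cj)))
    }
    tensors[[j]] <- mixed
    coeff_log[[as.character(j)]] <- stats::setNames(
      cj, vapply(updates[contrib], `[[`, integer(1), "node_id"))
  }
  losses <- vapply(updates, `[[`, numeric(1), "local_loss")
  # the global objective counts each node once; when a node contributes
  # several cached updates, its freshest (least stale) report is used
  nodes <- vapply(updates, `[[`, integer(1), "node_id")
  fresh <- order(staleness)
  keep <- fresh[!duplicated(nodes[fresh])]
  global$model <- model_parameters(tensors, global$model$partition_index)
  global$round_clock <- now + 1L
  global$current_loss <- global_loss(sizes[keep], losses[keep])
  global$history[[length(global$history) + 1L]] <- list(
    time = global$round_clock,
    nodes = vapply(updates, `[[`, integer(1), "node_id"),
    kinds = vapply(updates, `[[`, character(1), "kind"),
    staleness = staleness,
    elements = vapply(updates, message_elements, integer(1)),
    coefficients = coeff_log,
    loss = global$current_loss)
  global
}

#' Synchronous federated-averaging aggregation (baseline)
#'
#' The classical data-size-weighted mean of full parameter sets: every
#' update must carry all tensors, and the staleness weight is fixed at 1,
#' so the result coincides with the temporally weighted aggregation at
#' zero staleness.
#'
#' @param updates Non-empty list of [update_message()]s, each carrying the
#'   full parameter collection.
#' @param global A [global_state()].
#' @param config A [federation_config()].
#' @return The updated [global_state()].
#' @export
fedavg_aggregate <- function(updates, global, config = federation_config()) {
  k <- length(global$model$tensors)
  for (u in updates)
    if (!identical(u$tensor_indices, seq_len(k)))
      stop("aggregation error: synchronous updates must carry full ",
           "parameter sets", call. = FALSE)
  aggregate_updates(updates, global, staleness = rep(0, length(updates)),
                    config = config)
}

#' Run the server loop until the loss threshold is reached
#'
#' Repeatedly pulls a batch of updates from `update_stream` and aggregates
#' it, stopping as soon as the current global loss is `<= E`, the safety
#' cap `max_updates` is reached, or the stream is exhausted. The returned
#' state carries a `stop_reason` of `"converged"`, `"max_updates"` or
#' `"stream_exhausted"`.
#'
#' @param global A [global_state()].
#' @param E Loss threshold (`>= 0`).
#' @param update_stream A function of no arguments returning the next
#'   batch (a list of [update_message()]s) or `NULL` when exhausted.
#' @param max_updates Safety cap on aggregation events (`>= 0`).
#' @param config A [federation_config()].
#' @return The final [global_state()] with `stop_reason` set.
#' @export
server_loop <- function(global, E, update_stream, max_updates = 500L,
                        config = federation_config()) {
  stopifnot(E >= 0, max_updates >= 0)
  done <- 0L
  while (global$current_loss > E) {
    if (done >= max_updates) {
      global$stop_reason <- "max_updates"
      return(global)
    }
    batch <- update_stream()
    if (is.null(batch)) {
      global$stop_reason <- "stream_exhausted"
      return(global)
    }
    global <- aggregate_updates(batch, global, config = config)
    done <- done + 1L
  }
  global$stop_reason <- "converged"
  global
}

#' Aggregation trace of a run
#'
#' One row per (aggregation event, contributing node): the server time,
#' node id, message kind, staleness, transmitted element count, the
#' normalised coefficient mass the node received, and the post-event
#' global loss.
#'
#' @param global A [global_state()].
#' @return A data frame; zero rows if nothing was aggregated.
#' @export
aggregation_trace <- function(global) {
  if (length(global$history) == 0L)
    return(data.frame(time = integer(0), node = integer(0),
                      kind = character(0), staleness = numeric(0),
                      elements = integer(0), loss = numeric(0)))
  do.call(rbind, lapply(global$history, function(h)
    data.frame(time = h$time, node = h$nodes, kind = h$kinds,
               staleness = h$staleness, elements = h$elements,
               loss = h$loss, stringsAsFactors = FALSE)))
}
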