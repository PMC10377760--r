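#' Client node state
#'
#' One node of the federation: its private encoded records, its local copy
#' of the shared model, an append-only block log auditing every global
#' model state it received, and the list of iterations at which it
#' performed a deep exchange. The raw records never leave this object, and
#' [purge_data()] removes them irreversibly at the end of a run.
#'
#' @param node_id Integer index of the node in `1..Z`.
#' @param model A [model_parameters()] object (the initially broadcast
#'   global model).
#' @param data A `heart_dataset` of the node's private records.
#' @param config A [federation_config()].
#' @return A `client_state` object.
#' @export
client_state <- function(node_id, model, data, config) {
  stopifnot(inherits(model, "model_parameters"),
            inherits(data, "heart_dataset"),
            inherits(config, "federation_config"))
  structure(list(node_id = as.integer(node_id), model = model, data = data,
                 block = .empty_block_log(), timesteps = integer(0),
                 purged = FALSE, config = config),
            class = "client_state")
}

.empty_block_log <- function() {
  data.frame(iteration = integer(0), fingerprint = character(0),
             note = character(0), timestamp = integer(0),
             stringsAsFactors = FALSE)
}

# logical clock: block entries are stamped with their own sequence number,
# keeping runs byte-reproducible
.append_block <- function(state, iteration, fingerprint, note) {
  if (nrow(state$block) &&
      iteration <= state$block$iteration[nrow(state$block)])
    stop("block log error: iterations must be strictly increasing",
         call. = FALSE)
  state$block <- rbind(state$block, data.frame(
    iteration = as.integer(iteration), fingerprint = fingerprint,
    note = note, timestamp = nrow(state$block) + 1L,
    stringsAsFactors = FALSE))
  state
}

.check_not_purged <- function(state) {
  if (isTRUE(state$purged) || is.null(state$data))
    stop("purged error: node ", state$node_id,
         " has deleted its private data", call. = FALSE)
}

#' Does the node hold enough data to participate?
#'
#' Compares the node's private data size against the minimum acceptable
#' size `beta`; nodes below the threshold stay silent for the whole run
#' (they still receive global broadcasts).
#'
#' @param state A [client_state()].
#' @return Logical participation flag.
#' @export
check_data_size <- function(state) {
  stopifnot(inherits(state, "client_state"))
  .check_not_purged(state)
  nrow(state$data$features) >= state$config$beta
}

#' Construct a client-to-server update message
#'
#' Deep messages (sent on iterations divisible by `Delta`) carry the deep
#' tensor group, the client's deep-exchange timestep and a digest of its
#' block log; shallow messages carry only the shallow tensor group.
#' `"full"` messages (the synchronous baseline) carry everything.
#'
#' @param node_id Sender index.
#' @param kind `"deep"`, `"shallow"` or `"full"`.
#' @param weights List of tensors being transmitted.
#' @param tensor_indices Positions of `weights` within the full parameter
#'   collection.
#' @param data_size Sender's private record count.
#' @param local_loss Sender's current local loss `f_i`.
#' @param timestep Deep messages only: the iteration recorded in the
#'   sender's timestep list.
#' @param block_digest Deep messages only: fingerprint of the sender's
#'   block log.
#' @return An `update_message` object.
#' @export
update_message <- function(node_id, kind, weights, tensor_indices, data_size,
                           local_loss, timestep = NULL, block_digest = NULL) {
  kind <- match.arg(kind, c("deep", "shallow", "full"))
  if (kind == "deep" && (is.null(timestep) || is.null(block_digest)))
    stop("deep messages must carry a timestep and block digest",
         call. = FALSE)
  if (kind == "shallow" && (!is.null(timestep) || !is.null(block_digest)))
    stop("shallow messages carry neither timestep nor block digest",
         call. = FALSE)
  stopifnot(length(weights) == length(tensor_indices))
  structure(list(node_id = as.integer(node_id), kind = kind,
                 weights = weights,
                 tensor_indices = as.integer(tensor_indices),
                 data_size = as.integer(data_size),
                 local_loss = local_loss, timestep = timestep,
                 block_digest = block_digest),
            class = "update_message")
}

#' Number of scalar parameters carried by a message
#' @param msg An [update_message()].
#' @return Integer element count.
#' @export
message_elements <- function(msg) {
  sum(vapply(msg$weights, length, integer(1)))
}

#' Run one client iteration of the asynchronous protocol
#'
#' Performs one local training pass, then extracts the parameter subset
#' due this iteration: on iterations with `l mod Delta == 0` the deep
#' group is extracted, `l` is appended to the node's timestep list and the
#' block-log digest is attached; otherwise the shallow group is extracted.
#'
#' @param state A [client_state()]; must not be purged.
#' @param l Iteration number in `1..L`.
#' @return List with `state` (updated [client_state()]) and `message`
#'   (the [update_message()] to transmit).
#' @export
client_iteration <- function(state, l) {
  stopifnot(inherits(state, "client_state"))
  .check_not_purged(state)
  cfg <- state$config
  if (l < 1L || l > cfg$L)
    stop("schedule error: iteration ", l, " outside 1..", cfg$L,
         call. = FALSE)
  fit <- train_local(state$model, state$data, epochs = cfg$epochs,
                     learning_rate = cfg$learning_rate,
                     seed = derive_seed(cfg$seed,
                                        paste0("train", state$node_id, ".", l)))
  state$model <- fit$params
  n <- nrow(state$data$features)
  if (l %% cfg$Delta == 0L) {
    state$timesteps <- c(state$timesteps, as.integer(l))
    idx <- deep_indices(state$model)
    msg <- update_message(state$node_id, "deep", state$model$tensors[idx],
                          idx, n, fit$loss, timestep = as.integer(l),
                          block_digest = block_digest(state))
  } else {
    idx <- shallow_indices(state$model)
    msg <- update_message(state$node_id, "shallow", state$model$tensors[idx],
                          idx, n, fit$loss)
  }
  list(state = state, message = msg)
}

#' Fingerprint of a node's block log
#' @param state A [client_state()].
#' @return Character digest of the log entries.
#' @export
block_digest <- function(state) {
  if (nrow(state$block) == 0L) return("00000000")
  param_fingerprint(list(as.numeric(state$block$iteration),
                         as.numeric(utf8ToInt(paste(
                           state$block$fingerprint, collapse = "|")))))
}

#' Install a broadcast global model on a node
#'
#' Replaces the node's local model with the received global parameters
#' (shapes must match) and appends a block-log entry recording the
#' iteration and the global model's fingerprint. In the layer-split
#' protocol the downlink mirrors the uplink: after a shallow exchange
#' only the shallow tensor group is replaced (`tensor_indices`), leaving
#' the node's locally evolving deep layers intact until its next deep
#' exchange.
#'
#' @param state A [client_state()].
#' @param global A [model_parameters()] object from the server.
#' @param l Iteration at which the broadcast is received; must exceed the
#'   last logged iteration.
#' @param note Audit note stored in the block log.
#' @param tensor_indices Positions of the tensors to take from the
#'   broadcast; `NULL` (the default) replaces the full model.
#' @return The updated [client_state()].
#' @export
apply_global <- function(state, global, l, note = "global-update",
                         tensor_indices = NULL) {
  stopifnot(inherits(state, "client_state"),
            inherits(global, "model_parameters"))
  old <- state$model$tensors
  new <- global$tensors
  if (length(old) != length(new))
    stop("shape error: expected ", length(old), " tensors, got ",
         length(new), call. = FALSE)
  for (i in seq_along(old)) {
    if (!identical(dim(old[[i]]) %||% length(old[[i]]),
                   dim(new[[i]]) %||% length(new[[i]])))
      stop("shape error: tensor ", i, " has mismatched dimensions",
           call. = FALSE)
  }
  idx <- tensor_indices %||% seq_along(old)
  old[idx] <- new[idx]
  state$model <- model_parameters(old, state$model$partition_index)
  .append_block(state, l, param_fingerprint(global), note)
}

#' Irreversibly delete a node's private data
#'
#' Implements the end-of-run purge: the records are dropped, the block log
#' and timestep record are retained for audit, and any later attempt to
#' train or read the data raises the purged error. Idempotent.
#'
#' @param state A [client_state()].
#' @return The purged [client_state()].
#' @export
purge_data <- function(state) {
  stopifnot(inherits(state, "client_state"))
  state$data <- NULL
  state$purged <- TRUE
  state
}
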