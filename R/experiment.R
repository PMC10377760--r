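# shared setup for both federation modes: split, partition, architecture,
# initial global model and client states
.prepare_federation <- function(config, dataset) {
  stopifnot(inherits(config, "federation_config"),
            inherits(dataset, "heart_dataset"))
  split <- split_train_test(dataset, config$test_fraction,
                            seed = derive_seed(config$seed, "split"))
  shards <- partition_clients(split$train, config$Z,
                              seed = derive_seed(config$seed, "partition"))
  p <- ncol(dataset$features)
  arch <- architecture(c(p, config$hidden, 1L), alpha = config$alpha)
  global <- global_state(init_model(arch, derive_seed(config$seed, "init")))
  states <- lapply(seq_len(config$Z), function(z)
    client_state(z, global$model, shards[[z]], config))
  participating <- vapply(states, check_data_size, logical(1))
  list(split = split, shards = shards, arch = arch, global = global,
       states = states, participating = participating)
}

.evaluate_global <- function(global, dataset) {
  if (nrow(dataset$features) == 0L)
    return(list(counts = NULL, metrics = list(accuracy = NA_real_,
                precision = NA_real_, recall = NA_real_, f1 = NA_real_,
                undefined = character(0))))
  pred <- as.integer(mlp_predict(global$model, dataset$features) > 0.5)
  counts <- confusion_counts(pred, dataset$labels)
  list(counts = counts, metrics = compute_metrics(counts))
}

.make_report <- function(mode, config, prep, global, loss_traj, rounds,
                         states, train_eval, test_eval, uplink) {
  if (is.null(uplink))
    uplink <- data.frame(time = integer(0), node = integer(0),
                         kind = character(0), elements = integer(0))
  trace <- aggregation_trace(global)
  per_client <- if (nrow(uplink))
    tapply(uplink$elements, factor(uplink$node, levels = seq_len(config$Z)),
           sum, default = 0L)
  else stats::setNames(rep(0L, config$Z), seq_len(config$Z))
  structure(list(
    mode = mode, Z = config$Z,
    loss_trajectory = loss_traj,
    rounds = rounds,
    stop_reason = global$stop_reason %||% NA_character_,
    counts = test_eval$counts,
    accuracy = test_eval$metrics$accuracy,
    precision = test_eval$metrics$precision,
    recall = test_eval$metrics$recall,
    f1 = test_eval$metrics$f1,
    train_accuracy = train_eval$metrics$accuracy,
    communication = list(messages = nrow(uplink),
                         parameters = sum(uplink$elements),
                         per_client = as.vector(per_client)),
    uplink = uplink,
    partition_sizes = vapply(prep$shards, function(d) nrow(d$features),
                             integer(1)),
    global = global, clients = states, trace = trace,
    seed = config$seed, config = config), class = "fl_report")
}

#' @export
print.fl_report <- function(x, ...) {
  cat(sprintf("Federated run (%s): Z=%d, %d aggregation event(s), stop: %s\n",
              x$mode, x$Z, x$rounds, x$stop_reason))
  cat(sprintf("  final global loss %.4f | test accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f\n",
              utils::tail(x$loss_trajectory, 1L), x$accuracy, x$precision,
              x$recall, x$f1))
  cat(sprintf("  uplink: %d message(s), %d parameters transmitted\n",
              x$communication$messages, x$communication$parameters))
  invisible(x)
}

#' Run a synchronous federated-averaging experiment
#'
#' The baseline protocol: in every round all participating clients receive
#' the current global model, run their local gradient steps, and upload
#' their *full* parameter sets; the server replaces the global model by
#' the data-size-weighted average and the next round begins. The run stops
#' early once the size-weighted global loss reaches the threshold `E`.
#' After the final round every client's private data are purged.
#'
#' @param config A [federation_config()].
#' @param dataset A `heart_dataset`; internally split into train/test and
#'   partitioned across the `Z` clients.
#' @return An `fl_report` (see [print.fl_report()]): metrics on the
#'   held-out test split, the loss trajectory, communication totals, the
#'   aggregation trace and the purged client states.
#' @export
run_sync <- function(config, dataset) {
  prep <- .prepare_federation(config, dataset)
  global <- prep$global
  states <- prep$states
  if (!any(prep$participating))
    stop("no client meets the minimum data size beta", call. = FALSE)
  loss_traj <- numeric(0)
  rounds <- 0L
  uplink <- list()
  for (r in seq_len(config$L)) {
    msgs <- list()
    for (z in seq_len(config$Z)) {
      states[[z]] <- apply_global(states[[z]], global$model, r,
                                  note = "sync-broadcast")
      if (!prep$participating[z]) next
      fit <- train_local(states[[z]]$model, states[[z]]$data,
                         epochs = config$epochs,
                         learning_rate = config$learning_rate,
                         seed = derive_seed(config$seed,
                                            paste0("train", z, ".", r)))
      states[[z]]$model <- fit$params
      msg <- update_message(
        z, "full", fit$params$tensors, seq_along(fit$params$tensors),
        nrow(states[[z]]$data$features), fit$loss)
      msgs[[length(msgs) + 1L]] <- msg
      uplink[[length(uplink) + 1L]] <- data.frame(
        time = r, node = z, kind = "full",
        elements = message_elements(msg))
    }
    global <- fedavg_aggregate(msgs, global, config)
    loss_traj <- c(loss_traj, global$current_loss)
    rounds <- r
    if (global$current_loss <= config$E) break
  }
  global$stop_reason <- if (global$current_loss <= config$E) "converged"
                        else "iterations_exhausted"
  train_eval <- .evaluate_global(global, prep$split$train)
  test_eval <- .evaluate_global(global, prep$split$test)
  states <- lapply(states, purge_data)
  .make_report("sync", config, prep, global, loss_traj, rounds, states,
               train_eval, test_eval, do.call(rbind, uplink))
}

#' Arrival schedule for an asynchronous run
#'
#' Each client has a lag factor: client `z`'s `l`-th iteration arrives at
#' the server at simulated time `l * (1 + lag[z])`. The default (all lags
#' zero) makes every iteration's arrivals simultaneous, i.e. the lockstep
#' layer-split protocol in which only the deep/shallow exchange frequency
#' is asynchronous; unequal lags additionally desynchronise the client
#' clocks, interleaving slow and fast nodes so updates arrive stale and
#' the temporal weighting becomes active.
#'
#' @param Z Number of clients.
#' @param lags Numeric vector of per-client lag factors (`>= 0`), recycled
#'   to length `Z`.
#' @return An `async_schedule` object.
#' @export
async_schedule <- function(Z, lags = 0) {
  lags <- rep_len(lags, Z)
  if (any(lags < 0)) stop("lags must be >= 0", call. = FALSE)
  structure(list(Z = as.integer(Z), lags = lags), class = "async_schedule")
}

#' @rdname async_schedule
#' @param max_lag Upper bound for uniformly drawn random lags.
#' @param seed Integer seed for the draw.
#' @export
random_schedule <- function(Z, max_lag = 0.5, seed = 1L) {
  async_schedule(Z, with_seed(seed, stats::runif(Z, 0, max_lag)))
}

#' Run an asynchronous federated experiment
#'
#' Clients iterate on their own clocks: each runs up to `L` local
#' iterations, uploading the deep tensor group on iterations divisible by
#' `Delta` and the shallow group otherwise. The server keeps, per client,
#' the most recent deep and shallow update it has received; on each
#' arrival (arrivals sharing an arrival time form one batch) it
#' re-aggregates the global model as the convex combination of *all*
#' cached updates, each weighted by its sender's data size times a
#' staleness weight that decays with the number of aggregation events
#' since the update was received. Fresh arrivals therefore dominate while
#' clients that have fallen behind fade smoothly rather than being either
#' frozen in or discarded. The fresh global model is broadcast back to
#' the arriving client(s) only; the others pick it up at their next
#' arrival. The run stops once the size-weighted global loss reaches `E`
#' or every client has finished its `L` iterations; client data are
#' purged either way.
#'
#' @param config A [federation_config()].
#' @param dataset A `heart_dataset`.
#' @param schedule An [async_schedule()]; default is the lockstep
#'   zero-lag schedule. Use [random_schedule()] to desynchronise the
#'   client clocks.
#' @return An `fl_report`, as for [run_sync()]. Communication totals count
#'   actual client-to-server transmissions, not cache reads.
#' @export
run_async <- function(config, dataset, schedule = NULL) {
  prep <- .prepare_federation(config, dataset)
  if (is.null(schedule))
    schedule <- async_schedule(config$Z)
  stopifnot(inherits(schedule, "async_schedule"),
            schedule$Z == config$Z)
  global <- prep$global
  states <- prep$states
  if (!any(prep$participating))
    stop("no client meets the minimum data size beta", call. = FALSE)

  # arrival queue: client z's l-th update lands at l * (1 + lag_z)
  active <- which(prep$participating)
  events <- do.call(rbind, lapply(active, function(z)
    data.frame(time = seq_len(config$L) * (1 + schedule$lags[z]),
               z = z, l = seq_len(config$L))))
  events <- events[order(events$time, events$z), , drop = FALSE]
  groups <- split(seq_len(nrow(events)), match(events$time,
                                               unique(events$time)))

  total_size <- sum(vapply(states[active], function(s)
    nrow(s$data$features), integer(1)))
  last_sync <- rep(0L, config$Z)
  uplink <- list()
  loss_traj <- numeric(0)
  stopped <- FALSE
  for (g in groups) {
    now <- global$round_clock
    msgs <- list()
    for (i in g) {
      z <- events$z[i]; l <- events$l[i]
      step <- client_iteration(states[[z]], l)
      states[[z]] <- step$state
      msgs[[length(msgs) + 1L]] <- step$message
      uplink[[length(uplink) + 1L]] <- data.frame(
        time = now, node = z, kind = step$message$kind,
        elements = message_elements(step$message))
    }
    # staleness on the federation-round scale: one round of wall time is
    # one arrival from each active client, i.e. Z_active server events
    staleness <- as.numeric(now - last_sync[events$z[g]]) / length(active)
    global <- aggregate_updates(msgs, global, staleness = staleness,
                                config = config, total_size = total_size)
    for (i in g) {
      z <- events$z[i]
      # downlink mirrors uplink: the client takes back the tensor group
      # it just exchanged and keeps the other group evolving locally
      kind <- if (events$l[i] %% config$Delta == 0L) "deep" else "shallow"
      idx <- if (kind == "deep") deep_indices(states[[z]]$model)
             else shallow_indices(states[[z]]$model)
      states[[z]] <- apply_global(states[[z]], global$model, events$l[i],
                                  note = paste0("async-", kind, "-broadcast"),
                                  tensor_indices = idx)
      last_sync[z] <- global$round_clock
    }
    loss_traj <- c(loss_traj, global$current_loss)
    if (global$current_loss <= config$E) { stopped <- TRUE; break }
  }
  global$stop_reason <- if (stopped) "converged" else "iterations_exhausted"
  # silent (below-beta) clients still receive the final broadcast
  for (z in which(!prep$participating))
    states[[z]] <- apply_global(states[[z]], global$model, config$L + 1L,
                                note = "final-broadcast")
  train_eval <- .evaluate_global(global, prep$split$train)
  test_eval <- .evaluate_global(global, prep$split$test)
  states <- lapply(states, purge_data)
  .make_report("async", config, prep, global, loss_traj,
               global$round_clock, states, train_eval, test_eval,
               do.call(rbind, uplink))
}

#' Uplink communication cost of the layer-split schedule
#'
#' Over `L` iterations with deep-exchange period `Delta`, each
#' participating client uploads the deep tensor group `floor(L / Delta)`
#' times and the shallow group the remaining `L - floor(L / Delta)` times,
#' so the per-client uplink is
#' `floor(L/Delta) * deep + (L - floor(L/Delta)) * shallow` scalar
#' parameters. The synchronous baseline uploads the full model every
#' round: `L * (deep + shallow)` per client.
#'
#' @param deep_elements Scalar parameters in the deep tensor group.
#' @param shallow_elements Scalar parameters in the shallow group.
#' @param Delta Deep-exchange period.
#' @param L Iterations per client.
#' @param Z Number of participating clients.
#' @param trace Optional aggregation trace (a data frame with an
#'   `elements` column) from a completed full-length run; when supplied,
#'   its transmitted totals must reconcile exactly with the schedule
#'   arithmetic, otherwise an accounting error is raised.
#' @return List with `per_client_uplink`, `total_uplink`, `messages`,
#'   `deep_messages_per_client`, `sync_baseline_per_client` and
#'   `sync_baseline_total` (all in scalar-parameter or message counts).
#' @examples
#' communication_cost(300, 700, Delta = 5, L = 10, Z = 1)$per_client_uplink
#' @export
communication_cost <- function(deep_elements, shallow_elements, Delta, L, Z,
                               trace = NULL) {
  stopifnot(Delta >= 1, L >= 1, Z >= 1)
  n_deep <- L %/% Delta
  per_client <- n_deep * deep_elements + (L - n_deep) * shallow_elements
  out <- list(per_client_uplink = per_client,
              total_uplink = per_client * Z,
              messages = L * Z,
              deep_messages_per_client = n_deep,
              sync_baseline_per_client = L * (deep_elements + shallow_elements),
              sync_baseline_total = L * (deep_elements + shallow_elements) * Z)
  if (!is.null(trace)) {
    got <- sum(trace$elements)
    if (got != out$total_uplink)
      stop("accounting error: trace carries ", got,
           " parameters but the schedule implies ", out$total_uplink,
           call. = FALSE)
  }
  out
}

#' Sweep the federation size for both protocols
#'
#' Runs one synchronous and one asynchronous experiment per node count and
#' collects accuracy, precision and F1 into a method-by-metric grid with
#' one column per node count.
#'
#' @param config A [federation_config()]; its `Z` is overridden per run.
#' @param dataset A `heart_dataset`.
#' @param node_counts Integer vector of federation sizes (all `>= 1`).
#' @return An `fl_sweep`: list with `reports` (nested by mode then node
#'   count) and `grid` (data frame: method, metric, one column per Z).
#' @export
sweep_nodes <- function(config, dataset, node_counts = c(2L, 4L, 6L, 8L, 10L)) {
  stopifnot(all(node_counts >= 1))
  reports <- list(sync = list(), async = list())
  for (Z in node_counts) {
    cfg <- config
    cfg$Z <- as.integer(Z)
    reports$sync[[as.character(Z)]] <- run_sync(cfg, dataset)
    reports$async[[as.character(Z)]] <- run_async(cfg, dataset)
  }
  metrics <- c("accuracy", "precision", "f1")
  grid <- do.call(rbind, lapply(c("sync", "async"), function(m)
    do.call(rbind, lapply(metrics, function(met) {
      row <- data.frame(method = paste0(m, "-FL"), metric = met,
                        stringsAsFactors = FALSE)
      for (Z in node_counts)
        row[[paste0("Z", Z)]] <- reports[[m]][[as.character(Z)]][[met]]
      row
    }))))
  structure(list(reports = reports, grid = grid,
                 node_counts = node_counts, config = config),
            class = "fl_sweep")
}

#' @export
print.fl_sweep <- function(x, digits = 3, ...) {
  cat("Federation-size sweep (", paste(x$node_counts, collapse = ", "),
      " nodes)\n", sep = "")
  g <- x$grid
  num <- vapply(g, is.numeric, logical(1))
  g[num] <- lapply(g[num], round, digits)
  print(g, row.names = FALSE)
  invisible(x)
}
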