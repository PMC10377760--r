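contrib_cfg <- function(...) federation_config(blend = "contributors", ...)

test_that("staleness weight is 1 when fresh and strictly decays", {
  expect_equal(temporal_weight(5, 5), 1)
  expect_equal(temporal_weight(5, 4), (exp(1) / 2)^(-1))
  expect_equal(temporal_weight(10, 7), (exp(1) / 2)^(-3))
  w <- temporal_weight(10, 10:0)
  expect_true(all(diff(w) < 0))
  expect_error(temporal_weight(3, 4), "causality error")
})

test_that("aggregation forms a normalized convex combination per tensor", {
  m <- init_model(tiny_arch(), 1)
  g <- global_state(m)
  # all clients identical -> global exactly equals them
  u1 <- scalar_update(1L, 0.5, m, 10L, 0.4)
  u2 <- scalar_update(2L, 0.5, m, 30L, 0.8)
  out <- aggregate_updates(list(u1, u2), g)
  expect_true(all(vapply(out$model$tensors,
                         function(t) all(t == 0.5), logical(1))))
  # equal sizes, equal staleness, scalar values 0 and 2 -> 1
  out2 <- aggregate_updates(list(scalar_update(1L, 0, m, 10L, 0.5),
                                 scalar_update(2L, 2, m, 10L, 0.5)), g)
  expect_true(all(vapply(out2$model$tensors,
                         function(t) all(t == 1), logical(1))))
  # sizes (1,3), losses (0.4, 0.8): values mix 0.25/0.75 and Eq-loss is 0.7
  out3 <- aggregate_updates(list(scalar_update(1L, 0.4, m, 1L, 0.4),
                                 scalar_update(2L, 0.8, m, 3L, 0.8)), g)
  expect_equal(out3$model$tensors[[1]][1, 1], 0.25 * 0.4 + 0.75 * 0.8)
  expect_equal(out3$current_loss, 0.7)
  expect_equal(out3$round_clock, 1L)
  # coefficients recorded in the trace always sum to 1 per tensor
  for (cf in out3$history[[1]]$coefficients)
    expect_equal(sum(cf), 1)
  expect_error(aggregate_updates(list(), g), "aggregation error")
})

test_that("aggregation is permutation-invariant and shape-checked", {
  set.seed(41)
  m <- init_model(tiny_arch(), 2)
  g <- global_state(m)
  us <- lapply(1:4, function(z) {
    tensors <- lapply(m$tensors, function(t) {
      t[] <- rnorm(length(t)); t
    })
    update_message(z, "full", tensors, seq_along(tensors),
                   sample(5:50, 1), runif(1))
  })
  a <- aggregate_updates(us, g)
  b <- aggregate_updates(rev(us), g)
  expect_equal(a$model$tensors, b$model$tensors, tolerance = 1e-12)
  bad <- us[[1]]
  bad$weights[[1]] <- matrix(0, 5, 5)
  expect_error(aggregate_updates(list(bad), g), "shape error")
})

test_that("shallow-only aggregation leaves every deep global tensor bit-identical", {
  m <- init_model(architecture(c(4, 3, 2, 1), alpha = 0.5), 3)
  g <- global_state(m)
  si <- shallow_indices(m)
  di <- deep_indices(m)
  shallow_msg <- update_message(1L, "shallow",
                                lapply(m$tensors[si], function(t) t + 1),
                                si, 10L, 0.5)
  out <- aggregate_updates(list(shallow_msg), g)
  expect_identical(out$model$tensors[di], m$tensors[di])
  expect_equal(out$model$tensors[[si[1]]], m$tensors[[si[1]]] + 1)
})

test_that("stale updates are down-weighted by the staleness schedule", {
  m <- init_model(tiny_arch(), 4)
  g <- global_state(m)
  g$round_clock <- 3L
  fresh <- scalar_update(1L, 1, m, 10L, 0.5)
  stale <- scalar_update(2L, 0, m, 10L, 0.5)
  out <- aggregate_updates(list(fresh, stale), g, staleness = c(0, 2),
                           config = contrib_cfg())
  wf <- 1
  ws <- (exp(1) / 2)^(-2)
  expect_equal(out$model$tensors[[1]][1, 1], wf / (wf + ws),
               tolerance = 1e-12)
  expect_error(aggregate_updates(list(fresh), g, staleness = -1),
               "causality")
})

test_that("the global blend folds arrivals into the global by their weighted data share", {
  m <- init_model(tiny_arch(), 5)
  zero <- model_parameters(lapply(m$tensors, function(t) {
    t[] <- 0; t
  }), m$partition_index)
  g <- global_state(zero)
  lone <- scalar_update(1L, 1, m, 20L, 0.5)
  out <- aggregate_updates(list(lone), g, staleness = 1,
                           config = federation_config(blend = "global"),
                           total_size = 100L)
  w <- 20 * (exp(1) / 2)^(-1) / 100
  expect_equal(out$model$tensors[[1]][1, 1], w, tolerance = 1e-12)
  # with a full fresh batch the blend reduces to the pure convex combination
  full <- list(scalar_update(1L, 0, m, 30L, 0.5),
               scalar_update(2L, 2, m, 70L, 0.5))
  out2 <- aggregate_updates(full, g, staleness = c(0, 0),
                            config = federation_config(blend = "global"),
                            total_size = 100L)
  expect_equal(out2$model$tensors[[1]][1, 1], 1.4, tolerance = 1e-12)
})

test_that("synchronous averaging equals the element-wise weighted-mean oracle", {
  set.seed(55)
  for (i in 1:100) {
    m <- init_model(tiny_arch(p = sample(2:5, 1)), i)
    g <- global_state(m)
    k <- sample(2:6, 1)
    sizes <- sample(1:100, k)
    us <- lapply(seq_len(k), function(z) {
      tensors <- lapply(m$tensors, function(t) {
        t[] <- rnorm(length(t)); t
      })
      update_message(z, "full", tensors, seq_along(tensors), sizes[z],
                     runif(1))
    })
    out <- fedavg_aggregate(us, g)
    wts <- sizes / sum(sizes)
    for (j in seq_along(m$tensors)) {
      oracle <- Reduce(`+`, Map(function(u, w) u$weights[[j]] * w, us,
                                as.list(wts)))
      expect_equal(out$model$tensors[[j]], oracle, tolerance = 1e-12)
    }
  }
})

test_that("fedavg requires full parameter sets and handles a single client", {
  m <- init_model(tiny_arch(), 6)
  g <- global_state(m)
  u <- scalar_update(1L, 3, m, 10L, 0.2)
  out <- fedavg_aggregate(list(u), g)
  expect_identical(out$model$tensors, u$weights)
  trio <- lapply(1:3, function(z) scalar_update(z, (z - 1) * 3, m, 10L, 0.5))
  out3 <- fedavg_aggregate(trio, g)
  expect_equal(out3$model$tensors[[1]][1, 1], 3)
  partial <- update_message(1L, "shallow", m$tensors[1:2], 1:2, 10L, 0.5)
  expect_error(fedavg_aggregate(list(partial), g), "full")
})

test_that("the server loop stops on threshold, exhaustion or the safety cap", {
  m <- init_model(tiny_arch(), 7)
  # scripted stream with losses crossing E = 0.45 at the seventh update
  losses <- c(1, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3)
  mk_stream <- function(ls) {
    i <- 0L
    function() {
      i <<- i + 1L
      if (i > length(ls)) return(NULL)
      list(scalar_update(1L, 0, m, 10L, ls[i]))
    }
  }
  out <- server_loop(global_state(m), E = 0.45, mk_stream(losses))
  expect_equal(out$round_clock, 7L)
  expect_identical(out$stop_reason, "converged")
  # already converged global performs zero aggregations
  g2 <- global_state(m)
  g2$current_loss <- 0.1
  out2 <- server_loop(g2, E = 0.45, mk_stream(losses))
  expect_equal(out2$round_clock, 0L)
  expect_identical(out2$stop_reason, "converged")
  # E = 0 with positive losses runs to the cap
  out3 <- server_loop(global_state(m), E = 0,
                      mk_stream(rep(0.5, 100)), max_updates = 5L)
  expect_equal(out3$round_clock, 5L)
  expect_identical(out3$stop_reason, "max_updates")
  out4 <- server_loop(global_state(m), E = 0, mk_stream(c(0.9, 0.8)))
  expect_identical(out4$stop_reason, "stream_exhausted")
})
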