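test_that("single-node synchronous FL equals centralized gradient descent", {
  d <- generate_dataset(generator_config(n = 120, seed = 2))
  cfg <- federation_config(Z = 1, Delta = 1, L = 15, alpha = 1, E = 0,
                           seed = 9, epochs = 2)
  rep1 <- run_sync(cfg, d)
  sp <- split_train_test(d, cfg$test_fraction,
                         seed = fedheart:::derive_seed(cfg$seed, "split"))
  m0 <- init_model(architecture(c(ncol(d$features), cfg$hidden, 1L),
                                alpha = cfg$alpha),
                   fedheart:::derive_seed(cfg$seed, "init"))
  central <- train_local(m0, sp$train, epochs = cfg$L * cfg$epochs,
                         learning_rate = cfg$learning_rate)
  expect_equal(unlist(rep1$global$model$tensors),
               unlist(central$params$tensors), tolerance = 1e-10)
})

test_that("async with zero lags, Delta 1 and alpha 1 reproduces the sync trajectory", {
  d <- generate_dataset(generator_config(n = 150, seed = 3))
  cfg <- federation_config(Z = 4, Delta = 1, L = 12, alpha = 1, E = 0,
                           seed = 5, epochs = 1)
  rs <- run_sync(cfg, d)
  ra <- run_async(cfg, d, async_schedule(4, lags = 0))
  expect_equal(unlist(ra$global$model$tensors),
               unlist(rs$global$model$tensors), tolerance = 1e-10)
  expect_equal(ra$loss_trajectory, rs$loss_trajectory, tolerance = 1e-10)
})

test_that("runs are deterministic under a fixed master seed", {
  d <- generate_dataset(generator_config(n = 100, seed = 4))
  cfg <- federation_config(Z = 3, Delta = 2, L = 6, seed = 21, epochs = 1)
  a <- run_sync(cfg, d)
  b <- run_sync(cfg, d)
  expect_identical(a$global$model$tensors, b$global$model$tensors)
  expect_identical(a$loss_trajectory, b$loss_trajectory)
  expect_identical(a$counts, b$counts)
  sched <- random_schedule(3, max_lag = 0.4, seed = 8)
  c1 <- run_async(cfg, d, sched)
  c2 <- run_async(cfg, d, sched)
  expect_identical(c1$global$model$tensors, c2$global$model$tensors)
  expect_identical(c1$accuracy, c2$accuracy)
  expect_identical(c1$trace, c2$trace)
})

test_that("a 200-record cohort with no held-out fraction splits 40/40/40/40/40", {
  d <- generate_dataset(generator_config(n = 200, seed = 6))
  cfg <- federation_config(Z = 5, L = 3, test_fraction = 0, seed = 2,
                           epochs = 1)
  rep5 <- run_sync(cfg, d)
  expect_identical(rep5$partition_sizes, rep(40L, 5))
  expect_identical(rep5$config$Z, 5L)  # config echo for provenance
})

test_that("uplink accounting follows the layer-split schedule arithmetic", {
  cc <- communication_cost(300, 700, Delta = 5, L = 10, Z = 1)
  expect_equal(cc$per_client_uplink, 2 * 300 + 8 * 700)  # 6200
  expect_equal(cc$deep_messages_per_client, 2)
  expect_equal(cc$sync_baseline_per_client, 10 * 1000)
  # full exchange every iteration: uplink equals the sync baseline
  cc2 <- communication_cost(1000, 0, Delta = 1, L = 10, Z = 3)
  expect_equal(cc2$per_client_uplink, cc2$sync_baseline_per_client)
  # async never exceeds sync, strictly less when Delta > 1 and deep < P
  set.seed(61)
  for (i in 1:20) {
    de <- sample(1:500, 1); sh <- sample(1:500, 1)
    Dl <- sample(2:6, 1); L <- sample(Dl:40, 1)
    cci <- communication_cost(de, sh, Delta = Dl, L = L, Z = 2)
    expect_lt(cci$per_client_uplink, cci$sync_baseline_per_client)
  }
})

test_that("a full async run reconciles its trace with the schedule arithmetic", {
  d <- generate_dataset(generator_config(n = 120, seed = 7))
  cfg <- federation_config(Z = 4, Delta = 3, L = 9, alpha = 0.5, E = 0,
                           seed = 13, epochs = 1, test_fraction = 0)
  ra <- run_async(cfg, d)
  m <- ra$global$model
  de <- parameter_count(m, "deep")
  sh <- parameter_count(m, "shallow")
  cc <- communication_cost(de, sh, Delta = 3, L = 9, Z = 4,
                           trace = ra$uplink)
  expect_equal(ra$communication$parameters, cc$total_uplink)
  expect_equal(ra$communication$messages, cc$messages)
  expect_true(all(ra$communication$per_client == cc$per_client_uplink))
  # per client: floor(L/Delta) deep uplinks, the rest shallow
  deep_per_node <- tapply(ra$uplink$kind == "deep", ra$uplink$node, sum)
  expect_true(all(deep_per_node == 3))
  # conservation against the report
  expect_equal(nrow(ra$uplink), 4 * 9)
})

test_that("classification metrics follow their definitions with flagged zero denominators", {
  perfect <- compute_metrics(c(TP = 5, FP = 0, FN = 0, TN = 5))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  m <- compute_metrics(c(TP = 8, FP = 2, FN = 1, TN = 9))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 8 / 9)
  expect_equal(m$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))
  z <- compute_metrics(c(TP = 0, FP = 0, FN = 3, TN = 7))
  expect_equal(z$precision, 0)
  expect_true("precision" %in% z$undefined)
  expect_error(compute_metrics(c(TP = 0, FP = 0, FN = 0, TN = 0)),
               "empty evaluation")
  cts <- confusion_counts(c(1L, 0L, 1L, 1L), c(1L, 0L, 0L, 1L))
  expect_equal(unclass(cts), c(TP = 2L, FP = 1L, FN = 0L, TN = 1L))
})

test_that("reports keep metrics in range and totals consistent", {
  d <- generate_dataset(generator_config(n = 150, seed = 10))
  cfg <- federation_config(Z = 3, Delta = 2, L = 5, seed = 4, epochs = 1)
  for (r in list(run_sync(cfg, d), run_async(cfg, d))) {
    for (met in c("accuracy", "precision", "recall", "f1")) {
      expect_gte(r[[met]], 0)
      expect_lte(r[[met]], 1)
    }
    expect_equal(sum(r$communication$per_client),
                 r$communication$parameters)
    expect_equal(nrow(r$uplink), r$communication$messages)
  }
})

test_that("below-threshold clients stay silent but still receive the model", {
  d <- generate_dataset(generator_config(n = 100, seed = 12))
  # Z=4 shards of 25; beta of 26 silences everyone -> error
  cfg_all_silent <- federation_config(Z = 4, beta = 26, L = 3, seed = 1,
                                      test_fraction = 0, epochs = 1)
  expect_error(run_sync(cfg_all_silent, d), "minimum data size")
  # uneven split: 7 clients get 15/15/14/14/14/14/14; beta 15 keeps two
  cfg <- federation_config(Z = 7, beta = 15, L = 3, seed = 1,
                           test_fraction = 0, epochs = 1)
  r <- run_sync(cfg, d)
  expect_setequal(unique(r$uplink$node), 1:2)
  silent <- r$clients[[7]]
  expect_gt(nrow(silent$block), 0)   # received broadcasts
  expect_true(silent$purged)
})

test_that("the node sweep produces a grid shaped method x metric x nodes", {
  d <- generate_dataset(generator_config(n = 80, seed = 14))
  cfg <- federation_config(L = 3, seed = 5, epochs = 1)
  sw <- sweep_nodes(cfg, d, node_counts = c(2L, 4L))
  expect_length(sw$reports$sync, 2L)
  expect_length(sw$reports$async, 2L)
  expect_identical(names(sw$grid), c("method", "metric", "Z2", "Z4"))
  expect_equal(nrow(sw$grid), 6L)  # 2 methods x 3 metrics
  expect_identical(sw$reports$sync[["4"]]$Z, 4L)
})

test_that("every client is purged after a completed run in either mode", {
  d <- generate_dataset(generator_config(n = 90, seed = 15))
  cfg <- federation_config(Z = 3, L = 4, seed = 6, epochs = 1)
  for (r in list(run_sync(cfg, d), run_async(cfg, d))) {
    for (st in r$clients) {
      expect_true(st$purged)
      expect_null(st$data)
      expect_error(client_iteration(st, 1L), "purged error")
      expect_true(all(diff(st$block$iteration) > 0))
    }
  }
})
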