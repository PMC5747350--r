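test_that("objective is zero on self-consistent noise-free data", {
  ds <- toy_data_clean()$dataset
  loss <- objective(toy_truth()$params, toy_net(), ds)
  expect_gte(loss, 0)
  expect_lt(loss, 1e-10)
})

test_that("a single perturbed observation gives the closed-form loss", {
  sd <- toy_data_clean()
  ds <- sd$dataset
  m <- ds$measurements
  delta <- 0.07
  i <- which(m$node == "P1" & m$condition == "untreated")[1]
  v <- m$value[i] + delta
  m$value[i] <- min(v, 1)
  delta <- m$value[i] - (v - delta)
  ds$measurements <- m
  W <- sum(m$weight)
  expect_equal(objective(toy_truth()$params, toy_net(), ds),
               delta^2 * 1 / W, tolerance = 1e-6)
})

test_that("the penalty switches off at lambda = 0 and reacts to lambda", {
  net <- chol_net()
  tab <- compile_network(net)$par_table
  p <- named_params(tab)
  conds <- default_conditions()[1:3, ]
  sim <- vapply(seq_len(nrow(conds)), function(i)
    simulate_network(net, p, conds[i, ], end_time = conds$end_time[i])$terminal,
    numeric(length(dynamic_nodes(net))))
  rownames(sim) <- dynamic_nodes(net)
  meas <- measured_nodes(net)
  m <- data.frame(cell_line = "L1", node = rep(meas, nrow(conds)),
                  condition = rep(conds$condition, each = length(meas)),
                  replicate = 1,
                  time = rep(conds$end_time, each = length(meas)),
                  value = pmin(as.vector(sim[meas, ]), 1), weight = 1,
                  differential = FALSE, pseudo = FALSE)
  ds <- scaled_dataset(m, conds)
  l0 <- objective(p, net, ds, objective_config(lambda = 0))
  l1 <- objective(p, net, ds, objective_config(lambda = 1))
  l2 <- objective(p, net, ds, objective_config(lambda = 2))
  expect_lt(l0, 1e-10)  # data reproduced exactly, no penalty
  expect_gt(l1, 0)      # unmeasured nodes drift from 0.5 -> penalty
  expect_equal(l2 - l1, l1 - l0, tolerance = 1e-8)  # linear in lambda
})

test_that("bootstrap resampling is deterministic, shape-preserving, unbiased", {
  sd <- simulate_dataset(toy_net(), toy_truth(), cv = 0.2, bio_replicates = 3,
                         seed = 31)
  b1 <- bootstrap_dataset(sd$dataset, seed = 99)
  b2 <- bootstrap_dataset(sd$dataset, seed = 99)
  expect_identical(b1$measurements, b2$measurements)
  expect_identical(dim(b1$measurements), dim(sd$dataset$measurements))
  expect_setequal(unique(b1$measurements$value),
                  intersect(unique(b1$measurements$value),
                            sd$dataset$measurements$value))

  # single replicate everywhere: identical to input for any seed
  sd1 <- toy_data_clean()
  for (s in c(1, 77)) {
    expect_identical(bootstrap_dataset(sd1$dataset, s)$measurements$value,
                     sd1$dataset$measurements$value)
  }

  # bootstrap mean of replicates {0.2, 0.4, 0.6} is unbiased for 0.4
  reps <- data.frame(cell_line = "L1", node = "A", condition = "untreated",
                     replicate = 1:3, time = 10, value = c(0.2, 0.4, 0.6),
                     weight = 1, differential = FALSE, pseudo = FALSE)
  cond <- data.frame(condition = "untreated", end_time = 10, untreated = TRUE)
  ds <- scaled_dataset(reps, cond)
  means <- vapply(1:1000, function(s)
    mean(bootstrap_dataset(ds, s)$measurements$value), numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.4), 4 * se + 1e-3)
})

test_that("fitting rejects bad budgets and is deterministic", {
  ds <- toy_data_clean()$dataset
  expect_error(fit_once(toy_net(), ds, budget = 0), "budget")
  expect_error(fit_once(toy_net(), ds, budget = -5), "budget")
  f1 <- fit_once(toy_net(), ds, budget = 120, seed = 4, par_table = toy_tab(),
                 np = 12)
  f2 <- fit_once(toy_net(), ds, budget = 120, seed = 4, par_table = toy_tab(),
                 np = 12)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$loss, f2$loss)
  # fixed parameters never move
  fixed <- toy_tab()$name[toy_tab()$fixed]
  expect_identical(unname(f1$par[fixed]),
                   toy_tab()$value[toy_tab()$fixed])
})

test_that("more evaluations do not worsen the best-found loss (median over fits)", {
  ds <- toy_data_clean()$dataset
  small <- vapply(1:5, function(s)
    fit_once(toy_net(), ds, budget = 120, seed = s, par_table = toy_tab(),
             np = 12)$loss, numeric(1))
  large <- vapply(1:5, function(s)
    fit_once(toy_net(), ds, budget = 700, seed = s, par_table = toy_tab(),
             np = 12)$loss, numeric(1))
  expect_lte(median(large), median(small))
})

test_that("ensembles have the right shape, seeds and reproducibility", {
  ds <- toy_data_clean()$dataset
  e1 <- fit_ensemble(toy_net(), ds, n_models = 3, budget = 120, base_seed = 2,
                     cell_line = "cellline1", par_table = toy_tab())
  expect_s3_class(e1, "ensemble")
  expect_identical(nrow(e1$parameters), 3L)
  expect_identical(colnames(e1$parameters),
                   toy_tab()$name[!toy_tab()$fixed])
  e2 <- fit_ensemble(toy_net(), ds, n_models = 3, budget = 120, base_seed = 2,
                     cell_line = "cellline1", par_table = toy_tab())
  expect_identical(ensemble_losses(e1), ensemble_losses(e2))
  # degenerate single-model ensemble is valid
  e3 <- fit_ensemble(toy_net(), ds, n_models = 1, budget = 120,
                     par_table = toy_tab())
  expect_identical(nrow(e3$parameters), 1L)
})
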