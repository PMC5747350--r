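test_that("normalized Hill transfer is pinned, monotone and validated", {
  for (k in c(0.1, 0.5, 0.9)) {
    for (n in c(1, 2, 7)) {
      expect_identical(hill_transfer(0, k, n), 0)
      expect_equal(hill_transfer(1, k, n), 1)
    }
  }
  expect_equal(hill_transfer(0.5, k = 0.5, n = 2), 0.625)
  x <- seq(0, 1, by = 0.01)
  y <- hill_transfer(x, 0.3, 4)
  expect_true(all(diff(y) > 0))
  expect_true(all(y >= 0 & y <= 1))
  # agreement with the independently written closed form
  set.seed(1)
  for (i in 1:20) {
    xx <- runif(1); kk <- runif(1, 0.01, 1); nn <- runif(1, 1, 10)
    expect_equal(hill_transfer(xx, kk, nn), hill_oracle(xx, kk, nn))
  }
  expect_error(hill_transfer(1.2, 0.5, 2), "\\[0,1\\]")
  expect_error(hill_transfer(0.5, 0, 2), "k must")
  expect_error(hill_transfer(0.5, 0.5, 0.5), "n must")
})

test_that("build_rhs reproduces the hand-coded toy equations", {
  p <- named_params(toy_tab())
  f <- build_rhs(toy_net(), p)
  set.seed(11)
  for (i in 1:25) {
    x <- stats::setNames(runif(6), c("TF", "P1", "P2", "M1", "M2", "M3"))
    S <- runif(1); D <- runif(1)
    expect_equal(f(x, c(S = S, D = D)), toy_rhs_oracle(x, S, D, as.list(p)),
                 tolerance = 1e-12)
  }
  # single activating edge at the fixed point: input 1 drives B = 1, dx = 0
  x <- stats::setNames(c(1, 0.5, 0.5, 0.5, 0.5, 0.5),
                       c("TF", "P1", "P2", "M1", "M2", "M3"))
  expect_equal(unname(f(x, c(S = 1, D = 0))["TF"]), 0)
  expect_error(build_rhs(toy_net(), p[-1]), "missing parameter")
})

test_that("acetyl-CoA source term reduces to 0.5*k1 when downstream rates vanish", {
  p <- named_params(compile_network(chol_net())$par_table)
  p[c("k2", "k3", "k7")] <- 0
  p["tau_AcetylCoA"] <- 1
  f <- build_rhs(chol_net(), p)
  x <- initial_state(chol_net())
  expect_equal(unname(f(x, NULL)["AcetylCoA"]), 0.5 * p[["k1"]])
})

test_that("HMG-CoA flux reduces to plain Michaelis-Menten without inhibitor", {
  p <- named_params(toy_tab())
  f <- build_rhs(toy_net(), p)
  x <- stats::setNames(c(0.5, 0.5, 0.8, 0.5, 0.4, 0.2),
                       c("TF", "P1", "P2", "M1", "M2", "M3"))
  d0 <- f(x, c(S = 0.5, D = 0))
  plain <- p[["k4"]] * 0.8 * 0.4 / (p[["kM4"]] + 0.4)
  expect_equal(unname(d0["M3"]), plain - p[["k5"]] * 0.2)
})

test_that("adaptive terminal states match a fine-grid Euler oracle", {
  p <- named_params(toy_tab())
  u <- c(S = 0.7, D = 0.4)
  sim <- simulate_network(toy_net(), p, u, end_time = 60)
  pl <- as.list(p)
  x_euler <- euler_integrate(
    function(x) toy_rhs_oracle(x, u[["S"]], u[["D"]], pl),
    initial_state(toy_net()), t_end = 60, dt = 5e-4)
  expect_equal(sim$terminal, x_euler[names(sim$terminal)], tolerance = 1e-4)
})

test_that("the two integration routes agree", {
  p <- named_params(toy_tab())
  a <- simulate_network(toy_net(), p, c(S = 0.5, D = 1), end_time = 80)
  b <- simulate_network(toy_net(), p, c(S = 0.5, D = 1), end_time = 80,
                        method = "lsoda")
  expect_equal(a$terminal, b$terminal, tolerance = 1e-5)
})

test_that("regulatory states stay in [0,1] and metabolites non-negative", {
  tab <- compile_network(chol_net())$par_table
  set.seed(3)
  conds <- default_conditions()
  for (i in 1:5) {
    p <- tab$value
    free <- !tab$fixed
    p[free] <- runif(sum(free), tab$lower[free], tab$upper[free])
    names(p) <- tab$name
    ci <- sample(nrow(conds), 1)
    sim <- simulate_network(chol_net(), p, conds[ci, ],
                            end_time = conds$end_time[ci])
    reg <- c("SREBP", "SREBP1", "SREBP2", "LXR", "HMGCR", "FASN", "ABCA1",
             "AtorvaIn", "T09In", "CholMedia")
    expect_true(all(sim$states[, reg] >= 0 & sim$states[, reg] <= 1))
    expect_true(all(sim$states >= 0))
  }
})

test_that("simulation is deterministic", {
  p <- named_params(toy_tab())
  a <- simulate_network(toy_net(), p, c(S = 0.3, D = 0.8), end_time = 100)
  b <- simulate_network(toy_net(), p, c(S = 0.3, D = 0.8), end_time = 100)
  expect_identical(a$states, b$states)
})

test_that("statin input raises terminal HMG-CoA, confirmed by an Euler check", {
  p <- named_params(compile_network(chol_net())$par_table)
  conds <- default_conditions()
  untr <- simulate_network(chol_net(), p, conds[conds$condition == "untreated", ],
                           end_time = 100)
  statin <- simulate_network(chol_net(), p,
                             conds[conds$condition == "atorva_high", ],
                             end_time = 100)
  expect_gt(statin$terminal[["HMGCoA"]], untr$terminal[["HMGCoA"]])

  # brute-force fixed-step Euler on the same RHS reproduces both levels
  f <- build_rhs(chol_net(), p)
  for (cond in list(conds[conds$condition == "untreated", ],
                    conds[conds$condition == "atorva_high", ])) {
    xe <- euler_integrate(function(x) f(x, cond), initial_state(chol_net()),
                          t_end = 100, dt = 0.01)
    ref <- if (cond$condition == "untreated") untr else statin
    expect_equal(xe[["HMGCoA"]], ref$terminal[["HMGCoA"]], tolerance = 1e-3)
  }
})

test_that("infinite inhibition constant equals zero inhibitor", {
  p <- named_params(toy_tab())
  no_drug <- simulate_network(toy_net(), p, c(S = 0.5, D = 0), end_time = 100)
  p2 <- p
  p2["kI"] <- 1e12
  huge_ki <- simulate_network(toy_net(), p2, c(S = 0.5, D = 1), end_time = 100)
  expect_equal(no_drug$terminal, huge_ki$terminal, tolerance = 1e-5)
})

test_that("flux summaries implement the uptake/synthesis arithmetic", {
  p <- c(k5 = 1, k6 = 1)
  ts <- rbind(
    equal = c(CholMedia = 0.5, LDLR = 0.8, NPC1 = 0.5, Mevalonate = 0.2),
    high_uptake = c(CholMedia = 1, LDLR = 0.6, NPC1 = 0.5, Mevalonate = 0.1),
    dead = c(CholMedia = 0, LDLR = 0, NPC1 = 0, Mevalonate = 0))
  fl <- flux_summaries(ts, p)
  expect_equal(fl$uptake[1], 0.2)
  expect_equal(fl$fraction[1], 0.5)   # uptake == synthesis
  expect_equal(fl$uptake[2], 0.3)
  expect_equal(fl$fraction[2], 0.75)  # 0.3 / (0.3 + 0.1)
  expect_false(fl$fraction_defined[3])
  expect_true(is.na(fl$fraction[3]))

  fl2 <- flux_summaries(rbind(control = c(CholMedia = 1, LDLR = 1, NPC1 = 0.5,
                                          Mevalonate = 0),
                              treated = c(CholMedia = 1, LDLR = 1, NPC1 = 0.8,
                                          Mevalonate = 0)), p)
  expect_equal(relative_flux_change(fl2, "treated", "control"), 0.6)
})
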