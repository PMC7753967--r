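test_that("the hyperbolic rate law evaluates correctly and handles edge cases", {
  # direct-substitution oracle
  num <- 90 * 1.46e4 * 5e-3 * 5e-5 * 1e-6
  den <- 0 + 90 * 5e-3 + 1.46e4 * 5e-5
  expect_equal(eq1_rate(90, 0, 1.46e4, 5e-3, 5e-5, 1e-6), num / den)
  expect_equal(eq1_rate(90, 0, 1.46e4, 5e-3, 0, 1e-6), 0)
  expect_equal(eq1_rate(90, 0, 1.46e4, 5e-3, 5e-5, 0), 0)
  expect_equal(eq1_rate(0, 0, 0, 0, 0, 1e-6), 0) # zero denominator
  expect_error(eq1_rate(-1, 0, 1, 1, 1, 1), "nonnegative")
})

test_that("zero rate constants give constant trajectories", {
  net <- single_substrate_network(k_cat = 0, k_act = 0)
  prof <- simulate_network(net, initial_state(net, conc = c(S = 5e-5)),
                           times = seq(0, 8 * 3600, length.out = 50))
  expect_true(all(abs(prof$S - 5e-5) < 1e-12))
  expect_true(all(abs(prof$cat_resting - 1e-6) < 1e-12))
  rhs <- assemble_rate_equations(net)
  d <- rhs(0, initial_state(net, conc = c(S = 5e-5)))[[1]]
  expect_true(all(d == 0))
})

test_that("assembled derivatives transcribe the network topology", {
  net <- propranolol_network()
  rhs <- assemble_rate_equations(net)
  st <- initial_state(net, conc = c(P = 1e-5, D = 2e-6, E = 3e-6))
  st["cat_active"] <- 4e-7
  d <- rhs(0, st)[[1]]
  names(d) <- names(st)
  kD <- net$catalytic_steps$k_cat[net$catalytic_steps$substrate == "D"]
  kE <- net$catalytic_steps$k_cat[net$catalytic_steps$substrate == "E"]
  expect_equal(d[["F"]], kD * 4e-7 * 2e-6 + kE * 4e-7 * 3e-6)
  expect_equal(d[["P"]], -1.70e4 * 4e-7 * 1e-5)
})

test_that("reference simulation conserves catalyst and the organic unit", {
  prof <- reference_profile()
  rep <- conservation_report(prof, propranolol_network())
  expect_lt(rep$catalyst, 1e-6)
  expect_lt(rep$ring_unit, 1e-6)
  ring <- rowSums(as.data.frame(prof)[, attr(prof, "species")])
  expect_true(all(abs(ring - 5e-5) / 5e-5 < 1e-8))
})

test_that("a tampered trajectory shows up as a conservation violation", {
  prof <- reference_profile()
  broken <- prof
  broken$C <- 0
  rep <- conservation_report(broken, propranolol_network())
  share <- max(prof$C) / 5e-5
  expect_gt(rep$ring_unit, 0.9 * share)
})

test_that("oxidant consumption matches activation plus direct-step bookkeeping", {
  net <- propranolol_network()
  net$constant_oxidant <- FALSE
  prof <- simulate_network(net, initial_state(net, conc = c(P = 5e-5)),
                           times = seq(0, 8 * 3600, by = 60))
  rep <- conservation_report(prof, net)
  expect_lt(rep$oxidant, 1e-6)
  expect_lt(prof$H2O2[nrow(prof)], 5e-3) # some oxidant actually consumed
})

test_that("full ODE matches the steady-state rate law in the QSSA limit", {
  net <- single_substrate_network(k_cat = 1.46e4, k_inact = 0)
  prof <- simulate_network(net, initial_state(net, conc = c(S = 5e-5)),
                           times = seq(0, 120, by = 1))
  rhs <- assemble_rate_equations(net)
  after <- prof$time_s > 10 & prof$S > 1e-6
  for (i in which(after)) {
    st <- unlist(prof[i, -1])
    dS <- rhs(prof$time_s[i], st)[[1]][1]
    pred <- eq1_rate(90, 0, 1.46e4, 5e-3, st[["S"]], 1e-6)
    expect_equal(-dS, pred, tolerance = 0.01)
  }
})

test_that("peak_time matches the consecutive-reaction closed form", {
  a <- 2e-3; b <- 1e-3
  net <- chain_network(a, b)
  prof <- simulate_network(net, initial_state(net, conc = c(S1 = 1e-5)),
                           times = seq(0, 3600, by = 1))
  t_expect <- log(a / b) / (a - b)
  expect_equal(peak_time(prof, "S2"), t_expect, tolerance = 2 / t_expect)
  expect_equal(peak_time(prof, "S1"), 0) # monotone decay peaks at the origin
  expect_error(peak_time(prof, "nope"), "not present")
})

test_that("propranolol is digested well within 30 min in the reference scenario", {
  prof <- reference_profile()
  p30 <- prof$P[prof$time_s == 1800]
  expect_lt(p30, 0.05 * 5e-5)
})

test_that("stronger inactivation never increases terminal product", {
  net <- propranolol_network()
  t_check <- c(600, 1800, 3600, 14400, 28800)
  f_prev <- NULL
  for (ki in c(5e-4, 1.7e-3, 5e-3, 2e-2)) {
    net$catalyst$k_inact <- ki
    prof <- simulate_network(net, initial_state(net, conc = c(P = 5e-5)),
                             times = seq(0, 8 * 3600, by = 60))
    f_now <- prof$F[match(t_check, prof$time_s)]
    if (!is.null(f_prev)) expect_true(all(f_now <= f_prev * (1 + 1e-9)))
    f_prev <- f_now
  }
})

test_that("trajectories are converged with respect to solver tolerances", {
  net <- propranolol_network()
  times <- seq(0, 8 * 3600, by = 120)
  init <- initial_state(net, conc = c(P = 5e-5))
  p1 <- simulate_network(net, init, times, solver_options())
  p2 <- simulate_network(net, init, times,
                         solver_options(rtol = 5e-9, atol = 5e-13))
  for (s in c("P", "A", "C", "D", "E", "F")) {
    scale <- max(p1[[s]], 5e-5 * 1e-4)
    expect_lt(max(abs(p1[[s]] - p2[[s]])) / scale, 1e-4)
  }
})

test_that("simulate_network validates its inputs", {
  net <- propranolol_network()
  init <- initial_state(net, conc = c(P = 5e-5))
  init["A"] <- -1e-9
  expect_error(simulate_network(net, init, times = c(0, 10)), "negative")
  expect_error(simulate_network(net, initial_state(net), times = c(10, 20)),
               "start at 0")
  expect_error(initial_state(net, conc = c(Z = 1)), "unknown species")
})

test_that("profiles round-trip through the tidy CSV dialect", {
  prof <- reference_profile()
  sub <- prof[prof$time_s %% 600 == 0, ]
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_profile(sub, path)
  back <- read_profile(path)
  expect_equal(back$time_s, sub$time_s)
  for (s in names(sub)[-1]) {
    expect_equal(back[[s]], sub[[s]], tolerance = 1e-12)
  }
  expect_setequal(attr(back, "species"), attr(prof, "species"))
})
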