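eq1_design <- function(k_act, k_cat, s0 = 5e-5, fe = 1e-6, n = 8,
                       h_range = c(2e-4, 2e-2)) {
  h <- exp(seq(log(h_range[1]), log(h_range[2]), length.out = n))
  data.frame(h2o2 = h, v0 = eq1_rate(k_act, 0, k_cat, h, s0, fe),
             substrate_conc0 = s0, fe_total = fe)
}

test_that("initial rates are recovered from decay traces", {
  # exact linear decay: least squares reproduces the slope exactly
  tt <- seq(0, 100, by = 10)
  expect_equal(estimate_initial_rate(tt, 1e-5 - 2e-9 * tt), 2e-9)
  # constant concentration: zero rate
  expect_equal(estimate_initial_rate(tt, rep(1e-5, length(tt))), 0)
  # exponential decay, 5% window: v0 within 3% of the analytic derivative k*S0
  k <- 1e-3; s0 <- 1e-5
  tt <- seq(0, 120, by = 5)
  v0 <- estimate_initial_rate(tt, s0 * exp(-k * tt),
                              max_conversion_fraction = 0.05)
  expect_equal(v0, k * s0, tolerance = 0.03)
  # too few points inside the window
  expect_error(estimate_initial_rate(c(0, 50, 100), s0 * exp(-0.1 * c(0, 50, 100)),
                                     max_conversion_fraction = 0.01),
               "insufficient")
})

test_that("the hyperbolic fit recovers generating rate constants exactly", {
  for (truth in list(c(107, 2.0e4), c(90, 1.46e4))) {
    fit <- fit_eq1(eq1_design(truth[1], truth[2]))
    expect_true(fit$converged)
    expect_equal(unname(fit$parameters["k_act"]), truth[1], tolerance = 1e-3)
    expect_equal(unname(fit$parameters["k_cat"]), truth[2], tolerance = 1e-3)
    expect_false("weakly_identified" %in% fit$flags)
  }
})

test_that("the hyperbolic fit matches a brute-force log-grid search", {
  pts <- eq1_design(107, 2.0e4, n = 6)
  # independent oracle: exhaustive 200 x 200 log-grid minimization
  ka_grid <- exp(seq(log(10), log(1000), length.out = 200))
  kc_grid <- exp(seq(log(2e3), log(2e5), length.out = 200))
  sse <- outer(ka_grid, kc_grid, Vectorize(function(ka, kc) {
    sum((pts$v0 - eq1_rate(ka, 0, kc, pts$h2o2, pts$substrate_conc0,
                           pts$fe_total))^2)
  }))
  best <- arrayInd(which.min(sse), dim(sse))
  fit <- fit_eq1(pts)
  # agreement within the grid resolution (grid spacing ~2.3% and ~2.3%)
  expect_equal(unname(fit$parameters["k_act"]), ka_grid[best[1]],
               tolerance = 0.05)
  expect_equal(unname(fit$parameters["k_cat"]), kc_grid[best[2]],
               tolerance = 0.05)
})

test_that("saturating-only oxidant designs are flagged weakly identified", {
  # k_act * h >> k_cat * S0 throughout: the plateau pins k_cat but k_act
  # drops out of the rate
  pts <- eq1_design(90, 1.46e4, h_range = c(0.5, 5))
  fit <- fit_eq1(pts)
  expect_true("weakly_identified" %in% fit$flags)
  rel_se <- fit$std_errors["k_act"] / fit$parameters["k_act"]
  expect_true(!is.finite(rel_se) || rel_se > 0.5)
})

test_that("degenerate initial-rate data raise errors", {
  pts <- eq1_design(90, 1.46e4)
  pts$v0 <- 0
  expect_error(fit_eq1(pts), "degenerate")
  expect_error(fit_eq1(eq1_design(90, 1.46e4)[1:3, ]), "4")
})

test_that("pseudo-first-order analysis recovers k2 from noiseless decays", {
  tt <- seq(0, 4 * 3600, by = 600)
  k2 <- 3.4e-2; h <- 5e-3
  fit <- fit_pseudo_first_order(tt, 3e-5 * exp(-k2 * h * tt), h)
  expect_true(fit$converged)
  expect_equal(unname(fit$parameters["k2"]), k2, tolerance = 1e-3)
  expect_false("no_decay" %in% fit$flags)
})

test_that("constant traces yield k2 ~ 0 with the no_decay flag", {
  tt <- seq(0, 3600, by = 300)
  fit <- fit_pseudo_first_order(tt, rep(2e-5, length(tt)), 5e-3)
  expect_true("no_decay" %in% fit$flags)
  expect_lt(unname(fit$parameters["k_obs"]) * 3600, 1e-3)
  expect_error(fit_pseudo_first_order(tt, rep(-1e-6, length(tt)), 5e-3),
               "negative")
})

test_that("pseudo-first-order recovery tolerates proportional noise", {
  tt <- seq(0, 4 * 3600, by = 300)
  k2 <- 3.4e-2; h <- 5e-3
  truth <- 3e-5 * exp(-k2 * h * tt)
  set.seed(11)
  noisy <- pmax(truth * (1 + rnorm(length(tt), 0, 0.05)), 0)
  fit <- fit_pseudo_first_order(tt, noisy, h)
  expect_equal(unname(fit$parameters["k2"]), k2, tolerance = 0.10)
})

test_that("noisy-data recovery stays within 20% and 2 standard errors", {
  # proportional 5% + additive 2e-7 M noise at fixed seeds; pooled over the
  # fitted parameters, at least 90% of the checks must land within 20% of
  # truth and within 2 reported standard errors
  k2 <- 3.4e-2; h <- 5e-3
  tt <- seq(0, 4 * 3600, by = 300)
  truth <- 3e-5 * exp(-k2 * h * tt)
  checks <- NULL
  for (s in 1:20) {
    set.seed(100 + s)
    noisy <- pmax(truth * (1 + rnorm(length(tt), 0, 0.05)) +
                    rnorm(length(tt), 0, 2e-7), 0)
    fit <- fit_pseudo_first_order(tt, noisy, h)
    est <- unname(fit$parameters["k2"])
    se <- unname(fit$std_errors["k2"])
    checks <- c(checks, abs(est - k2) / k2 < 0.20, abs(est - k2) <= 2 * se)
  }
  ka <- 90; kc <- 1.46e4
  for (s in 1:20) {
    set.seed(200 + s)
    pts <- eq1_design(ka, kc)
    pts$v0 <- pmax(pts$v0 * (1 + rnorm(8, 0, 0.05)), 0)
    fit <- fit_eq1(pts)
    checks <- c(checks,
                abs(fit$parameters["k_act"] - ka) / ka < 0.20,
                abs(fit$parameters["k_cat"] - kc) / kc < 0.20,
                abs(fit$parameters["k_act"] - ka) <=
                  2 * fit$std_errors["k_act"],
                abs(fit$parameters["k_cat"] - kc) <=
                  2 * fit$std_errors["k_cat"])
  }
  expect_gte(mean(checks), 0.9)
})

test_that("the global fit recovers the inactivation constant from noiseless data", {
  scen <- default_scenario()
  obs <- noiseless_observations(scen)
  fit <- global_fit(scen$network, obs, "k_inact", init = scen$init,
                    starts = 3, seed = 5)
  expect_true(fit$converged)
  expect_equal(unname(fit$parameters["k_inact"]), 1.7e-3, tolerance = 0.01)
  # objective is non-increasing along the accepted iteration trace
  expect_true(all(diff(fit$trace) <= 1e-12))
})

test_that("the global fit recovers a catalytic step constant", {
  scen <- default_scenario()
  obs <- noiseless_observations(scen)
  fit <- global_fit(scen$network, obs, "k_cat:C->E", init = scen$init,
                    starts = 3, seed = 5,
                    bounds = list("k_cat:C->E" = c(1, 1e6)))
  expect_equal(unname(fit$parameters["k_cat:C->E"]), 3.5e3, tolerance = 0.01)
})

test_that("global fit handles empty parameter sets and bad names", {
  scen <- default_scenario()
  obs <- noiseless_observations(scen)
  fit0 <- global_fit(scen$network, obs, character(0), init = scen$init)
  expect_true(fit0$converged)
  expect_length(fit0$parameters, 0)
  expect_lt(fit0$rss, 1e-10) # observations are the model's own forward run
  expect_error(global_fit(scen$network, obs, "k_cat:X->Y", init = scen$init),
               "unknown free parameter")
  bogus <- obs
  bogus$species_id[1] <- "Z"
  expect_error(global_fit(scen$network, bogus, "k_inact", init = scen$init),
               "absent from the network")
})
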