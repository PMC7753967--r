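# --- fit result container ----------------------------------------------------

fit_result <- function(parameters, std_errors = NULL, rss = NA_real_,
                       converged = FALSE, n_eval = NA_integer_,
                       flags = character(), trace = NULL, details = list()) {
  if (is.null(std_errors)) {
    std_errors <- setNames(rep(NA_real_, length(parameters)), names(parameters))
  }
  structure(list(parameters = parameters, std_errors = std_errors, rss = rss,
                 converged = converged, n_eval = n_eval, flags = flags,
                 trace = trace, details = details),
            class = "kintox_fit")
}

#' @export
print.kintox_fit <- function(x, ...) {
  cat("<kintox_fit>", if (x$converged) "converged" else "NOT converged",
      sprintf(" rss = %.6g, evaluations = %s\n", x$rss, x$n_eval))
  if (length(x$parameters)) {
    tab <- data.frame(estimate = x$parameters, std_error = x$std_errors)
    print(tab)
  } else {
    cat("  (no free parameters)\n")
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Finite-difference Jacobian of vector function f at x (central differences).
fd_jacobian <- function(f, x, rel = 1e-6, abs_min = 1e-10) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- max(abs(x[j]) * rel, abs_min)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# Covariance-based standard errors from a residual function at the optimum.
# Heteroscedasticity-robust (HC3 sandwich) by default: measurement error in
# chromatographic data is proportional-plus-additive, so the classical
# constant-variance covariance is miscalibrated, and the leverage-corrected
# HC3 form keeps reasonable coverage at the small point counts typical of
# initial-rate designs. Returns list(se, cond, reliable); `par` on the
# optimizer's scale.
se_from_residuals <- function(resid_fn, par, rss, n_res, robust = TRUE) {
  p <- length(par)
  dof <- max(n_res - p, 1)
  J <- fd_jacobian(resid_fn, par)
  sv <- svd(J)$d
  cond <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  bread <- try(solve(crossprod(J)), silent = TRUE)
  if (inherits(bread, "try-error")) {
    return(list(se = rep(Inf, p), cond = cond, reliable = FALSE))
  }
  covm <- if (robust) {
    r <- as.numeric(resid_fn(par))
    lev <- pmin(rowSums((J %*% bread) * J), 0.999)
    meat <- crossprod(J * (r / (1 - lev)))
    bread %*% meat %*% bread
  } else {
    bread * rss / dof
  }
  list(se = sqrt(pmax(diag(covm), 0)), cond = cond,
       reliable = is.finite(cond) && cond <= 1e8)
}

# Subsequence of an optimizer's objective trace formed by the accepted
# (running-best) iterations; trial steps with unchanged or worse objective
# are dropped.
accepted_trace <- function(x) {
  if (!length(x)) return(x)
  x[x <= cummin(x)]
}

# --- initial rates -----------------------------------------------------------

#' Initial rate from a concentration-time trace
#'
#' Ordinary least-squares slope through the low-conversion window of a decay
#' trace: only points with conversion `(C0 - C)/C0` at or below
#' `max_conversion_fraction` enter the fit, and the initial rate is minus the
#' fitted slope.
#'
#' @param times Sampling times in seconds, strictly increasing.
#' @param concentrations Concentrations in mol/L, same length.
#' @param max_conversion_fraction Conversion window (default 0.10).
#' @return Initial rate v0 in M/s.
#' @export
estimate_initial_rate <- function(times, concentrations,
                                  max_conversion_fraction = 0.10) {
  if (length(times) != length(concentrations)) {
    stop("'times' and 'concentrations' must have equal length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  c0 <- concentrations[1]
  conv <- if (c0 > 0) (c0 - concentrations) / c0 else rep(0, length(times))
  keep <- which(conv <= max_conversion_fraction + 1e-12)
  if (length(keep) < 3) {
    stop("insufficient data: fewer than 3 points within the conversion window",
         call. = FALSE)
  }
  fit <- lm(concentrations[keep] ~ times[keep])
  -unname(coef(fit)[2])
}

# --- hyperbolic (initial-rate vs oxidant) fit --------------------------------

#' Fit the catalytic-cycle rate law to initial-rate data
#'
#' Nonlinear least-squares fit of [eq1_rate()] to initial rates measured as a
#' function of oxidant concentration, estimating the activation constant
#' `k_act` and the substrate-oxidation constant `k_cat` (`k_rev` fixed, by
#' default at 0). The fit runs in log-parameter space with a
#' Levenberg-Marquardt minimizer from a small set of deterministic starting
#' heuristics. Standard errors come from the Jacobian-based covariance at the
#' optimum; if the oxidant design does not constrain both the rising and the
#' saturating regime the result is flagged `weakly_identified`.
#'
#' @param points Data frame with columns `h2o2` (mol/L), `v0` (M/s),
#'   `substrate_conc0` (mol/L), `fe_total` (mol/L); at least 4 rows.
#' @param k_rev Fixed reverse rate constant (s-1), default 0.
#' @return A `kintox_fit` with parameters `k_act`, `k_cat`.
#' @export
fit_eq1 <- function(points, k_rev = 0) {
  points <- as.data.frame(points)
  need <- c("h2o2", "v0", "substrate_conc0", "fe_total")
  if (!all(need %in% names(points))) {
    stop("'points' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(points) < 4) {
    stop("at least 4 initial-rate points are required", call. = FALSE)
  }
  if (any(points$h2o2 <= 0) || any(points$substrate_conc0 <= 0) ||
      any(points$fe_total <= 0) || any(points$v0 < 0)) {
    stop("initial-rate points must have positive h2o2, substrate_conc0, ",
         "fe_total and nonnegative v0", call. = FALSE)
  }
  if (all(points$v0 == 0)) {
    stop("degenerate data: all initial rates are zero", call. = FALSE)
  }

  resid_fn <- function(lp) {
    points$v0 - eq1_rate(exp(lp[1]), k_rev, exp(lp[2]), points$h2o2,
                         points$substrate_conc0, points$fe_total)
  }
  # plateau rate ~ k_cat * S0 * Fe; half-saturation when k_act*h ~ k_cat*S0
  k_cat0 <- max(points$v0) / (mean(points$fe_total) *
                                mean(points$substrate_conc0))
  k_act0 <- k_cat0 * mean(points$substrate_conc0) / median(points$h2o2)
  starts <- list(c(k_act0, k_cat0), c(k_act0 * 10, k_cat0 / 10),
                 c(k_act0 / 10, k_cat0 * 10), c(k_act0 * 100, k_cat0),
                 c(k_act0, k_cat0 * 100))
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(par = log(s), fn = resid_fn,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 500)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("hyperbolic fit failed from all starts", call. = FALSE)

  est_log <- best$par
  est <- setNames(exp(est_log), c("k_act", "k_cat"))
  se_info <- se_from_residuals(resid_fn, est_log, best$deviance, nrow(points))
  se <- setNames(est * se_info$se, names(est))  # delta method from log scale
  flags <- character()
  if (!se_info$reliable) flags <- c(flags, "covariance_unreliable")
  # design diagnostic: the ratio k_act*h / (k_cat*S0) says which term of the
  # denominator dominates. A design confined to the saturating regime leaves
  # k_act unconstrained; one confined to the rising regime leaves k_cat
  # unconstrained. Inflate the affected standard error to at least the
  # estimate itself (>= 100% relative uncertainty).
  regime <- est[["k_act"]] * points$h2o2 /
    (est[["k_cat"]] * points$substrate_conc0)
  weak <- character()
  if (all(regime > 10)) weak <- "k_act"
  if (all(regime < 0.1)) weak <- "k_cat"
  rel_se <- se / est
  if (length(weak) || !all(is.finite(rel_se)) || any(rel_se > 1) ||
      se_info$cond > 1e8) {
    flags <- c(flags, "weakly_identified")
    se[weak] <- pmax(se[weak], est[weak])
  }
  converged <- best$info %in% 1:4
  fit_result(est, se, rss = best$deviance, converged = converged,
             n_eval = length(best$rsstrace), flags = flags,
             trace = accepted_trace(best$rsstrace),
             details = list(condition_number = se_info$cond, k_rev = k_rev,
                            regime_ratio = range(regime),
                            info = best$info, message = best$message))
}

# --- pseudo-first-order fit --------------------------------------------------

#' Pseudo-first-order rate constant under excess oxidant
#'
#' Fits an exponential decay `C(t) = C0 exp(-k_obs t)` to a trace measured
#' under a large (>= 20-fold) excess of oxidant, so that the oxidant is
#' effectively constant, and reports the second-order constant
#' `k2 = k_obs / [H2O2]`. Non-decaying traces yield `k2 ~ 0` with the
#' `no_decay` flag rather than an error.
#'
#' @param times Sampling times in seconds.
#' @param concentrations Substrate concentrations in mol/L (nonnegative).
#' @param h2o2 Constant oxidant concentration in mol/L.
#' @return A `kintox_fit` with parameters `k2` (M-1 s-1), `k_obs` (s-1) and
#'   `C0` (mol/L).
#' @export
fit_pseudo_first_order <- function(times, concentrations, h2o2) {
  if (length(times) != length(concentrations) || length(times) < 4) {
    stop("at least 4 matching (time, concentration) points are required",
         call. = FALSE)
  }
  if (any(concentrations < 0)) {
    stop("negative concentrations are not allowed", call. = FALSE)
  }
  if (!is.numeric(h2o2) || length(h2o2) != 1 || h2o2 <= 0) {
    stop("'h2o2' must be a single positive concentration", call. = FALSE)
  }
  if (h2o2 < 20 * max(concentrations)) {
    warning("oxidant excess below 20-fold; pseudo-first-order assumption ",
            "may be poor", call. = FALSE)
  }
  span <- diff(range(times))
  c0 <- max(concentrations[1], max(concentrations) * 1e-6)
  # log-linear slope as a starting value; guards against zeros
  pos <- concentrations > 0
  k_start <- if (sum(pos) >= 2) {
    sl <- unname(coef(lm(log(concentrations[pos]) ~ times[pos]))[2])
    max(-sl, 1e-3 / span)
  } else 1 / span
  resid_fn <- function(p) concentrations - p[1] * exp(-p[2] * times)
  fit <- minpack.lm::nls.lm(par = c(c0, k_start), fn = resid_fn,
                            lower = c(0, 0),
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  c0_hat <- fit$par[1]
  k_obs <- fit$par[2]
  se_info <- se_from_residuals(resid_fn, fit$par, fit$deviance, length(times))
  flags <- character()
  if (!se_info$reliable) flags <- c(flags, "covariance_unreliable")
  if (k_obs * span < 1e-3) flags <- c(flags, "no_decay")
  est <- c(k2 = k_obs / h2o2, k_obs = k_obs, C0 = c0_hat)
  se <- c(k2 = se_info$se[2] / h2o2, k_obs = se_info$se[2], C0 = se_info$se[1])
  fit_result(est, se, rss = fit$deviance, converged = fit$info %in% 1:4,
             n_eval = length(fit$rsstrace), flags = flags,
             trace = accepted_trace(fit$rsstrace),
             details = list(h2o2 = h2o2, condition_number = se_info$cond,
                            info = fit$info, message = fit$message))
}

# --- global network fit ------------------------------------------------------

# Resolve a free-parameter name ("k_inact", "k_cat:P->A", "k_direct:C->D")
# against a network; returns a getter/setter pair.
resolve_parameter <- function(network, name) {
  if (identical(name, "k_inact")) {
    return(list(
      get = function(net) net$catalyst$k_inact,
      set = function(net, v) { net$catalyst$k_inact <- v; net },
      default_bounds = c(1e-6, 1)
    ))
  }
  m <- regmatches(name, regexec("^(k_cat|k_direct):(.+)->(.+)$", name))[[1]]
  if (length(m) == 4) {
    tab <- if (m[2] == "k_cat") "catalytic_steps" else "direct_steps"
    kcol <- if (m[2] == "k_cat") "k_cat" else "k_direct"
    row <- which(network[[tab]]$substrate == m[3] &
                   network[[tab]]$product == m[4])
    if (length(row) == 1) {
      return(list(
        get = function(net) net[[tab]][[kcol]][row],
        set = function(net, v) { net[[tab]][[kcol]][row] <- v; net },
        default_bounds = c(1e-6, 1e7)
      ))
    }
  }
  stop("unknown free parameter \"", name, "\" (use \"k_inact\", ",
       "\"k_cat:S->P\" or \"k_direct:S->P\" naming an existing step)",
       call. = FALSE)
}

#' Global least-squares fit of network rate constants
#'
#' Fits selected rate constants of a degradation network to observed
#' concentration-time data by simulating the full network at each parameter
#' vector and minimizing the weighted sum of squared deviations over all
#' species and times. This replaces manual tuning of simulated profiles
#' against measured ones with a reproducible objective: per-species weights
#' default to `1/max(observed)^2`, which puts species of very different
#' concentration scales on an equal footing. Optimization runs in
#' log-parameter space under bound constraints with a Levenberg-Marquardt
#' minimizer and seeded log-uniform multi-start; the best start is reported.
#'
#' @param network A validated `reaction_network` providing the topology and
#'   the fixed rate constants.
#' @param observations Data frame with columns `time_s`, `species_id`,
#'   `conc_M` and optionally `censored_flag` (censored rows are excluded from
#'   the objective by default).
#' @param free_parameters Character vector naming the constants to float:
#'   `"k_inact"`, `"k_cat:S->P"` or `"k_direct:S->P"`. May be empty, in which
#'   case only the forward-simulation residual is reported.
#' @param bounds Optional named list of `c(lower, upper)` per parameter;
#'   defaults: 1e-6 to 1e7 for second-order constants, 1e-6 to 1 s-1 for
#'   `k_inact`.
#' @param weights Optional named per-species weights replacing the default.
#' @param init Initial kinetic state; defaults to [initial_state()] with
#'   species observed at time 0 set to their (uncensored) observed values.
#' @param starts Number of log-uniform multi-starts (default 5).
#' @param seed Integer seed for the start draws (default 1).
#' @param censored_policy `"exclude"` (default) drops censored rows;
#'   `"as_zero"` keeps them as zero-concentration observations.
#' @param options [solver_options()] used for the embedded simulations.
#' @return A `kintox_fit`; `details` records the per-start results, seed and
#'   weights.
#' @export
global_fit <- function(network, observations, free_parameters,
                       bounds = NULL, weights = NULL, init = NULL,
                       starts = 5, seed = 1,
                       censored_policy = c("exclude", "as_zero"),
                       options = solver_options()) {
  censored_policy <- match.arg(censored_policy)
  obs <- as.data.frame(observations)
  need <- c("time_s", "species_id", "conc_M")
  if (!all(need %in% names(obs))) {
    stop("'observations' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(obs$censored_flag)) obs$censored_flag <- FALSE
  unknown_sp <- setdiff(unique(obs$species_id), network$species$id)
  if (length(unknown_sp)) {
    stop("observations reference species absent from the network: ",
         paste(unknown_sp, collapse = ", "), call. = FALSE)
  }
  if (censored_policy == "exclude") {
    obs <- obs[!obs$censored_flag, , drop = FALSE]
  } else {
    obs$conc_M[obs$censored_flag] <- 0
  }
  if (!nrow(obs)) stop("no usable observations", call. = FALSE)

  if (is.null(init)) {
    init <- initial_state(network)
    at0 <- obs[obs$time_s == 0, , drop = FALSE]
    if (nrow(at0)) init[at0$species_id] <- pmax(at0$conc_M, 0)
  }

  if (is.null(weights)) {
    mx <- tapply(abs(obs$conc_M), obs$species_id, max)
    mx[mx <= 0] <- max(mx, 1e-30)
    weights <- 1 / mx^2
  }
  w_row <- sqrt(weights[obs$species_id])

  t_grid <- sort(unique(c(0, obs$time_s)))
  row_t <- match(obs$time_s, t_grid)

  sim_resid <- function(net) {
    prof <- simulate_network(net, init = init, times = t_grid,
                             options = options)
    sim <- vapply(seq_len(nrow(obs)),
                  function(i) prof[[obs$species_id[i]]][row_t[i]],
                  numeric(1))
    w_row * (obs$conc_M - sim)
  }

  if (!length(free_parameters)) {
    r <- sim_resid(network)
    return(fit_result(setNames(numeric(0), character(0)),
                      rss = sum(r^2), converged = TRUE, n_eval = 1L,
                      flags = "no_free_parameters",
                      details = list(weights = weights)))
  }

  accessors <- lapply(free_parameters, resolve_parameter, network = network)
  names(accessors) <- free_parameters
  lb <- ub <- numeric(length(free_parameters))
  for (i in seq_along(free_parameters)) {
    b <- bounds[[free_parameters[i]]]
    if (is.null(b)) b <- accessors[[i]]$default_bounds
    lb[i] <- b[1]; ub[i] <- b[2]
  }

  resid_fn <- function(lp) {
    net <- network
    for (i in seq_along(lp)) net <- accessors[[i]]$set(net, exp(lp[i]))
    tryCatch(sim_resid(net),
             error = function(e) rep(1e6, nrow(obs)))
  }

  start_mat <- with_seed(seed, matrix(
    runif(starts * length(free_parameters), log(lb), log(ub)),
    nrow = starts, byrow = TRUE))
  best <- NULL
  trials <- list()
  for (s in seq_len(starts)) {
    # epsfcn keeps the finite-difference step of the internal Jacobian well
    # above the ODE integration error, which would otherwise drown the
    # gradient signal and stall the optimizer
    fit <- try(minpack.lm::nls.lm(par = start_mat[s, ], fn = resid_fn,
                                  lower = log(lb), upper = log(ub),
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 200, epsfcn = 1e-6)),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      trials[[s]] <- list(start = exp(start_mat[s, ]), rss = NA_real_,
                          error = attr(fit, "condition")$message)
      next
    }
    trials[[s]] <- list(start = exp(start_mat[s, ]), rss = fit$deviance,
                        par = exp(fit$par), info = fit$info)
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    stop("global fit failed on all starts; trace: ",
         paste(vapply(trials, function(t) t$error %||% "ok", character(1)),
               collapse = "; "), call. = FALSE)
  }

  est <- setNames(exp(best$par), free_parameters)
  se_info <- se_from_residuals(resid_fn, best$par, best$deviance, nrow(obs))
  se <- setNames(est * se_info$se, free_parameters)
  flags <- character()
  if (!se_info$reliable) flags <- c(flags, "covariance_unreliable")
  fit_result(est, se, rss = best$deviance, converged = best$info %in% 1:4,
             n_eval = length(best$rsstrace), flags = flags,
             trace = accepted_trace(best$rsstrace),
             details = list(starts = trials, seed = seed, weights = weights,
                            bounds = rbind(lower = lb, upper = ub),
                            condition_number = se_info$cond,
                            n_obs = nrow(obs), info = best$info))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a fit report as JSON
#'
#' Serializes a `kintox_fit` (parameters, standard errors, residual sum of
#' squares, convergence, flags, seed and multi-start summary) to a JSON file.
#'
#' @param fit A `kintox_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  starts <- fit$details$starts
  report <- list(
    parameters = as.list(fit$parameters),
    std_errors = as.list(fit$std_errors),
    rss = fit$rss,
    converged = fit$converged,
    n_eval = fit$n_eval,
    flags = fit$flags,
    seed = fit$details$seed,
    starts = if (!is.null(starts)) {
      lapply(starts, function(t) list(start = t$start, rss = t$rss))
    }
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
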