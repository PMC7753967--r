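#' Solver options for network simulation
#'
#' @param rtol Relative tolerance (default 1e-8). The degradation networks
#'   modelled here span rate scales from ~3e-2 to ~1e5 M-1 s-1, so tight
#'   tolerances with a stiff-capable method are the default.
#' @param atol Absolute tolerance in mol/L (default 1e-12).
#' @param stiff Use a stiffness-switching integrator (`lsoda`); `FALSE`
#'   selects the non-stiff Adams method.
#' @param max_step Maximal internal step size in seconds (default unlimited).
#' @return List of class `solver_options`.
#' @export
solver_options <- function(rtol = 1e-8, atol = 1e-12, stiff = TRUE,
                           max_step = Inf) {
  if (!is.numeric(rtol) || rtol <= 0 || !is.numeric(atol) || atol <= 0) {
    stop("solver tolerances must be > 0", call. = FALSE)
  }
  structure(list(rtol = rtol, atol = atol, stiff = isTRUE(stiff),
                 max_step = max_step),
            class = "solver_options")
}

# Canonical state layout: species..., cat_resting, cat_active, cat_inactive, H2O2
state_names <- function(network) {
  c(network$species$id, "cat_resting", "cat_active", "cat_inactive", "H2O2")
}

#' Initial kinetic state for a network
#'
#' Builds the canonical state vector: all species at zero unless overridden,
#' the catalyst entirely in its resting form, and the oxidant at the network's
#' initial concentration.
#'
#' @param network A `reaction_network`.
#' @param conc Named numeric vector of initial species concentrations (mol/L)
#'   overriding the zero default, e.g. `c(P = 5e-5)`.
#' @param catalyst_total Total catalyst concentration (mol/L); defaults to the
#'   network's catalyst block.
#' @param oxidant Initial H2O2 concentration (mol/L); defaults to the network.
#' @return Named numeric state vector.
#' @export
initial_state <- function(network, conc = NULL,
                          catalyst_total = network$catalyst$total_conc,
                          oxidant = network$oxidant_conc0) {
  st <- setNames(numeric(length(network$species$id) + 4), state_names(network))
  if (!is.null(conc)) {
    bad <- setdiff(names(conc), network$species$id)
    if (length(bad)) {
      stop("unknown species in initial concentrations: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    st[names(conc)] <- conc
  }
  st["cat_resting"] <- catalyst_total
  st["H2O2"] <- oxidant
  st
}

#' Assemble the mass-action rate equations of a network
#'
#' Translates the network into elementary mass-action steps: catalyst
#' activation (resting + H2O2 -> active, `k_act`), its reverse (`k_rev`),
#' substrate oxidation by the active form (active + S -> resting + product,
#' `k_cat`), direct oxidation by the oxidant (S + H2O2 -> product,
#' `k_direct`), and first-order inactivation of the active form (`k_inact`).
#' One oxidant molecule is consumed per catalytic activation and per direct
#' step; with `constant_oxidant` the oxidant derivative is zero.
#'
#' @param network A validated `reaction_network`.
#' @return A function `f(t, state, parms = NULL)` in the form expected by
#'   [deSolve::ode()], returning `list(derivatives)` over the canonical state
#'   layout (species, `cat_resting`, `cat_active`, `cat_inactive`, `H2O2`).
#' @export
assemble_rate_equations <- function(network) {
  sp <- network$species$id
  n <- length(sp)
  idx <- setNames(seq_len(n), sp)
  cs <- network$catalytic_steps
  ds <- network$direct_steps

  # stoichiometry matrices species x steps (substrate -1, product +1)
  Sc <- matrix(0, n, nrow(cs))
  if (nrow(cs)) {
    for (j in seq_len(nrow(cs))) {
      Sc[idx[[cs$substrate[j]]], j] <- -1
      Sc[idx[[cs$product[j]]], j] <- Sc[idx[[cs$product[j]]], j] + 1
    }
  }
  Sd <- matrix(0, n, nrow(ds))
  if (nrow(ds)) {
    for (j in seq_len(nrow(ds))) {
      Sd[idx[[ds$substrate[j]]], j] <- -1
      Sd[idx[[ds$product[j]]], j] <- Sd[idx[[ds$product[j]]], j] + 1
    }
  }
  cs_sub <- idx[cs$substrate]
  ds_sub <- idx[ds$substrate]
  kc <- cs$k_cat
  kd <- ds$k_direct
  k_act <- network$catalyst$k_act
  k_rev <- network$catalyst$k_rev
  k_inact <- network$catalyst$k_inact
  const_ox <- network$constant_oxidant
  ir <- n + 1L; ia <- n + 2L; ii <- n + 3L; ih <- n + 4L

  function(t, state, parms = NULL) {
    act <- state[[ia]]
    h <- state[[ih]]
    vc <- if (length(kc)) kc * act * state[cs_sub] else numeric(0)
    vd <- if (length(kd)) kd * h * state[ds_sub] else numeric(0)
    dsp <- if (length(vc)) drop(Sc %*% vc) else numeric(n)
    if (length(vd)) dsp <- dsp + drop(Sd %*% vd)
    act_flux <- k_act * state[[ir]] * h
    rev_flux <- k_rev * act
    inact_flux <- k_inact * act
    turn <- sum(vc)
    d <- numeric(n + 4L)
    d[seq_len(n)] <- dsp
    d[ir] <- -act_flux + rev_flux + turn
    d[ia] <- act_flux - rev_flux - turn - inact_flux
    d[ii] <- inact_flux
    d[ih] <- if (const_ox) 0 else -(act_flux + sum(vd))
    list(d)
  }
}

#' Steady-state rate law of the two-step catalytic cycle
#'
#' Quasi-steady-state rate of substrate disappearance for the cycle
#' resting + H2O2 -> active (`k_act`), active -> resting (`k_rev`),
#' active + S -> resting + product (`k_cat`):
#' \deqn{-d[S]/dt = \frac{k_{act} k_{cat} [H_2O_2][S]}
#'   {k_{rev} + k_{act}[H_2O_2] + k_{cat}[S]}\,[Fe]_{tot}.}
#' The hyperbolic dependence on oxidant and substrate is the working rate law
#' for initial-rate analysis of catalytic oxidations.
#'
#' @param k_act Activation rate constant, M-1 s-1.
#' @param k_rev Reverse rate constant, s-1.
#' @param k_cat Substrate oxidation rate constant, M-1 s-1.
#' @param h2o2 Oxidant concentration, mol/L.
#' @param s Substrate concentration, mol/L.
#' @param fe_total Total catalyst concentration, mol/L.
#' @return Rate in M/s (0 where the denominator vanishes). Vectorized.
#' @examples
#' eq1_rate(90, 0, 1.46e4, 5e-3, 5e-5, 1e-6) # ~2.78e-7 M/s
#' @export
eq1_rate <- function(k_act, k_rev, k_cat, h2o2, s, fe_total) {
  args <- list(k_act, k_rev, k_cat, h2o2, s, fe_total)
  if (any(vapply(args, function(a) any(!is.finite(a)) || any(a < 0), logical(1)))) {
    stop("all arguments to eq1_rate must be finite and nonnegative",
         call. = FALSE)
  }
  num <- k_act * k_cat * h2o2 * s * fe_total
  den <- k_rev + k_act * h2o2 + k_cat * s
  ifelse(den == 0, 0, num / den)
}

#' Simulate a degradation network
#'
#' Integrates the mass-action ODE system assembled by
#' [assemble_rate_equations()] over a time grid. Two bookkeeping integrals
#' (cumulative catalytic activations and direct-step events) are carried along
#' for oxidant stoichiometry checks. Tiny negative concentrations from solver
#' round-off are clipped to zero in the reported profile; the raw solution is
#' retained in the `"raw"` attribute.
#'
#' @param network A validated `reaction_network`.
#' @param init Initial state from [initial_state()]; defaults to an empty
#'   system (all species zero).
#' @param times Strictly increasing output time grid in seconds, starting at 0.
#' @param options A [solver_options()] list.
#' @return A `conc_profile`: data frame with `time_s`, one column per species,
#'   and the pseudo-species `cat_resting`, `cat_active`, `cat_inactive`,
#'   `H2O2`. Attributes: `species` (ids), `raw` (unclipped solution),
#'   `aux` (cumulative activation/direct-event integrals).
#' @export
simulate_network <- function(network, init = NULL, times,
                             options = solver_options()) {
  if (is.null(init)) init <- initial_state(network)
  expected <- state_names(network)
  if (!identical(names(init), expected)) {
    init <- init[expected]
    if (any(is.na(init))) {
      stop("initial state is missing entries for: ",
           paste(expected[is.na(init)], collapse = ", "), call. = FALSE)
    }
  }
  if (any(init < 0)) {
    stop("negative initial concentration for: ",
         paste(names(init)[init < 0], collapse = ", "), call. = FALSE)
  }
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0)) {
    stop("'times' must start at 0 and be strictly increasing", call. = FALSE)
  }
  rhs <- assemble_rate_equations(network)
  n_state <- length(init)
  ext_rhs <- function(t, y, parms = NULL) {
    core <- y[seq_len(n_state)]
    d <- rhs(t, core, parms)[[1]]
    act_flux <- network$catalyst$k_act * core[["cat_resting"]] * core[["H2O2"]]
    vd_sum <- if (nrow(network$direct_steps)) {
      sum(network$direct_steps$k_direct * core[["H2O2"]] *
            core[network$direct_steps$substrate])
    } else 0
    list(c(d, act_flux, vd_sum))
  }
  y0 <- c(init, cum_activation = 0, cum_direct = 0)
  method <- if (options$stiff) "lsoda" else "adams"
  out <- try(deSolve::ode(y = y0, times = times, func = ext_rhs, parms = NULL,
                          method = method, rtol = options$rtol,
                          atol = options$atol,
                          hmax = if (is.finite(options$max_step))
                            options$max_step else NULL),
             silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(times)) {
    stop("ODE integration failed: ",
         if (inherits(out, "try-error")) attr(out, "condition")$message
         else "solver returned a truncated grid", call. = FALSE)
  }
  raw <- as.data.frame(out)
  names(raw)[1] <- "time_s"
  prof <- raw[, c("time_s", expected)]
  prof[expected] <- lapply(prof[expected], function(col) pmax(col, 0))
  structure(prof,
            species = network$species$id,
            raw = raw[, c("time_s", expected)],
            aux = raw[, c("time_s", "cum_activation", "cum_direct")],
            class = c("conc_profile", "data.frame"))
}

#' Time of the concentration maximum of one species
#'
#' Returns the grid time at which the trajectory attains its maximum; ties are
#' broken toward the earliest time.
#'
#' @param profile A `conc_profile` (or any data frame with `time_s` and a
#'   column per species).
#' @param species_id Species column to inspect.
#' @return Time in seconds.
#' @export
peak_time <- function(profile, species_id) {
  if (!species_id %in% names(profile)) {
    stop("species \"", species_id, "\" not present in profile", call. = FALSE)
  }
  profile$time_s[which.max(profile[[species_id]])]
}

#' Conservation diagnostics for a simulated profile
#'
#' Checks the two exact balances of the model: catalyst conservation
#' (resting + active + inactive constant) and organic-unit conservation (the
#' sum over all tracked species is constant, since every step maps one tracked
#' molecule to one tracked molecule). When the oxidant is consumed, the
#' bookkeeping integrals are used to verify that oxidant loss equals catalytic
#' activations plus direct-step events.
#'
#' @param profile A `conc_profile` from [simulate_network()].
#' @param network The network it was simulated from.
#' @return List with maximal relative violations: `catalyst`, `ring_unit`,
#'   and `oxidant` (`NA` when the oxidant is held constant or bookkeeping is
#'   unavailable).
#' @export
conservation_report <- function(profile, network) {
  sp <- network$species$id
  cat_cols <- c("cat_resting", "cat_active", "cat_inactive")
  rel_dev <- function(total) {
    ref <- total[1]
    if (ref <= 0) return(max(abs(total - ref)))
    max(abs(total - ref)) / ref
  }
  cat_tot <- rowSums(as.data.frame(profile)[, cat_cols, drop = FALSE])
  ring_tot <- rowSums(as.data.frame(profile)[, sp, drop = FALSE])
  oxidant <- NA_real_
  aux <- attr(profile, "aux")
  if (!network$constant_oxidant && !is.null(aux)) {
    consumed <- profile$H2O2[1] - profile$H2O2
    predicted <- aux$cum_activation + aux$cum_direct
    scale <- max(consumed, 1e-30)
    oxidant <- max(abs(consumed - predicted)) / scale
  }
  list(catalyst = rel_dev(cat_tot), ring_unit = rel_dev(ring_tot),
       oxidant = oxidant)
}

#' Write / read a concentration profile as tidy CSV
#'
#' One row per time point and (pseudo-)species, columns `time_s`,
#' `species_id`, `conc_M`, in deterministic order (time, then species in
#' network order followed by the catalyst states and the oxidant). Numbers
#' carry 15 significant digits.
#'
#' @param profile A `conc_profile`.
#' @param path Output CSV path.
#' @return `path` invisibly for the writer; a `conc_profile` for the reader.
#' @export
write_profile <- function(profile, path) {
  cols <- setdiff(names(profile), "time_s")
  long <- data.frame(
    time_s = rep(profile$time_s, times = length(cols)),
    species_id = rep(cols, each = nrow(profile)),
    conc_M = unlist(profile[cols], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  long <- long[order(match(long$time_s, profile$time_s),
                     match(long$species_id, cols)), ]
  long$time_s <- fmt_num(long$time_s)
  long$conc_M <- fmt_num(long$conc_M)
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "species_id", "conc_M")
  if (!all(need %in% names(long))) {
    stop("profile CSV must have columns time_s, species_id, conc_M",
         call. = FALSE)
  }
  cols <- unique(long$species_id)
  times <- sort(unique(long$time_s))
  wide <- data.frame(time_s = times)
  for (s in cols) {
    sub <- long[long$species_id == s, ]
    wide[[s]] <- sub$conc_M[match(times, sub$time_s)]
  }
  pseudo <- c("cat_resting", "cat_active", "cat_inactive", "H2O2")
  structure(wide, species = setdiff(cols, pseudo),
            class = c("conc_profile", "data.frame"))
}
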