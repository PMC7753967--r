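# Atomic masses (IUPAC 2021 conventional values), g/mol. Only C/H/N/O are
# supported: the degradation chemistry modelled here tracks the organic
# skeleton of CHNO micropollutants; salts, halogens etc. are out of scope.
.ATOMIC_MASS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999)

#' Parse a molecular formula into element counts
#'
#' Accepts a Hill-style formula string such as `"C16H21NO2"` and returns a
#' named integer vector with counts for C, H, N and O (zero where absent).
#'
#' @param formula A formula string, or an already-parsed named numeric vector.
#' @return Named numeric vector with elements `C`, `H`, `N`, `O`.
#' @examples
#' parse_formula("C16H21NO2")
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula) && !is.null(names(formula))) {
    bad <- setdiff(names(formula), names(.ATOMIC_MASS))
    if (length(bad)) {
      stop("unsupported formula: element(s) ", paste(bad, collapse = ", "),
           " outside C/H/N/O", call. = FALSE)
    }
    out <- .ATOMIC_MASS * 0
    out[names(formula)] <- as.numeric(formula)
    return(out)
  }
  if (!is.character(formula) || length(formula) != 1L || is.na(formula)) {
    stop("formula must be a single string, e.g. \"C16H21NO2\"", call. = FALSE)
  }
  f <- gsub("[[:space:]]", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
  if (!nzchar(f) || paste(toks, collapse = "") != f) {
    stop("cannot parse formula \"", formula, "\"", call. = FALSE)
  }
  el <- sub("[0-9]*$", "", toks)
  ct <- sub("^[A-Za-z]+", "", toks)
  ct <- ifelse(nzchar(ct), as.numeric(ct), 1)
  bad <- setdiff(el, names(.ATOMIC_MASS))
  if (length(bad)) {
    stop("unsupported formula \"", formula, "\": element(s) ",
         paste(bad, collapse = ", "), " outside C/H/N/O", call. = FALSE)
  }
  out <- .ATOMIC_MASS * 0
  for (i in seq_along(el)) out[el[i]] <- out[el[i]] + ct[i]
  out
}

#' Molar mass from a CHNO formula
#'
#' @inheritParams parse_formula
#' @return Molar mass in g/mol.
#' @examples
#' molar_mass_from_formula("C16H21NO2") # propranolol free base, ~259.35
#' @export
molar_mass_from_formula <- function(formula) {
  cnt <- parse_formula(formula)
  sum(cnt * .ATOMIC_MASS[names(cnt)])
}

#' Hydrogen peroxide equivalents for complete mineralization
#'
#' Number of two-electron H2O2 oxidation equivalents needed to fully
#' mineralize a CHNO compound to carbon dioxide, water and nitric acid,
#' obtained by element balance of
#' \deqn{C_xH_yN_zO_w + n\,H_2O_2 \rightarrow x\,CO_2 + z\,HNO_3 + m\,H_2O,}
#' which gives \eqn{n = (4x + y + 5z - 2w)/2}. Nitrogen is taken to the
#' nitrate oxidation state, the endpoint observed for deep oxidative
#' degradation in water.
#'
#' @inheritParams parse_formula
#' @return The number of H2O2 equivalents (may be fractional).
#' @examples
#' mineralization_equivalents("C16H21NO2") # 43
#' mineralization_equivalents("CH4O")      # 3
#' @export
mineralization_equivalents <- function(formula) {
  cnt <- parse_formula(formula)
  if (cnt[["C"]] < 1) {
    stop("formula must contain at least one carbon atom", call. = FALSE)
  }
  (4 * cnt[["C"]] + cnt[["H"]] + 5 * cnt[["N"]] - 2 * cnt[["O"]]) / 2
}

#' Construct a degradation reaction network
#'
#' A reaction network couples a pool of organic species to a peroxide-activated
#' catalyst. Species are transformed either catalytically (active catalyst +
#' substrate -> resting catalyst + product, rate constant `k_cat`) or directly
#' by the oxidant (substrate + H2O2 -> product, rate constant `k_direct`). The
#' catalyst block carries the activation constant `k_act` (M-1 s-1), the
#' reverse constant `k_rev` (s-1, usually negligible) and the first-order
#' operational-inactivation constant `k_inact` (s-1) acting on the active form.
#'
#' The constructor is deliberately permissive: structural invariants (acyclic
#' step graph, declared endpoints, mass consistency, ...) are checked by
#' [validate_network()], and [load_network()] refuses invalid configurations.
#'
#' @param species `data.frame` with columns `id`, `name`, `formula` and
#'   optionally `molar_mass` (g/mol, computed from the formula when missing),
#'   `lc50` (mg/L), `lc50_surrogate`, `quantified`, `terminal`.
#' @param catalytic_steps `data.frame` with columns `substrate`, `product`,
#'   `k_cat` (M-1 s-1); may be `NULL`.
#' @param direct_steps `data.frame` with columns `substrate`, `product`,
#'   `k_direct` (M-1 s-1); may be `NULL`.
#' @param catalyst list with `total_conc` (mol/L), `k_act`, `k_rev`, `k_inact`.
#' @param oxidant_conc0 initial H2O2 concentration, mol/L.
#' @param constant_oxidant logical; hold the oxidant at its initial value
#'   (appropriate under large excess) instead of consuming it.
#' @return An object of class `reaction_network`.
#' @seealso [propranolol_network()], [validate_network()], [load_network()]
#' @export
reaction_network <- function(species, catalytic_steps = NULL,
                             direct_steps = NULL, catalyst,
                             oxidant_conc0, constant_oxidant = TRUE) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  if (!all(c("id", "formula") %in% names(species))) {
    stop("species table must have 'id' and 'formula' columns", call. = FALSE)
  }
  if (is.null(species$name)) species$name <- species$id
  if (is.null(species$molar_mass)) species$molar_mass <- NA_real_
  miss <- is.na(species$molar_mass)
  if (any(miss)) {
    species$molar_mass[miss] <-
      vapply(species$formula[miss], molar_mass_from_formula, numeric(1))
  }
  if (is.null(species$lc50)) species$lc50 <- NA_real_
  if (is.null(species$lc50_surrogate)) species$lc50_surrogate <- NA_character_
  if (is.null(species$quantified)) species$quantified <- TRUE
  if (is.null(species$terminal)) species$terminal <- FALSE

  empty_step <- function(kcol) {
    out <- data.frame(substrate = character(), product = character())
    out[[kcol]] <- numeric()
    out
  }
  catalytic_steps <- if (is.null(catalytic_steps) || !NROW(catalytic_steps)) {
    empty_step("k_cat")
  } else as.data.frame(catalytic_steps, stringsAsFactors = FALSE)
  direct_steps <- if (is.null(direct_steps) || !NROW(direct_steps)) {
    empty_step("k_direct")
  } else as.data.frame(direct_steps, stringsAsFactors = FALSE)

  catalyst <- list(
    total_conc = as.numeric(catalyst$total_conc),
    k_act = as.numeric(catalyst$k_act),
    k_rev = if (is.null(catalyst$k_rev)) 0 else as.numeric(catalyst$k_rev),
    k_inact = if (is.null(catalyst$k_inact)) 0 else as.numeric(catalyst$k_inact)
  )

  structure(
    list(species = species,
         catalytic_steps = catalytic_steps,
         direct_steps = direct_steps,
         catalyst = catalyst,
         oxidant_conc0 = as.numeric(oxidant_conc0),
         constant_oxidant = isTRUE(constant_oxidant)),
    class = "reaction_network"
  )
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network>", nrow(x$species), "species,",
      nrow(x$catalytic_steps), "catalytic steps,",
      nrow(x$direct_steps), "direct steps\n")
  cat("  catalyst: total", format(x$catalyst$total_conc), "M, k_act",
      format(x$catalyst$k_act), "M-1 s-1, k_inact",
      format(x$catalyst$k_inact), "s-1\n")
  cat("  oxidant:", format(x$oxidant_conc0), "M",
      if (x$constant_oxidant) "(held constant)" else "(consumed)", "\n")
  invisible(x)
}

# Edge list of the step graph (substrate -> product), both step kinds pooled.
network_edges <- function(network) {
  rbind(
    data.frame(from = network$catalytic_steps$substrate,
               to = network$catalytic_steps$product,
               kind = rep("catalytic", nrow(network$catalytic_steps))),
    data.frame(from = network$direct_steps$substrate,
               to = network$direct_steps$product,
               kind = rep("direct", nrow(network$direct_steps)))
  )
}

# Species reachable from `from` by following steps (includes `from`).
reachable_species <- function(network, from) {
  edges <- network_edges(network)
  seen <- from
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(edges$to[edges$from %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- union(seen, frontier)
  }
  seen
}

#' Validate a reaction network
#'
#' Checks the structural invariants of a [reaction_network()]: unique species
#' ids, declared step endpoints, no self-loops, no cycles, nonnegative rate
#' constants, every non-terminal species consumed by at least one step, molar
#' masses consistent with formulas (within 0.5 g/mol), positive LC50 values
#' and a well-formed catalyst block. Issues are reported, not raised.
#'
#' @param network A `reaction_network`.
#' @return Character vector of human-readable issues; empty when valid.
#' @export
validate_network <- function(network) {
  issues <- character()
  sp <- network$species
  if (!nrow(sp)) return("species list is empty")
  dup <- unique(sp$id[duplicated(sp$id)])
  for (d in dup) issues <- c(issues, sprintf("duplicate species_id \"%s\"", d))

  edges <- network_edges(network)
  for (i in seq_len(nrow(edges))) {
    for (endpt in c("from", "to")) {
      s <- edges[[endpt]][i]
      if (!s %in% sp$id) {
        issues <- c(issues, sprintf(
          "step %s->%s (%s) references undeclared species \"%s\"",
          edges$from[i], edges$to[i], edges$kind[i], s))
      }
    }
    if (identical(edges$from[i], edges$to[i])) {
      issues <- c(issues, sprintf("self-loop at species \"%s\"", edges$from[i]))
    }
  }

  kc <- network$catalytic_steps$k_cat
  kd <- network$direct_steps$k_direct
  if (any(!is.finite(kc)) || any(kc < 0)) {
    issues <- c(issues, "negative or non-finite k_cat in catalytic_steps")
  }
  if (any(!is.finite(kd)) || any(kd < 0)) {
    issues <- c(issues, "negative or non-finite k_direct in direct_steps")
  }

  # cycle detection by iterative removal of sink nodes (Kahn on reversed graph)
  ed <- edges[edges$from %in% sp$id & edges$to %in% sp$id &
                edges$from != edges$to, , drop = FALSE]
  nodes <- unique(c(ed$from, ed$to))
  repeat {
    sinks <- setdiff(nodes, ed$from)
    if (!length(sinks)) break
    nodes <- setdiff(nodes, sinks)
    ed <- ed[!(ed$to %in% sinks), , drop = FALSE]
    if (!nrow(ed)) break
  }
  if (nrow(ed)) {
    issues <- c(issues, paste0("cycle detected involving species: ",
                               paste(sort(unique(c(ed$from, ed$to))),
                                     collapse = ", ")))
  }

  substrates <- unique(edges$from)
  for (i in seq_len(nrow(sp))) {
    if (!isTRUE(sp$terminal[i]) && !(sp$id[i] %in% substrates)) {
      issues <- c(issues, sprintf(
        "non-terminal species \"%s\" is not the substrate of any step", sp$id[i]))
    }
  }

  for (i in seq_len(nrow(sp))) {
    mm <- tryCatch(molar_mass_from_formula(sp$formula[i]), error = function(e) NA)
    if (is.na(mm)) {
      issues <- c(issues, sprintf("species \"%s\": unparseable formula \"%s\"",
                                  sp$id[i], sp$formula[i]))
    } else if (abs(mm - sp$molar_mass[i]) > 0.5) {
      issues <- c(issues, sprintf(
        "species \"%s\": molar_mass %.3f differs from formula mass %.3f by > 0.5 g/mol",
        sp$id[i], sp$molar_mass[i], mm))
    }
    if (!is.na(sp$lc50[i]) && sp$lc50[i] <= 0) {
      issues <- c(issues, sprintf("species \"%s\": lc50 must be > 0", sp$id[i]))
    }
  }

  cat_par <- unlist(network$catalyst)
  if (any(!is.finite(cat_par)) || any(cat_par < 0)) {
    issues <- c(issues, "catalyst parameters must be finite and nonnegative")
  }
  if (!is.finite(network$oxidant_conc0) || network$oxidant_conc0 < 0) {
    issues <- c(issues, "oxidant_conc0 must be finite and nonnegative")
  }
  issues
}

#' Built-in propranolol degradation network
#'
#' The oxidative degradation cascade of the beta-blocker propranolol under a
#' peroxide-activating iron catalyst at pH 7, 25 C. The naphthalene unit of the
#' drug passes through 1-naphthol (A), 1,4-dihydroxynaphthalene (B, a very fast
#' transforming intermediate), 1,4-naphthoquinone (C), its epoxide (D) and
#' 2-hydroxynaphthalene-1,4-dione (E) before ending at phthalic acid (F); the
#' aliphatic fragment split off in the first step is not tracked. Rate
#' constants are the simulation-derived values at pH 7/25 C in M, s units;
#' LC50 entries are zebrafish lethality values (embryo or larvae; menadione
#' and juglone serve as structural surrogates for C and E).
#'
#' Conditions for the reference scenario: catalyst 1e-6 M, propranolol 5e-5 M,
#' H2O2 5e-3 M (held constant, ~100-fold excess).
#'
#' @return A validated `reaction_network`.
#' @examples
#' net <- propranolol_network()
#' validate_network(net)
#' @export
propranolol_network <- function() {
  species <- data.frame(
    id = c("P", "A", "B", "C", "D", "E", "F"),
    name = c("propranolol", "1-naphthol", "1,4-dihydroxynaphthalene",
             "1,4-naphthoquinone",
             "2,3-dihydro-2,3-epoxynaphthalene-1,4-dione",
             "2-hydroxynaphthalene-1,4-dione", "phthalic acid"),
    formula = c("C16H21NO2", "C10H8O", "C10H8O2", "C10H6O2", "C10H6O3",
                "C10H6O3", "C8H6O4"),
    lc50 = c(2.48, 30, NA, 0.2686, NA, 0.1079, NA),
    lc50_surrogate = c(NA, NA, NA,
                       "2-methyl-1,4-naphthoquinone (menadione), zebrafish embryo ~76-h LC50",
                       NA,
                       "5-hydroxy-1,4-naphthoquinone (juglone), zebrafish embryo ~76-h LC50",
                       NA),
    quantified = c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
    terminal = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  catalytic <- data.frame(
    substrate = c("P", "A", "C", "D", "E"),
    product   = c("A", "B", "E", "F", "F"),
    k_cat     = c(1.70e4, 9.3e4, 3.5e3, 70, 5.0e4),
    stringsAsFactors = FALSE
  )
  direct <- data.frame(
    substrate = c("B", "C"),
    product   = c("C", "D"),
    k_direct  = c(3.5e3, 3.4e-2),
    stringsAsFactors = FALSE
  )
  reaction_network(
    species = species,
    catalytic_steps = catalytic,
    direct_steps = direct,
    catalyst = list(total_conc = 1e-6, k_act = 90, k_rev = 0, k_inact = 1.7e-3),
    oxidant_conc0 = 5e-3,
    constant_oxidant = TRUE
  )
}

#' Read a reaction network from a YAML configuration file
#'
#' The configuration holds blocks `species` (list of `id`, `name`, `formula`,
#' optional `molar_mass`, `lc50`, `lc50_surrogate`, `quantified`, `terminal`),
#' `catalytic_steps` (`substrate`, `product`, `k_cat`), `direct_steps`
#' (`substrate`, `product`, `k_direct`), `catalyst` (`total_conc`, `k_act`,
#' `k_rev`, `k_inact`) and `oxidant` (`conc0`, `constant`). Units are fixed:
#' mol/L, s, M-1 s-1 and mg/L. [write_network()] emits the identical dialect.
#'
#' @param config Path to a YAML file, or an equivalent nested list.
#' @return A validated `reaction_network`; invalid configurations raise an
#'   error naming the offending field or step.
#' @export
load_network <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) {
      stop("configuration error: file not found: ", config, call. = FALSE)
    }
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    stop("configuration error: 'config' must be a path or a list", call. = FALSE)
  }

  need_block <- function(name) {
    if (is.null(cfg[[name]])) {
      stop("configuration error: missing block '", name, "'", call. = FALSE)
    }
    cfg[[name]]
  }
  sp_list <- need_block("species")
  if (!length(sp_list)) {
    stop("configuration error: 'species' must be a non-empty list", call. = FALSE)
  }
  get_field <- function(entry, field, default, where) {
    val <- entry[[field]]
    if (is.null(val)) {
      if (identical(default, quote(required))) {
        stop("configuration error: missing field '", field, "' in ", where,
             call. = FALSE)
      }
      default
    } else val
  }
  species <- do.call(rbind, lapply(seq_along(sp_list), function(i) {
    e <- sp_list[[i]]
    where <- sprintf("species[%d]", i)
    data.frame(
      id = as.character(get_field(e, "id", quote(required), where)),
      name = as.character(get_field(e, "name", get_field(e, "id", "", where), where)),
      formula = as.character(get_field(e, "formula", quote(required), where)),
      molar_mass = as.numeric(get_field(e, "molar_mass", NA_real_, where)),
      lc50 = as.numeric(get_field(e, "lc50", NA_real_, where)),
      lc50_surrogate = as.character(get_field(e, "lc50_surrogate", NA_character_, where)),
      quantified = isTRUE(get_field(e, "quantified", TRUE, where)),
      terminal = isTRUE(get_field(e, "terminal", FALSE, where)),
      stringsAsFactors = FALSE
    )
  }))

  read_steps <- function(block, kfield) {
    lst <- cfg[[block]]
    if (!length(lst)) return(NULL)
    do.call(rbind, lapply(seq_along(lst), function(i) {
      e <- lst[[i]]
      where <- sprintf("%s[%d]", block, i)
      out <- data.frame(
        substrate = as.character(get_field(e, "substrate", quote(required), where)),
        product = as.character(get_field(e, "product", quote(required), where)),
        stringsAsFactors = FALSE
      )
      out[[kfield]] <- as.numeric(get_field(e, kfield, quote(required), where))
      out
    }))
  }
  cat_block <- need_block("catalyst")
  oxi_block <- need_block("oxidant")
  for (f in c("total_conc", "k_act")) {
    if (is.null(cat_block[[f]])) {
      stop("configuration error: missing field '", f, "' in catalyst", call. = FALSE)
    }
  }
  if (is.null(oxi_block$conc0)) {
    stop("configuration error: missing field 'conc0' in oxidant", call. = FALSE)
  }

  net <- reaction_network(
    species = species,
    catalytic_steps = read_steps("catalytic_steps", "k_cat"),
    direct_steps = read_steps("direct_steps", "k_direct"),
    catalyst = cat_block,
    oxidant_conc0 = oxi_block$conc0,
    constant_oxidant = if (is.null(oxi_block$constant)) TRUE else isTRUE(oxi_block$constant)
  )
  issues <- validate_network(net)
  if (length(issues)) {
    stop("invalid network configuration:\n", paste0("  - ", issues, collapse = "\n"),
         call. = FALSE)
  }
  net
}

#' Write a reaction network to a YAML configuration file
#'
#' Emits the dialect read by [load_network()], so that networks round-trip.
#'
#' @param network A `reaction_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  sp <- network$species
  drop_na <- function(x) x[!vapply(x, function(v) is.null(v) ||
                                     (length(v) == 1 && is.na(v)), logical(1))]
  cfg <- list(
    species = lapply(seq_len(nrow(sp)), function(i) drop_na(list(
      id = sp$id[i], name = sp$name[i], formula = sp$formula[i],
      molar_mass = sp$molar_mass[i], lc50 = sp$lc50[i],
      lc50_surrogate = sp$lc50_surrogate[i],
      quantified = sp$quantified[i], terminal = sp$terminal[i]
    ))),
    catalytic_steps = lapply(seq_len(nrow(network$catalytic_steps)), function(i)
      list(substrate = network$catalytic_steps$substrate[i],
           product = network$catalytic_steps$product[i],
           k_cat = network$catalytic_steps$k_cat[i])),
    direct_steps = lapply(seq_len(nrow(network$direct_steps)), function(i)
      list(substrate = network$direct_steps$substrate[i],
           product = network$direct_steps$product[i],
           k_direct = network$direct_steps$k_direct[i])),
    catalyst = network$catalyst,
    oxidant = list(conc0 = network$oxidant_conc0,
                   constant = network$constant_oxidant)
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
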