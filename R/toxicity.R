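#' Convert molar concentration trajectories to mass concentrations
#'
#' Multiplies each species trajectory by its molar mass:
#' `mg/L = mol/L * molar_mass * 1000`. Catalyst states and the oxidant are not
#' converted.
#'
#' @param profile A `conc_profile` (or data frame with `time_s` plus species
#'   columns).
#' @param species_specs A `reaction_network` or a species data frame with
#'   columns `id` and `molar_mass`.
#' @return Data frame of class `mass_profile`: `time_s` plus one mg/L column
#'   per species.
#' @export
to_mass_concentration <- function(profile, species_specs) {
  sp <- if (inherits(species_specs, "reaction_network")) {
    species_specs$species
  } else as.data.frame(species_specs)
  prof_sp <- attr(profile, "species")
  if (is.null(prof_sp)) {
    prof_sp <- setdiff(names(profile),
                       c("time_s", "cat_resting", "cat_active",
                         "cat_inactive", "H2O2"))
  }
  missing_mm <- setdiff(prof_sp, sp$id[!is.na(sp$molar_mass)])
  if (length(missing_mm)) {
    stop("no molar mass available for species: ",
         paste(missing_mm, collapse = ", "), call. = FALSE)
  }
  mm <- setNames(sp$molar_mass, sp$id)
  out <- data.frame(time_s = profile$time_s)
  for (s in prof_sp) out[[s]] <- profile[[s]] * mm[[s]] * 1000
  structure(out, species = prof_sp, units = "mg/L",
            class = c("mass_profile", "data.frame"))
}

#' LC50 table of a network
#'
#' Extracts the per-species lethality data carried by a network into the
#' tabular form consumed by [toxic_units()]. Species without an LC50 are
#' listed with `NA`, not dropped.
#'
#' @param network A `reaction_network`.
#' @return Data frame with columns `species_id`, `lc50_mg_per_L`,
#'   `surrogate_of`, `source`.
#' @export
lc50_table <- function(network) {
  sp <- network$species
  data.frame(species_id = sp$id,
             lc50_mg_per_L = sp$lc50,
             surrogate_of = sp$lc50_surrogate,
             source = rep(NA_character_, nrow(sp)),
             stringsAsFactors = FALSE)
}

#' Toxic-unit profile of a degrading mixture
#'
#' Divides each mass-concentration trajectory by the species' LC50 to give
#' dimensionless toxic units, `TU_j(t) = mgL_j(t) / LC50_j`, and sums them
#' under concentration addition into a composite trajectory. Species without
#' an LC50 entry are excluded from the composite and reported, never silently
#' dropped.
#'
#' @param mass_profile A `mass_profile` from [to_mass_concentration()].
#' @param lc50 A data frame with columns `species_id` and `lc50_mg_per_L`
#'   (as produced by [lc50_table()] or [read_lc50_table()]).
#' @return Data frame of class `toxicity_profile` with `time_s`, one TU column
#'   per included species and a `composite` column; attributes `included` and
#'   `excluded` list the species bookkeeping.
#' @export
toxic_units <- function(mass_profile, lc50) {
  lc50 <- as.data.frame(lc50)
  if (!all(c("species_id", "lc50_mg_per_L") %in% names(lc50))) {
    stop("'lc50' must have columns species_id and lc50_mg_per_L", call. = FALSE)
  }
  usable <- lc50[!is.na(lc50$lc50_mg_per_L), , drop = FALSE]
  if (any(usable$lc50_mg_per_L <= 0)) {
    stop("LC50 values must be > 0", call. = FALSE)
  }
  prof_sp <- attr(mass_profile, "species")
  if (is.null(prof_sp)) prof_sp <- setdiff(names(mass_profile), "time_s")
  included <- intersect(prof_sp, usable$species_id)
  excluded <- setdiff(prof_sp, included)
  if (!length(included)) {
    stop("no species of the profile has an LC50 entry", call. = FALSE)
  }
  lcv <- setNames(usable$lc50_mg_per_L, usable$species_id)
  out <- data.frame(time_s = mass_profile$time_s)
  for (s in included) out[[s]] <- mass_profile[[s]] / lcv[[s]]
  out$composite <- unname(rowSums(out[, included, drop = FALSE]))
  structure(out, included = included, excluded = excluded,
            class = c("toxicity_profile", "data.frame"))
}

#' Summary statistics of a composite toxic-unit trajectory
#'
#' @param tox_profile A `toxicity_profile` from [toxic_units()].
#' @return List with `tu_initial` (composite TU at t = 0), `tu_peak`,
#'   `t_peak_s`, `t_exceed_s` (first time the composite strictly exceeds its
#'   initial value; `NA` if never) and `tu_final`.
#' @export
toxicity_summary <- function(tox_profile) {
  if (!nrow(tox_profile)) stop("empty toxicity profile", call. = FALSE)
  comp <- tox_profile$composite
  tt <- tox_profile$time_s
  exceed <- which(comp > comp[1])
  list(tu_initial = comp[1],
       tu_peak = max(comp),
       t_peak_s = tt[which.max(comp)],
       t_exceed_s = if (length(exceed)) tt[exceed[1]] else NA_real_,
       tu_final = comp[length(comp)])
}

#' Read / write an LC50 table as CSV
#'
#' Columns: `species_id`, `lc50_mg_per_L`, `surrogate_of`, `source`.
#'
#' @param path CSV path.
#' @param table Table to write.
#' @return The table (reader) or `path` invisibly (writer).
#' @export
read_lc50_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species_id", "lc50_mg_per_L") %in% names(tab))) {
    stop("LC50 CSV must have columns species_id and lc50_mg_per_L",
         call. = FALSE)
  }
  if (is.null(tab$surrogate_of)) tab$surrogate_of <- NA_character_
  if (is.null(tab$source)) tab$source <- NA_character_
  tab
}

#' @rdname read_lc50_table
#' @export
write_lc50_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write a toxicity profile as tidy CSV
#'
#' One row per time and species (plus the pseudo-species `composite`), columns
#' `time_s`, `species_id`, `toxic_units`.
#'
#' @param tox_profile A `toxicity_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_toxicity_profile <- function(tox_profile, path) {
  cols <- setdiff(names(tox_profile), "time_s")
  long <- data.frame(
    time_s = rep(tox_profile$time_s, times = length(cols)),
    species_id = rep(cols, each = nrow(tox_profile)),
    toxic_units = unlist(tox_profile[cols], use.names = FALSE)
  )
  long <- long[order(match(long$time_s, tox_profile$time_s),
                     match(long$species_id, cols)), ]
  long$time_s <- fmt_num(long$time_s)
  long$toxic_units <- fmt_num(long$toxic_units)
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
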