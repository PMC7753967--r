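#' Measurement noise model for synthetic observations
#'
#' Gaussian proportional-plus-additive error, the standard working model for
#' chromatographic quantitation: `observed = truth * (1 + eps_p) + eps_a` with
#' `eps_p ~ N(0, prop_sd^2)` and `eps_a ~ N(0, add_sd^2)`.
#'
#' @param prop_sd Proportional standard deviation as a fraction (default 0.05).
#' @param add_sd Additive standard deviation in mol/L (default 2e-7).
#' @param seed Optional integer seed making generation reproducible.
#' @return List of class `noise_model`.
#' @export
noise_model <- function(prop_sd = 0.05, add_sd = 2e-7, seed = NULL) {
  if (prop_sd < 0 || add_sd < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  structure(list(prop_sd = prop_sd, add_sd = add_sd, seed = seed),
            class = "noise_model")
}

#' Generate chromatography-style synthetic observations
#'
#' Simulates the network, samples the true concentrations at the requested
#' times, perturbs them with the noise model and applies detection-limit
#' censoring: rows whose observed value falls below `lod` keep their value but
#' carry `censored_flag = TRUE`, so downstream censoring policy stays
#' explicit. With `quantified_only` only species marked `quantified` in the
#' network (those a UPLC calibration would cover) are emitted.
#'
#' @param network A validated `reaction_network`.
#' @param init Initial state from [initial_state()].
#' @param sample_times Sampling times in seconds (0 is added if absent).
#' @param noise A [noise_model()].
#' @param lod,loq Limit of detection / quantitation in mol/L.
#' @param quantified_only Restrict output to quantified species (default TRUE).
#' @param options [solver_options()] for the underlying simulation.
#' @return Data frame of class `observation_table` with columns `time_s`,
#'   `species_id`, `conc_M`, `censored_flag`; attributes `lod`, `loq`,
#'   `truth` (noiseless values) and `metadata`.
#' @export
generate_observations <- function(network, init, sample_times,
                                  noise = noise_model(), lod = 1e-7,
                                  loq = 3e-7, quantified_only = TRUE,
                                  options = solver_options()) {
  sample_times <- sort(unique(sample_times))
  t_grid <- sort(unique(c(0, sample_times)))
  prof <- simulate_network(network, init = init, times = t_grid,
                           options = options)
  species <- network$species$id
  if (quantified_only) species <- species[network$species$quantified]
  rows <- expand.grid(time_s = sample_times, species_id = species,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rows[order(match(rows$time_s, sample_times),
                     match(rows$species_id, species)), ]
  truth <- vapply(seq_len(nrow(rows)), function(i) {
    prof[[rows$species_id[i]]][match(rows$time_s[i], t_grid)]
  }, numeric(1))
  observed <- with_seed(noise$seed, {
    truth * (1 + rnorm(length(truth), 0, noise$prop_sd)) +
      rnorm(length(truth), 0, noise$add_sd)
  })
  out <- data.frame(time_s = rows$time_s, species_id = rows$species_id,
                    conc_M = observed,
                    censored_flag = observed < lod,
                    stringsAsFactors = FALSE)
  structure(out, lod = lod, loq = loq, truth = truth,
            metadata = list(seed = noise$seed, prop_sd = noise$prop_sd,
                            add_sd = noise$add_sd, lod = lod, loq = loq,
                            sample_times = sample_times,
                            quantified_only = quantified_only),
            class = c("observation_table", "data.frame"))
}

#' Default degradation scenario
#'
#' The reference observation design for the built-in propranolol network:
#' catalyst 1e-6 M, propranolol 5e-5 M, H2O2 5e-3 M; sampling at 0, 5, 15,
#' 30, 60, 120, 240 and 480 min (dense early, sparse late, covering the full
#' 8 h over which intermediates remain observable); 5% proportional plus
#' 2e-7 M additive noise; LOD 1e-7 M, LOQ 3e-7 M.
#'
#' @param seed Optional seed stored in the scenario's noise model.
#' @return List with elements `network`, `init`, `sample_times`, `noise`,
#'   `lod`, `loq`.
#' @export
default_scenario <- function(seed = NULL) {
  network <- propranolol_network()
  list(network = network,
       init = initial_state(network, conc = c(P = 5e-5)),
       sample_times = c(0, 5, 15, 30, 60, 120, 240, 480) * 60,
       noise = noise_model(prop_sd = 0.05, add_sd = 2e-7, seed = seed),
       lod = 1e-7,
       loq = 3e-7)
}

#' Write / read observation tables as tidy CSV
#'
#' Columns `time_s`, `species_id`, `conc_M`, `censored_flag`; 15 significant
#' digits. The writer can drop a JSON sidecar (`<path>.meta.json`) recording
#' the generation parameters for provenance.
#'
#' @param observations An `observation_table` (or plain data frame).
#' @param path CSV path.
#' @param sidecar Write the provenance sidecar when metadata is available.
#' @return `path` invisibly (writer); an `observation_table` (reader).
#' @export
write_observations <- function(observations, path, sidecar = TRUE) {
  out <- data.frame(time_s = fmt_num(observations$time_s),
                    species_id = observations$species_id,
                    conc_M = fmt_num(observations$conc_M),
                    censored_flag = observations$censored_flag)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta <- attr(observations, "metadata")
  if (sidecar && !is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "species_id", "conc_M")
  if (!all(need %in% names(tab))) {
    stop("observations CSV must have columns time_s, species_id, conc_M",
         call. = FALSE)
  }
  if (is.null(tab$censored_flag)) tab$censored_flag <- FALSE
  tab$censored_flag <- as.logical(tab$censored_flag)
  structure(tab, class = c("observation_table", "data.frame"))
}
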