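#' Test-aerosol parameters for the campaign simulator
#'
#' Describes the dried sodium-chloride challenge aerosol as a lognormal
#' number-size distribution. Defaults emulate the standard NaCl test aerosol:
#' count median diameter 80 nm (inside the 60-100 nm validity band), GSD 1.8,
#' and a number concentration calibrated so that the detected chamber mass
#' concentration on the canonical grid is about 8 mg/m3, the midpoint of the
#' 4-12 mg/m3 validity band. The `ramp` models the rig's start-up transient:
#' concentrations during the first two minutes are below equilibrium, which
#' is why the evaluation protocol discards them.
#'
#' @param cmd_nm count median diameter, nm.
#' @param gsd geometric standard deviation (> 1).
#' @param number_conc_per_cm3 chamber number concentration, particles/cm3.
#' @param nacl_density_kg_m3 particle mass density; 2165 kg/m3 for NaCl.
#' @param ramp per-minute multiplicative start-up factors in (0, 1], trailing
#'   values 1; its length sets the default run length.
#' @return An object of class `aerosol_params`.
#' @export
aerosol_params <- function(cmd_nm = 80, gsd = 1.8,
                           number_conc_per_cm3 = 3.3e6,
                           nacl_density_kg_m3 = 2165,
                           ramp = c(0.5, 0.8, 1, 1, 1)) {
  stopifnot(cmd_nm > 0, gsd > 1, number_conc_per_cm3 >= 0, nacl_density_kg_m3 > 0)
  if (any(ramp <= 0) || any(ramp > 1))
    stop("ramp factors must lie in (0, 1]", call. = FALSE)
  if (ramp[length(ramp)] != 1)
    stop("trailing ramp factor must be 1 (equilibrium)", call. = FALSE)
  structure(list(cmd_nm = cmd_nm, gsd = gsd,
                 number_conc_per_cm3 = number_conc_per_cm3,
                 nacl_density_kg_m3 = nacl_density_kg_m3, ramp = ramp),
            class = "aerosol_params")
}

#' Size-dependent mask penetration model for the simulator
#'
#' Penetration (the fraction of particles of a given size that pass the
#' filter) is modelled as a Gaussian in log-diameter centred on the most
#' penetrating particle size (MPPS) - the simplest unimodal shape consistent
#' with depth-filtration behaviour. Mask-to-mask variability is a single
#' lognormal multiplier on the whole curve, plus a defect mixture: with
#' probability `defect_fraction` a mask is a defect with flat penetration
#' `defect_p`, producing the bimodal per-batch spreads seen in poor batches.
#'
#' @param p_mpps peak penetration fraction at the MPPS, in `[0, 1]` (0 is a
#'   perfect filter).
#' @param d_mpps_nm most-penetrating particle diameter, nm.
#' @param curvature_k curvature of the log-diameter Gaussian (>= 0; 0 gives a
#'   size-independent flat curve).
#' @param mask_sigma lognormal sigma of the per-mask multiplier (0 = identical
#'   masks).
#' @param defect_fraction probability that a mask is a defect.
#' @param defect_p flat penetration fraction of defect masks (>= `p_mpps`).
#' @return An object of class `mask_model`.
#' @export
mask_model <- function(p_mpps = 0.04, d_mpps_nm = 200, curvature_k = 0.5,
                       mask_sigma = 0.25, defect_fraction = 0.02,
                       defect_p = 0.30) {
  stopifnot(p_mpps >= 0, p_mpps <= 1, d_mpps_nm > 0, curvature_k >= 0,
            mask_sigma >= 0, defect_fraction >= 0, defect_fraction <= 1)
  if (defect_p < p_mpps)
    stop("defect_p must be at least p_mpps", call. = FALSE)
  structure(list(p_mpps = p_mpps, d_mpps_nm = d_mpps_nm,
                 curvature_k = curvature_k, mask_sigma = mask_sigma,
                 defect_fraction = defect_fraction, defect_p = defect_p),
            class = "mask_model")
}

#' Flame-photometer noise model
#'
#' The flame photometer reports the total NaCl mass concentration of the
#' sampled stream; its reading is modelled as the true concentration times
#' `(1 + eps)` with `eps ~ Normal(0, noise_cv)` truncated below at -1.
#'
#' @param noise_cv multiplicative noise coefficient of variation (>= 0).
#' @return An object of class `flame_model`.
#' @export
flame_model <- function(noise_cv = 0.01) {
  stopifnot(is.numeric(noise_cv), noise_cv >= 0)
  structure(list(noise_cv = noise_cv), class = "flame_model")
}

#' Penetration fraction at a given diameter
#'
#' Evaluates `min(1, mask_effect * p_mpps * exp(-curvature_k * ln^2(d / d_mpps)))`,
#' unimodal in log-diameter with its maximum at the MPPS.
#'
#' @param d_nm particle diameter(s), nm (> 0).
#' @param model a [mask_model()].
#' @param mask_effect per-mask multiplier on the whole curve (default 1).
#' @return Penetration fraction(s) in `[0, 1]`.
#' @examples
#' m <- mask_model(p_mpps = 0.04, d_mpps_nm = 200, curvature_k = 0.5)
#' penetration_curve(200, m)   # 0.04, the peak
#' penetration_curve(100, m)   # ~0.0314
#' @export
penetration_curve <- function(d_nm, model, mask_effect = 1) {
  stopifnot(inherits(model, "mask_model"))
  if (any(!is.finite(d_nm)) || any(d_nm <= 0))
    stop("diameters must be positive", call. = FALSE)
  pmin(1, mask_effect * model$p_mpps *
         exp(-model$curvature_k * log(d_nm / model$d_mpps_nm)^2))
}

#' Discretized lognormal class probabilities
#'
#' Probability that a particle drawn from the aerosol's lognormal number-size
#' distribution falls into each class of the grid. The probabilities sum to
#' the distribution's mass inside `[d_lower, d_upper]`; particles outside the
#' grid are not counted by the instrument.
#'
#' @param aerosol an [aerosol_params()].
#' @param grid a [size_grid()].
#' @return Numeric vector of length `grid$n_classes`.
#' @export
class_probabilities <- function(aerosol, grid) {
  stopifnot(inherits(aerosol, "aerosol_params"), inherits(grid, "size_grid"))
  diff(stats::plnorm(grid$class_edges_nm, log(aerosol$cmd_nm), log(aerosol$gsd)))
}

# Expected counts per class per minute at equilibrium (ramp = 1).
reference_rates <- function(aerosol, grid, sample_flow_lpm = 0.1, dilution = 1) {
  p <- class_probabilities(aerosol, grid)
  flow_cm3_min <- sample_flow_lpm * 1000
  p * aerosol$number_conc_per_cm3 * flow_cm3_min / dilution
}

#' Simulate a reference (empty-mount) measurement
#'
#' Draws per-minute per-class Poisson counts for a run without a mask: the
#' expected count in class i during minute t is the lognormal class
#' probability times the number concentration, sample flow, and the minute's
#' ramp factor, divided by the dilution factor.
#'
#' @param aerosol an [aerosol_params()].
#' @param grid a [size_grid()].
#' @param n_minutes run length in minutes (protocol: 5; must cover the ramp).
#' @param sample_flow_lpm,dilution spectrometer sample flow (L/min) and
#'   dilution factor.
#' @param seed integer seed; fixed seed gives identical counts.
#' @param measurement_id,batch_id identifiers for the returned record.
#' @param ... further metadata passed to [measurement()].
#' @return A [measurement()] with `role = "reference"`.
#' @export
simulate_reference <- function(aerosol = aerosol_params(), grid = size_grid(),
                               n_minutes = 5, sample_flow_lpm = 0.1, dilution = 1,
                               seed = NULL, measurement_id = "ref",
                               batch_id = "", ...) {
  stopifnot(inherits(aerosol, "aerosol_params"))
  if (n_minutes < length(aerosol$ramp))
    stop("n_minutes must cover the start-up ramp (length ",
         length(aerosol$ramp), ")", call. = FALSE)
  rates <- reference_rates(aerosol, grid, sample_flow_lpm, dilution)
  if (aerosol$number_conc_per_cm3 > 0 && sum(rates) == 0)
    stop("aerosol distribution has no support on the size grid", call. = FALSE)
  ramp <- c(aerosol$ramp, rep(1, n_minutes - length(aerosol$ramp)))
  if (!is.null(seed)) set.seed(seed)
  lam <- outer(ramp, rates)
  counts <- matrix(stats::rpois(length(lam), lam), n_minutes, grid$n_classes)
  measurement(measurement_id, "reference", counts, grid, batch_id = batch_id,
              sample_flow_lpm = sample_flow_lpm, dilution_factor = dilution, ...)
}

#' Simulate a mask measurement against known reference rates
#'
#' Draws one mask from the penetration model (lognormal whole-curve
#' multiplier; with probability `defect_fraction` the mask is a defect with
#' flat penetration `defect_p`), then draws per-minute per-class Poisson
#' counts with mean `rate_i * ramp_t * penetration(d_min_i)`. The planted
#' per-class penetration is returned alongside the measurement so downstream
#' estimators can be checked against ground truth.
#'
#' @param ref_rates per-class expected counts per minute at equilibrium, as
#'   produced internally by the reference simulator (nonnegative).
#' @param model a [mask_model()].
#' @param grid a [size_grid()].
#' @param seed integer seed.
#' @param n_minutes,ramp run length and per-minute start-up factors.
#' @param measurement_id,batch_id,mask_id identifiers.
#' @param ... further metadata passed to [measurement()] (flows must match
#'   the reference run for a meaningful comparison).
#' @return A list with elements `measurement`, `penetration` (per-class
#'   planted truth), `mask_effect`, and `is_defect`.
#' @export
simulate_mask_measurement <- function(ref_rates, model, grid = size_grid(),
                                      seed = NULL, n_minutes = 5,
                                      ramp = c(0.5, 0.8, 1, 1, 1),
                                      measurement_id = "mask",
                                      batch_id = "", mask_id = "m1", ...) {
  stopifnot(inherits(model, "mask_model"), inherits(grid, "size_grid"),
            length(ref_rates) == grid$n_classes, all(ref_rates >= 0))
  if (!is.null(seed)) set.seed(seed)
  is_defect <- stats::runif(1) < model$defect_fraction
  if (is_defect) {
    mask_effect <- NA_real_
    pen <- rep(min(1, model$defect_p), grid$n_classes)
  } else {
    mask_effect <- if (model$mask_sigma > 0)
      exp(stats::rnorm(1, 0, model$mask_sigma)) else 1
    pen <- penetration_curve(grid$d_min_nm, model, mask_effect)
  }
  ramp <- c(ramp, rep(1, max(0, n_minutes - length(ramp))))[seq_len(n_minutes)]
  lam <- outer(ramp, ref_rates * pen)
  counts <- matrix(stats::rpois(length(lam), lam), n_minutes, grid$n_classes)
  meas <- measurement(measurement_id, "sample", counts, grid,
                      batch_id = batch_id, mask_id = mask_id, ...)
  list(measurement = meas, penetration = pen,
       mask_effect = mask_effect, is_defect = is_defect)
}

#' Simulate one flame-photometer reading
#'
#' @param true_mass_conc true NaCl mass concentration, mg/m3 (>= 0).
#' @param model a [flame_model()].
#' @param seed integer seed.
#' @return The noisy reading in mg/m3 (never negative).
#' @export
simulate_flame_reading <- function(true_mass_conc, model = flame_model(),
                                   seed = NULL) {
  stopifnot(inherits(model, "flame_model"), all(true_mass_conc >= 0))
  if (!is.null(seed)) set.seed(seed)
  eps <- pmax(-1, stats::rnorm(length(true_mass_conc), 0, model$noise_cv))
  true_mass_conc * (1 + eps)
}

#' Simulate a complete test campaign for one mask batch
#'
#' Produces one shared reference run, `n_masks` mask runs drawn from the
#' penetration model, paired flame-photometer readings for the upstream
#' (reference) and downstream (behind-mask) streams, and a ground-truth table
#' with each mask's planted mass-weighted total passage.
#'
#' @param n_masks number of masks in the batch (>= 1).
#' @param aerosol an [aerosol_params()].
#' @param model a [mask_model()].
#' @param grid a [size_grid()].
#' @param seed integer seed driving all randomness in the campaign.
#' @param flame a [flame_model()].
#' @param batch_id batch identifier.
#' @param declared_standard protection class label for the batch.
#' @param n_minutes,sample_flow_lpm,dilution protocol settings shared by all
#'   runs.
#' @return An object of class `campaign`: a list with `measurements` (the
#'   reference first, then one per mask), `flame` (long table:
#'   `measurement_id`, `stream`, `reading_mg_m3`), `truth` (per-mask planted
#'   values incl. `true_total_passage`), and the `grid`.
#' @examples
#' camp <- simulate_batch(5, seed = 1)
#' length(camp$measurements)  # 1 reference + 5 masks
#' @export
simulate_batch <- function(n_masks, aerosol = aerosol_params(),
                           model = mask_model(), grid = size_grid(),
                           seed = NULL, flame = flame_model(),
                           batch_id = "batch1", declared_standard = "FFP2",
                           n_minutes = 5, sample_flow_lpm = 0.1, dilution = 1) {
  stopifnot(n_masks >= 1)
  if (!is.null(seed)) set.seed(seed)
  rates <- reference_rates(aerosol, grid, sample_flow_lpm, dilution)
  dens <- aerosol$nacl_density_kg_m3

  ref <- simulate_reference(aerosol, grid, n_minutes, sample_flow_lpm, dilution,
                            seed = NULL,
                            measurement_id = paste0(batch_id, "_ref"),
                            batch_id = batch_id,
                            declared_standard = declared_standard)
  # true detected chamber mass concentration (minimum-volume convention), mg/m3
  v_kg <- pi / 6 * (grid$d_min_nm * 1e-9)^3 * dens
  upstream_true <- sum(rates * v_kg) / (sample_flow_lpm * 1e-3) * dilution * 1e6

  flame_rows <- data.frame(measurement_id = ref$measurement_id,
                           stream = "upstream",
                           reading_mg_m3 = simulate_flame_reading(upstream_true, flame),
                           stringsAsFactors = FALSE)
  measurements <- vector("list", n_masks + 1L)
  measurements[[1L]] <- ref
  truth <- data.frame(measurement_id = character(n_masks), mask_id = character(n_masks),
                      mask_effect = numeric(n_masks), is_defect = logical(n_masks),
                      true_total_passage = numeric(n_masks), stringsAsFactors = FALSE)
  w <- rates * v_kg
  for (j in seq_len(n_masks)) {
    mid <- sprintf("%s_mask%02d", batch_id, j)
    sim <- simulate_mask_measurement(
      rates, model, grid, seed = NULL, n_minutes = n_minutes,
      ramp = aerosol$ramp, measurement_id = mid, batch_id = batch_id,
      mask_id = sprintf("m%02d", j), declared_standard = declared_standard,
      sample_flow_lpm = sample_flow_lpm, dilution_factor = dilution,
      mask_dp_mbar = 2.5
    )
    measurements[[j + 1L]] <- sim$measurement
    p_true <- sum(w * sim$penetration) / sum(w)
    truth[j, ] <- list(mid, sprintf("m%02d", j), sim$mask_effect,
                       sim$is_defect, p_true)
    flame_rows <- rbind(flame_rows, data.frame(
      measurement_id = mid, stream = "downstream",
      reading_mg_m3 = simulate_flame_reading(upstream_true * p_true, flame),
      stringsAsFactors = FALSE
    ))
  }
  names(measurements) <- vapply(measurements, `[[`, "", "measurement_id")
  structure(list(measurements = measurements, flame = flame_rows,
                 truth = truth, grid = grid, batch_id = batch_id,
                 declared_standard = declared_standard,
                 upstream_true_mg_m3 = upstream_true),
            class = "campaign")
}

#' @export
print.campaign <- function(x, ...) {
  cat(sprintf("<campaign %s> %d measurements (1 reference + %d masks), standard %s\n",
              x$batch_id, length(x$measurements), nrow(x$truth),
              x$declared_standard))
  invisible(x)
}

#' Export a simulated campaign to the CSV interchange files
#'
#' Writes counts, metadata, flame-photometer and ground-truth CSVs into
#' `dir`, named `<prefix>_counts.csv` etc.
#'
#' @param campaign a [simulate_batch()] result (or a merged campaign).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, a named vector of the four paths.
#' @export
write_campaign <- function(campaign, dir, prefix = "campaign") {
  stopifnot(inherits(campaign, "campaign"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, paste0(prefix, "_counts.csv")),
    metadata = file.path(dir, paste0(prefix, "_metadata.csv")),
    flame = file.path(dir, paste0(prefix, "_flame.csv")),
    truth = file.path(dir, paste0(prefix, "_truth.csv"))
  )
  write_measurements(campaign$measurements, paths[["counts"]], paths[["metadata"]])
  utils::write.csv(campaign$flame, paths[["flame"]], row.names = FALSE)
  utils::write.csv(campaign$truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
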