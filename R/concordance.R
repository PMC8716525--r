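#' Lin's concordance correlation coefficient
#'
#' Agreement statistic between two measurement methods reporting the same
#' quantity: `rho_c = 2*s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`,
#' with population (n-denominator) moments. It equals 1 exactly when every
#' pair lies on the identity line, and is penalised both by scatter (like
#' Pearson's r) and by location/scale shifts away from the bisector.
#'
#' @param x,y paired numeric vectors of equal length (>= 2).
#' @param form `"lin"` (default) squares the mean difference, the canonical
#'   definition; `"printed"` leaves it unsquared, an audit variant matching a
#'   typeset form that can exceed 1 and is not recommended for inference.
#' @param range_label free-text label for the data range the pairs cover.
#' @return An object of class `concordance_result` with `rho_c`, `n`,
#'   `mean_x`, `mean_y`, `var_x`, `var_y`, `cov_xy`, `pearson_r`,
#'   `range_label`, `form`.
#' @examples
#' concordance_coefficient(c(1, 2, 3), c(2, 3, 4))$rho_c   # 4/7
#' @export
concordance_coefficient <- function(x, y, form = c("lin", "printed"),
                                    range_label = "full") {
  form <- match.arg(form)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L)
    stop("need at least 2 complete pairs", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2)           # population moments, per Lin's definition
  vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  loc <- if (form == "lin") (mx - my)^2 else (mx - my)
  denom <- vx + vy + loc
  if (denom == 0)
    stop("both series are constant with equal means: rho_c is 0/0", call. = FALSE)
  r <- if (vx > 0 && vy > 0) cxy / sqrt(vx * vy) else NA_real_
  structure(list(rho_c = 2 * cxy / denom, n = n, mean_x = mx, mean_y = my,
                 var_x = vx, var_y = vy, cov_xy = cxy, pearson_r = r,
                 range_label = range_label, form = form),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Concordance (%s range, n = %d): rho_c = %.4f (Pearson r = %.4f)\n",
              x$range_label, x$n, x$rho_c, x$pearson_r))
  invisible(x)
}

#' Detector-equivalence analysis between two passage readouts
#'
#' Compares the mass-weighted total passage derived from the size-resolved
#' spectrometer counts with the passage derived from the size-blind flame
#' photometer, over the full data range and over restricted ranges (by
#' default pairs where both readouts are at most 10%, the clinically
#' relevant span containing all certification limits). A cutoff subset with
#' fewer than 2 pairs is reported as not estimable.
#'
#' @param spectrometer_pct,photometer_pct paired passage values in percent.
#' @param cutoffs_pct upper bounds (in %) defining the restricted ranges; a
#'   pair enters a subset only if both members are at or below the cutoff.
#' @param form passed to [concordance_coefficient()].
#' @return An object of class `detector_equivalence`: a list of
#'   `concordance_result` (or `"not estimable"` markers), one per range,
#'   plus the paired data.
#' @export
detector_equivalence <- function(spectrometer_pct, photometer_pct,
                                 cutoffs_pct = 10, form = "lin") {
  stopifnot(length(spectrometer_pct) == length(photometer_pct))
  out <- list(full = concordance_coefficient(spectrometer_pct, photometer_pct,
                                             form = form, range_label = "full"))
  for (cut in cutoffs_pct) {
    lab <- sprintf("<=%g%%", cut)
    keep <- is.finite(spectrometer_pct) & is.finite(photometer_pct) &
      spectrometer_pct <= cut & photometer_pct <= cut
    out[[lab]] <- if (sum(keep) < 2L) {
      structure(list(rho_c = NA_real_, n = sum(keep), range_label = lab,
                     not_estimable = TRUE),
                class = "concordance_result")
    } else {
      concordance_coefficient(spectrometer_pct[keep], photometer_pct[keep],
                              form = form, range_label = lab)
    }
  }
  structure(list(results = out,
                 pairs = data.frame(spectrometer_pct = spectrometer_pct,
                                    photometer_pct = photometer_pct)),
            class = "detector_equivalence")
}

#' @export
print.detector_equivalence <- function(x, ...) {
  cat("Detector equivalence (spectrometer vs flame photometer):\n")
  for (r in x$results) {
    if (isTRUE(r$not_estimable))
      cat(sprintf("  %-8s n = %d: not estimable\n", r$range_label, r$n))
    else
      cat(sprintf("  %-8s n = %d: rho_c = %.4f\n", r$range_label, r$n, r$rho_c))
  }
  invisible(x)
}

#' @export
plot.detector_equivalence <- function(x, ...) {
  p <- x$pairs
  lim <- range(c(p$spectrometer_pct, p$photometer_pct), finite = TRUE)
  graphics::plot(p$spectrometer_pct, p$photometer_pct, xlim = lim, ylim = lim,
                 pch = 16, cex = 0.7,
                 xlab = "spectrometer passage [%]",
                 ylab = "flame photometer passage [%]", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate a detector-equivalence validation study
#'
#' Generates the scatter used to validate the spectrometer readout against
#' the flame photometer: `n_masks` flat-penetration masks whose true total
#' passages are evenly spaced over `passage_range`, each measured by both
#' detectors against one shared reference run. The spectrometer readout is
#' the mass-weighted total passage computed from Poisson counts; the
#' photometer readout is the ratio of noisy downstream to upstream mass
#' readings.
#'
#' @param n_masks number of masks (>= 2).
#' @param passage_range true-passage span as fractions, default 0 to 1.
#' @param aerosol an [aerosol_params()].
#' @param grid a [size_grid()].
#' @param flame a [flame_model()] (default 1% multiplicative noise).
#' @param seed integer seed.
#' @param n_discard initial minutes excluded from the spectrometer window.
#' @return A data frame with `true_passage_pct`, `spectrometer_pct`,
#'   `photometer_pct`, one row per mask.
#' @export
simulate_equivalence_study <- function(n_masks = 60, passage_range = c(0, 1),
                                       aerosol = aerosol_params(),
                                       grid = size_grid(),
                                       flame = flame_model(0.01),
                                       seed = NULL, n_discard = 2) {
  stopifnot(n_masks >= 2, length(passage_range) == 2,
            all(passage_range >= 0), all(passage_range <= 1))
  if (!is.null(seed)) set.seed(seed)
  ref <- simulate_reference(aerosol, grid, measurement_id = "eq_ref")
  ref_mass <- measurement_mass(ref, n_discard, aerosol$nacl_density_kg_m3)
  rates <- reference_rates(aerosol, grid, ref$sample_flow_lpm, ref$dilution_factor)
  v_kg <- pi / 6 * (grid$d_min_nm * 1e-9)^3 * aerosol$nacl_density_kg_m3
  upstream_true <- sum(rates * v_kg) / (ref$sample_flow_lpm * 1e-3) *
    ref$dilution_factor * 1e6
  q <- seq(passage_range[1L], passage_range[2L], length.out = n_masks)
  spect <- phot <- numeric(n_masks)
  for (j in seq_len(n_masks)) {
    model <- mask_model(p_mpps = q[j], curvature_k = 0, mask_sigma = 0,
                        defect_fraction = 0, defect_p = max(q[j], 1))
    sim <- simulate_mask_measurement(rates, model, grid, ramp = aerosol$ramp,
                                     measurement_id = sprintf("eq_m%02d", j))
    mask_mass <- measurement_mass(sim$measurement, n_discard,
                                  aerosol$nacl_density_kg_m3)
    spect[j] <- 100 * class_passage(mask_mass, ref_mass)$p_total
    up <- simulate_flame_reading(upstream_true, flame)
    dn <- simulate_flame_reading(upstream_true * q[j], flame)
    phot[j] <- 100 * dn / up
  }
  data.frame(true_passage_pct = 100 * q, spectrometer_pct = spect,
             photometer_pct = phot)
}

#' Photometer-derived passages from a flame-readings table
#'
#' Converts the long flame table of a campaign (one upstream reading per
#' reference, one downstream reading per mask) into per-mask passage
#' percentages, pairing each downstream reading with the campaign's upstream
#' reading from the same reference.
#'
#' @param flame data frame with columns `measurement_id`, `stream`
#'   (`"upstream"`/`"downstream"`), `reading_mg_m3`.
#' @param passage_table the `table` element of an [evaluate_passage()] result
#'   (used to map each mask to its reference).
#' @return The input `passage_table` with an added `p_flame_pct` column.
#' @export
flame_passage <- function(flame, passage_table) {
  need <- c("measurement_id", "stream", "reading_mg_m3")
  if (!all(need %in% names(flame)))
    stop("flame table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  up <- flame[flame$stream == "upstream", ]
  dn <- flame[flame$stream == "downstream", ]
  up_by_id <- stats::setNames(up$reading_mg_m3, up$measurement_id)
  dn_by_id <- stats::setNames(dn$reading_mg_m3, dn$measurement_id)
  passage_table$p_flame_pct <- vapply(seq_len(nrow(passage_table)), function(i) {
    u <- up_by_id[[passage_table$reference_id[i]]]
    d <- dn_by_id[[passage_table$measurement_id[i]]]
    if (is.null(u) || is.null(d) || u <= 0) return(NA_real_)
    100 * d / u
  }, numeric(1))
  passage_table
}
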