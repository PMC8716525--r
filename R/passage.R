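#' Average counts over the equilibrium window
#'
#' The rig needs time to equilibrate after closing the chamber, so the first
#' minutes of every run are discarded and the per-class counts are averaged
#' over the remaining window (protocol: minutes 3-5 of a 5-minute run).
#'
#' @param m a [measurement()].
#' @param n_discard number of initial minutes to exclude (default 2).
#' @return Per-class mean counts per minute (length `n_classes`), with the
#'   window minutes attached as attribute `window_minutes`.
#' @export
select_equilibrium_window <- function(m, n_discard = 2) {
  stopifnot(inherits(m, "measurement"))
  if (m$n_minutes <= n_discard)
    stop("measurement ", m$measurement_id, " has only ", m$n_minutes,
         " minute(s); need more than n_discard = ", n_discard, call. = FALSE)
  window <- (n_discard + 1L):m$n_minutes
  out <- colMeans(m$counts[window, , drop = FALSE])
  attr(out, "window_minutes") <- window
  out
}

#' Convert per-class count rates to a detected mass spectrum
#'
#' Each counted particle of class i is assigned its minimum volume, a sphere
#' at the class's lower edge diameter. The detected mass concentration per
#' class is then
#' `m_i = N_i * (pi * d_min_i^3 / 6) * rho / V_sample * dilution`,
#' with `N_i` the mean counts per minute, `rho` the particle density and
#' `V_sample` the spectrometer's sample flow converted to m3/min. The density
#' sets only the absolute scale: it cancels in every passage ratio.
#'
#' @param mean_counts_per_min per-class mean counts per minute (e.g. from
#'   [select_equilibrium_window()]).
#' @param grid a [size_grid()].
#' @param density_kg_m3 particle mass density (NaCl: 2165 kg/m3).
#' @param sample_flow_lpm spectrometer sample flow, L/min (> 0).
#' @param dilution dilution factor applied upstream of the counter (>= 1).
#' @return An object of class `mass_spectrum`: per-class detected mass
#'   concentration in kg/m3.
#' @examples
#' g <- size_grid(100, 1000, 10)
#' n <- c(1000, rep(0, 9))
#' ms <- class_mass(n, g, 2165, 0.1)
#' ms$m_kg_m3[1]   # ~1.13e-11 kg/m3
#' @export
class_mass <- function(mean_counts_per_min, grid, density_kg_m3 = 2165,
                       sample_flow_lpm = 0.1, dilution = 1) {
  stopifnot(inherits(grid, "size_grid"),
            length(mean_counts_per_min) == grid$n_classes,
            all(mean_counts_per_min >= 0))
  if (!is.numeric(sample_flow_lpm) || sample_flow_lpm <= 0)
    stop("sample flow must be positive", call. = FALSE)
  if (!is.numeric(density_kg_m3) || density_kg_m3 <= 0)
    stop("density must be positive", call. = FALSE)
  d_m <- grid$d_min_nm * 1e-9
  flow_m3_min <- sample_flow_lpm * 1e-3
  m <- as.numeric(mean_counts_per_min) * (pi * d_m^3 / 6) * density_kg_m3 /
    flow_m3_min * dilution
  structure(list(m_kg_m3 = m, grid = grid,
                 window_minutes = attr(mean_counts_per_min, "window_minutes")),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum> %d classes, total %.4g kg/m3 (%.4g mg/m3)\n",
              length(x$m_kg_m3), sum(x$m_kg_m3), sum(x$m_kg_m3) * 1e6))
  invisible(x)
}

#' Measurement-to-mass-spectrum convenience wrapper
#'
#' Applies [select_equilibrium_window()] then [class_mass()] using the
#' measurement's own flow and dilution metadata.
#'
#' @inheritParams select_equilibrium_window
#' @param density_kg_m3 particle density.
#' @return A `mass_spectrum`.
#' @export
measurement_mass <- function(m, n_discard = 2, density_kg_m3 = 2165) {
  class_mass(select_equilibrium_window(m, n_discard), m$grid, density_kg_m3,
             m$sample_flow_lpm, m$dilution_factor)
}

#' Per-class particle passage
#'
#' The passage in class i is the ratio of detected mass behind the mask to
#' detected mass in the reference run, `P_i = m_filter,i / m_reference,i`.
#' The particle density cancels in this ratio. Classes where the reference
#' detected no mass (the sparse upper end of the grid) are flagged undefined
#' (`NA`) rather than forced to 0 or 1.
#'
#' @param filter `mass_spectrum` of the mask run.
#' @param reference `mass_spectrum` of the reference run.
#' @return An object of class `passage_result` with `p_class` (per-class
#'   fractions, `NA` where undefined), `defined` (logical mask), `p_total`
#'   (mass-weighted total, see [total_passage()]), and the grid.
#' @export
class_passage <- function(filter, reference) {
  stopifnot(inherits(filter, "mass_spectrum"), inherits(reference, "mass_spectrum"))
  if (!same_grid(filter$grid, reference$grid))
    stop("filter and reference spectra use different size grids", call. = FALSE)
  if (!is.null(filter$window_minutes) && !is.null(reference$window_minutes) &&
      length(filter$window_minutes) != length(reference$window_minutes))
    stop("filter and reference were averaged over windows of different length",
         call. = FALSE)
  defined <- reference$m_kg_m3 > 0
  p <- rep(NA_real_, length(defined))
  p[defined] <- filter$m_kg_m3[defined] / reference$m_kg_m3[defined]
  p_tot <- if (sum(reference$m_kg_m3) > 0)
    sum(filter$m_kg_m3) / sum(reference$m_kg_m3) else NA_real_
  structure(list(p_class = p, defined = defined, p_total = p_tot,
                 grid = filter$grid),
            class = "passage_result")
}

#' Mass-weighted total passage
#'
#' `P_total = sum(m_filter,i) / sum(m_reference,i)`: the fraction of total
#' detected aerosol mass that passed the mask. Algebraically this equals the
#' reference-mass-weighted mean of the per-class passages, so it is the
#' quantity a size-blind mass detector (flame photometer) reports. Values
#' slightly above 1 can occur through counting noise on a transparent mask; a
#' warning is raised above 1.05.
#'
#' @inheritParams class_passage
#' @return The total passage as a single fraction.
#' @export
total_passage <- function(filter, reference) {
  stopifnot(inherits(filter, "mass_spectrum"), inherits(reference, "mass_spectrum"))
  if (!same_grid(filter$grid, reference$grid))
    stop("filter and reference spectra use different size grids", call. = FALSE)
  tot_ref <- sum(reference$m_kg_m3)
  if (tot_ref <= 0)
    stop("reference spectrum has zero total mass", call. = FALSE)
  p <- sum(filter$m_kg_m3) / tot_ref
  if (p > 1.05)
    warning(sprintf("total passage %.3f exceeds 1.05; check pairing or counts", p),
            call. = FALSE)
  p
}

#' @export
print.passage_result <- function(x, ...) {
  cat(sprintf("<passage_result> P_total = %.4g%% (%d of %d classes defined)\n",
              100 * x$p_total, sum(x$defined), length(x$defined)))
  invisible(x)
}

#' @export
plot.passage_result <- function(x, ..., log = "x") {
  d <- x$grid$d_mid_nm[x$defined]
  p <- 100 * x$p_class[x$defined]
  graphics::plot(d, p, log = log, type = "b", pch = 16, cex = 0.6,
                 xlab = "particle diameter [nm]", ylab = "passage [%]", ...)
  graphics::abline(h = 100 * x$p_total, lty = 2)
  invisible(x)
}

#' Evaluate every mask run of a campaign against its reference
#'
#' Pairs each sample measurement with the nearest preceding reference run in
#' list order (ties broken by file order), converts both to mass spectra over
#' the equilibrium window and computes per-class and total passage. Quality
#' control flags are attached per measurement.
#'
#' @param measurements list of [measurement()] objects in file order (e.g.
#'   from [read_measurements()]) or a `campaign`.
#' @param n_discard initial minutes to exclude (default 2).
#' @param density_kg_m3 particle density (cancels in all passages).
#' @param policy QC thresholds, see [qc_policy()].
#' @return An object of class `passage_set`: a list with `results` (one
#'   `passage_result` per sample measurement, named), `table` (data frame
#'   with `measurement_id`, `batch_id`, `mask_id`, `declared_standard`,
#'   `production_date`, `p_total_pct`, `p_unweighted_pct`, `qc_pass`,
#'   `reference_id`), `qc` (per-measurement [qc_measurement()] reports) and
#'   the `grid`.
#' @export
evaluate_passage <- function(measurements, n_discard = 2, density_kg_m3 = 2165,
                             policy = qc_policy()) {
  if (inherits(measurements, "campaign")) measurements <- measurements$measurements
  stopifnot(length(measurements) >= 2L)
  roles <- vapply(measurements, `[[`, "", "role")
  if (!any(roles == "reference"))
    stop("campaign contains no reference measurement", call. = FALSE)

  ref_spectrum <- NULL
  ref_id <- NA_character_
  ref_summary <- NULL
  results <- list()
  qc_reports <- list()
  rows <- list()
  grid <- measurements[[1L]]$grid

  for (m in measurements) {
    if (m$role == "reference") {
      ref_spectrum <- measurement_mass(m, n_discard, density_kg_m3)
      ref_id <- m$measurement_id
      ref_summary <- aerosol_summary(m, n_discard)
      qc_reports[[m$measurement_id]] <- qc_measurement(m, ref_summary, policy)
      next
    }
    if (is.null(ref_spectrum))
      stop("sample measurement ", m$measurement_id,
           " appears before any reference run", call. = FALSE)
    fil <- measurement_mass(m, n_discard, density_kg_m3)
    res <- class_passage(fil, ref_spectrum)
    qc <- qc_measurement(m, ref_summary, policy)
    results[[m$measurement_id]] <- res
    qc_reports[[m$measurement_id]] <- qc
    rows[[length(rows) + 1L]] <- data.frame(
      measurement_id = m$measurement_id, batch_id = m$batch_id,
      mask_id = m$mask_id, declared_standard = m$declared_standard,
      production_date = as.character(m$production_date),
      p_total_pct = 100 * res$p_total,
      p_unweighted_pct = 100 * mean(res$p_class[res$defined]),
      qc_pass = qc$pass, reference_id = ref_id,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows))
    stop("campaign contains no sample measurements", call. = FALSE)
  structure(list(results = results, table = do.call(rbind, rows),
                 qc = qc_reports, grid = grid),
            class = "passage_set")
}

#' @export
print.passage_set <- function(x, ...) {
  cat(sprintf("<passage_set> %d mask measurements, %d QC-clean\n",
              nrow(x$table), sum(x$table$qc_pass)))
  print(utils::head(x$table[, c("measurement_id", "batch_id", "p_total_pct", "qc_pass")], 10))
  if (nrow(x$table) > 10) cat("...\n")
  invisible(x)
}

#' @export
summary.passage_set <- function(object, ...) {
  t <- object$table
  cat(sprintf("Mask passage over %d measurements in %d batch(es):\n",
              nrow(t), length(unique(t$batch_id))))
  print(summary(t$p_total_pct))
  invisible(object)
}
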