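#' Quality-control thresholds for the test rig
#'
#' The evaluation protocol is only valid inside narrow operating bands:
#' the chamber must run at -3 to -7 mbar below ambient, a mask must show a
#' clear pressure drop (a near-zero drop means it is leaking past the
#' mount), the challenge aerosol must have a count median diameter between
#' 60 and 100 nm at a chamber mass concentration of 4-12 mg/m3, and the
#' relative humidity must stay at or below 40%.
#'
#' @param chamber_dp_range_mbar allowed chamber pressure band, mbar.
#' @param leak_threshold_mbar minimum |pressure drop| across a mounted mask.
#' @param cmd_range_nm allowed aerosol count-median-diameter band, nm.
#' @param mass_range_mg_m3 allowed chamber mass-concentration band, mg/m3.
#' @param rh_max_pct maximum relative humidity, %.
#' @return A list of class `qc_policy`.
#' @export
qc_policy <- function(chamber_dp_range_mbar = c(-7, -3),
                      leak_threshold_mbar = 0.1,
                      cmd_range_nm = c(60, 100),
                      mass_range_mg_m3 = c(4, 12),
                      rh_max_pct = 40) {
  structure(list(chamber_dp_range_mbar = chamber_dp_range_mbar,
                 leak_threshold_mbar = leak_threshold_mbar,
                 cmd_range_nm = cmd_range_nm,
                 mass_range_mg_m3 = mass_range_mg_m3,
                 rh_max_pct = rh_max_pct),
            class = "qc_policy")
}

#' Summarise the challenge aerosol from a reference run
#'
#' Computes the count median diameter (count-weighted median over the grid's
#' geometric class midpoints, linearly interpolated within the median class)
#' and the detected chamber mass concentration over the equilibrium window.
#' Both refer to the instrument's size range: particles below the smallest
#' class are invisible to the counter, so for a distribution with substantial
#' mass below the grid the detected CMD overestimates the generator's CMD.
#'
#' @param m a reference [measurement()].
#' @param n_discard initial minutes to exclude.
#' @param density_kg_m3 particle density.
#' @return A list with `cmd_nm`, `mass_conc_mg_m3`, and `total_counts_per_min`.
#' @export
aerosol_summary <- function(m, n_discard = 2, density_kg_m3 = 2165) {
  stopifnot(inherits(m, "measurement"))
  w <- select_equilibrium_window(m, n_discard)
  spec <- class_mass(w, m$grid, density_kg_m3, m$sample_flow_lpm, m$dilution_factor)
  list(cmd_nm = count_median_diameter(as.numeric(w), m$grid),
       mass_conc_mg_m3 = sum(spec$m_kg_m3) * 1e6,
       total_counts_per_min = sum(w))
}

# Count-weighted median diameter over geometric class midpoints, with linear
# interpolation between the midpoints bracketing the half-count point.
count_median_diameter <- function(w, grid) {
  tot <- sum(w)
  if (tot <= 0) return(NA_real_)
  mids <- grid$d_mid_nm
  # cumulative count fraction attributed to each midpoint (half its own class)
  cf <- (cumsum(w) - w / 2) / tot
  if (cf[1L] >= 0.5) return(mids[1L])
  n <- length(mids)
  if (cf[n] <= 0.5) return(mids[n])
  k <- max(which(cf < 0.5))
  mids[k] + (0.5 - cf[k]) / (cf[k + 1L] - cf[k]) * (mids[k + 1L] - mids[k])
}

#' Quality-control check of one measurement
#'
#' Emits error flags for: chamber pressure outside the protocol band; a
#' mounted mask whose pressure drop is close to zero (leak past the mount);
#' reference aerosol CMD outside the validity band; reference chamber mass
#' concentration outside the validity band; relative humidity above the
#' limit. All findings are flags, never exceptions; `pass` is `TRUE` iff no
#' error-severity flag was raised.
#'
#' @param m a [measurement()].
#' @param reference_summary the paired reference's [aerosol_summary()]
#'   (`NULL` skips the aerosol checks).
#' @param policy a [qc_policy()].
#' @return An object of class `qc_report` with `flags` (data frame: `code`,
#'   `severity`, `message`) and `pass`.
#' @export
qc_measurement <- function(m, reference_summary = NULL, policy = qc_policy()) {
  stopifnot(inherits(m, "measurement"), inherits(policy, "qc_policy"))
  flags <- list()
  add <- function(code, severity, message)
    flags[[length(flags) + 1L]] <<- data.frame(code = code, severity = severity,
                                               message = message,
                                               stringsAsFactors = FALSE)

  dp <- m$chamber_dp_mbar
  rng <- policy$chamber_dp_range_mbar
  if (!is.na(dp) && (dp < min(rng) || dp > max(rng)))
    add("chamber_pressure", "error",
        sprintf("chamber pressure %.2f mbar outside [%g, %g]", dp, min(rng), max(rng)))

  if (m$role == "sample" && !is.na(m$mask_dp_mbar) &&
      abs(m$mask_dp_mbar) < policy$leak_threshold_mbar)
    add("mask_leak", "error",
        sprintf("mask pressure drop %.3f mbar is close to zero: check mount seal",
                m$mask_dp_mbar))

  if (!is.null(reference_summary)) {
    cmd <- reference_summary$cmd_nm
    if (!is.na(cmd) && (cmd < policy$cmd_range_nm[1L] || cmd > policy$cmd_range_nm[2L]))
      add("aerosol_cmd", "error",
          sprintf("aerosol count median diameter %.1f nm outside [%g, %g] nm",
                  cmd, policy$cmd_range_nm[1L], policy$cmd_range_nm[2L]))
    mc <- reference_summary$mass_conc_mg_m3
    if (!is.na(mc) && (mc < policy$mass_range_mg_m3[1L] || mc > policy$mass_range_mg_m3[2L]))
      add("aerosol_mass", "error",
          sprintf("chamber mass concentration %.2f mg/m3 outside [%g, %g]",
                  mc, policy$mass_range_mg_m3[1L], policy$mass_range_mg_m3[2L]))
  }

  if (!is.na(m$rh_pct) && m$rh_pct > policy$rh_max_pct)
    add("humidity", "error",
        sprintf("relative humidity %.1f%% exceeds %g%%", m$rh_pct, policy$rh_max_pct))

  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(code = character(), severity = character(), message = character(),
               stringsAsFactors = FALSE)
  structure(list(measurement_id = m$measurement_id, flags = flags,
                 pass = !any(flags$severity == "error")),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report %s> %s\n", x$measurement_id,
              if (x$pass) "PASS" else "FAIL"))
  if (nrow(x$flags))
    cat(paste0("  [", x$flags$severity, "] ", x$flags$code, ": ",
               x$flags$message, collapse = "\n"), "\n")
  invisible(x)
}
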