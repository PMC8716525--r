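config_defaults <- function() {
  list(
    grid = list(d_lower_nm = 90, d_upper_nm = 7500, n_classes = 99),
    protocol = list(n_minutes = 5, n_discard = 2),
    qc = list(chamber_dp_range_mbar = c(-7, -3), leak_threshold_mbar = 0.1,
              cmd_range_nm = c(60, 100), mass_range_mg_m3 = c(4, 12),
              rh_max_pct = 40),
    standards = list(),            # named overrides, e.g. FFP2: 5.5
    simulate = NULL,               # optional block: n_masks, batches, aerosol, mask, flame
    weighting = "mass_weighted",
    class_range_nm = c(90, 500),
    seed = 1,
    output_dir = "maskpassage_out"
  )
}

#' Build a run configuration
#'
#' Merges user settings over the documented defaults. Settings can come from
#' a YAML file (`path`) and/or a named list (`overrides`, applied last).
#' Unknown keys at any level are rejected so typos fail loudly.
#'
#' Blocks and defaults: `grid` (d_lower_nm 90, d_upper_nm 7500, n_classes
#' 99), `protocol` (n_minutes 5, n_discard 2), `qc` (the [qc_policy()]
#' thresholds), `standards` (named limit overrides), `simulate` (optional
#' simulator block with `n_masks`, `batches`, and `aerosol` / `mask` /
#' `flame` parameter sub-blocks), `weighting` ("mass_weighted" or
#' "unweighted"), `class_range_nm` (90-500), `seed` (1), `output_dir`.
#'
#' @param path optional YAML file.
#' @param overrides optional named list of settings.
#' @return A list of class `run_config`.
#' @export
run_config <- function(path = NULL, overrides = NULL) {
  cfg <- config_defaults()
  apply_over <- function(base, new, where) {
    for (k in names(new)) {
      if (!k %in% names(base))
        stop("unknown configuration key '", k, "' in ", where, call. = FALSE)
      if (is.list(base[[k]]) && is.list(new[[k]]) && !is.null(names(base[[k]])) &&
          length(base[[k]]))
        base[[k]] <- apply_over(base[[k]], new[[k]], paste0(where, "$", k))
      else base[[k]] <- new[[k]]
    }
    base
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    cfg <- apply_over(cfg, yaml::read_yaml(path), "config file")
  }
  if (!is.null(overrides)) cfg <- apply_over(cfg, overrides, "overrides")
  structure(cfg, class = "run_config")
}

config_grid <- function(cfg)
  size_grid(cfg$grid$d_lower_nm, cfg$grid$d_upper_nm, cfg$grid$n_classes)

config_qc_policy <- function(cfg) do.call(qc_policy, cfg$qc)

simulate_from_config <- function(cfg, grid) {
  sim <- cfg$simulate
  if (is.null(sim)) stop("config has no `simulate` block", call. = FALSE)
  aer <- do.call(aerosol_params, if (is.null(sim$aerosol)) list() else sim$aerosol)
  flm <- do.call(flame_model, if (is.null(sim$flame)) list() else sim$flame)
  batches <- sim$batches
  if (is.null(batches))
    batches <- list(list(batch_id = "batch1", n_masks = sim$n_masks %||% 10,
                         mask = sim$mask, standard = sim$standard %||% "FFP2"))
  set.seed(cfg$seed)
  camps <- lapply(batches, function(b) {
    mm <- do.call(mask_model, if (is.null(b$mask)) list() else b$mask)
    simulate_batch(b$n_masks %||% 10, aer, mm, grid, seed = NULL, flame = flm,
                   batch_id = b$batch_id %||% "batch1",
                   declared_standard = b$standard %||% "FFP2",
                   n_minutes = cfg$protocol$n_minutes)
  })
  merge_campaigns(camps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge several single-batch campaigns into one
#'
#' @param campaigns list of `campaign` objects on the same grid.
#' @return A single `campaign` whose measurement list keeps each batch's
#'   reference immediately before its masks (preserving reference pairing).
#' @export
merge_campaigns <- function(campaigns) {
  stopifnot(length(campaigns) >= 1L)
  if (length(campaigns) == 1L) return(campaigns[[1L]])
  meas <- do.call(c, lapply(campaigns, `[[`, "measurements"))
  structure(list(
    measurements = meas,
    flame = do.call(rbind, lapply(campaigns, `[[`, "flame")),
    truth = do.call(rbind, lapply(campaigns, function(x) {
      tr <- x$truth; tr$batch_id <- x$batch_id; tr
    })),
    grid = campaigns[[1L]]$grid,
    batch_id = paste(vapply(campaigns, `[[`, "", "batch_id"), collapse = "+"),
    declared_standard = campaigns[[1L]]$declared_standard
  ), class = "campaign")
}

#' Run the full evaluation pipeline end to end
#'
#' Executes QC, passage evaluation, the batch report and (when flame
#' readings are available) the detector-equivalence analysis, and writes all
#' artifacts plus a manifest with MD5 checksums into the configured output
#' directory. Inputs are either CSV paths or, when `counts_path` is `NULL`
#' and the config has a `simulate` block, a freshly simulated campaign
#' (deterministic for a given config seed).
#'
#' @param config a [run_config()].
#' @param counts_path,metadata_path,flame_path optional input CSVs.
#' @return Invisibly, a list with `report` (the [campaign_report()]),
#'   `passage` (the [evaluate_passage()] result), `equivalence` (or `NULL`),
#'   and `manifest` (named file paths).
#' @export
run_campaign <- function(config = run_config(), counts_path = NULL,
                         metadata_path = NULL, flame_path = NULL) {
  stopifnot(inherits(config, "run_config"))
  grid <- config_grid(config)
  flame <- NULL

  if (is.null(counts_path)) {
    message("stage simulate: generating campaign (seed ", config$seed, ")")
    camp <- simulate_from_config(config, grid)
    measurements <- camp$measurements
    flame <- camp$flame
  } else {
    message("stage read: ", counts_path)
    if (is.null(metadata_path))
      stop("stage read: metadata_path is required with counts_path", call. = FALSE)
    measurements <- read_measurements(counts_path, metadata_path, grid)
    if (!is.null(flame_path)) {
      if (!file.exists(flame_path))
        stop("stage read: flame file not found: ", flame_path, call. = FALSE)
      flame <- utils::read.csv(flame_path, stringsAsFactors = FALSE)
    }
  }

  message("stage passage: evaluating ", length(measurements), " measurements")
  ps <- evaluate_passage(measurements, n_discard = config$protocol$n_discard,
                         policy = config_qc_policy(config))

  message("stage batch-report")
  registry <- standards_registry(if (length(config$standards)) config$standards)
  rep <- campaign_report(ps, registry, weighting = config$weighting,
                         class_range_nm = config$class_range_nm, qc_only = FALSE)

  eq <- NULL
  if (!is.null(flame)) {
    message("stage concordance")
    tab <- flame_passage(flame, ps$table)
    ok <- is.finite(tab$p_flame_pct)
    if (sum(ok) >= 2L)
      eq <- detector_equivalence(tab$p_total_pct[ok], tab$p_flame_pct[ok])
  }

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  utils::write.csv(ps$table, out("passage_results.csv"), row.names = FALSE)
  qc_json <- lapply(ps$qc, function(q)
    list(measurement_id = q$measurement_id, pass = q$pass, flags = q$flags))
  jsonlite::write_json(qc_json, out("qc_report.json"), auto_unbox = TRUE,
                       dataframe = "rows", pretty = TRUE)
  utils::write.csv(as.data.frame(rep), out("batch_report.csv"), row.names = FALSE)
  if (!is.null(eq)) {
    jsonlite::write_json(
      lapply(eq$results, function(r)
        list(range = r$range_label, n = r$n, rho_c = r$rho_c)),
      out("concordance.json"), auto_unbox = TRUE, pretty = TRUE)
    utils::write.csv(eq$pairs, out("concordance_pairs.csv"), row.names = FALSE)
  }
  files <- list.files(config$output_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, out("manifest.json"), dataframe = "rows",
                       pretty = TRUE)
  invisible(list(report = rep, passage = ps, equivalence = eq,
                 manifest = stats::setNames(files, basename(files))))
}
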