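#' A single spectrometer run (reference or mask sample)
#'
#' One measurement is a short run of the test rig recorded by the laser
#' aerosol spectrometer: an integer matrix of particle counts (one row per
#' one-minute interval, one column per size class) plus the rig metadata
#' needed for evaluation and quality control. A `role = "reference"` run is
#' taken with the empty mask mount and quantifies the unfiltered challenge
#' aerosol; a `role = "sample"` run has a mask installed.
#'
#' @param measurement_id unique identifier.
#' @param role `"reference"` or `"sample"`.
#' @param counts integer matrix, minutes x size classes, nonnegative.
#' @param grid the [size_grid()] the counts refer to.
#' @param batch_id,mask_id batch and mask identifiers (`mask_id` must be
#'   empty for a reference run).
#' @param declared_standard protection class the batch is certified to
#'   (`"FFP2"`, `"FFP3"`, `"KN95"`, `"N95"`).
#' @param production_date optional `"YYYY-MM"` string.
#' @param flow_lpm chamber feed flow in L/min (protocol: 95).
#' @param sample_flow_lpm spectrometer sample flow in L/min (default 0.1).
#' @param dilution_factor dilution applied upstream of the counter (>= 1);
#'   detected mass is multiplied back by this factor.
#' @param chamber_dp_mbar chamber pressure relative to ambient, mbar
#'   (protocol band: -7 to -3).
#' @param mask_dp_mbar pressure drop across the mask, mbar (`NA` for a
#'   reference run; values near zero indicate a leaking mount).
#' @param temp_c,rh_pct chamber temperature (deg C) and relative humidity (%).
#'
#' @return An object of class `measurement`.
#' @export
measurement <- function(measurement_id, role, counts, grid,
                        batch_id = "", mask_id = "",
                        declared_standard = "FFP2", production_date = NA_character_,
                        flow_lpm = 95, sample_flow_lpm = 0.1, dilution_factor = 1,
                        chamber_dp_mbar = -5, mask_dp_mbar = NA_real_,
                        temp_c = 22, rh_pct = 30) {
  stopifnot(inherits(grid, "size_grid"))
  role <- match.arg(role, c("reference", "sample"))
  counts <- as.matrix(counts)
  if (ncol(counts) != grid$n_classes)
    stop("counts must have one column per size class (", grid$n_classes,
         "), got ", ncol(counts), call. = FALSE)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  storage.mode(counts) <- "double"  # large Poisson counts overflow 32-bit ints
  if (!is.numeric(sample_flow_lpm) || sample_flow_lpm <= 0)
    stop("sample_flow_lpm must be positive", call. = FALSE)
  if (!is.numeric(dilution_factor) || dilution_factor < 1)
    stop("dilution_factor must be >= 1", call. = FALSE)
  if (role == "reference") {
    if (nzchar(mask_id))
      stop("a reference measurement must not carry a mask_id", call. = FALSE)
    mask_dp_mbar <- NA_real_
  }

  structure(
    list(
      measurement_id = as.character(measurement_id),
      role = role,
      batch_id = as.character(batch_id),
      mask_id = as.character(mask_id),
      counts = counts,
      n_minutes = nrow(counts),
      grid = grid,
      declared_standard = declared_standard,
      production_date = production_date,
      flow_lpm = flow_lpm,
      sample_flow_lpm = sample_flow_lpm,
      dilution_factor = dilution_factor,
      chamber_dp_mbar = chamber_dp_mbar,
      mask_dp_mbar = mask_dp_mbar,
      temp_c = temp_c,
      rh_pct = rh_pct
    ),
    class = "measurement"
  )
}

#' @export
print.measurement <- function(x, ...) {
  cat(sprintf(
    "<measurement %s> %s%s, %d min x %d classes, %.3g counts total\n",
    x$measurement_id, x$role,
    if (x$role == "sample") sprintf(" (batch %s, mask %s)", x$batch_id, x$mask_id) else "",
    x$n_minutes, ncol(x$counts), sum(x$counts)
  ))
  invisible(x)
}

meta_columns <- c(
  "measurement_id", "role", "batch_id", "mask_id", "declared_standard",
  "production_date", "flow_lpm", "sample_flow_lpm", "dilution_factor",
  "chamber_dp_mbar", "mask_dp_mbar", "temp_c", "rh_pct"
)

#' Write a set of measurements to the two-file CSV interchange format
#'
#' The on-disk format is a long-format counts table (`measurement_id`,
#' `minute_index`, `class_index`, `count`; both indices 1-based) plus a
#' one-row-per-measurement metadata table. Writing then reading back
#' reproduces the counts matrices exactly.
#'
#' @param measurements list of [measurement()] objects.
#' @param counts_path,metadata_path output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_measurements <- function(measurements, counts_path, metadata_path) {
  stopifnot(length(measurements) >= 1L)
  cnt <- do.call(rbind, lapply(measurements, function(m) {
    data.frame(
      measurement_id = m$measurement_id,
      minute_index   = rep(seq_len(m$n_minutes), times = ncol(m$counts)),
      class_index    = rep(seq_len(ncol(m$counts)), each = m$n_minutes),
      count          = as.vector(m$counts),
      stringsAsFactors = FALSE
    )
  }))
  meta <- do.call(rbind, lapply(measurements, function(m) {
    as.data.frame(m[meta_columns], stringsAsFactors = FALSE)
  }))
  utils::write.csv(cnt, counts_path, row.names = FALSE)
  utils::write.csv(meta, metadata_path, row.names = FALSE)
  invisible(c(counts = counts_path, metadata = metadata_path))
}

#' Read measurements from the CSV interchange format
#'
#' @param counts_path long-format counts CSV (see [write_measurements()]).
#' @param metadata_path per-measurement metadata CSV.
#' @param grid the [size_grid()] to validate class indices against.
#' @return A named list of [measurement()] objects, in metadata-file order
#'   (file order defines reference pairing downstream).
#' @export
read_measurements <- function(counts_path, metadata_path, grid = size_grid()) {
  stopifnot(inherits(grid, "size_grid"))
  if (!file.exists(counts_path)) stop("counts file not found: ", counts_path, call. = FALSE)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path, call. = FALSE)
  cnt <- utils::read.csv(counts_path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)

  need <- c("measurement_id", "minute_index", "class_index", "count")
  miss <- setdiff(need, names(cnt))
  if (length(miss))
    stop("counts file is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(meta_columns, names(meta))
  if (length(miss))
    stop("metadata file is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)

  bad <- which(cnt$class_index < 1 | cnt$class_index > grid$n_classes)
  if (length(bad))
    stop("class_index out of 1..", grid$n_classes, " at counts row ", bad[1L],
         " (measurement ", cnt$measurement_id[bad[1L]], ")", call. = FALSE)
  bad <- which(cnt$count < 0 | cnt$count != round(cnt$count))
  if (length(bad))
    stop("negative or non-integer count at counts row ", bad[1L], call. = FALSE)
  key <- paste(cnt$measurement_id, cnt$minute_index, cnt$class_index)
  if (anyDuplicated(key))
    stop("duplicate (measurement_id, minute_index, class_index) at counts row ",
         which(duplicated(key))[1L], call. = FALSE)
  if (anyDuplicated(meta$measurement_id))
    stop("duplicate measurement_id in metadata: ",
         meta$measurement_id[which(duplicated(meta$measurement_id))[1L]], call. = FALSE)

  out <- lapply(seq_len(nrow(meta)), function(i) {
    md <- meta[i, ]
    rows <- cnt[cnt$measurement_id == md$measurement_id, ]
    if (nrow(rows) == 0L)
      stop("no counts found for measurement ", md$measurement_id, call. = FALSE)
    n_min <- max(rows$minute_index)
    if (nrow(rows) != n_min * grid$n_classes)
      stop("incomplete counts grid for measurement ", md$measurement_id,
           ": expected ", n_min * grid$n_classes, " rows, got ", nrow(rows), call. = FALSE)
    m <- matrix(0, n_min, grid$n_classes)
    m[cbind(rows$minute_index, rows$class_index)] <- rows$count
    measurement(
      measurement_id = md$measurement_id, role = md$role, counts = m, grid = grid,
      batch_id = as.character(md$batch_id), mask_id = na_to_empty(md$mask_id),
      declared_standard = md$declared_standard,
      production_date = as.character(md$production_date),
      flow_lpm = md$flow_lpm, sample_flow_lpm = md$sample_flow_lpm,
      dilution_factor = md$dilution_factor, chamber_dp_mbar = md$chamber_dp_mbar,
      mask_dp_mbar = md$mask_dp_mbar, temp_c = md$temp_c, rh_pct = md$rh_pct
    )
  })
  stats::setNames(out, meta$measurement_id)
}

na_to_empty <- function(x) {
  x <- as.character(x)
  if (length(x) != 1L || is.na(x)) "" else x
}
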