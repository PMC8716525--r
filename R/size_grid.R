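#' Geometric particle-size grid of an optical aerosol spectrometer
#'
#' Constructs the discrete size-class grid used throughout the package: a
#' geometric progression of `n_classes` classes between a lower and an upper
#' diameter. Optical particle counters report counts per such class; the
#' canonical instrument grid spans 99 classes from 90 nm to 7.5 um, giving a
#' per-class width of about 4.6%.
#'
#' The lower edge of each class is the diameter used when a counted particle
#' is converted to a mass ("minimum-volume" convention): a particle sorted
#' into class i is at least as large as the class's lower edge, so the
#' conversion is a conservative lower bound on the detected mass.
#'
#' @param d_lower_nm lower bound of the smallest class, in nm.
#' @param d_upper_nm upper bound of the largest class, in nm.
#' @param n_classes number of size classes (>= 1).
#'
#' @return An object of class `size_grid` with fields `n_classes`,
#'   `d_lower_nm`, `d_upper_nm`, `class_edges_nm` (length `n_classes + 1`),
#'   `ratio` (constant edge-to-edge geometric factor), and the derived
#'   per-class vectors `d_min_nm` (lower edges) and `d_mid_nm` (geometric
#'   midpoints).
#'
#' @examples
#' g <- size_grid()                  # canonical 99-class instrument grid
#' g$ratio                           # ~1.0457, i.e. ~4.6% class width
#' range(g$class_edges_nm)           # 90 7500
#' @export
size_grid <- function(d_lower_nm = 90, d_upper_nm = 7500, n_classes = 99L) {
  if (!is.numeric(d_lower_nm) || length(d_lower_nm) != 1L || !is.finite(d_lower_nm) ||
      d_lower_nm <= 0)
    stop("`d_lower_nm` must be a single positive number", call. = FALSE)
  if (!is.numeric(d_upper_nm) || length(d_upper_nm) != 1L || !is.finite(d_upper_nm) ||
      d_upper_nm <= d_lower_nm)
    stop("`d_upper_nm` must be a single number greater than `d_lower_nm`", call. = FALSE)
  n_classes <- as.integer(n_classes)
  if (is.na(n_classes) || n_classes < 1L)
    stop("`n_classes` must be a positive integer", call. = FALSE)

  ratio <- (d_upper_nm / d_lower_nm)^(1 / n_classes)
  edges <- d_lower_nm * ratio^(0:n_classes)
  # endpoints must be exact, not merely close: they define the integration bounds
  edges[1L] <- d_lower_nm
  edges[n_classes + 1L] <- d_upper_nm

  structure(
    list(
      n_classes      = n_classes,
      d_lower_nm     = d_lower_nm,
      d_upper_nm     = d_upper_nm,
      class_edges_nm = edges,
      ratio          = ratio,
      d_min_nm       = edges[seq_len(n_classes)],
      d_mid_nm       = sqrt(edges[seq_len(n_classes)] * edges[-1L])
    ),
    class = "size_grid"
  )
}

#' @export
print.size_grid <- function(x, ...) {
  cat(sprintf(
    "Geometric size grid: %d classes, %.6g-%.6g nm (ratio %.6f, width %.2f%%)\n",
    x$n_classes, x$d_lower_nm, x$d_upper_nm, x$ratio, 100 * (x$ratio - 1)
  ))
  invisible(x)
}

#' @export
format.size_grid <- function(x, ...) {
  sprintf("size_grid(%g, %g, %d)", x$d_lower_nm, x$d_upper_nm, x$n_classes)
}

# Two grids are interchangeable if their edges agree to relative 1e-9.
same_grid <- function(a, b) {
  inherits(a, "size_grid") && inherits(b, "size_grid") &&
    a$n_classes == b$n_classes &&
    all(abs(a$class_edges_nm - b$class_edges_nm) <=
          1e-9 * pmax(a$class_edges_nm, b$class_edges_nm))
}
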