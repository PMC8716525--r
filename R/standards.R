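#' Filtering-facepiece protection standards
#'
#' The four protection classes handled by the evaluation pipeline, each with
#' the maximum total aerosol passage its certification standard allows:
#' FFP2 (6%, DIN EN 149), FFP3 (1%, DIN EN 149), N95 (5%, NIOSH-42CFR84) and
#' KN95 (5%, GB 2626-2006).
#'
#' @param overrides optional named list (or data frame with columns `name`,
#'   `max_passage_pct`) replacing or adding limits, e.g.
#'   `list(FFP2 = 5.5, P100 = 0.03)`.
#'
#' @return A data frame of class `standards_registry` with columns `name`
#'   and `max_passage_pct`.
#' @seealso [standard_spec()] for a single lookup.
#' @examples
#' standards_registry()
#' standard_spec("ffp3")$max_passage_pct   # 1; lookups are case-insensitive
#' @export
standards_registry <- function(overrides = NULL) {
  reg <- data.frame(
    name = c("FFP2", "FFP3", "KN95", "N95"),
    max_passage_pct = c(6, 1, 5, 5),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    if (is.data.frame(overrides)) {
      ov <- as.list(stats::setNames(overrides$max_passage_pct, overrides$name))
    } else if (is.list(overrides) && !is.null(names(overrides))) {
      ov <- overrides
    } else {
      stop("`overrides` must be a named list or a data frame with columns ",
           "`name` and `max_passage_pct`", call. = FALSE)
    }
    for (nm in names(ov)) {
      lim <- as.numeric(ov[[nm]])
      if (!is.finite(lim) || lim <= 0 || lim >= 100)
        stop("override for ", nm, ": max_passage_pct must lie in (0, 100)",
             call. = FALSE)
      hit <- toupper(reg$name) == toupper(nm)
      if (any(hit)) reg$max_passage_pct[hit] <- lim
      else reg <- rbind(reg, data.frame(name = nm, max_passage_pct = lim))
    }
  }
  class(reg) <- c("standards_registry", "data.frame")
  reg
}

#' Look up one protection standard
#'
#' @param name standard name (case-insensitive), e.g. `"FFP2"`.
#' @param registry a registry from [standards_registry()].
#' @return A list of class `standard_spec` with `name` and `max_passage_pct`.
#' @export
standard_spec <- function(name, registry = standards_registry()) {
  stopifnot(is.character(name), length(name) == 1L)
  hit <- which(toupper(registry$name) == toupper(name))
  if (length(hit) != 1L)
    stop("unknown standard '", name, "'; known: ",
         paste(registry$name, collapse = ", "), call. = FALSE)
  structure(
    list(name = registry$name[hit], max_passage_pct = registry$max_passage_pct[hit]),
    class = "standard_spec"
  )
}

#' @export
print.standard_spec <- function(x, ...) {
  cat(sprintf("%s: maximum total passage %g%%\n", x$name, x$max_passage_pct))
  invisible(x)
}
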