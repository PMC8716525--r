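#' Headline passage of one mask
#'
#' Reduces a per-class passage result to the single percentage used in batch
#' statistics. `"mass_weighted"` is the total mass passage (what a flame
#' photometer certifies against); `"unweighted"` averages the defined
#' per-class passages within `class_range_nm`, giving every detected size
#' class equal weight and hence more influence to small particles.
#'
#' @param r a `passage_result` from [class_passage()].
#' @param weighting `"mass_weighted"` (default) or `"unweighted"`.
#' @param class_range_nm diameter range (by class lower edge) entering the
#'   unweighted mean; default the full grid.
#' @return Passage in percent.
#' @export
mask_headline_passage <- function(r, weighting = c("mass_weighted", "unweighted"),
                                  class_range_nm = NULL) {
  stopifnot(inherits(r, "passage_result"))
  weighting <- match.arg(weighting)
  if (weighting == "mass_weighted") return(100 * r$p_total)
  keep <- r$defined
  if (!is.null(class_range_nm))
    keep <- keep & r$grid$d_min_nm >= class_range_nm[1L] &
      r$grid$d_min_nm <= class_range_nm[2L]
  if (!any(keep))
    stop("no defined size classes in the requested range", call. = FALSE)
  100 * mean(r$p_class[keep])
}

#' Distributional summary of per-mask passages in a batch
#'
#' The violin-plot statistics: median and quartiles (linear interpolation),
#' whiskers extending to the most extreme values within 1.5 IQR of the
#' quartiles, and a Gaussian kernel density (Scott's-rule bandwidth). The
#' batch is compliant when its mean passage does not exceed the standard's
#' limit; the fraction of individual masks over the limit is reported
#' alongside, since per-mask certification judges individuals.
#'
#' @param values_pct per-mask passage values, percent (>= 1 value).
#' @param standard a [standard_spec()].
#' @param kde_bw bandwidth: `"nrd"` (Scott's rule, default) or a number.
#' @param batch_id identifier carried into the result.
#' @return An object of class `batch_summary` with the fields `batch_id`,
#'   `n_masks`, `values_pct`, `mean_pct`, `median_pct`, `q1_pct`, `q3_pct`,
#'   `whisker_low_pct`, `whisker_high_pct`, `kde` (`x`, `y` or `NULL` when
#'   degenerate), `compliant`, `frac_over_limit`, `standard`.
#' @examples
#' s <- batch_summary(c(1, 2, 3, 4, 100), standard_spec("FFP2"))
#' s$whisker_high_pct   # 4: the 100 is an outlier beyond q3 + 1.5 IQR
#' @export
batch_summary <- function(values_pct, standard, kde_bw = "nrd",
                          batch_id = "") {
  stopifnot(inherits(standard, "standard_spec"))
  values_pct <- as.numeric(values_pct)
  if (!length(values_pct) || anyNA(values_pct))
    stop("values_pct must be non-empty and free of NA", call. = FALSE)
  q <- unname(stats::quantile(values_pct, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3L] - q[1L]
  inside <- values_pct[values_pct >= q[1L] - 1.5 * iqr &
                         values_pct <= q[3L] + 1.5 * iqr]
  kde <- NULL
  if (length(values_pct) >= 2L && stats::sd(values_pct) > 0) {
    bw <- if (identical(kde_bw, "nrd")) stats::bw.nrd(values_pct) else as.numeric(kde_bw)
    d <- stats::density(values_pct, bw = bw, kernel = "gaussian", n = 256)
    kde <- list(x = d$x, y = d$y, bw = bw)
  }
  mean_pct <- mean(values_pct)
  structure(list(
    batch_id = batch_id, n_masks = length(values_pct), values_pct = values_pct,
    mean_pct = mean_pct, median_pct = q[2L], q1_pct = q[1L], q3_pct = q[3L],
    whisker_low_pct = min(inside), whisker_high_pct = max(inside), kde = kde,
    compliant = mean_pct <= standard$max_passage_pct,
    frac_over_limit = mean(values_pct > standard$max_passage_pct),
    standard = standard
  ), class = "batch_summary")
}

#' @export
print.batch_summary <- function(x, ...) {
  cat(sprintf(
    "<batch_summary %s> n = %d, mean %.3g%%, median %.3g%% [q1 %.3g, q3 %.3g], %s vs %s (%g%%)\n",
    x$batch_id, x$n_masks, x$mean_pct, x$median_pct, x$q1_pct, x$q3_pct,
    if (x$compliant) "COMPLIANT" else "NOT compliant",
    x$standard$name, x$standard$max_passage_pct
  ))
  invisible(x)
}

#' @export
plot.batch_summary <- function(x, ...) {
  if (!is.null(x$kde)) {
    w <- x$kde$y / max(x$kde$y) * 0.4
    graphics::plot(NA, xlim = c(-0.5, 0.5), ylim = range(x$kde$x),
                   xlab = "", ylab = "passage [%]", xaxt = "n",
                   main = x$batch_id, ...)
    graphics::polygon(c(w, -rev(w)), c(x$kde$x, rev(x$kde$x)),
                      col = "grey85", border = "grey40")
  } else {
    graphics::plot(NA, xlim = c(-0.5, 0.5), ylim = range(x$values_pct) + c(-1, 1),
                   xlab = "", ylab = "passage [%]", xaxt = "n",
                   main = x$batch_id, ...)
  }
  graphics::segments(0, x$whisker_low_pct, 0, x$whisker_high_pct)
  graphics::rect(-0.06, x$q1_pct, 0.06, x$q3_pct, col = "black")
  graphics::points(0, x$median_pct, pch = 21, bg = "white", cex = 1.2)
  graphics::abline(h = x$standard$max_passage_pct, lty = 2)
  invisible(x)
}

#' Size-resolved passage profile of a batch
#'
#' Averages the per-class passage over all masks of a batch (defined classes
#' only) and summarises the profile across the size classes whose lower edge
#' lies in `class_range_nm`: the median passage, the relative spread
#' (population standard deviation / mean), and the maximum per-class
#' passage. The evaluation range defaults to 90-500 nm, the span in which
#' submicron counting statistics are reliable.
#'
#' @param results list of `passage_result` objects (the batch's masks).
#' @param grid a [size_grid()].
#' @param class_range_nm evaluated diameter range (class lower edges), nm.
#' @param batch_id identifier carried into the result.
#' @return An object of class `size_profile` with `p_class_mean` (full-grid
#'   per-class mean, `NA` where undefined for every mask),
#'   `median_over_classes_pct`, `rel_std_over_classes`,
#'   `max_class_passage_pct`, `mpps_nm` (diameter of the peak class within
#'   the range), `class_range_nm`, `n_classes_evaluated`.
#' @export
size_profile <- function(results, grid, class_range_nm = c(90, 500),
                         batch_id = "") {
  stopifnot(length(results) >= 1L, inherits(grid, "size_grid"))
  pmat <- do.call(rbind, lapply(results, function(r) {
    stopifnot(inherits(r, "passage_result"))
    r$p_class
  }))
  p_mean <- colMeans(pmat)                     # NA where any mask undefined
  p_mean_any <- apply(pmat, 2L, function(col) {
    if (all(is.na(col))) NA_real_ else mean(col, na.rm = TRUE)
  })
  in_range <- grid$d_min_nm >= class_range_nm[1L] & grid$d_min_nm <= class_range_nm[2L]
  vals <- p_mean_any[in_range]
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2L)
    stop("fewer than 2 defined size classes in the evaluated range", call. = FALSE)
  mu <- mean(vals)
  rel_std <- if (mu > 0) sqrt(mean((vals - mu)^2)) / mu else NA_real_
  idx_range <- which(in_range)[!is.na(p_mean_any[in_range])]
  mpps_nm <- grid$d_min_nm[idx_range[which.max(p_mean_any[idx_range])]]
  structure(list(
    batch_id = batch_id, p_class_mean = p_mean_any,
    median_over_classes_pct = 100 * stats::median(vals),
    rel_std_over_classes = rel_std,
    max_class_passage_pct = 100 * max(vals),
    mpps_nm = mpps_nm,
    class_range_nm = class_range_nm,
    n_classes_evaluated = length(vals),
    grid = grid
  ), class = "size_profile")
}

#' @export
print.size_profile <- function(x, ...) {
  cat(sprintf(
    "<size_profile %s> %d classes in %g-%g nm: median %.3g%%, max %.3g%% (at %d nm), rel. std %.3g\n",
    x$batch_id, x$n_classes_evaluated, x$class_range_nm[1L], x$class_range_nm[2L],
    x$median_over_classes_pct, x$max_class_passage_pct, round(x$mpps_nm),
    x$rel_std_over_classes
  ))
  invisible(x)
}

#' Size-dependent batch category (A/B/C)
#'
#' Classifies a batch's size-resolved behaviour against a standard's limit:
#' category A complies in every size class (median and maximum per-class
#' passage at or below the limit), category B complies overall but exceeds
#' the limit in some size classes (median <= limit < max; typically masks
#' that retain large particles while letting small ones through), category C
#' exceeds the limit overall (median > limit). Ties at the limit resolve
#' toward compliance.
#'
#' @param profile a [size_profile()].
#' @param standard a [standard_spec()].
#' @return `"A"`, `"B"`, or `"C"`.
#' @export
categorize <- function(profile, standard) {
  stopifnot(inherits(profile, "size_profile"), inherits(standard, "standard_spec"))
  lim <- standard$max_passage_pct
  if (profile$median_over_classes_pct > lim) return("C")
  if (profile$max_class_passage_pct > lim) return("B")
  "A"
}

#' Campaign-level batch report
#'
#' One row per batch: size, headline mean/median passage under the chosen
#' weighting, compliance verdict, size category, and production date; plus
#' campaign totals as attributes.
#'
#' @param passage_set an [evaluate_passage()] result covering one or more
#'   batches.
#' @param registry a [standards_registry()].
#' @param weighting headline weighting, see [mask_headline_passage()].
#' @param class_range_nm size-profile evaluation range.
#' @param qc_only if `TRUE` (default), only QC-clean measurements enter the
#'   statistics.
#' @return An object of class `campaign_report`: a data frame with one row
#'   per batch (`batch_id`, `declared_standard`, `production_date`,
#'   `n_masks`, `mean_pct`, `median_pct`, `compliant`, `frac_over_limit`,
#'   `category`, `max_class_passage_pct`, `rel_std_over_classes`), with
#'   attributes `n_batches`, `n_compliant`, `summaries` (per-batch
#'   [batch_summary()]) and `profiles` (per-batch [size_profile()]).
#' @export
campaign_report <- function(passage_set, registry = standards_registry(),
                            weighting = "mass_weighted",
                            class_range_nm = c(90, 500), qc_only = TRUE) {
  stopifnot(inherits(passage_set, "passage_set"))
  t <- passage_set$table
  if (qc_only) t <- t[t$qc_pass, , drop = FALSE]
  if (!nrow(t)) stop("no measurements left after QC filtering", call. = FALSE)
  batches <- unique(t$batch_id)
  summaries <- list(); profiles <- list(); rows <- list()
  for (b in batches) {
    tb <- t[t$batch_id == b, , drop = FALSE]
    std <- standard_spec(tb$declared_standard[1L], registry)
    res_b <- passage_set$results[tb$measurement_id]
    vals <- vapply(res_b, mask_headline_passage, numeric(1),
                   weighting = weighting, class_range_nm = class_range_nm)
    bs <- batch_summary(vals, std, batch_id = b)
    sp <- size_profile(res_b, passage_set$grid, class_range_nm, batch_id = b)
    summaries[[b]] <- bs; profiles[[b]] <- sp
    rows[[b]] <- data.frame(
      batch_id = b, declared_standard = std$name,
      production_date = tb$production_date[1L],
      n_masks = bs$n_masks, mean_pct = bs$mean_pct, median_pct = bs$median_pct,
      compliant = bs$compliant, frac_over_limit = bs$frac_over_limit,
      category = categorize(sp, std),
      max_class_passage_pct = sp$max_class_passage_pct,
      rel_std_over_classes = sp$rel_std_over_classes,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_batches") <- nrow(out)
  attr(out, "n_compliant") <- sum(out$compliant)
  attr(out, "summaries") <- summaries
  attr(out, "profiles") <- profiles
  class(out) <- c("campaign_report", "data.frame")
  out
}

#' @export
print.campaign_report <- function(x, ...) {
  cat(sprintf("Campaign report: %d batch(es), %d compliant\n",
              attr(x, "n_batches"), attr(x, "n_compliant")))
  print.data.frame(x[, c("batch_id", "declared_standard", "n_masks",
                         "mean_pct", "median_pct", "compliant", "category")],
                   digits = 4)
  invisible(x)
}
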