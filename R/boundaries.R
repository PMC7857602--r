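#' Detect an expression-domain boundary
#'
#' Walks from the high-expression end of the profile (the bin holding the
#' maximum) outward and returns the first angle at which expression falls
#' below `fraction` of the profile maximum, located by linear
#' interpolation between the bracketing bins.  Empty (`NA`) bins are
#' skipped.  By default the raw bin means are used: smoothing a sharp
#' domain edge displaces the crossing outward by a sizeable fraction of
#' the smoothing window, so the raw means give the less biased call.
#'
#' @param profile an `angular_profile` or data.frame with `angle_deg` and
#'   the value column.
#' @param fraction fraction of maximum defining the boundary (default
#'   0.10).
#' @param value_col column to threshold; `"mean_au"` by default, set to
#'   `"smoothed_au"` to call on the smoothed curve.
#' @param side walk direction from the maximum: `"right"` (toward larger
#'   angles, the usual DV case), `"left"`, or `"auto"` (the side with more
#'   room).
#' @param refine_sharp_edges when the crossing falls on an edge that drops
#'   from plateau to background within the two bracketing bins (an edge
#'   unresolved at bin scale), place the boundary so that the partial-bin
#'   intensities account for the covered fraction of each bin
#'   (mass-conserving edge localization).  Plain interpolation of such an
#'   edge is systematically displaced toward the off side by up to a bin
#'   width.  Graded profiles are unaffected.
#' @return list with `boundary_deg` (NA when the profile is flat or never
#'   exceeds its own cutoff), `flag` (`"ok"`, `"no_boundary"` or
#'   `"at_domain_edge"`) and `max_au`.
#' @export
detect_boundary <- function(profile, fraction = 0.10, value_col = "mean_au",
                            side = c("right", "left", "auto"),
                            refine_sharp_edges = TRUE) {
  side <- match.arg(side)
  stopifnot(fraction > 0, fraction < 1)
  ok <- !is.na(profile[[value_col]])
  x <- profile$angle_deg[ok]
  y <- profile[[value_col]][ok]
  if (length(y) == 0 || max(y) <= 0)
    return(list(boundary_deg = NA_real_, flag = "no_boundary",
                max_au = if (length(y)) max(y) else NA_real_))
  mx <- max(y)
  cutoff <- fraction * mx
  imax <- which.max(y)
  if (side == "auto") side <- if (imax <= length(y) / 2) "right" else "left"
  if (side == "left") {
    x <- rev(-x)
    y <- rev(y)
    imax <- length(y) - imax + 1L
  }
  below <- which(y < cutoff & seq_along(y) > imax)
  if (length(below) == 0) {
    bd <- x[length(x)]
    if (side == "left") bd <- -bd
    warning("expression never falls below ", signif(cutoff, 3),
            " A.U.; boundary reported at the domain edge")
    return(list(boundary_deg = bd, flag = "at_domain_edge", max_au = mx))
  }
  i <- below[1]
  bd <- x[i - 1] + (cutoff - y[i - 1]) * (x[i] - x[i - 1]) / (y[i] - y[i - 1])
  if (refine_sharp_edges && i - 2 >= imax && i + 1 <= length(y)) {
    v_on <- mean(y[max(imax, i - 4):(i - 2)])
    v_off <- mean(y[(i + 1):min(length(y), i + 3)])
    if (is.finite(v_on) && is.finite(v_off) &&
        v_on >= 0.5 * mx && v_off <= cutoff && v_on > v_off) {
      delta <- x[i] - x[i - 1]
      cov2 <- (pmin(pmax(y[i - 1], v_off), v_on) - v_off) +
        (pmin(pmax(y[i], v_off), v_on) - v_off)
      bd <- (x[i - 1] - delta / 2) + delta * cov2 / (v_on - v_off)
    }
  }
  if (side == "left") bd <- -bd
  list(boundary_deg = unname(bd), flag = "ok", max_au = mx)
}

#' Read out pSmad5 level and slope at a boundary
#'
#' Linearly interpolates the smoothed pSmad5 profile (and its slope
#' magnitude) at the boundary angle, and expresses the level as a percent
#' of the profile's own maximum smoothed value.
#'
#' @param psmad5_profile an `angular_profile` with `smoothed_au` and
#'   `slope_au_per_deg` (see [smooth_and_slope()]).
#' @param boundary_deg boundary angle; must lie inside the profile range.
#' @param slope_profile optional second profile from which to read the
#'   slope (e.g. a whole-cloud profile when the level comes from a band).
#' @return list with `level_au`, `level_pct_max`, `slope_au_per_deg`.
#' @export
readout_at_boundary <- function(psmad5_profile, boundary_deg,
                                slope_profile = psmad5_profile) {
  ok <- !is.na(psmad5_profile$smoothed_au)
  x <- psmad5_profile$angle_deg[ok]
  if (boundary_deg < min(x) || boundary_deg > max(x))
    stop("boundary angle ", boundary_deg, " outside profile range [",
         min(x), ", ", max(x), "]")
  s <- psmad5_profile$smoothed_au[ok]
  level <- stats::approx(x, s, xout = boundary_deg)$y
  ok2 <- !is.na(slope_profile$slope_au_per_deg)
  slope <- stats::approx(slope_profile$angle_deg[ok2],
                         slope_profile$slope_au_per_deg[ok2],
                         xout = boundary_deg)$y
  list(level_au = level, level_pct_max = 100 * level / max(s),
       slope_au_per_deg = slope)
}

#' Fraction of cells called expressing
#'
#' A cell expresses when its channel intensity is strictly greater than
#' `fraction` of the maximum signal intensity (default 10%).  The maximum
#' is taken over the supplied cells unless a `reference_max` is given
#' (e.g. the maximum over all conditions of an experiment).
#'
#' @param cells data.frame of cells.
#' @param channel intensity column.
#' @param fraction fraction of maximum (default 0.10).
#' @param reference_max optional externally determined maximum, A.U.
#' @return Proportion in \[0, 1\].
#' @export
expressing_fraction <- function(cells, channel, fraction = 0.10,
                                reference_max = NULL) {
  if (nrow(cells) == 0) stop("no cells supplied")
  if (!channel %in% names(cells)) stop("channel not found: ", channel)
  v <- cells[[channel]]
  mx <- if (is.null(reference_max)) max(v) else reference_max
  mean(v > fraction * mx)
}

#' Fraction of cells above a pSmad5 threshold
#'
#' @param cells data.frame with a `psmad5_au` column.
#' @param threshold_au threshold, A.U.
#' @return Proportion of cells with pSmad5 strictly above the threshold.
#' @export
above_threshold_fraction <- function(cells, threshold_au) {
  if (nrow(cells) == 0) stop("no cells supplied")
  mean(cells$psmad5_au > threshold_au)
}

#' Quantify one embryo: profiles and boundary calls
#'
#' Runs the measurement pipeline on a nuclei table: fit the sphere,
#' estimate the ventral pole from the pSmad5 gradient, assign angular
#' coordinates, extract the 40-um DV band profiles, call each gene's
#' expression boundary at `fraction` of maximum FISH intensity, and read
#' out the pSmad5 level (from the smoothed band profile) and gradient
#' slope (from the smoothed whole-cloud DV profile) at each boundary.
#'
#' @param nuclei one embryo's nuclei table.
#' @param genes character vector of gene names (default: all
#'   `fish_*_au` columns).
#' @param band_center,band_width_um,bin_width_deg band settings
#'   (see [band_profile()]).
#' @param fraction boundary fraction of maximum (default 0.10).
#' @param smoothing_fraction loess span (default 0.2).
#' @param animal_direction animal axis (default +z, the generator's
#'   convention).
#' @param use_truth use generator ground-truth angles instead of
#'   registration (default `FALSE`).
#' @return data.frame of boundary calls: one row per gene with
#'   `embryo_id`, `gene`, `axis`, `boundary_deg`, `level_au`,
#'   `level_pct_max`, `slope_au_per_deg`, `flag`.  Profiles are attached
#'   as the `"profiles"` attribute.
#' @export
quantify_embryo <- function(nuclei, genes = NULL, band_center = 90,
                            band_width_um = 40, bin_width_deg = 2,
                            fraction = 0.10, smoothing_fraction = 0.2,
                            animal_direction = c(0, 0, 1),
                            use_truth = FALSE) {
  if (is.null(genes))
    genes <- sub("^fish_(.*)_au$", "\\1",
                 grep("^fish_.*_au$", names(nuclei), value = TRUE))
  if (length(genes) == 0) stop("no FISH channels found")
  if (use_truth) {
    nuclei <- use_true_angles(nuclei)
  } else if (!all(c("dv_deg", "av_deg", "phi_deg") %in% names(nuclei))) {
    sph <- fit_sphere(nuclei)
    pole <- estimate_ventral_pole(nuclei, sph, animal_direction)
    if (!pole$orientable)
      stop("embryo is unorientable: no detectable pSmad5 gradient")
    nuclei <- assign_angles(nuclei, sph, pole$direction, animal_direction)
  }
  ps_band <- smooth_and_slope(
    band_profile(nuclei, "dv", band_center, band_width_um, bin_width_deg,
                 channel = "psmad5_au"),
    smoothing_fraction)
  ps_cloud <- smooth_and_slope(dv_profile(nuclei, "psmad5_au", bin_width_deg),
                               smoothing_fraction)
  calls <- lapply(genes, function(gn) {
    fp <- band_profile(nuclei, "dv", band_center, band_width_um,
                       bin_width_deg, channel = paste0("fish_", gn, "_au"))
    det <- detect_boundary(fp, fraction)
    if (is.na(det$boundary_deg)) {
      return(data.frame(embryo_id = nuclei$embryo_id[1], gene = gn,
                        axis = "DV", boundary_deg = NA_real_,
                        level_au = NA_real_, level_pct_max = NA_real_,
                        slope_au_per_deg = NA_real_, flag = det$flag,
                        stringsAsFactors = FALSE))
    }
    ro <- readout_at_boundary(ps_band, det$boundary_deg, ps_cloud)
    data.frame(embryo_id = nuclei$embryo_id[1], gene = gn, axis = "DV",
               boundary_deg = det$boundary_deg, level_au = ro$level_au,
               level_pct_max = ro$level_pct_max,
               slope_au_per_deg = ro$slope_au_per_deg, flag = det$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  attr(out, "profiles") <- list(psmad5_band = ps_band, psmad5_cloud = ps_cloud)
  out
}

#' Quantify a cohort of embryos
#'
#' @param embryos list of nuclei tables.
#' @param ... passed to [quantify_embryo()].
#' @return data.frame stacking all boundary calls.
#' @export
quantify_cohort <- function(embryos, ...) {
  do.call(rbind, lapply(embryos, quantify_embryo, ...))
}

#' Summarise boundary calls per gene
#'
#' @param calls boundary calls from [quantify_cohort()].
#' @return data.frame with per-gene means and standard deviations of the
#'   boundary angle, level and slope readouts.
#' @export
summarize_calls <- function(calls) {
  ok <- calls[!is.na(calls$boundary_deg), ]
  agg <- function(f) stats::aggregate(
    ok[c("boundary_deg", "level_au", "level_pct_max", "slope_au_per_deg")],
    by = list(gene = ok$gene), FUN = f)
  m <- agg(mean)
  s <- agg(stats::sd)
  names(s)[-1] <- paste0(names(s)[-1], "_sd")
  cbind(m, s[, -1, drop = FALSE], n = as.integer(table(ok$gene)[m$gene]))
}
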