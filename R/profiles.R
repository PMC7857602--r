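#' Calibration-bead normalization
#'
#' Rescales intensities so that imaging sessions with different detector
#' gains are comparable: every value is multiplied by
#' `reference_bead / observed_bead`.
#'
#' @param intensities numeric vector, A.U.
#' @param observed_bead bead intensity in this session (> 0).
#' @param reference_bead bead intensity of the reference session (> 0).
#' @return Rescaled intensities.
#' @export
normalize_to_bead <- function(intensities, observed_bead, reference_bead) {
  if (!is.numeric(observed_bead) || observed_bead <= 0)
    stop("observed bead intensity must be > 0")
  if (!is.numeric(reference_bead) || reference_bead <= 0)
    stop("reference bead intensity must be > 0")
  intensities * reference_bead / observed_bead
}

#' Percentile normalization against reference cells
#'
#' Maps intensities onto a 0-100 scale anchored at the median of the
#' bottom 5% (-> 0) and the median of the top 5% (-> 100) of a reference
#' cell population (wild-type early gastrula cells).  Values outside
#' \[0, 100\] are possible and preserved.
#'
#' @param cell_intensities numeric vector to rescale.
#' @param reference_cells reference intensities (>= 20 values).
#' @return Rescaled intensities.
#' @export
normalize_percentile <- function(cell_intensities, reference_cells) {
  if (length(reference_cells) < 20)
    stop("need at least 20 reference cells")
  srt <- sort(reference_cells)
  k <- max(1L, floor(0.05 * length(srt)))
  m_low <- stats::median(srt[seq_len(k)])
  m_high <- stats::median(srt[seq.int(length(srt) - k + 1L, length(srt))])
  if (m_high <= m_low)
    stop("degenerate reference: top-5% median equals bottom-5% median")
  100 * (cell_intensities - m_low) / (m_high - m_low)
}

# --- censored-Gaussian bin means ------------------------------------------
# Intensities are additive-noise measurements clipped at zero, so the
# arithmetic mean of a dim bin overestimates the underlying signal:
# E[max(0, N(mu, s))] = mu * pnorm(mu/s) + s * dnorm(mu/s).  Inverting this
# per bin (noise sd estimated from bright bins, where clipping is
# negligible) de-biases the dim tail of a profile.
censored_mean_fun <- function(mu, s) mu * stats::pnorm(mu / s) + s * stats::dnorm(mu / s)

invert_censored_mean <- function(m, s) {
  if (is.na(m) || s <= 1e-9 || m <= 1e-12) return(m)
  lo <- -4 * s
  if (censored_mean_fun(lo, s) >= m) return(lo)
  stats::uniroot(function(mu) censored_mean_fun(mu, s) - m,
                 c(lo, m + s), tol = 1e-8)$root
}

correct_censoring <- function(mean_au, sd_au) {
  ok <- !is.na(mean_au)
  if (!any(ok)) return(mean_au)
  shat <- stats::median(sd_au[ok & mean_au > 0.5 * max(mean_au[ok])], na.rm = TRUE)
  if (!is.finite(shat) || shat <= 1e-9) return(mean_au)
  for (i in 1:2) {
    mu <- vapply(mean_au, invert_censored_mean, numeric(1), s = shat)
    s2 <- stats::median(sd_au[ok & mu > 3 * shat], na.rm = TRUE)
    if (is.finite(s2) && s2 > 1e-9) shat <- s2
  }
  vapply(mean_au, invert_censored_mean, numeric(1), s = shat)
}

bin_stats <- function(angle, values, breaks) {
  b <- cut(angle, breaks = breaks, labels = FALSE, include.lowest = TRUE)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  n <- tabulate(b, nbins = length(centers))
  mean_au <- rep(NA_real_, length(centers))
  sd_au <- rep(NA_real_, length(centers))
  mm <- tapply(values, b, mean)
  ss <- tapply(values, b, stats::sd)
  mean_au[as.integer(names(mm))] <- as.numeric(mm)
  sd_au[as.integer(names(ss))] <- as.numeric(ss)
  data.frame(angle_deg = centers, mean_au = mean_au, n = n, sd_au = sd_au)
}

#' Angular intensity profile from a band of cells
#'
#' Extracts the nuclei lying within `band_width_um` of the band's centre
#' circle and averages a channel in angular bins.  For the DV axis the
#' band is the circle of constant polar angle at `band_center` (in
#' animal-vegetal units, so 90 sits near the blastoderm margin) and
#' nuclei are binned by folded DV angle; for the AV axis the band follows
#' the ventral-animal-dorsal great circle and nuclei are binned by signed
#' AV position.  Per-bin values are arithmetic means; empty bins are kept
#' as `NA`, never zero.
#'
#' @param points nuclei with angles assigned ([assign_angles()] or
#'   generator truth via [use_true_angles()]).
#' @param axis `"dv"` or `"av"`.
#' @param band_center band location in AV units (DV axis) or band offset in
#'   um (AV axis, usually 0).
#' @param band_width_um band width, micrometres (default 40).
#' @param bin_width bin width in profile units (degrees for DV).
#' @param channel intensity column name.
#' @param radius_um sphere radius; taken from the points' sphere attribute
#'   when present.
#' @return An `angular_profile` data.frame with columns `angle_deg`,
#'   `mean_au`, `n`, `sd_au`.
#' @export
band_profile <- function(points, axis = c("dv", "av"), band_center = 90,
                         band_width_um = 40, bin_width = 2,
                         channel = "psmad5_au", radius_um = NULL) {
  axis <- match.arg(axis)
  stopifnot(band_width_um > 0, bin_width > 0)
  if (!channel %in% names(points)) stop("channel not found: ", channel)
  if (is.null(radius_um)) {
    sph <- attr(points, "sphere")
    radius_um <- if (!is.null(sph)) sph$radius else
      stop("radius_um not given and points carry no sphere fit")
  }
  if (axis == "dv") {
    cap <- attr(points, "cap_extent_deg")
    if (is.null(cap)) cap <- max(points$phi_deg)
    phi0 <- band_center / 100 * cap
    arc <- radius_um * abs(points$phi_deg - phi0) * pi / 180
    inband <- arc <= band_width_um / 2
    angle <- points$dv_deg[inband]
    breaks <- seq(0, 180, by = bin_width)
  } else {
    inband <- abs(points$gc_offset_um - band_center) <= band_width_um / 2
    angle <- points$av_deg[inband]
    breaks <- seq(-100, 100, by = bin_width)
  }
  if (!any(inband)) stop("no nuclei fall inside the requested band")
  out <- bin_stats(angle, points[[channel]][inband], breaks)
  class(out) <- c("angular_profile", "data.frame")
  attr(out, "axis") <- toupper(axis)
  attr(out, "band_center") <- band_center
  attr(out, "band_width_um") <- band_width_um
  attr(out, "channel") <- channel
  out
}

#' Whole-cloud DV intensity profile
#'
#' Bins every nucleus (both lateral halves folded together) by DV angle.
#' This is the profile used for gradient slope estimation, mirroring slope
#' extraction from sphere-averaged whole-embryo data rather than from a
#' narrow band.  One or several embryos may be pooled.
#'
#' @param points nuclei (or a list of nuclei tables to pool) with `dv_deg`.
#' @param channel intensity column.
#' @param bin_width_deg bin width, degrees.
#' @param correct_censoring de-bias dim bins for zero-clipped noise
#'   (default `TRUE`; see Details in [smooth_and_slope()]).
#' @return An `angular_profile` data.frame.
#' @export
dv_profile <- function(points, channel = "psmad5_au", bin_width_deg = 2,
                       correct_censoring = TRUE) {
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, lapply(points, function(p)
      p[, c("dv_deg", channel)]))
  out <- bin_stats(points$dv_deg, points[[channel]],
                   seq(0, 180, by = bin_width_deg))
  if (correct_censoring) out$mean_au <- correct_censoring(out$mean_au, out$sd_au)
  class(out) <- c("angular_profile", "data.frame")
  attr(out, "axis") <- "DV"
  attr(out, "channel") <- channel
  out
}

#' Smooth a profile and estimate its slope
#'
#' Fits a locally weighted polynomial regression (loess, degree 2 by
#' default) of the per-bin means on angle and differentiates the smoothed
#' curve by centred finite differences.  Slopes are reported as
#' magnitudes, matching the convention of quoting positive slope values
#' for a decreasing gradient.
#'
#' @param profile an `angular_profile` (or any data.frame with
#'   `angle_deg`, `mean_au`).
#' @param smoothing_fraction loess span as a fraction of non-empty bins
#'   (default 0.2).
#' @param degree local polynomial degree (2 recommended for slope work).
#' @return The profile with `smoothed_au` and `slope_au_per_deg` columns
#'   added (NA bins stay NA).
#' @export
smooth_and_slope <- function(profile, smoothing_fraction = 0.2, degree = 2) {
  ok <- !is.na(profile$mean_au)
  if (sum(ok) < 10)
    stop("need at least 10 non-empty bins to smooth (got ", sum(ok), ")")
  x <- profile$angle_deg[ok]
  y <- profile$mean_au[ok]
  fit <- stats::loess(y ~ x, span = smoothing_fraction, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  s <- stats::predict(fit, newdata = data.frame(x = x))
  n <- length(x)
  d <- rep(NA_real_, n)
  d[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  d[1] <- (s[2] - s[1]) / (x[2] - x[1])
  d[n] <- (s[n] - s[n - 1]) / (x[n] - x[n - 1])
  profile$smoothed_au <- NA_real_
  profile$slope_au_per_deg <- NA_real_
  profile$smoothed_au[ok] <- s
  profile$slope_au_per_deg[ok] <- abs(d)
  profile
}

#' Window-mean slope magnitude of a measured profile
#'
#' For a monotone profile the average of per-bin slope magnitudes over a
#' window telescopes to the net drop across the window divided by its
#' width; this estimator computes that drop directly from small local
#' averages of the (censoring-corrected) bin means at the window edges,
#' which avoids smoothing-induced bias at the scale of shallow dorsal
#' drops.
#'
#' @param profile an `angular_profile` (means already censoring-corrected
#'   if desired).
#' @param lo,hi window limits, degrees.
#' @param edge_halfwidth_deg half-width of the local average taken at each
#'   window edge.
#' @return Mean slope magnitude, A.U./degree.
#' @export
window_mean_slope <- function(profile, lo, hi, edge_halfwidth_deg = 3) {
  stopifnot(hi > lo)
  edge <- function(at) {
    sel <- abs(profile$angle_deg - at) <= edge_halfwidth_deg & !is.na(profile$mean_au)
    if (!any(sel)) stop("no bins near window edge ", at)
    mean(profile$mean_au[sel])
  }
  abs(edge(lo) - edge(hi)) / (hi - lo)
}

#' 8x8 expression heat map
#'
#' Partitions the embryo into 8 animal-vegetal rows by 16 DV columns over
#' the full circumference, averages the channel per bin, folds the two
#' lateral halves together into 8 DV columns, and normalizes by the
#' maximum bin.  `dv_profile` is the column sum of the normalized values
#' (the total expression at each DV position).
#'
#' @param points nuclei with `dv_deg` and `av_deg` (or `phi_deg`).
#' @param channel intensity column.
#' @return list of class `grid_heatmap` with `gene`, `values` (8x8 matrix,
#'   max 1 unless all zero; empty bins `NA`), and `dv_profile` (length 8).
#' @export
grid_heatmap <- function(points, channel) {
  if (!channel %in% names(points)) stop("channel not found: ", channel)
  if (nrow(points) == 0) stop("no nuclei to grid")
  pol <- if ("phi_deg" %in% names(points)) points$phi_deg / max(points$phi_deg)
         else abs(points$av_deg) / 100
  ri <- pmin(floor(pol * 8), 7) + 1                    # 1 animal .. 8 margin
  ci <- pmin(floor(points$dv_deg / 180 * 8), 7) + 1    # folded halves pooled
  vals <- matrix(NA_real_, 8, 8)
  agg <- tapply(points[[channel]], list(ri, ci), mean)
  vals[as.matrix(expand.grid(as.integer(rownames(agg)),
                             as.integer(colnames(agg))))] <- as.numeric(agg)
  mx <- max(vals, na.rm = TRUE)
  if (is.finite(mx) && mx > 0) vals <- vals / mx
  dvp <- colSums(vals, na.rm = TRUE)
  structure(list(gene = sub("^fish_(.*)_au$", "\\1", channel),
                 values = vals, dv_profile = dvp),
            class = "grid_heatmap")
}

#' @export
print.grid_heatmap <- function(x, ...) {
  cat("<grid_heatmap>", x$gene, "\n")
  print(round(x$values, 2))
  cat("DV profile:", paste(round(x$dv_profile, 2), collapse = " "), "\n")
  invisible(x)
}

#' Use generator ground-truth angles as assigned angles
#'
#' Copies the `*_true_deg` columns written by [sample_embryo()] into the
#' working `dv_deg`/`av_deg`/`phi_deg` columns, bypassing registration.
#' Useful for testing the profile machinery in isolation.
#'
#' @param points a generated nuclei table.
#' @param radius_um sphere radius to attach.
#' @return points with angle columns set.
#' @export
use_true_angles <- function(points, radius_um = 350) {
  stopifnot(all(c("dv_true_deg", "av_true_deg", "phi_true_deg") %in% names(points)))
  points$dv_deg <- points$dv_true_deg
  points$av_deg <- points$av_true_deg
  points$phi_deg <- points$phi_true_deg
  points$azimuth_deg <- points$dv_true_deg * sign(points$av_true_deg + 1e-12)
  points$gc_offset_um <- radius_um *
    sin(points$phi_true_deg * pi / 180) * sin(points$dv_true_deg * pi / 180) *
    sign(points$azimuth_deg)
  attr(points, "sphere") <- structure(list(center = c(0, 0, 0),
                                           radius = radius_um,
                                           rms_residual = 0),
                                      class = "sphere_fit")
  attr(points, "cap_extent_deg") <- max(points$phi_true_deg)
  points
}
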