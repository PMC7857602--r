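#' Fit a sphere to nuclear positions
#'
#' Algebraic least-squares sphere (Coope's linearisation): solving
#' `|p|^2 = 2 c.p + (r^2 - |c|^2)` for the centre by linear least squares
#' minimises the summed squared radial residuals to first order.
#'
#' @param points data.frame with `x_um`, `y_um`, `z_um` columns, or a
#'   numeric matrix with 3 columns.
#' @return Object of class `sphere_fit` with `center` (length-3, um),
#'   `radius` (um) and `rms_residual` (um).
#' @export
fit_sphere <- function(points) {
  P <- as_xyz(points)
  if (nrow(P) < 4) stop("sphere fit needs at least 4 points")
  C <- sweep(P, 2, colMeans(P))
  if (svd(C, nu = 0, nv = 0)$d[3] < 1e-8 * max(svd(C, nu = 0, nv = 0)$d[1], 1))
    stop("points are (near-)coplanar; sphere fit is underdetermined")
  rhs <- rowSums(P^2)
  A <- cbind(2 * P, 1)
  coef <- qr.solve(A, rhs)
  center <- coef[1:3]
  radius <- sqrt(coef[4] + sum(center^2))
  d <- sqrt(rowSums(sweep(P, 2, center)^2))
  structure(list(center = unname(center), radius = unname(radius),
                 rms_residual = sqrt(mean((d - radius)^2))),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("<sphere_fit> center (%.2f, %.2f, %.2f) um, radius %.2f um, rms %.3f um\n",
              x$center[1], x$center[2], x$center[3], x$radius, x$rms_residual))
  invisible(x)
}

as_xyz <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 3)
    return(points)
  }
  stopifnot(all(c("x_um", "y_um", "z_um") %in% names(points)))
  as.matrix(points[, c("x_um", "y_um", "z_um")])
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length direction vector")
  v / n
}

#' Assign angular coordinates to nuclei
#'
#' Converts 3-D positions into the embryo's angular frame.  `dv_deg` is
#' the azimuth of the nucleus around the animal axis measured from the
#' ventral meridian, folded so both lateral halves map to \[0, 180\]
#' (0 = ventral-most, 180 = dorsal-most).  `av_deg` is the signed arc
#' position along the ventral margin -> animal pole -> dorsal margin arc,
#' scaled to \[-100, 100\] (negative on the ventral half).  The polar
#' angle from the animal pole (`phi_deg`) and the signed distance from the
#' ventral-dorsal great-circle plane (`gc_offset_um`) are also recorded
#' for band extraction and patching.
#'
#' @param points nuclei data.frame with `x_um`, `y_um`, `z_um`.
#' @param sphere a [fit_sphere()] result.
#' @param ventral_direction,animal_direction unit vectors; must not be
#'   parallel.  `ventral_direction` is re-orthogonalised against the
#'   animal axis.
#' @param cap_extent_deg cap extent used to scale `av_deg`; if `NULL`
#'   (default) the maximum observed polar angle is used.
#' @return `points` with `dv_deg`, `av_deg`, `phi_deg`, `azimuth_deg` and
#'   `gc_offset_um` columns added; the sphere fit and cap extent are
#'   attached as attributes.
#' @export
assign_angles <- function(points, sphere, ventral_direction, animal_direction,
                          cap_extent_deg = NULL) {
  a <- unit(animal_direction)
  v <- ventral_direction - sum(ventral_direction * a) * a
  if (sqrt(sum(v^2)) < 1e-8)
    stop("ventral and animal directions are parallel")
  v <- unit(v)
  w <- c(a[2] * v[3] - a[3] * v[2],   # a x v, completes the frame
         a[3] * v[1] - a[1] * v[3],
         a[1] * v[2] - a[2] * v[1])
  P <- sweep(as_xyz(points), 2, sphere$center)
  U <- P / sqrt(rowSums(P^2))
  cosphi <- pmin(pmax(U %*% a, -1), 1)
  phi_deg <- acos(cosphi) * 180 / pi
  azim <- atan2(U %*% w, U %*% v) * 180 / pi    # signed, ventral meridian = 0
  dv <- abs(azim)
  if (is.null(cap_extent_deg)) cap_extent_deg <- max(phi_deg)
  av <- 100 * phi_deg / cap_extent_deg * ifelse(dv <= 90, -1, 1)
  # distance from the ventral->animal->dorsal great-circle plane (normal w)
  gc_off <- sphere$radius * asin(pmin(pmax(U %*% w, -1), 1))
  points$dv_deg <- as.numeric(dv)
  points$av_deg <- as.numeric(av)
  points$phi_deg <- as.numeric(phi_deg)
  points$azimuth_deg <- as.numeric(azim)
  points$gc_offset_um <- as.numeric(gc_off)
  attr(points, "sphere") <- sphere
  attr(points, "cap_extent_deg") <- cap_extent_deg
  points
}

#' Estimate the ventral pole from the pSmad5 gradient
#'
#' The ventral direction is taken as the intensity-weighted mean direction
#' of the brightest decile of nuclei, projected orthogonal to the animal
#' axis and normalised.  Replaces the manual DV alignment of an imaging
#' pipeline.  A flat signal (e.g. a bmp7-null embryo) leaves the
#' projection with no preferred direction; such clouds are flagged as
#' unorientable.
#'
#' @param points nuclei data.frame including the signal channel.
#' @param sphere a [fit_sphere()] result.
#' @param animal_direction unit vector of the animal axis.
#' @param channel signal column name (default `"psmad5_au"`).
#' @param min_concentration minimum length of the mean projected direction
#'   (0-1) below which the cloud is declared unorientable.
#' @return list with `direction` (unit vector or `NA`), `orientable`
#'   (logical) and `concentration` (mean resultant length).
#' @export
estimate_ventral_pole <- function(points, sphere, animal_direction,
                                  channel = "psmad5_au",
                                  min_concentration = 0.2) {
  if (!channel %in% names(points)) stop("channel not found: ", channel)
  sig <- points[[channel]]
  if (stats::sd(sig) == 0) {
    return(list(direction = rep(NA_real_, 3), orientable = FALSE,
                concentration = 0))
  }
  a <- unit(animal_direction)
  top <- sig >= stats::quantile(sig, 0.9)
  P <- sweep(as_xyz(points)[top, , drop = FALSE], 2, sphere$center)
  U <- P / sqrt(rowSums(P^2))
  Uproj <- U - (U %*% a) %*% t(a)
  len <- sqrt(rowSums(Uproj^2))
  keep <- len > 1e-9
  w <- sig[top][keep]
  D <- Uproj[keep, , drop = FALSE] / len[keep]
  m <- colSums(D * w) / sum(w)
  conc <- sqrt(sum(m^2))
  if (conc < min_concentration) {
    return(list(direction = rep(NA_real_, 3), orientable = FALSE,
                concentration = conc))
  }
  list(direction = unname(unit(m)), orientable = TRUE, concentration = conc)
}

#' Rigidly align a nuclei cloud to a reference cloud
#'
#' Both clouds are sphere-fitted and pole-estimated; the rotation mapping
#' the cloud's (animal, ventral) frame onto the reference frame is applied
#' to the centred cloud.  This pole-frame rigid registration stands in for
#' nonrigid point-set registration, which synthetic spherical embryos do
#' not need.
#'
#' @param cloud,reference_cloud nuclei data.frames.
#' @param animal_direction,reference_animal_direction animal axes (unit
#'   vectors) of the two clouds.
#' @param channel signal channel used for pole estimation.
#' @return list with `rotation` (3x3 matrix), `points` (the transformed
#'   cloud, centred on the reference sphere centre) and the two pole
#'   estimates.
#' @export
align_to_reference <- function(cloud, reference_cloud,
                               animal_direction = c(0, 0, 1),
                               reference_animal_direction = animal_direction,
                               channel = "psmad5_au") {
  s1 <- fit_sphere(cloud)
  s2 <- fit_sphere(reference_cloud)
  p1 <- estimate_ventral_pole(cloud, s1, animal_direction, channel)
  p2 <- estimate_ventral_pole(reference_cloud, s2,
                              reference_animal_direction, channel)
  if (!p1$orientable || !p2$orientable)
    stop("cannot align: cloud is unorientable (no detectable gradient)")
  frame <- function(a, v) {
    a <- unit(a); v <- unit(v - sum(v * a) * a)
    cbind(v, c(a[2] * v[3] - a[3] * v[2], a[3] * v[1] - a[1] * v[3],
               a[1] * v[2] - a[2] * v[1]), a)
  }
  R <- unname(frame(reference_animal_direction, p2$direction) %*%
                t(frame(animal_direction, p1$direction)))
  dimnames(R) <- NULL
  P <- sweep(as_xyz(cloud), 2, s1$center) %*% t(R)
  out <- cloud
  out$x_um <- P[, 1] + s2$center[1]
  out$y_um <- P[, 2] + s2$center[2]
  out$z_um <- P[, 3] + s2$center[3]
  list(rotation = R, points = out, pole = p1$direction,
       reference_pole = p2$direction)
}

#' Average intensities over triangular surface patches
#'
#' Tessellates the angular domain into `rows x cols` rectangles (polar
#' angle from the animal pole by signed azimuth), splits each along its
#' diagonal into two triangles, and averages each channel within every
#' patch.  With the default 4,800 patches this reproduces a 40 x 60 x 2
#' triangulation.  Every nucleus falls in exactly one patch; patches
#' without nuclei are flagged empty (`NA` means), never zero-filled.
#'
#' @param points nuclei with `phi_deg` and `azimuth_deg` assigned (see
#'   [assign_angles()]).
#' @param n_patches total number of triangles; must be expressible as
#'   `rows * cols * 2`.
#' @param channels intensity columns to average; defaults to all
#'   `*_au` columns.
#' @return data.frame with one row per patch: `patch_id`, `phi_center_deg`,
#'   `azimuth_center_deg`, `n_nuclei` and one mean column per channel.
#' @export
patch_means <- function(points, n_patches = 4800, channels = NULL) {
  stopifnot(all(c("phi_deg", "azimuth_deg") %in% names(points)),
            n_patches >= 8)
  dims <- patch_grid_dims(n_patches)
  rows <- dims[1]; cols <- dims[2]
  if (is.null(channels))
    channels <- grep("_au$", names(points), value = TRUE)
  u <- pmin(points$phi_deg / 180, 1 - 1e-12)          # polar fraction
  v <- pmin((points$azimuth_deg + 180) / 360, 1 - 1e-12)
  ri <- floor(u * rows)
  ci <- floor(v * cols)
  fu <- u * rows - ri
  fv <- v * cols - ci
  tri <- as.integer(fu + fv >= 1)                     # diagonal split
  pid <- (ri * cols + ci) * 2L + tri + 1L
  idx <- seq_len(rows * cols * 2L)
  grid_r <- (idx - 1L) %/% 2L %/% cols
  grid_c <- (idx - 1L) %/% 2L %% cols
  out <- data.frame(
    patch_id = idx,
    phi_center_deg = (grid_r + 0.5) * 180 / rows,
    azimuth_center_deg = (grid_c + 0.5) * 360 / cols - 180,
    n_nuclei = as.integer(tabulate(pid, nbins = rows * cols * 2L)))
  for (ch in channels) {
    m <- rep(NA_real_, rows * cols * 2L)
    agg <- tapply(points[[ch]], pid, mean)
    m[as.integer(names(agg))] <- as.numeric(agg)
    out[[paste0("mean_", ch)]] <- m
  }
  out$empty <- out$n_nuclei == 0L
  attr(out, "grid") <- c(rows = rows, cols = cols)
  out
}

# choose rows x cols with cols/rows closest to 3/2 (40 x 60 default shape)
patch_grid_dims <- function(n_patches) {
  if (n_patches %% 2 != 0) {
    stop("n_patches must be rows x cols x 2; nearest valid counts: ",
         n_patches - 1, ", ", n_patches + 1)
  }
  half <- n_patches / 2
  divs <- which(half %% seq_len(half) == 0)
  rows <- divs[which.min(abs(half / divs / divs - 1.5))]
  c(rows, half / rows)
}
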