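#' Monotone gradient profiles
#'
#' A `gradient_profile` describes nuclear pSmad5 intensity as a function of
#' dorsal-ventral (DV) angle (0 degrees = ventral-most, 180 = dorsal-most).
#' The curve is a cubic Hermite spline through a small set of anchors, each
#' anchor carrying an angle, an intensity value (A.U.) and a derivative
#' (A.U./degree).  Anchors must be strictly increasing in angle, start at 0
#' and end at 180, have non-increasing values and non-positive derivatives,
#' and every segment must satisfy the Fritsch-Carlson monotonicity
#' condition (each endpoint derivative lies between 3x the segment secant
#' and 0), so that the interpolant is monotone non-increasing.
#'
#' @param anchors data.frame with columns `angle_deg`, `value_au`,
#'   `deriv_au_per_deg`.
#' @param genotype character label, e.g. `"wild_type"`.
#' @return An object of class `gradient_profile`.
#' @seealso [make_canonical_gradient()], [gradient_value()],
#'   [boundary_angle_analytic()]
#' @export
gradient_profile <- function(anchors, genotype = "custom") {
  stopifnot(is.data.frame(anchors),
            all(c("angle_deg", "value_au", "deriv_au_per_deg") %in% names(anchors)))
  a <- anchors[order(anchors$angle_deg), , drop = FALSE]
  if (any(diff(a$angle_deg) <= 0))
    stop("anchor angles must be strictly increasing")
  if (a$angle_deg[1] != 0 || a$angle_deg[nrow(a)] != 180)
    stop("anchors must start at 0 and end at 180 degrees")
  if (any(a$value_au < 0)) stop("anchor values must be non-negative")
  if (any(diff(a$value_au) > 0)) stop("anchor values must be non-increasing")
  if (any(a$deriv_au_per_deg > 0)) stop("anchor derivatives must be <= 0")
  bad <- which(!fritsch_carlson_ok(a))
  if (length(bad))
    stop("segment(s) ", paste(bad, collapse = ", "),
         " violate the Fritsch-Carlson monotonicity condition")
  structure(list(anchors = a, genotype = genotype), class = "gradient_profile")
}

#' Check the Fritsch-Carlson monotonicity condition per segment
#'
#' For non-increasing data each endpoint derivative of a segment must lie
#' in `[3 * secant, 0]` for the cubic Hermite interpolant to be monotone.
#'
#' @param anchors anchor data.frame (see [gradient_profile()]).
#' @return logical vector, one entry per segment.
#' @export
fritsch_carlson_ok <- function(anchors) {
  sec <- diff(anchors$value_au) / diff(anchors$angle_deg)
  d0 <- anchors$deriv_au_per_deg[-nrow(anchors)]
  d1 <- anchors$deriv_au_per_deg[-1]
  d0 >= 3 * sec & d0 <= 0 & d1 >= 3 * sec & d1 <= 0
}

hermite <- function(theta, ang, val, der, deriv = FALSE) {
  theta <- pmin(pmax(theta, ang[1]), ang[length(ang)])
  i <- findInterval(theta, ang, rightmost.closed = TRUE, all.inside = TRUE)
  h <- ang[i + 1] - ang[i]
  t <- (theta - ang[i]) / h
  t2 <- t * t
  t3 <- t2 * t
  if (!deriv) {
    (2 * t3 - 3 * t2 + 1) * val[i] + (t3 - 2 * t2 + t) * h * der[i] +
      (-2 * t3 + 3 * t2) * val[i + 1] + (t3 - t2) * h * der[i + 1]
  } else {
    ((6 * t2 - 6 * t) * val[i] + (3 * t2 - 4 * t + 1) * h * der[i] +
       (-6 * t2 + 6 * t) * val[i + 1] + (3 * t2 - 2 * t) * h * der[i + 1]) / h
  }
}

#' Evaluate a gradient profile
#'
#' @param profile a [gradient_profile()].
#' @param theta_deg DV angles in degrees; values outside \[0, 180\] are
#'   clamped to the ends.
#' @return Intensity in A.U. ([gradient_value()]) or the signed derivative
#'   in A.U./degree ([gradient_deriv()]).  Evaluation at an anchor returns
#'   the anchor value and derivative exactly.
#' @export
gradient_value <- function(profile, theta_deg) {
  a <- profile$anchors
  hermite(theta_deg, a$angle_deg, a$value_au, a$deriv_au_per_deg)
}

#' @rdname gradient_value
#' @export
gradient_deriv <- function(profile, theta_deg) {
  a <- profile$anchors
  hermite(theta_deg, a$angle_deg, a$value_au, a$deriv_au_per_deg, deriv = TRUE)
}

#' @export
print.gradient_profile <- function(x, ...) {
  cat("<gradient_profile> genotype:", x$genotype, "\n")
  print(x$anchors, row.names = FALSE)
  invisible(x)
}

canonical_genotypes <- c("wild_type", "chordin_mutant", "bmp7_mutant")

#' Canonical genotype gradient profiles
#'
#' Returns the package's reference pSmad5 gradients.  The wild-type profile
#' peaks at 100 A.U. at the ventral pole and carries the three measured
#' boundary readouts as anchors: 60 A.U. with slope -1.4 A.U./degree at the
#' sizzled boundary, 25 A.U. with slope -0.76 at the foxi1 boundary and
#' 7 A.U. with slope -0.35 at the bambia boundary.  Anchor angles are spaced
#' so that each segment secant lies between its endpoint derivatives, which
#' makes the printed value/slope pairs mutually consistent (the derivative
#' varies monotonically within every segment).
#'
#' The chordin-mutant profile is calibrated against the wild type (see
#' [calibrate_chordin_gradient()]): the highest signal region expands
#' laterally and the window-mean slope magnitude over 25-75 degrees is half
#' the wild-type value while over 125-155 degrees it is twice the wild-type
#' value.  The bmp7-null profile is flat at 1 A.U.
#'
#' @param genotype one of `"wild_type"`, `"chordin_mutant"`, `"bmp7_mutant"`.
#' @return A [gradient_profile()].
#' @examples
#' wt <- make_canonical_gradient("wild_type")
#' gradient_value(wt, 75)   # 60 A.U.
#' gradient_deriv(wt, 75)   # -1.4 A.U./degree
#' @export
make_canonical_gradient <- function(genotype = canonical_genotypes) {
  if (length(genotype) != 1L || !genotype %in% canonical_genotypes)
    stop("unknown genotype label; valid labels: ",
         paste(canonical_genotypes, collapse = ", "))
  switch(genotype,
    wild_type = gradient_profile(data.frame(
      angle_deg        = c(0, 75, 105, 135, 180),
      value_au         = c(100, 60, 25, 7, 0.5),
      deriv_au_per_deg = c(0, -1.4, -0.76, -0.35, 0)
    ), genotype = "wild_type"),
    chordin_mutant = calibrate_chordin_gradient(make_canonical_gradient("wild_type")),
    bmp7_mutant = gradient_profile(data.frame(
      angle_deg        = c(0, 180),
      value_au         = c(1, 1),
      deriv_au_per_deg = c(0, 0)
    ), genotype = "bmp7_mutant")
  )
}

#' Window-mean slope magnitude of a gradient profile
#'
#' Mean of `|dG/dtheta|` over an angular window, computed by adaptive
#' quadrature on the spline.
#'
#' @param profile a [gradient_profile()].
#' @param lo,hi window limits in degrees.
#' @return Mean slope magnitude in A.U./degree.
#' @export
gradient_window_mean_slope <- function(profile, lo, hi) {
  stopifnot(hi > lo)
  stats::integrate(function(x) abs(gradient_deriv(profile, x)), lo, hi,
                   subdivisions = 400L)$value / (hi - lo)
}

#' Calibrate the chordin-mutant gradient against a wild-type profile
#'
#' Constructs the chordin-mutant pSmad5 profile from the wild-type one:
#' a ventral plateau at the wild-type maximum extending to 40 degrees
#' (high BMP signalling expands laterally when the dorsal sink is lost),
#' a lateral descent calibrated so the net drop over 25-75 degrees is half
#' the wild-type drop, the sizzled-level crossing (60 A.U.) pinned at
#' 100 degrees with slope -0.7 A.U./degree, and an exactly linear dorsal
#' segment spanning 122-158 degrees whose slope is twice the wild-type
#' 125-155 degree window mean.  Both slope-ratio constraints then hold
#' analytically; [gradient_window_mean_slope()] verifies them by quadrature.
#'
#' @param wt the wild-type [gradient_profile()].
#' @return A calibrated chordin-mutant [gradient_profile()].
#' @export
calibrate_chordin_gradient <- function(wt) {
  drop_vl <- gradient_window_mean_slope(wt, 25, 75) * 50    # ventral-lateral
  drop_dl <- gradient_window_mean_slope(wt, 125, 155) * 30  # dorsal-lateral
  v75 <- 100 - drop_vl / 2
  m2 <- 2 * drop_dl / 30
  gradient_profile(data.frame(
    angle_deg        = c(0, 40, 75, 100, 112, 122, 158, 180),
    value_au         = c(100, 100, v75, 60, 50, 33, 33 - 36 * m2, 1),
    deriv_au_per_deg = c(0, 0, (v75 - 100) / 35, -0.7, -0.9, -m2, -m2, 0)
  ), genotype = "chordin_mutant")
}

#' Analytic boundary angle for a given signal level
#'
#' Root of `gradient(theta) = level_au` found by bisection on the monotone
#' spline.
#'
#' @param profile a [gradient_profile()].
#' @param level_au signal level in A.U.; must lie strictly between the
#'   profile's terminal values.
#' @param tol bisection tolerance in degrees.
#' @return Boundary angle in degrees.
#' @export
boundary_angle_analytic <- function(profile, level_au, tol = 1e-9) {
  a <- profile$anchors
  v0 <- a$value_au[1]
  v1 <- a$value_au[nrow(a)]
  if (level_au >= v0 || level_au <= v1)
    stop("level ", level_au, " A.U. is not crossed by this profile (range ",
         v1, " to ", v0, ")")
  stats::uniroot(function(x) gradient_value(profile, x) - level_au,
                 c(0, 180), tol = tol)$root
}
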