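sphere_points <- function(n, center = c(0, 0, 0), radius = 350, seed = 1) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  data.frame(x_um = center[1] + radius * u[, 1],
             y_um = center[2] + radius * u[, 2],
             z_um = center[3] + radius * u[, 3])
}

test_that("exact sphere points are fitted exactly", {
  f <- fit_sphere(sphere_points(200))
  expect_equal(f$center, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(f$radius, 350, tolerance = 1e-6)
  expect_lt(f$rms_residual, 1e-6)
})

test_that("jittered sphere fit agrees with a nonlinear least-squares oracle", {
  p <- sphere_points(400, center = c(10, -20, 5), seed = 2)
  set.seed(3)
  p[] <- p[] + rnorm(1200, 0, 2)
  f <- fit_sphere(p)
  expect_lt(sqrt(sum((f$center - c(10, -20, 5))^2)), 1)
  expect_lt(abs(f$radius - 350), 1)
  # direct nonlinear least squares on the radial residuals
  obj <- function(par) {
    d <- sqrt((p$x_um - par[1])^2 + (p$y_um - par[2])^2 + (p$z_um - par[3])^2)
    sum((d - par[4])^2)
  }
  nls_fit <- optim(c(0, 0, 0, 300), obj, method = "BFGS")
  expect_equal(f$center, nls_fit$par[1:3], tolerance = 0.05)
  expect_equal(f$radius, nls_fit$par[4], tolerance = 0.05)
})

test_that("degenerate point sets are rejected", {
  expect_error(fit_sphere(sphere_points(3)), "at least 4")
  flat <- data.frame(x_um = runif(30), y_um = runif(30), z_um = 0)
  expect_error(fit_sphere(flat), "coplanar")
})

test_that("angle conventions: ventral margin and dorsal meridian anchors", {
  sph <- structure(list(center = c(0, 0, 0), radius = 1, rms_residual = 0),
                   class = "sphere_fit")
  pts <- data.frame(
    x_um = c(sin(2), 0, -sin(1)),       # margin on ventral meridian (phi=2rad
    y_um = c(0, 0, 0),                  # with cap 2rad), animal pole, dorsal
    z_um = c(cos(2), 1, cos(1)))
  a <- assign_angles(pts, sph, ventral_direction = c(1, 0, 0),
                     animal_direction = c(0, 0, 1))
  expect_equal(a$dv_deg[1], 0)
  expect_equal(a$av_deg[1], -100)        # ventral margin
  expect_equal(a$dv_deg[3], 180)         # dorsal meridian
  expect_gt(a$av_deg[3], 0)
  expect_error(assign_angles(pts, sph, c(0, 0, 1), c(0, 0, 1)), "parallel")
})

test_that("generated embryos round-trip position -> angles within 0.5 degrees", {
  e <- small_embryo(seed = 21, n = 4000)
  sph <- fit_sphere(e)
  a <- assign_angles(e, sph, ventral_direction = c(1, 0, 0),
                     animal_direction = c(0, 0, 1))
  expect_lt(max(abs(a$dv_deg - e$dv_true_deg)), 0.5)
  expect_lt(max(abs(a$av_deg - e$av_true_deg)), 0.5)
  # translation invariance of the assigned angles
  e2 <- e
  e2$x_um <- e$x_um + 500; e2$y_um <- e$y_um - 120; e2$z_um <- e$z_um + 40
  a2 <- assign_angles(e2, fit_sphere(e2), c(1, 0, 0), c(0, 0, 1))
  expect_equal(a2$dv_deg, a$dv_deg, tolerance = 1e-6)
})

test_that("ventral pole recovery is accurate, equivariant, and flags flat signal", {
  e <- sample_embryo(embryo_spec(n_nuclei = 4000, noise_sd = 0, seed = 8),
                     make_canonical_gradient("wild_type"))
  sph <- fit_sphere(e)
  pole <- estimate_ventral_pole(e, sph, c(0, 0, 1))
  expect_lt(acos(min(1, sum(pole$direction * c(1, 0, 0)))) * 180 / pi, 2)
  # rotate the cloud 40 degrees about the animal axis -> pole follows
  th <- 40 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  er <- e
  er[, c("x_um", "y_um", "z_um")] <- as.matrix(e[, c("x_um", "y_um", "z_um")]) %*% t(R)
  pr <- estimate_ventral_pole(er, fit_sphere(er), c(0, 0, 1))
  expect_equal(as.numeric(R %*% pole$direction), pr$direction, tolerance = 0.02)
  # bmp7 mutant: flat gradient, unorientable
  b <- sample_embryo(embryo_spec(n_nuclei = 2000, seed = 9),
                     make_canonical_gradient("bmp7_mutant"))
  pb <- estimate_ventral_pole(b, fit_sphere(b), c(0, 0, 1))
  expect_false(pb$orientable)
})

test_that("alignment recovers identity and a known 30-degree rotation", {
  e <- small_embryo(seed = 31, n = 3000)
  self <- align_to_reference(e, e)
  expect_equal(self$rotation, diag(3), tolerance = 1e-6)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  er <- e
  er[, c("x_um", "y_um", "z_um")] <- as.matrix(e[, c("x_um", "y_um", "z_um")]) %*% t(R)
  al <- align_to_reference(er, e)
  ang <- acos((sum(diag(al$rotation)) - 1) / 2) * 180 / pi
  expect_lt(abs(ang - 30), 1)
  b <- sample_embryo(embryo_spec(n_nuclei = 2000, seed = 9),
                     make_canonical_gradient("bmp7_mutant"))
  expect_error(align_to_reference(b, e), "unorientable")
})

test_that("patch assignment partitions the nuclei and averages correctly", {
  e <- use_true_angles(small_embryo(seed = 41, n = 2000))
  pm <- patch_means(e, 4800)
  expect_equal(unname(attr(pm, "grid")), c(40, 60))
  expect_equal(nrow(pm), 4800)
  expect_equal(sum(pm$n_nuclei), nrow(e))        # partition property
  expect_true(all(is.na(pm$mean_psmad5_au[pm$empty])))
  # uniform intensity -> every non-empty patch mean equals it
  e$psmad5_au <- 5
  pm5 <- patch_means(e, 4800, channels = "psmad5_au")
  expect_equal(unique(pm5$mean_psmad5_au[!pm5$empty]), 5)
  expect_error(patch_means(e, 4801), "nearest valid counts: 4800, 4802")
})
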