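test_that("bead normalization is the expected linear rescaling", {
  x <- c(0, 10, 55.5)
  expect_equal(normalize_to_bead(x, 100, 100), x)
  expect_equal(normalize_to_bead(x, 50, 100), 2 * x)
  expect_error(normalize_to_bead(x, 0, 100), "> 0")
  # two imaging sessions differing by a known gain agree after normalization
  set.seed(2)
  session1 <- runif(50, 0, 100)
  session2 <- session1 * 0.37          # same cells, lower detector gain
  expect_equal(normalize_to_bead(session2, observed_bead = 0.37 * 80,
                                 reference_bead = 80),
               session1)
})

test_that("percentile normalization maps the reference extremes to 0 and 100", {
  ref <- 0:100                          # uniform grid
  srt <- sort(ref)
  m_low <- median(srt[1:5])             # brute-force percentile medians
  m_high <- median(srt[97:101])
  expect_equal(normalize_percentile(m_low, ref), 0)
  expect_equal(normalize_percentile(m_high, ref), 100)
  expect_equal(normalize_percentile(50, ref), 100 * (50 - m_low) / (m_high - m_low))
  expect_error(normalize_percentile(1, rep(5, 40)), "degenerate")
  expect_error(normalize_percentile(1, 1:10), "at least 20")
})

test_that("band profiles average correctly and respect the band", {
  e <- use_true_angles(small_embryo(seed = 51, n = 4000))
  e$psmad5_au <- 5                      # uniform intensity
  p <- band_profile(e, "dv", channel = "psmad5_au")
  expect_s3_class(p, "angular_profile")
  expect_equal(unique(p$mean_au[!is.na(p$mean_au)]), 5)
  expect_equal(attr(p, "band_width_um"), 40)
  # intensity equal to the DV angle: bin means track bin centers
  e$psmad5_au <- e$dv_true_deg
  p2 <- band_profile(e, "dv", channel = "psmad5_au")
  ok <- !is.na(p2$mean_au) & p2$n >= 2
  expect_lt(max(abs(p2$mean_au[ok] - p2$angle_deg[ok])), 1)
  # brute-force per-bin average oracle for one bin
  sph_r <- attr(e, "sphere")$radius
  cap <- attr(e, "cap_extent_deg")
  inband <- abs(sph_r * (e$phi_true_deg - 0.9 * cap) * pi / 180) <= 20
  bin <- inband & e$dv_true_deg >= 40 & e$dv_true_deg < 42
  expect_equal(p2$mean_au[p2$angle_deg == 41], mean(e$psmad5_au[bin]))
  expect_equal(p2$n[p2$angle_deg == 41], sum(bin))
  expect_error(band_profile(e, "dv", band_center = 90, band_width_um = 40,
                            channel = "nope"), "channel")
})

test_that("band profile means are invariant to nucleus ordering", {
  e <- use_true_angles(small_embryo(seed = 52, n = 2000))
  p1 <- band_profile(e, "dv", channel = "psmad5_au")
  set.seed(1)
  shuffled <- e[sample(nrow(e)), ]
  attr(shuffled, "sphere") <- attr(e, "sphere")
  attr(shuffled, "cap_extent_deg") <- attr(e, "cap_extent_deg")
  p2 <- band_profile(shuffled, "dv", channel = "psmad5_au")
  expect_equal(p1$mean_au, p2$mean_au)
})

test_that("smoothing recovers a linear profile's slope everywhere", {
  prof <- data.frame(angle_deg = seq(1, 179, 2), mean_au = 100 - seq(1, 179, 2))
  s <- smooth_and_slope(prof)
  expect_equal(s$smoothed_au, prof$mean_au, tolerance = 1e-6)
  expect_equal(s$slope_au_per_deg, rep(1, nrow(prof)), tolerance = 1e-6)
  expect_error(smooth_and_slope(prof[1:5, ]), "at least 10")
})

test_that("noiseless canonical profile: smoothed slope at the sizzled anchor", {
  wt <- make_canonical_gradient("wild_type")
  grid <- seq(0, 180, by = 1)
  prof <- data.frame(angle_deg = grid, mean_au = gradient_value(wt, grid))
  s <- smooth_and_slope(prof)
  slope75 <- approx(s$angle_deg, s$slope_au_per_deg, 75)$y
  expect_lt(abs(slope75 - 1.4) / 1.4, 0.05)
  # smoothed curve tracks the analytic spline closely away from the ends
  mid <- s$angle_deg > 10 & s$angle_deg < 170
  expect_lt(max(abs(s$smoothed_au[mid] - prof$mean_au[mid])), 1.5)
  # analytic derivative oracle: smoothed slope within 10% at the gene anchors
  for (th in c(105, 135)) {
    sl <- approx(s$angle_deg, s$slope_au_per_deg, th)$y
    expect_lt(abs(sl - abs(gradient_deriv(wt, th))) / abs(gradient_deriv(wt, th)),
              0.10, label = paste("slope at", th))
  }
})

test_that("censoring-corrected dv profile de-biases the clipped dorsal tail", {
  wt <- make_canonical_gradient("wild_type")
  es <- lapply(1:10, function(i)
    sample_embryo(embryo_spec(seed = 300 + i), wt))
  pooled <- lapply(es, use_true_angles)
  raw <- dv_profile(pooled, correct_censoring = FALSE)
  cor <- dv_profile(pooled, correct_censoring = TRUE)
  truth <- gradient_value(wt, raw$angle_deg)
  tail_bins <- raw$angle_deg > 150
  expect_gt(mean(raw$mean_au[tail_bins] - truth[tail_bins]), 0.5)  # raw biased up
  expect_lt(mean(abs(cor$mean_au[tail_bins] - truth[tail_bins])), 0.35)
  # correction is inert where clipping cannot occur
  bright <- raw$angle_deg < 60
  expect_equal(cor$mean_au[bright], raw$mean_au[bright], tolerance = 0.02)
})

test_that("window-mean slope matches the analytic window mean on cohorts", {
  wt <- make_canonical_gradient("wild_type")
  prof <- cohort_dv_profile(lapply(1:10, function(i)
    sample_embryo(embryo_spec(seed = 500 + i), wt)), use_truth = TRUE)
  for (w in list(c(25, 75), c(125, 155))) {
    truth <- gradient_window_mean_slope(wt, w[1], w[2])
    expect_lt(abs(window_mean_slope(prof, w[1], w[2]) - truth) / truth, 0.08,
              label = paste("window", w[1], "-", w[2]))
  }
})

test_that("grid heat maps normalize, fold symmetrically, and sum consistently", {
  e <- use_true_angles(small_embryo(seed = 61, n = 4000))
  # all intensity concentrated in the ventral-most animal corner bin
  e$fish_test_au <- as.numeric(e$dv_true_deg < 22.5 & e$phi_true_deg <
                                 max(e$phi_true_deg) / 8)
  hm <- grid_heatmap(e, "fish_test_au")
  expect_equal(hm$values[1, 1], 1)
  expect_equal(sum(hm$values > 0, na.rm = TRUE), 1)
  # bilaterally symmetric input: folding leaves values unchanged
  hm2 <- grid_heatmap(e, "psmad5_au")
  mirrored <- e
  mirrored$y_um <- -mirrored$y_um      # reflection leaves dv/av untouched
  expect_equal(grid_heatmap(mirrored, "psmad5_au")$values, hm2$values)
  # dv_profile equals brute-force column sums
  expect_equal(hm2$dv_profile, colSums(hm2$values, na.rm = TRUE))
  expect_equal(max(hm2$values, na.rm = TRUE), 1)
})
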