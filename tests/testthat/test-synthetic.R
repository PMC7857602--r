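test_that("a fixed seed gives bit-identical embryo tables", {
  wt <- make_canonical_gradient("wild_type")
  spec <- embryo_spec(n_nuclei = 500, seed = 42)
  a <- sample_embryo(spec, wt)
  b <- sample_embryo(spec, wt)
  expect_identical(a, b)
  c <- sample_embryo(embryo_spec(n_nuclei = 500, seed = 43), wt)
  expect_false(identical(a$x_um, c$x_um))
})

test_that("noiseless threshold expression is exactly the threshold-crossing region", {
  wt <- make_canonical_gradient("wild_type")
  genes <- gene_truth("sizzled", 60, 10)
  spec <- embryo_spec(n_nuclei = 3000, noise_sd = 0, seed = 3)
  e <- sample_embryo(spec, wt, genes, readout_model("threshold", genes),
                     exposure_minutes = 60)
  boundary <- boundary_angle_analytic(wt, 60)
  on <- e$fish_sizzled_au > 0
  expect_true(all(e$dv_true_deg[on] <= boundary + 1e-9))
  expect_true(all(e$dv_true_deg[!on] >= boundary - 1e-9))
  expect_equal(sort(unique(e$fish_sizzled_au)), c(0, 100))
})

test_that("no gene is expressed before its onset delay", {
  wt <- make_canonical_gradient("wild_type")
  spec <- embryo_spec(n_nuclei = 1000, noise_sd = 0, seed = 5)
  e <- sample_embryo(spec, wt, exposure_minutes = 5)   # all onsets >= 10
  for (ch in grep("^fish_", names(e), value = TRUE))
    expect_equal(e[[ch]], rep(0, nrow(e)), info = ch)
})

test_that("nuclei lie on the cap with matching ground-truth angles", {
  spec <- embryo_spec(n_nuclei = 2000, seed = 11)
  e <- sample_embryo(spec, make_canonical_gradient("wild_type"))
  r <- sqrt(e$x_um^2 + e$y_um^2 + e$z_um^2)
  expect_equal(r, rep(spec$radius_um, nrow(e)), tolerance = 1e-9)
  expect_true(all(e$phi_true_deg <= spec$cap_extent_deg))
  expect_equal(acos(e$z_um / r) * 180 / pi, e$phi_true_deg, tolerance = 1e-9)
  expect_equal(abs(atan2(e$y_um, e$x_um)) * 180 / pi, e$dv_true_deg,
               tolerance = 1e-9)
})

test_that("pulse rules follow the threshold and duration models", {
  genes <- gene_truth(c("sizzled", "foxi1", "bambia", "ved"),
                      c(60, 25, 7, 7), c(10, 20, 30, 10))
  thr <- readout_model("threshold", genes)
  # high 30-minute pulse turns all four genes on
  r30 <- simulate_pulse_experiment(80, 30, genes, thr)
  expect_true(all(r30$expressed))
  # 10-minute pulse: only the fast-onset genes
  r10 <- simulate_pulse_experiment(80, 10, genes, thr)
  expect_equal(r10$gene[r10$expressed], c("sizzled", "ved"))
  # sub-threshold pulse activates only low-threshold genes
  r_low <- simulate_pulse_experiment(10, 60, genes, thr)
  expect_equal(sort(r_low$gene[r_low$expressed]), c("bambia", "ved"))
  # duration model: only genes whose required duration fits in the pulse
  dur <- readout_model("duration", genes[1:3, ],
                       required_duration = c(sizzled = 240, foxi1 = 120,
                                             bambia = 30))
  rd <- simulate_pulse_experiment(80, 30, genes[1:3, ], dur)
  expect_equal(rd$gene[rd$expressed], "bambia")
  # slope model undefined for uniform exposure
  slp <- readout_model("slope", genes, slope_criterion = c(
    sizzled = 1, foxi1 = 1, bambia = 1, ved = 1))
  expect_error(simulate_pulse_experiment(80, 30, genes, slp), "uniform")
})

test_that("dissociated assays follow the dose calibration and threshold rules", {
  genes <- canonical_gene_truths()
  hi <- simulate_dissociated_assay(20, 4000, genes, seed = 1)
  lo <- simulate_dissociated_assay(5, 4000, genes, seed = 2)
  # expression is exactly the threshold indicator (noiseless channels)
  expect_equal(hi$fish_sizzled_au > 0, hi$psmad5_au >= 60)
  expect_equal(lo$fish_bambia_au > 0, lo$psmad5_au >= 7)
  # high dose: most cells above the sizzled threshold; low dose: almost none,
  # but most above the bambia threshold
  expect_gt(mean(hi$psmad5_au > 60), 0.5)
  expect_lt(mean(lo$psmad5_au > 60), 0.01)
  expect_gt(mean(lo$psmad5_au > 7), 0.9)
  # dose 0: no signal, no expression
  z <- simulate_dissociated_assay(0, 100, genes, seed = 3)
  expect_equal(z$psmad5_au, rep(0, 100))
  expect_true(all(z$fish_sizzled_au == 0))
  expect_error(simulate_dissociated_assay(10, 10, genes), "unsupported dose")
})

test_that("dose-20 pSmad5 tail matches the analytic normal tail probability", {
  n <- 20000
  hi <- simulate_dissociated_assay(20, n, seed = 9)
  p_hat <- mean(hi$psmad5_au > 60)
  p_true <- pnorm(60, 75, 15, lower.tail = FALSE)   # closed-form oracle
  mc_se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(p_hat - p_true), 3 * mc_se)
})
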