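#' Synthetic embryo specification
#'
#' Geometry and noise settings for the synthetic blastoderm: nuclei are
#' placed uniformly on a spherical cap of `cap_extent_deg` degrees around
#' the animal pole of a sphere of radius `radius_um`.  Channel intensities
#' receive additive Gaussian noise clipped at zero.
#'
#' @param radius_um embryo radius, micrometres (default 350, the scale of a
#'   zebrafish gastrula).
#' @param cap_extent_deg angular extent of the blastoderm cap from the
#'   animal pole, degrees in (0, 180].
#' @param n_nuclei number of nuclei.
#' @param noise_sd intensity noise standard deviation, A.U.
#' @param expression_amplitude FISH intensity of an expressing nucleus, A.U.
#' @param seed integer seed; every generated table is reproducible for a
#'   fixed seed.
#' @return An object of class `embryo_spec`.
#' @export
embryo_spec <- function(radius_um = 350, cap_extent_deg = 120,
                        n_nuclei = 4000, noise_sd = 5,
                        expression_amplitude = 100, seed = 1L) {
  stopifnot(radius_um > 0, n_nuclei >= 1, noise_sd >= 0,
            cap_extent_deg > 0, cap_extent_deg <= 180,
            expression_amplitude >= 0)
  structure(list(radius_um = radius_um, cap_extent_deg = cap_extent_deg,
                 n_nuclei = as.integer(n_nuclei), noise_sd = noise_sd,
                 expression_amplitude = expression_amplitude,
                 seed = as.integer(seed)),
            class = "embryo_spec")
}

#' Sample a synthetic embryo
#'
#' Generates a nuclei table emulating a confocal-imaged gastrula: positions
#' uniform on the blastoderm cap (animal pole along +z, ventral meridian
#' along +x), nuclear pSmad5 set by the gradient profile at the nucleus'
#' DV angle, and one FISH channel per gene set by the readout model
#' (`expression_amplitude` times the activation indicator).  Gaussian
#' noise of sd `noise_sd` is added to every intensity and clipped at zero.
#'
#' Ground-truth angular coordinates are stored in `dv_true_deg`,
#' `av_true_deg` and `phi_true_deg` columns (dropped by
#' [write_nuclei()] unless requested).
#'
#' @param spec an [embryo_spec()].
#' @param gradient a [gradient_profile()].
#' @param genes a [gene_truth()] table naming the FISH channels.
#' @param model a [readout_model()].
#' @param exposure_minutes minutes of BMP exposure at fixation (>= 0);
#'   endogenous signalling lasts about 4 hours, so the default is 240.
#' @param embryo_id identifier written into the table.
#' @return data.frame with columns `embryo_id`, `nucleus_id`, `x_um`,
#'   `y_um`, `z_um`, `psmad5_au`, one `fish_<gene>_au` column per gene,
#'   and the ground-truth angle columns.
#' @export
sample_embryo <- function(spec, gradient, genes = canonical_gene_truths(),
                          model = readout_model("threshold", genes),
                          exposure_minutes = 240, embryo_id = "embryo1") {
  stopifnot(inherits(spec, "embryo_spec"), inherits(gradient, "gradient_profile"),
            exposure_minutes >= 0)
  set.seed(spec$seed)
  n <- spec$n_nuclei
  # uniform on the cap: cos(phi) uniform over [cos(cap), 1]
  cosphi <- stats::runif(n, cos(spec$cap_extent_deg * pi / 180), 1)
  phi <- acos(cosphi)                       # polar angle from animal pole
  azim <- stats::runif(n, -pi, pi)          # signed azimuth from ventral meridian
  sinphi <- sin(phi)
  x <- spec$radius_um * sinphi * cos(azim)
  y <- spec$radius_um * sinphi * sin(azim)
  z <- spec$radius_um * cosphi
  dv <- abs(azim) * 180 / pi                # folded DV angle, 0 ventral
  phi_deg <- phi * 180 / pi
  av <- 100 * phi_deg / spec$cap_extent_deg * ifelse(dv <= 90, -1, 1)

  clip0 <- function(v) pmax(0, v)
  sig <- gradient_value(gradient, dv)
  out <- data.frame(
    embryo_id = embryo_id,
    nucleus_id = seq_len(n),
    x_um = x, y_um = y, z_um = z,
    psmad5_au = clip0(sig + stats::rnorm(n, 0, spec$noise_sd)),
    stringsAsFactors = FALSE)
  slope_mag <- abs(gradient_deriv(gradient, dv))
  for (gn in genes$gene) {
    on <- model_activates(model, gn, sig, slope_mag, exposure_minutes)
    out[[paste0("fish_", gn, "_au")]] <-
      clip0(spec$expression_amplitude * as.numeric(on) +
              stats::rnorm(n, 0, spec$noise_sd))
  }
  out$dv_true_deg <- dv
  out$av_true_deg <- av
  out$phi_true_deg <- phi_deg
  attr(out, "spec") <- spec
  out
}

#' Simulate a dissociated animal-cap cell assay
#'
#' Cells from bmp7-null animal caps carry no endogenous BMP signal; bathing
#' them in recombinant BMP2/7 exposes every cell to a spatially uniform
#' dose.  Per-cell pSmad5 is drawn from a dose-calibrated clipped normal
#' distribution: 20 ng/ml ~ N(75, 15) (recapitulating endogenous ventral
#' high signalling), 5 ng/ml ~ N(20, 8) (endogenous low), 0 ng/ml gives no
#' signal.  Gene expression is assigned cell-autonomously by the readout
#' model from each cell's pSmad5; exposure is treated as 120 minutes,
#' longer than every onset delay.
#'
#' @param dose_ng_per_ml 0, 5 or 20.
#' @param n_cells number of cells (>= 1).
#' @param genes a [gene_truth()] table.
#' @param model a [readout_model()]; the slope kind is rejected because a
#'   spatially uniform bath has no gradient slope to read.
#' @param seed integer seed.
#' @param noise_sd FISH/pSmad5 measurement noise sd, A.U. (default 0; the
#'   per-cell slide intensities are modelled as noiseless).
#' @return data.frame with `cell_id`, `psmad5_au` and `fish_<gene>_au`
#'   columns.
#' @export
simulate_dissociated_assay <- function(dose_ng_per_ml, n_cells = 2000,
                                       genes = canonical_gene_truths(),
                                       model = readout_model("threshold", genes),
                                       seed = 1L, noise_sd = 0) {
  if (!dose_ng_per_ml %in% c(0, 5, 20))
    stop("unsupported dose: ", dose_ng_per_ml, " (supported: 0, 5, 20 ng/ml)")
  stopifnot(n_cells >= 1, noise_sd >= 0)
  if (model$kind == "slope")
    stop("the slope readout model is undefined for dissociated cells: ",
         "a uniform bath exposes every cell to zero spatial gradient")
  set.seed(as.integer(seed))
  mu_sd <- switch(as.character(dose_ng_per_ml),
                  "0" = c(0, 0), "5" = c(20, 8), "20" = c(75, 15))
  ps <- pmax(0, stats::rnorm(n_cells, mu_sd[1], mu_sd[2]))
  out <- data.frame(cell_id = seq_len(n_cells),
                    psmad5_au = pmax(0, ps + stats::rnorm(n_cells, 0, noise_sd)))
  amp <- 100
  for (gn in genes$gene) {
    on <- model_activates(model, gn, ps, slope_mag = 0, exposure_minutes = 120)
    out[[paste0("fish_", gn, "_au")]] <-
      pmax(0, amp * as.numeric(on) + stats::rnorm(n_cells, 0, noise_sd))
  }
  out
}

#' Simulate a uniform BMP ligand pulse
#'
#' A bolus of BMP2/7 protein injected into a bmp7-null embryo exposes all
#' cells to a uniform signal of `pulse_level_au` for `pulse_minutes`.
#' Under the threshold model a gene is expressed iff the pulse level
#' reaches its threshold and the pulse outlasts its onset delay; under the
#' duration model iff the level reaches the common minimal level and the
#' pulse outlasts the gene's required duration.  The slope model is
#' rejected: a spatially uniform exposure has no gradient slope.
#'
#' @param pulse_level_au uniform pSmad5 level, A.U. (>= 0).
#' @param pulse_minutes pulse duration, minutes (>= 0).
#' @param genes a [gene_truth()] table.
#' @param model a [readout_model()].
#' @return data.frame with columns `gene`, `expressed` (logical).
#' @export
simulate_pulse_experiment <- function(pulse_level_au, pulse_minutes,
                                      genes = canonical_gene_truths(),
                                      model = readout_model("threshold", genes)) {
  stopifnot(pulse_level_au >= 0, pulse_minutes >= 0)
  if (model$kind == "slope")
    stop("the slope readout model is undefined for a spatially uniform ",
         "pulse: there is no gradient slope to read")
  expressed <- vapply(genes$gene, function(gn)
    model_activates(model, gn, pulse_level_au, slope_mag = 0,
                    exposure_minutes = pulse_minutes),
    logical(1))
  data.frame(gene = genes$gene, expressed = unname(expressed),
             stringsAsFactors = FALSE)
}
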