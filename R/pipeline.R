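#' Simulate a cohort of embryos
#'
#' Generates `n_embryos` independent synthetic embryos from one genotype's
#' canonical gradient under a readout model, with per-embryo seeds
#' `seed_base + 1 .. seed_base + n_embryos`.
#'
#' @param genotype canonical genotype label (see
#'   [make_canonical_gradient()]).
#' @param n_embryos cohort size.
#' @param seed_base seed offset; embryo i uses `seed_base + i`.
#' @param genes a [gene_truth()] table.
#' @param model a [readout_model()].
#' @param exposure_minutes exposure at fixation.
#' @param spec_args named list overriding [embryo_spec()] defaults.
#' @return list of nuclei tables.
#' @export
simulate_cohort <- function(genotype = "wild_type", n_embryos = 20,
                            seed_base = 0L, genes = canonical_gene_truths(),
                            model = readout_model("threshold", genes),
                            exposure_minutes = 240, spec_args = list()) {
  gradient <- make_canonical_gradient(genotype)
  lapply(seq_len(n_embryos), function(i) {
    spec <- do.call(embryo_spec, c(spec_args, list(seed = seed_base + i)))
    sample_embryo(spec, gradient, genes, model, exposure_minutes,
                  embryo_id = sprintf("%s_%03d", genotype, i))
  })
}

#' Pooled cohort DV profile
#'
#' Pools all nuclei of a cohort into one censoring-corrected, smoothed DV
#' profile; angular coordinates are assigned per embryo by the standard
#' registration (sphere fit plus ventral-pole estimate) unless already
#' present.
#'
#' @param embryos list of nuclei tables.
#' @param channel intensity column.
#' @param bin_width_deg bin width, degrees.
#' @param smoothing_fraction loess span.
#' @param animal_direction animal axis.
#' @param use_truth use generator ground-truth angles.
#' @return A smoothed `angular_profile`.
#' @export
cohort_dv_profile <- function(embryos, channel = "psmad5_au",
                              bin_width_deg = 2, smoothing_fraction = 0.2,
                              animal_direction = c(0, 0, 1),
                              use_truth = FALSE) {
  registered <- lapply(embryos, function(e) {
    if (use_truth) return(use_true_angles(e))
    if ("dv_deg" %in% names(e)) return(e)
    sph <- fit_sphere(e)
    pole <- estimate_ventral_pole(e, sph, animal_direction)
    if (!pole$orientable) stop("unorientable embryo in cohort")
    assign_angles(e, sph, pole$direction, animal_direction)
  })
  smooth_and_slope(dv_profile(registered, channel, bin_width_deg),
                   smoothing_fraction)
}
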