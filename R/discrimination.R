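#' Compare boundary readouts between genotypes
#'
#' For each gene, runs Welch two-sample t-tests on per-embryo pSmad5
#' levels and slope magnitudes at the expression boundary across the two
#' genotypes, and computes relative deviations of the cohort means:
#' `rho_level = |L_wt - L_mut| / L_wt`, and likewise `rho_slope`.  The
#' threshold (concentration) model is supported when every gene's level
#' deviation is at most `rho_cutoff`; the slope model when every gene's
#' slope deviation is, and (if a profile is supplied) the boundary slope
#' value identifies a unique DV position.
#'
#' The `rho_cutoff` of 0.15 quantifies "similar readout"; it is a package
#' convention, reported in every verdict.
#'
#' @param calls_wt,calls_mut boundary-call tables ([quantify_cohort()]),
#'   at least 3 embryos per genotype per gene.
#' @param rho_cutoff maximum relative deviation for a readout to count as
#'   conserved.
#' @param psmad5_profile optional smoothed wild-type pSmad5 profile used
#'   for the slope positional-ambiguity check.
#' @return Object of class `model_verdict`: per-gene table plus
#'   `threshold_supported` / `slope_supported` flags.
#' @export
compare_genotypes <- function(calls_wt, calls_mut, rho_cutoff = 0.15,
                              psmad5_profile = NULL) {
  genes <- intersect(unique(calls_wt$gene), unique(calls_mut$gene))
  if (length(genes) == 0) stop("no genes shared between the two cohorts")
  per_gene <- lapply(genes, function(gn) {
    w <- calls_wt[calls_wt$gene == gn & !is.na(calls_wt$level_au), ]
    m <- calls_mut[calls_mut$gene == gn & !is.na(calls_mut$level_au), ]
    if (nrow(w) < 3 || nrow(m) < 3)
      stop("need >= 3 embryos per genotype for gene ", gn)
    rho <- function(a, b) abs(mean(a) - mean(b)) / mean(a)
    amb <- if (!is.null(psmad5_profile))
      slope_positions(psmad5_profile, mean(w$slope_au_per_deg)) >= 2
    else NA
    data.frame(
      gene = gn,
      level_wt = mean(w$level_au), level_mut = mean(m$level_au),
      slope_wt = mean(w$slope_au_per_deg), slope_mut = mean(m$slope_au_per_deg),
      rho_level = rho(w$level_au, m$level_au),
      rho_slope = rho(w$slope_au_per_deg, m$slope_au_per_deg),
      p_level = stats::t.test(w$level_au, m$level_au)$p.value,
      p_slope = stats::t.test(w$slope_au_per_deg, m$slope_au_per_deg)$p.value,
      slope_ambiguous = amb,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_gene)
  structure(list(
    per_gene = tab,
    rho_cutoff = rho_cutoff,
    threshold_supported = all(tab$rho_level <= rho_cutoff),
    slope_supported = all(tab$rho_slope <= rho_cutoff) &&
      !isTRUE(any(tab$slope_ambiguous))),
    class = "model_verdict")
}

#' Count DV positions sharing a slope value
#'
#' How many distinct angular positions on a smoothed profile carry the
#' given slope magnitude (within crossings of the slope curve)?  Two or
#' more positions mean the slope value cannot by itself encode position.
#'
#' @param profile a smoothed `angular_profile` with `slope_au_per_deg`.
#' @param slope_value slope magnitude, A.U./degree.
#' @return Integer count of crossings.
#' @export
slope_positions <- function(profile, slope_value) {
  ok <- !is.na(profile$slope_au_per_deg)
  s <- profile$slope_au_per_deg[ok]
  d <- s - slope_value
  sum(d[-length(d)] * d[-1] < 0 | d[-length(d)] == 0)
}

#' Test the duration model with uniform ligand pulses
#'
#' Endogenous patterning exposes cells to roughly 4 hours of BMP
#' signalling.  If a brief high-level pulse (<= `short_pulse_min`)
#' activates every target gene, gene-specific signal durations cannot be
#' what distinguishes the targets, and the duration model is rejected.
#' Expression order across pulse lengths is also compared with the onset
#' delays.
#'
#' @param pulse_results data.frame with columns `gene`, `pulse_minutes`,
#'   `expressed` for two or more pulse lengths.
#' @param onsets a [gene_truth()] table supplying onset delays.
#' @param short_pulse_min pulse length far below endogenous exposure
#'   (default 30 minutes).
#' @return list with `duration_rejected`, `all_on_at_short`,
#'   `order_follows_onsets` and the earliest expressing pulse per gene.
#' @export
duration_test <- function(pulse_results, onsets, short_pulse_min = 30) {
  if (length(unique(pulse_results$pulse_minutes)) < 2)
    stop("need results for at least 2 pulse lengths")
  short <- pulse_results[pulse_results$pulse_minutes <= short_pulse_min, ]
  all_on <- length(unique(short$gene[short$expressed])) ==
    length(unique(pulse_results$gene))
  first_on <- stats::aggregate(
    pulse_minutes ~ gene, data = pulse_results[pulse_results$expressed, ],
    FUN = min)
  names(first_on)[2] <- "first_pulse_min"
  ord <- merge(first_on, onsets[, c("gene", "onset_min")], by = "gene")
  order_ok <- !is.unsorted(ord$first_pulse_min[order(ord$onset_min)])
  list(duration_rejected = all_on, all_on_at_short = all_on,
       order_follows_onsets = order_ok, first_expressing_pulse = first_on)
}

#' Test the threshold model with uniform-concentration assays
#'
#' Compares, per gene and dose, the fraction of cells expressing the gene
#' (FISH above 10% of the experiment-wide maximum) with the fraction of
#' cells above the gene's predicted pSmad5 threshold.  The threshold
#' model is supported when the two fractions agree within `agreement` at
#' every dose and the high-threshold gene stays off at the low dose
#' despite the long (2-hour) exposure.
#'
#' @param assay_low,assay_high [simulate_dissociated_assay()] tables for
#'   the low and high dose.
#' @param truths a [gene_truth()] table.
#' @param agreement maximum allowed |expressing - above-threshold|
#'   difference (default 0.05).
#' @param off_fraction maximum expressing fraction that still counts as
#'   "off" (default 0.05).
#' @return list with the per-gene/per-dose table and
#'   `threshold_supported`.
#' @export
concentration_test <- function(assay_low, assay_high, truths,
                               agreement = 0.05, off_fraction = 0.05) {
  rows <- list()
  for (gn in truths$gene) {
    ch <- paste0("fish_", gn, "_au")
    if (!ch %in% names(assay_low)) next
    ref_max <- max(assay_low[[ch]], assay_high[[ch]])
    thr <- truths$threshold_au[truths$gene == gn]
    for (dose in c("low", "high")) {
      cells <- if (dose == "low") assay_low else assay_high
      ef <- expressing_fraction(cells, ch, reference_max = ref_max)
      af <- above_threshold_fraction(cells, thr)
      rows[[paste(gn, dose)]] <- data.frame(
        gene = gn, dose = dose, expressing = ef, above_threshold = af,
        agree = abs(ef - af) <= agreement, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  hi_gene <- truths$gene[which.max(truths$threshold_au)]
  hi_off_low <- tab$expressing[tab$gene == hi_gene & tab$dose == "low"] <= off_fraction
  structure(list(per_dose = tab,
                 high_threshold_gene = hi_gene,
                 high_gene_off_at_low_dose = isTRUE(hi_off_low),
                 threshold_supported = all(tab$agree) && isTRUE(hi_off_low)),
            class = "concentration_verdict")
}

#' One-way ANOVA across gene boundary positions
#'
#' Tests whether the expression domains of different genes end at
#' distinct DV positions.
#'
#' @param calls boundary-call table with `gene` and `boundary_deg`.
#' @return The ANOVA p-value.
#' @export
anova_boundaries <- function(calls) {
  ok <- calls[!is.na(calls$boundary_deg), ]
  counts <- table(ok$gene)
  if (length(counts) < 2) stop("need boundary calls for at least 2 genes")
  if (any(counts < 2))
    stop("need at least 2 embryos per gene (got: ",
         paste(names(counts), counts, sep = "=", collapse = ", "), ")")
  fit <- stats::aov(boundary_deg ~ gene, data = ok)
  summary(fit)[[1]][["Pr(>F)"]][1]
}

#' @export
print.model_verdict <- function(x, ...) {
  cat("<model_verdict>  (relative-deviation cutoff", x$rho_cutoff, ")\n")
  print(x$per_gene, row.names = FALSE, digits = 3)
  cat("threshold model supported:", x$threshold_supported, "\n")
  cat("slope model supported:    ", x$slope_supported, "\n")
  invisible(x)
}

#' Combined three-experiment verdict
#'
#' Merges the genotype-reshape comparison, the pulse-duration test and the
#' uniform-concentration test into a single per-model support table: the
#' threshold model must pass all three experiments; the slope model the
#' reshape comparison (including positional uniqueness); the duration
#' model the pulse test.
#'
#' @param genotype_verdict a [compare_genotypes()] result.
#' @param duration_verdict a [duration_test()] result (or `NULL`).
#' @param concentration_verdict a [concentration_test()] result (or
#'   `NULL`).
#' @return list of class `discrimination_verdict` with `supported`
#'   (named logical for threshold/slope/duration) and `partial` (TRUE
#'   when an experiment was missing).
#' @export
discriminate_models <- function(genotype_verdict, duration_verdict = NULL,
                                concentration_verdict = NULL) {
  partial <- is.null(duration_verdict) || is.null(concentration_verdict)
  thr <- genotype_verdict$threshold_supported &&
    (is.null(concentration_verdict) || concentration_verdict$threshold_supported)
  dur <- if (is.null(duration_verdict)) NA else !duration_verdict$duration_rejected
  structure(list(
    supported = c(threshold = thr,
                  slope = genotype_verdict$slope_supported,
                  duration = dur),
    partial = partial,
    genotype = genotype_verdict,
    duration = duration_verdict,
    concentration = concentration_verdict),
    class = "discrimination_verdict")
}

#' @export
print.discrimination_verdict <- function(x, ...) {
  cat("<discrimination_verdict>", if (x$partial) "(partial)" else "", "\n")
  for (m in names(x$supported))
    cat(sprintf("  %-10s %s\n", m,
                if (is.na(x$supported[m])) "not tested"
                else if (x$supported[m]) "SUPPORTED" else "rejected"))
  invisible(x)
}
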