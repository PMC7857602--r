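#' Gene activation ground truths
#'
#' Per-gene parameters used by the synthetic generator: the pSmad5
#' activation threshold (A.U.) and the transcriptional onset delay
#' (minutes after the start of BMP exposure before transcripts are
#' detectable).
#'
#' @param gene character vector of gene names.
#' @param threshold_au activation thresholds, A.U. (> 0).
#' @param onset_min onset delays, minutes (>= 0).
#' @return data.frame with columns `gene`, `threshold_au`, `onset_min`.
#' @export
gene_truth <- function(gene, threshold_au, onset_min) {
  stopifnot(length(gene) == length(threshold_au),
            length(gene) == length(onset_min))
  if (any(threshold_au <= 0)) stop("thresholds must be > 0")
  if (any(onset_min < 0)) stop("onset delays must be >= 0")
  data.frame(gene = as.character(gene), threshold_au = threshold_au,
             onset_min = onset_min, stringsAsFactors = FALSE)
}

#' Canonical gene truths
#'
#' The four BMP target genes used throughout: sizzled (high threshold,
#' 60 A.U., expressed within 10 minutes), foxi1 (25 A.U., 20 minutes),
#' bambia (low threshold, 7 A.U., 30 minutes) and ved (7 A.U., rapidly
#' activated, taken as 10 minutes).
#'
#' @return data.frame as from [gene_truth()].
#' @export
canonical_gene_truths <- function() {
  gene_truth(gene = c("sizzled", "foxi1", "bambia", "ved"),
             threshold_au = c(60, 25, 7, 7),
             onset_min = c(10, 20, 30, 10))
}

#' Gradient interpretation (readout) models
#'
#' A readout model maps a cell's signal history to a binary expression
#' decision for each gene:
#' \describe{
#'   \item{threshold}{express when local pSmad5 exceeds a gene-specific
#'     concentration threshold (and exposure has lasted at least the
#'     gene's onset delay).}
#'   \item{slope}{express when the local spatial derivative magnitude of
#'     the gradient exceeds a gene-specific criterion (A.U./degree).}
#'   \item{duration}{express when exposure above a common minimal level
#'     has lasted at least a gene-specific duration.}
#' }
#'
#' @param kind `"threshold"`, `"slope"` or `"duration"`.
#' @param genes a [gene_truth()] table; supplies thresholds and onsets.
#' @param slope_criterion named numeric, A.U./degree per gene (slope kind).
#' @param required_duration named numeric, minutes per gene (duration kind).
#' @param minimal_level_au common minimal signal level for the duration
#'   kind, A.U.; defaults to the lowest gene threshold.
#' @return An object of class `readout_model`.
#' @export
readout_model <- function(kind = c("threshold", "slope", "duration"),
                          genes = canonical_gene_truths(),
                          slope_criterion = NULL,
                          required_duration = NULL,
                          minimal_level_au = min(genes$threshold_au)) {
  kind <- match.arg(kind)
  if (kind == "slope") {
    if (is.null(slope_criterion) || is.null(names(slope_criterion)))
      stop("slope kind needs a named slope_criterion vector")
    if (any(slope_criterion <= 0)) stop("slope criteria must be > 0")
  }
  if (kind == "duration") {
    if (is.null(required_duration) || is.null(names(required_duration)))
      stop("duration kind needs a named required_duration vector")
    if (any(required_duration <= 0)) stop("required durations must be > 0")
    if (minimal_level_au <= 0) stop("minimal_level_au must be > 0")
  }
  structure(list(kind = kind, genes = genes,
                 slope_criterion = slope_criterion,
                 required_duration = required_duration,
                 minimal_level_au = minimal_level_au),
            class = "readout_model")
}

# per-gene parameter lookup with a clear error when a gene is missing
model_param <- function(model, gene, what) {
  v <- switch(what,
    threshold = stats::setNames(model$genes$threshold_au, model$genes$gene)[gene],
    onset = stats::setNames(model$genes$onset_min, model$genes$gene)[gene],
    slope = model$slope_criterion[gene],
    duration = model$required_duration[gene])
  if (any(is.na(v)))
    stop("no ", what, " parameter for gene(s): ",
         paste(gene[is.na(v)], collapse = ", "))
  unname(v)
}

# does the model activate `gene` at positions with the given local signal
# value/slope after `exposure_minutes` of exposure?  Vectorised over cells.
model_activates <- function(model, gene, value_au, slope_mag, exposure_minutes) {
  switch(model$kind,
    threshold = value_au >= model_param(model, gene, "threshold") &
      exposure_minutes >= model_param(model, gene, "onset"),
    slope = slope_mag >= model_param(model, gene, "slope") &
      exposure_minutes >= model_param(model, gene, "onset"),
    duration = value_au >= model$minimal_level_au &
      exposure_minutes >= model_param(model, gene, "duration"))
}

#' @export
print.readout_model <- function(x, ...) {
  cat("<readout_model>", x$kind, "kind;", nrow(x$genes), "genes\n")
  invisible(x)
}
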