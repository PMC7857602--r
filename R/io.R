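#' Write and read nuclei tables
#'
#' Nuclei tables are comma-separated text with header columns
#' `embryo_id, nucleus_id, x_um, y_um, z_um, psmad5_au`, then one
#' `fish_<gene>_au` column per gene.  A comment line records the seed and
#' configuration hash for reproducibility.
#'
#' @param nuclei a nuclei data.frame.
#' @param path output file.
#' @param keep_truth also write the generator's ground-truth angle
#'   columns (default `FALSE`).
#' @param seed,config_hash provenance recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_nuclei <- function(nuclei, path, keep_truth = FALSE, seed = NULL,
                         config_hash = NULL) {
  cols <- c("embryo_id", "nucleus_id", "x_um", "y_um", "z_um", "psmad5_au",
            grep("^fish_.*_au$", names(nuclei), value = TRUE))
  if (keep_truth)
    cols <- c(cols, intersect(c("dv_true_deg", "av_true_deg", "phi_true_deg"),
                              names(nuclei)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# bmpgrad nuclei table",
                    if (!is.null(seed)) paste0(" seed=", seed),
                    if (!is.null(config_hash)) paste0(" config=", config_hash)),
             con)
  utils::write.csv(nuclei[, cols], con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nuclei
#' @param required columns that must be present when reading.
#' @export
read_nuclei <- function(path, required = c("embryo_id", "nucleus_id", "x_um",
                                           "y_um", "z_um", "psmad5_au")) {
  out <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(out))
  if (length(missing))
    stop("nuclei table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(out) == 0) stop("nuclei table ", path, " is empty")
  known <- c(required, grep("^fish_.*_au$", names(out), value = TRUE),
             "dv_true_deg", "av_true_deg", "phi_true_deg",
             "dv_deg", "av_deg", "phi_deg", "azimuth_deg", "gc_offset_um")
  extra <- setdiff(names(out), known)
  if (length(extra))
    message("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  out
}

#' Write an angular profile as delimited text
#'
#' Columns: `angle_deg, mean_au, n, smoothed_au, slope_au_per_deg`.
#'
#' @param profile an `angular_profile`.
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  cols <- intersect(c("angle_deg", "mean_au", "n", "smoothed_au",
                      "slope_au_per_deg"), names(profile))
  utils::write.csv(as.data.frame(profile)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write boundary calls as delimited text
#'
#' @param calls a boundary-call table.
#' @param path output file.
#' @export
write_boundary_calls <- function(calls, path) {
  utils::write.csv(calls, path, row.names = FALSE)
  invisible(path)
}

#' Export / import a gradient profile as key/value text
#'
#' Plain-text format: a `genotype` line followed by one `anchor` line per
#' anchor (`anchor <angle> <value> <derivative>`).
#'
#' @param profile a [gradient_profile()].
#' @param path file path.
#' @export
write_gradient_config <- function(profile, path) {
  a <- profile$anchors
  writeLines(c(paste("genotype", profile$genotype),
               sprintf("anchor %.10g %.10g %.10g",
                       a$angle_deg, a$value_au, a$deriv_au_per_deg)),
             path)
  invisible(path)
}

#' @rdname write_gradient_config
#' @export
read_gradient_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  toks <- strsplit(trimws(lines), "\\s+")
  genotype <- "custom"
  anchors <- list()
  for (tk in toks) {
    if (tk[1] == "genotype") genotype <- tk[2]
    else if (tk[1] == "anchor")
      anchors[[length(anchors) + 1]] <- as.numeric(tk[2:4])
  }
  if (!length(anchors)) stop("no anchor lines in ", path)
  m <- do.call(rbind, anchors)
  gradient_profile(data.frame(angle_deg = m[, 1], value_au = m[, 2],
                              deriv_au_per_deg = m[, 3]),
                   genotype = genotype)
}

#' Export / import gene truths as key/value text
#'
#' One line per gene: `gene <name> <threshold_au> <onset_min>`.
#'
#' @param truths a [gene_truth()] table.
#' @param path file path.
#' @export
write_gene_config <- function(truths, path) {
  writeLines(sprintf("gene %s %.10g %.10g", truths$gene,
                     truths$threshold_au, truths$onset_min), path)
  invisible(path)
}

#' @rdname write_gene_config
#' @export
read_gene_config <- function(path) {
  lines <- readLines(path)
  toks <- strsplit(trimws(lines[nzchar(trimws(lines))]), "\\s+")
  toks <- Filter(function(tk) tk[1] == "gene", toks)
  if (!length(toks)) stop("no gene lines in ", path)
  gene_truth(vapply(toks, `[`, "", 2),
             as.numeric(vapply(toks, `[`, "", 3)),
             as.numeric(vapply(toks, `[`, "", 4)))
}

#' Read a run configuration
#'
#' Plain-text `key = value` lines; `#` comments allowed.  Unknown keys are
#' kept verbatim.
#'
#' @param path file path.
#' @return Named list of values (numeric where possible).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- list()
  for (p in kv) {
    if (length(p) != 2) stop("malformed config line: ", paste(p, collapse = "="))
    v <- suppressWarnings(as.numeric(p[2]))
    out[[trimws(p[1])]] <- if (is.na(v)) trimws(p[2]) else v
  }
  out
}

config_hash <- function(x) {
  # small stable hash of a configuration list for output provenance
  s <- paste(deparse(x[order(names(unlist(x)))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}
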