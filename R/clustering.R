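#' DV positions where a gene is expressed
#'
#' A gene counts as expressed in a DV bin when the summed expression
#' intensity there exceeds the cutoff (0.5 A.U. of predicted expression
#' by default).
#'
#' @param dv_profile numeric length-8 vector: summed expression per DV
#'   position (see [grid_heatmap()]).
#' @param cutoff expression cutoff, A.U.
#' @return Integer vector of expressed DV positions (subset of 1..8).
#' @export
expressed_bins <- function(dv_profile, cutoff = 0.5) {
  if (length(dv_profile) != 8)
    stop("dv_profile must have exactly 8 values (got ", length(dv_profile), ")")
  which(dv_profile > cutoff)
}

#' Assign a gene to a DV expression cluster
#'
#' Cluster 1: expression confined to the first 4 DV positions (ventral);
#' cluster 2: extends into position 5; cluster 3: extends into positions
#' 6-7; cluster 4: reaches the dorsal-most position, is empty, or is
#' dorsally enriched.
#'
#' @param bins integer vector of expressed DV positions (from
#'   [expressed_bins()]).
#' @param dorsal_enrichment logical: more expression in positions 5-8 than
#'   1-4 (routes to cluster 4).
#' @return Integer cluster id in 1..4.
#' @export
assign_cluster <- function(bins, dorsal_enrichment = FALSE) {
  stopifnot(all(bins %in% 1:8))
  if (dorsal_enrichment || length(bins) == 0 || 8 %in% bins) return(4L)
  top <- max(bins)
  if (top <= 4) 1L else if (top == 5) 2L else 3L
}

#' Cluster a gene from its 8x8 heat map
#'
#' Convenience wrapper: computes expressed bins and dorsal enrichment from
#' a [grid_heatmap()] and assigns the cluster.
#'
#' @param heatmap a `grid_heatmap`.
#' @param cutoff expression cutoff, A.U.
#' @return list with `gene`, `expressed_bins`, `dorsal_enrichment`,
#'   `cluster`.
#' @export
cluster_gene <- function(heatmap, cutoff = 0.5) {
  dvp <- heatmap$dv_profile
  bins <- expressed_bins(dvp, cutoff)
  dorsal <- sum(dvp[5:8]) > sum(dvp[1:4])
  list(gene = heatmap$gene, expressed_bins = bins,
       dorsal_enrichment = dorsal,
       cluster = assign_cluster(bins, dorsal))
}
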