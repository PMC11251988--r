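#' Pipeline configuration
#'
#' Bundles every tunable threshold of the integration workflow. Defaults
#' follow the published analysis settings for mouse-brain Visium + MALDI-MSI
#' sections; each can be overridden per call.
#'
#' @param minGenesPerSpot spots with fewer unique (detected) genes are
#'   removed during QC (default 50).
#' @param maxMitoFrac spots whose mitochondrial count fraction exceeds this
#'   are removed (default 0.38).
#' @param knnK number of candidate RNA-spot neighbours examined per MSI
#'   pixel during pairing (default 5).
#' @param maxPairDistPx pairing distance cutoff in common-frame pixels
#'   (default 35). The frame is whatever the positions file supplies —
#'   full-resolution histology pixels by convention.
#' @param fdrThreshold Benjamini-Hochberg q-value cutoff for the
#'   correlation screen (default 0.01).
#' @param nHVG number of highly variable genes (default 2000).
#' @param nPCs principal components for the joint co-embedding (default 30).
#' @param knnPeaks gene neighbours retained per peak in the cosine-kNN
#'   graph (default 10).
#' @param log2fcMin marker log2 fold-change threshold, strict (default 0.25).
#' @param padjMax marker adjusted-p threshold, strict (default 0.01).
#' @param seed integer seed for the stochastic steps (spinglass annealing).
#' @return a `PipelineConfig` object (validated list).
#' @examples
#' cfg <- pipelineConfig(maxPairDistPx = 50)
#' cfg$knn_k
#' @export
pipelineConfig <- function(minGenesPerSpot = 50L, maxMitoFrac = 0.38,
                           knnK = 5L, maxPairDistPx = 35,
                           fdrThreshold = 0.01, nHVG = 2000L, nPCs = 30L,
                           knnPeaks = 10L, log2fcMin = 0.25, padjMax = 0.01,
                           seed = 1L) {
  cfg <- list(
    min_genes_per_spot = as.integer(minGenesPerSpot),
    max_mito_frac = maxMitoFrac,
    knn_k = as.integer(knnK),
    max_pair_dist_px = maxPairDistPx,
    fdr_threshold = fdrThreshold,
    n_hvg = as.integer(nHVG),
    n_pcs = as.integer(nPCs),
    knn_peaks = as.integer(knnPeaks),
    log2fc_min = log2fcMin,
    padj_max = padjMax,
    seed = as.integer(seed)
  )
  pos <- c("min_genes_per_spot", "knn_k", "max_pair_dist_px", "fdr_threshold",
           "n_hvg", "n_pcs", "knn_peaks", "log2fc_min", "padj_max")
  bad <- pos[vapply(cfg[pos], function(v) !is.finite(v) || v <= 0, logical(1))]
  if (length(bad))
    stop("configuration values must be positive: ", paste(bad, collapse = ", "))
  if (cfg$max_mito_frac <= 0 || cfg$max_mito_frac >= 1)
    stop("max_mito_frac must lie strictly between 0 and 1")
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("PipelineConfig:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
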