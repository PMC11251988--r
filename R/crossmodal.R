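#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: with m p-values sorted ascending,
#' `q_(i) = min_{j >= i} (m * p_(j) / j)` capped at 1, returned in the input
#' order. Thin validated front-end over `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))   # all 0.04
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] with no NAs", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Metabolite-to-gene correlation screen
#'
#' Pearson correlation between one peak's intensity vector and every
#' retained gene's normalised expression across the paired observations.
#' Two-sided p-values come from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom
#' (observations treated as independent; spatial autocorrelation is not
#' corrected for — see the vignette), and q-values from [bhAdjust()] over
#' all tested genes. Genes with constant expression are recorded with
#' r = 0 and p = 1 so the table covers every retained gene.
#'
#' @param mm a [MultimodalDataset-class] with >= 10 observations.
#' @param peakMz m/z of the peak to screen; matched to the nearest stored
#'   peak within 1e-3 Da.
#' @param cfg a [pipelineConfig()]; `fdr_threshold` defines significance.
#' @param logPeak correlate against `log1p` peak intensities instead of raw
#'   (default `FALSE`).
#' @return data.frame (one row per gene, sorted by descending r) with
#'   columns `peak_mz`, `gene`, `r`, `pval`, `qval`, `significant`.
#' @export
peakGeneCorrelation <- function(mm, peakMz, cfg = pipelineConfig(),
                                logPeak = FALSE) {
  n <- ncol(mm)
  if (n < 10) stop("need >= 10 paired observations (got ", n, ")", call. = FALSE)
  mz <- rowData(altExp(mm, "peaks"))$mz
  d <- abs(mz - peakMz)
  if (min(d) > 1e-3) {
    near <- sort(mz[order(d)][1:min(3, length(mz))])
    stop(sprintf("no peak within 1e-3 Da of %.4f; nearest: %s", peakMz,
                 paste(sprintf("%.4f", near), collapse = ", ")), call. = FALSE)
  }
  pi <- which.min(d)
  pv <- assay(altExp(mm, "peaks"), "intensities")[pi, ]
  if (logPeak) pv <- log1p(pv)
  if (stats::sd(pv) == 0)
    stop("peak intensity vector is constant; correlation undefined",
         call. = FALSE)
  expr <- assay(mm, "logcounts")
  genes <- rownames(mm)

  sds <- apply(expr, 1, stats::sd)
  const <- sds == 0
  r <- rep(0, length(genes))
  if (any(!const))
    r[!const] <- as.vector(stats::cor(pv, t(expr[!const, , drop = FALSE])))
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[const] <- 1
  p <- pmin(p, 1)
  q <- bhAdjust(p)
  out <- data.frame(peak_mz = mz[pi], gene = genes, r = r, pval = p, qval = q,
                    significant = q < cfg$fdr_threshold, row.names = NULL)
  out[order(-out$r, out$gene), ]
}

#' Top correlated genes
#'
#' The n most strongly correlated significant genes from a
#' [peakGeneCorrelation()] table, in the requested direction.
#'
#' @param table output of [peakGeneCorrelation()].
#' @param n number of genes to return (fewer if fewer are significant).
#' @param direction `"positive"` (largest r) or `"negative"` (smallest r).
#' @return character vector of gene identifiers.
#' @export
topCorrelatedGenes <- function(table, n, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (nrow(table) == 0) stop("empty correlation table", call. = FALSE)
  sig <- table[table$significant, , drop = FALSE]
  if (nrow(sig) == 0) return(character(0))
  ord <- if (direction == "positive") order(-sig$r, sig$gene)
         else order(sig$r, sig$gene)
  utils::head(sig$gene[ord], n)
}
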