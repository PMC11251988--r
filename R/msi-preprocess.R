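#' Mean spectrum of an MSI raster
#'
#' Arithmetic mean intensity per peak over the selected pixels — the summary
#' used for section-to-section concordance checks.
#'
#' @param raster an [MSIRaster-class].
#' @param tissueOnly if `TRUE`, average over on-tissue pixels only; uses the
#'   stored `off_tissue` flags, computing them via [flagOfftissue()] first if
#'   absent.
#' @return a [MeanSpectrum-class].
#' @export
meanSpectrum <- function(raster, tissueOnly = FALSE) {
  if (ncol(raster) == 0) stop("raster has no pixels", call. = FALSE)
  sel <- rep(TRUE, ncol(raster))
  if (tissueOnly) {
    if (is.null(offTissue(raster))) raster <- flagOfftissue(raster)
    sel <- !offTissue(raster)
  }
  if (!any(sel)) stop("no pixels selected for the mean spectrum", call. = FALSE)
  new("MeanSpectrum", mz = mzValues(raster),
      mean_intensity = rowMeans(assay(raster, "intensities")[, sel, drop = FALSE]),
      n_pixels = sum(sel))
}

#' Concordance of two mean spectra
#'
#' Pearson correlation of `log10(1 + mean intensity)` between two spectra on
#' the same m/z axis — the molecule-side replicate concordance statistic.
#'
#' @param a,b [MeanSpectrum-class] objects with m/z axes agreeing within
#'   1e-4 Da peak by peak.
#' @return Pearson r in \[-1, 1\].
#' @export
spectrumCorrelation <- function(a, b) {
  if (length(a@mz) != length(b@mz))
    stop("spectra have different numbers of peaks (", length(a@mz), " vs ",
         length(b@mz), ")", call. = FALSE)
  d <- abs(a@mz - b@mz)
  if (any(d > 1e-4)) {
    i <- which(d > 1e-4)[1]
    stop(sprintf("m/z axes disagree, first at peak %d: %.4f vs %.4f", i,
                 a@mz[i], b@mz[i]), call. = FALSE)
  }
  if (identical(unname(a@mean_intensity), unname(b@mean_intensity)))
    return(1)                     # self-comparison is exact, not 1 - 1e-16
  r <- stats::cor(log10(1 + a@mean_intensity), log10(1 + b@mean_intensity))
  min(1, max(-1, r))
}

#' Flag off-tissue MSI pixels
#'
#' Pixels lying outside the tissue section carry near-zero, matrix-only
#' signal and separate from tissue pixels on the first principal component
#' of their (log-transformed) spectra. Procedure: PCA on centred
#' `log10(1 + intensity)` pixel profiles; split PC1 scores by 2-means
#' (initialised at the score extremes, hence deterministic); flag the
#' cluster with the lower mean total raw intensity as off-tissue.
#'
#' @param raster an [MSIRaster-class] with >= 10 pixels and >= 2 peaks.
#' @param pc1Threshold optional manual override: a PC1 score cutoff used
#'   instead of 2-means (the lower-intensity side is still the one flagged).
#' @return the raster with a logical `off_tissue` column added to its
#'   `colData` (retrieve with `offTissue()`). If all pixels are identical
#'   the split is degenerate: none are flagged, with a warning.
#' @export
flagOfftissue <- function(raster, pc1Threshold = NULL) {
  if (ncol(raster) < 10) stop("need >= 10 pixels", call. = FALSE)
  if (nrow(raster) < 2) stop("need >= 2 peaks", call. = FALSE)
  intens <- assay(raster, "intensities")
  L <- t(log10(1 + intens))              # pixels x peaks
  Lc <- sweep(L, 2, colMeans(L))
  if (all(abs(Lc) < 1e-12)) {
    warning("all pixels identical; flagging none as off-tissue")
    colData(raster)$off_tissue <- rep(FALSE, ncol(raster))
    return(raster)
  }
  pc1 <- stats::prcomp(L, center = TRUE, scale. = FALSE, rank. = 1)$x[, 1]
  if (is.null(pc1Threshold)) {
    km <- stats::kmeans(pc1, centers = matrix(c(min(pc1), max(pc1)), 2, 1))
    grp <- km$cluster
  } else {
    grp <- ifelse(pc1 > pc1Threshold, 2L, 1L)
    if (length(unique(grp)) == 1) {
      warning("pc1Threshold splits off no pixels; flagging none")
      colData(raster)$off_tissue <- rep(FALSE, ncol(raster))
      return(raster)
    }
  }
  tot <- colSums(intens)
  meanTot <- tapply(tot, grp, mean)
  flagged <- grp == as.integer(names(which.min(meanTot)))
  colData(raster)$off_tissue <- unname(flagged)
  raster
}

#' TIC-normalise an MSI raster
#'
#' Optional total-ion-current normalisation: scales every pixel spectrum to
#' the mean TIC of the raster. Off by default throughout the pipeline since
#' vendor-exported peak matrices are typically already normalised.
#'
#' @param raster an [MSIRaster-class].
#' @return the raster with rescaled intensities.
#' @export
normalizeTIC <- function(raster) {
  intens <- assay(raster, "intensities")
  tic <- colSums(intens)
  if (any(tic == 0))
    stop("pixel(s) with zero total ion current: ",
         paste(utils::head(which(tic == 0), 3), collapse = ", "), call. = FALSE)
  assays(raster)$intensities <- sweep(intens, 2, mean(tic) / tic, `*`)
  raster
}
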