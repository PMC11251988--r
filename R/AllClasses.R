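#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assay<- assays<- rowData colData colData<-
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment altExp altExps
NULL

#' SRTSection: a spatially resolved transcriptomics section
#'
#' An `SRTSection` holds a gene-by-spot count matrix together with spot
#' geometry, extending [SummarizedExperiment::SummarizedExperiment].
#' Columns are barcoded spots; `colData` carries, per spot:
#' \describe{
#'   \item{`x`, `y`}{spot centre in common-frame (full-resolution histology
#'     image) pixels: origin top-left, x rightward, y downward, 0-based.}
#'   \item{`array_row`, `array_col`}{integer position on the hexagonal
#'     capture-spot lattice.}
#'   \item{`in_tissue`}{logical; whether the spot lies under tissue.}
#'   \item{`annotation`}{optional character label (e.g. region, or hemisphere
#'     `"intact"` / `"lesioned"` in a unilateral lesion model).}
#' }
#'
#' @slot int_metadata list, internal bookkeeping (QC logs).
#' @seealso [SRTSection()] to construct, [readSRTdir()] to read from disk.
#' @export
setClass("SRTSection",
  contains = "SummarizedExperiment",
  slots = c(int_metadata = "list")
)

setValidity("SRTSection", function(object) {
  msg <- NULL
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
  }
  cd <- colData(object)
  need <- c("x", "y", "array_row", "array_col", "in_tissue")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  if (is.null(colnames(object)))
    msg <- c(msg, "spot barcodes (colnames) are required")
  else if (anyDuplicated(colnames(object)))
    msg <- c(msg, "spot barcodes must be unique")
  if (all(c("x", "y") %in% colnames(cd)) &&
      (!all(is.finite(cd$x)) || !all(is.finite(cd$y))))
    msg <- c(msg, "spot coordinates must be finite")
  if (is.null(msg)) TRUE else msg
})

#' Construct an SRTSection
#'
#' @param counts non-negative integer matrix, genes x spots (dense or
#'   `Matrix` sparse). Row names are gene identifiers, column names barcodes;
#'   both may instead be supplied via `geneIds` / `barcodes`.
#' @param spotXY numeric matrix or data.frame with two columns, the per-spot
#'   (x, y) centre in common-frame pixels.
#' @param arrayRC integer matrix/data.frame with two columns (array row, col).
#'   Defaults to zeros.
#' @param inTissue logical per spot; default all `TRUE`.
#' @param annotations optional character per spot.
#' @param geneIds,barcodes identifiers; default taken from `dimnames(counts)`.
#' @return an [SRTSection-class] object.
#' @examples
#' cts <- matrix(rpois(12, 3), 3, 4,
#'               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' sec <- SRTSection(cts, spotXY = cbind(x = 1:4 * 100, y = rep(0, 4)))
#' sec
#' @export
SRTSection <- function(counts, spotXY, arrayRC = NULL, inTissue = NULL,
                       annotations = NULL, geneIds = rownames(counts),
                       barcodes = colnames(counts)) {
  counts <- as(counts, "CsparseMatrix")
  n <- ncol(counts)
  if (is.null(geneIds)) geneIds <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(barcodes)) barcodes <- paste0("spot", seq_len(n))
  spotXY <- as.matrix(spotXY)
  stopifnot(nrow(spotXY) == n, ncol(spotXY) == 2)
  if (is.null(arrayRC)) arrayRC <- matrix(0L, n, 2)
  arrayRC <- as.matrix(arrayRC)
  if (is.null(inTissue)) inTissue <- rep(TRUE, n)
  cd <- DataFrame(
    x = as.numeric(spotXY[, 1]), y = as.numeric(spotXY[, 2]),
    array_row = as.integer(arrayRC[, 1]), array_col = as.integer(arrayRC[, 2]),
    in_tissue = as.logical(inTissue),
    annotation = if (is.null(annotations)) NA_character_ else as.character(annotations),
    row.names = barcodes
  )
  dimnames(counts) <- list(geneIds, barcodes)
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
  new("SRTSection", se, int_metadata = list())
}

#' MSIRaster: a mass spectrometry imaging peak raster
#'
#' Peak-by-pixel intensity matrix with the shared m/z axis and pixel
#' coordinates, extending [SummarizedExperiment::SummarizedExperiment].
#' `rowData` holds `mz` (Daltons, strictly increasing); `colData` holds pixel
#' `x`, `y` in MSI-native units and, once computed, the logical `off_tissue`
#' flag. Acquisition metadata (`pitch_um`, `matrix_name`, `polarity`) live in
#' `metadata()`.
#'
#' @seealso [MSIRaster()], [readMSI()], [flagOfftissue()].
#' @export
setClass("MSIRaster", contains = "SummarizedExperiment")

setValidity("MSIRaster", function(object) {
  msg <- NULL
  if (!"intensities" %in% names(assays(object)))
    msg <- c(msg, "assay 'intensities' is required")
  else if (any(assay(object, "intensities") < 0))
    msg <- c(msg, "intensities must be non-negative")
  mz <- rowData(object)$mz
  if (is.null(mz) || length(mz) != nrow(object))
    msg <- c(msg, "rowData$mz must have one value per peak")
  else if (is.unsorted(mz, strictly = TRUE))
    msg <- c(msg, "mz must be strictly increasing")
  cd <- colData(object)
  if (!all(c("x", "y") %in% colnames(cd)))
    msg <- c(msg, "colData must have pixel columns x, y")
  else if (anyDuplicated(cbind(cd$x, cd$y)))
    msg <- c(msg, "pixel (x, y) coordinates must be unique")
  p <- metadata(object)$pitch_um
  if (is.null(p) || !is.numeric(p) || p <= 0)
    msg <- c(msg, "metadata pitch_um must be a positive number")
  if (is.null(msg)) TRUE else msg
})

#' Construct an MSIRaster
#'
#' @param intensities non-negative numeric matrix, peaks x pixels.
#' @param mz numeric vector of m/z values (Daltons), one per peak. Peaks are
#'   sorted by ascending m/z on construction.
#' @param pixelXY two-column matrix/data.frame of pixel (x, y) coordinates in
#'   MSI-native units.
#' @param pitchUm lateral resolution in micrometres (default 100, typical of
#'   MALDI-FTICR tissue imaging).
#' @param matrixName MALDI matrix used (e.g. `"FMP-10"`, `"9-AA"`, `"DHB"`).
#' @param polarity `"positive"` or `"negative"` ionisation mode.
#' @return an [MSIRaster-class] object.
#' @export
MSIRaster <- function(intensities, mz, pixelXY, pitchUm = 100,
                      matrixName = "FMP-10",
                      polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  intensities <- as.matrix(intensities)
  mz <- as.numeric(mz)
  stopifnot(length(mz) == nrow(intensities))
  o <- order(mz)
  intensities <- intensities[o, , drop = FALSE]
  mz <- mz[o]
  pixelXY <- as.matrix(pixelXY)
  stopifnot(nrow(pixelXY) == ncol(intensities), ncol(pixelXY) == 2)
  rownames(intensities) <- sprintf("mz_%.4f", mz)
  colnames(intensities) <- paste0("px", seq_len(ncol(intensities)))
  se <- SummarizedExperiment(
    assays = list(intensities = intensities),
    rowData = DataFrame(mz = mz, row.names = rownames(intensities)),
    colData = DataFrame(x = as.numeric(pixelXY[, 1]),
                        y = as.numeric(pixelXY[, 2]),
                        row.names = colnames(intensities))
  )
  metadata(se) <- list(pitch_um = pitchUm, matrix_name = matrixName,
                       polarity = polarity)
  new("MSIRaster", se)
}

#' SimilarityTransform2D: rotation, isotropic scale and translation
#'
#' Maps a point p in the source plane (MSI-native coordinates) to
#' `scale * R(rotation) %*% p + translation` in the target (common histology
#' pixel) frame.
#'
#' @slot scale positive numeric.
#' @slot rotation_rad rotation angle in radians, counter-clockwise in a
#'   y-down frame.
#' @slot translation numeric length-2 (tx, ty).
#' @slot reflection logical; if `TRUE` the source is mirrored before rotation.
#' @seealso [fitSimilarity()], [applyTransform()], [invertTransform()].
#' @export
setClass("SimilarityTransform2D",
  slots = c(scale = "numeric", rotation_rad = "numeric",
            translation = "numeric", reflection = "logical"),
  prototype = prototype(scale = 1, rotation_rad = 0,
                        translation = c(0, 0), reflection = FALSE)
)

setValidity("SimilarityTransform2D", function(object) {
  msg <- NULL
  if (length(object@scale) != 1 || object@scale <= 0)
    msg <- c(msg, "scale must be a single positive number")
  if (length(object@translation) != 2 || !all(is.finite(object@translation)))
    msg <- c(msg, "translation must be two finite numbers")
  if (length(object@rotation_rad) != 1 || !is.finite(object@rotation_rad))
    msg <- c(msg, "rotation_rad must be a single finite number")
  if (is.null(msg)) TRUE else msg
})

#' @rdname SimilarityTransform2D-class
#' @param scale,rotationRad,translation,reflection transform parameters.
#' @return a `SimilarityTransform2D`.
#' @export
similarityTransform2D <- function(scale = 1, rotationRad = 0,
                                  translation = c(0, 0), reflection = FALSE) {
  new("SimilarityTransform2D", scale = scale, rotation_rad = rotationRad,
      translation = as.numeric(translation), reflection = reflection)
}

#' PairMap: per-MSI-pixel assignment to its nearest RNA spot
#'
#' One row per paired MSI pixel: `msi_pixel_index` (unique), `spot_index`
#' (may repeat: several MSI pixels can share a closest spot), and
#' `distance_px` in the common frame, bounded by the pairing cutoff.
#' Indices of MSI pixels left unpaired by the distance filter are kept in
#' `unpaired`.
#'
#' @slot pairs data.frame with columns msi_pixel_index, spot_index, distance_px.
#' @slot unpaired integer vector of unpaired MSI pixel indices.
#' @slot max_dist the distance cutoff (common-frame pixels) used.
#' @seealso [pairModalities()].
#' @export
setClass("PairMap",
  slots = c(pairs = "data.frame", unpaired = "integer", max_dist = "numeric")
)

setValidity("PairMap", function(object) {
  p <- object@pairs
  msg <- NULL
  need <- c("msi_pixel_index", "spot_index", "distance_px")
  if (!all(need %in% colnames(p)))
    msg <- c(msg, paste("pairs must have columns", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(p$msi_pixel_index))
      msg <- c(msg, "msi_pixel_index must be unique")
    if (any(p$distance_px < 0)) msg <- c(msg, "distances must be >= 0")
    if (length(object@max_dist) == 1 && nrow(p) &&
        any(p$distance_px > object@max_dist + 1e-9))
      msg <- c(msg, "a pair exceeds the distance cutoff")
  }
  if (is.null(msg)) TRUE else msg
})

#' MultimodalDataset: aligned SRT + MSI observations
#'
#' A [SingleCellExperiment::SingleCellExperiment] whose main experiment is the
#' gene assay over the paired observations (one column per MSI-pixel/spot
#' pair; a spot reused by several MSI pixels is duplicated column-wise) and
#' whose `altExp("peaks")` carries the matched MSI peak intensities.
#' `colData` records the originating spot barcode and MSI pixel index, the
#' pair distance, common-frame coordinates of the RNA spot, and inherited
#' annotations.
#'
#' @seealso [assembleMultimodal()], [peakGeneCorrelation()], [jointEmbedding()].
#' @export
setClass("MultimodalDataset", contains = "SingleCellExperiment")

setValidity("MultimodalDataset", function(object) {
  # altExps() cannot be called on a partially validated object (infinite
  # dispatch recursion); inspect the internal column data instead. altExps
  # are column-parallel by construction, so ncol needs no re-check.
  ae <- SingleCellExperiment::int_colData(object)[["altExps"]]
  if (is.null(ae) || !"peaks" %in% colnames(ae))
    "altExp 'peaks' is required" else TRUE
})

#' MeanSpectrum: per-peak mean intensity over a pixel selection
#'
#' @slot mz numeric m/z axis.
#' @slot mean_intensity numeric, same length as `mz`.
#' @slot n_pixels number of pixels averaged (>= 1).
#' @seealso [meanSpectrum()], [spectrumCorrelation()].
#' @export
setClass("MeanSpectrum",
  slots = c(mz = "numeric", mean_intensity = "numeric", n_pixels = "integer")
)

setValidity("MeanSpectrum", function(object) {
  msg <- NULL
  if (length(object@mz) != length(object@mean_intensity))
    msg <- c(msg, "mz and mean_intensity must have equal length")
  if (object@n_pixels < 1L) msg <- c(msg, "n_pixels must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' FeatureEmbedding: joint PCA coordinates of genes and peaks
#'
#' Rows are features (genes first, then peaks); columns are principal-axis
#' coordinates (loadings scaled by singular values).
#'
#' @slot coords numeric matrix, features x d (d >= 2), finite.
#' @slot feature_type character, `"gene"` or `"peak"` per row.
#' @seealso [jointEmbedding()], [peakKNN()].
#' @export
setClass("FeatureEmbedding",
  slots = c(coords = "matrix", feature_type = "character")
)

setValidity("FeatureEmbedding", function(object) {
  msg <- NULL
  if (!all(is.finite(object@coords))) msg <- c(msg, "coords must be finite")
  if (ncol(object@coords) < 2) msg <- c(msg, "embedding dimension must be >= 2")
  if (length(object@feature_type) != nrow(object@coords))
    msg <- c(msg, "feature_type must label every row")
  if (!all(object@feature_type %in% c("gene", "peak")))
    msg <- c(msg, "feature_type entries must be 'gene' or 'peak'")
  if (is.null(rownames(object@coords)))
    msg <- c(msg, "coords must have feature identifiers as rownames")
  if (is.null(msg)) TRUE else msg
})

#' PeakGeneGraph: directed cosine-kNN graph from peaks to genes
#'
#' Edges run from each peak to its k nearest gene features in the joint
#' embedding (cosine distance, ranked 1..k); gene nodes have out-degree 0.
#' After [detectModules()], `community` maps each node to an integer module
#' label.
#'
#' @slot nodes data.frame with columns id, type ("gene"/"peak") and, after
#'   community detection, community (integer).
#' @slot edges data.frame with columns peak, gene, cosine_distance, rank.
#' @slot k the number of gene neighbours requested per peak.
#' @seealso [peakKNN()], [detectModules()], [exportPeakGeneTable()].
#' @export
setClass("PeakGeneGraph",
  slots = c(nodes = "data.frame", edges = "data.frame", k = "integer")
)

setValidity("PeakGeneGraph", function(object) {
  msg <- NULL
  if (!all(c("id", "type") %in% colnames(object@nodes)))
    msg <- c(msg, "nodes need columns id, type")
  if (!all(c("peak", "gene", "cosine_distance", "rank") %in% colnames(object@edges)))
    msg <- c(msg, "edges need columns peak, gene, cosine_distance, rank")
  else {
    if (nrow(object@edges) &&
        (any(object@edges$cosine_distance < -1e-12) ||
         any(object@edges$cosine_distance > 2 + 1e-12)))
      msg <- c(msg, "cosine_distance must lie in [0, 2]")
    ft <- object@nodes$type[match(object@edges$peak, object@nodes$id)]
    if (nrow(object@edges) && !all(ft == "peak"))
      msg <- c(msg, "edges must originate from peak nodes")
  }
  if (is.null(msg)) TRUE else msg
})
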