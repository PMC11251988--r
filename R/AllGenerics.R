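#' @include AllClasses.R
NULL

#' Accessors for spatial multimodal objects
#'
#' `spotCoords` / `pixelCoords` return the two-column (x, y) coordinate
#' matrix of an [SRTSection-class] / [MSIRaster-class]; `inTissue` the
#' in-tissue flags; `annotations` the per-spot labels; `mzValues` the m/z
#' axis; `offTissue` the off-tissue pixel flags (computed by
#' [flagOfftissue()], `NULL` before that).
#'
#' @param x an object.
#' @param value replacement value.
#' @return the queried component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spotCoords", function(x) standardGeneric("spotCoords"))
#' @rdname accessors
#' @export
setGeneric("pixelCoords", function(x) standardGeneric("pixelCoords"))
#' @rdname accessors
#' @export
setGeneric("inTissue", function(x) standardGeneric("inTissue"))
#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname accessors
#' @export
setGeneric("annotations<-", function(x, value) standardGeneric("annotations<-"))
#' @rdname accessors
#' @export
setGeneric("mzValues", function(x) standardGeneric("mzValues"))
#' @rdname accessors
#' @export
setGeneric("offTissue", function(x) standardGeneric("offTissue"))

#' @rdname accessors
#' @export
setMethod("spotCoords", "SRTSection", function(x)
  cbind(x = colData(x)$x, y = colData(x)$y))

#' @rdname accessors
#' @export
setMethod("inTissue", "SRTSection", function(x) colData(x)$in_tissue)

#' @rdname accessors
#' @export
setMethod("annotations", "SRTSection", function(x) colData(x)$annotation)

#' @rdname accessors
#' @export
setMethod("annotations<-", "SRTSection", function(x, value) {
  colData(x)$annotation <- as.character(value)
  x
})

#' @rdname accessors
#' @export
setMethod("pixelCoords", "MSIRaster", function(x)
  cbind(x = colData(x)$x, y = colData(x)$y))

#' @rdname accessors
#' @export
setMethod("mzValues", "MSIRaster", function(x) rowData(x)$mz)

#' @rdname accessors
#' @export
setMethod("offTissue", "MSIRaster", function(x) colData(x)$off_tissue)

#' Extract the pair table from a PairMap
#' @param x a [PairMap-class].
#' @return data.frame with columns msi_pixel_index, spot_index, distance_px.
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname pairTable
#' @export
setMethod("pairTable", "PairMap", function(x) x@pairs)

#' Unpaired MSI pixel indices
#' @param x a [PairMap-class].
#' @return integer vector.
#' @export
setGeneric("unpairedPixels", function(x) standardGeneric("unpairedPixels"))

#' @rdname unpairedPixels
#' @export
setMethod("unpairedPixels", "PairMap", function(x) x@unpaired)

setMethod("show", "SRTSection", function(object) {
  cat("SRTSection:", nrow(object), "genes x", ncol(object), "spots\n")
  cat("  in tissue:", sum(colData(object)$in_tissue), "spots\n")
  ann <- colData(object)$annotation
  if (!all(is.na(ann)))
    cat("  annotations:", paste(utils::head(sort(unique(stats::na.omit(ann))), 6),
                                collapse = ", "), "\n")
  if (length(object@int_metadata$qc_log))
    cat("  QC: ", paste(names(object@int_metadata$qc_log),
                        unlist(object@int_metadata$qc_log),
                        sep = "=", collapse = ", "), "\n", sep = "")
})

setMethod("show", "MSIRaster", function(object) {
  md <- metadata(object)
  cat("MSIRaster:", nrow(object), "peaks x", ncol(object), "pixels\n")
  cat(sprintf("  m/z %.4f - %.4f | pitch %g um | matrix %s (%s mode)\n",
              min(rowData(object)$mz), max(rowData(object)$mz),
              md$pitch_um, md$matrix_name, md$polarity))
  ot <- colData(object)$off_tissue
  if (!is.null(ot)) cat("  off-tissue pixels flagged:", sum(ot), "\n")
})

setMethod("show", "SimilarityTransform2D", function(object) {
  cat(sprintf(
    "SimilarityTransform2D: scale %.6g, rotation %.6g rad (%.2f deg), translation (%.6g, %.6g)%s\n",
    object@scale, object@rotation_rad, object@rotation_rad * 180 / pi,
    object@translation[1], object@translation[2],
    if (object@reflection) ", reflected" else ""))
})

setMethod("show", "PairMap", function(object) {
  cat("PairMap:", nrow(object@pairs), "MSI pixel -> spot pairs (",
      length(unique(object@pairs$spot_index)), "distinct spots ),",
      length(object@unpaired), "unpaired pixels\n")
  if (nrow(object@pairs))
    cat(sprintf("  distance (px): median %.2f, max %.2f (cutoff %g)\n",
                stats::median(object@pairs$distance_px),
                max(object@pairs$distance_px), object@max_dist))
})

setMethod("show", "MultimodalDataset", function(object) {
  cat("MultimodalDataset:", ncol(object), "paired observations\n")
  cat("  genes:", nrow(object), "| peaks:", nrow(altExp(object, "peaks")), "\n")
  cat("  distinct spots:", length(unique(colData(object)$barcode)), "\n")
})

setMethod("show", "MeanSpectrum", function(object) {
  cat("MeanSpectrum over", object@n_pixels, "pixels,",
      length(object@mz), "peaks\n")
})

setMethod("show", "FeatureEmbedding", function(object) {
  cat("FeatureEmbedding:", sum(object@feature_type == "gene"), "genes +",
      sum(object@feature_type == "peak"), "peaks in",
      ncol(object@coords), "dimensions\n")
})

setMethod("show", "PeakGeneGraph", function(object) {
  cat("PeakGeneGraph:", sum(object@nodes$type == "peak"), "peaks,",
      sum(object@nodes$type == "gene"), "genes,",
      nrow(object@edges), "directed edges (k =", object@k, ")\n")
  if ("community" %in% colnames(object@nodes) &&
      !all(is.na(object@nodes$community)))
    cat("  communities:", length(unique(object@nodes$community)), "\n")
})
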