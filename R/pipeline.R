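#' Run the full integration workflow
#'
#' Chains the pipeline stages: spot/gene QC on the SRT side, off-tissue
#' flagging on the MSI side, landmark registration of the raster into the
#' common frame, MSI-to-spot pairing, and assembly of the aligned
#' two-modality dataset. Returns the intermediate objects so each stage can
#' be inspected.
#'
#' @param srt an [SRTSection-class].
#' @param raster an [MSIRaster-class].
#' @param landmarks a [landmarkPairs()] set (MSI-native -> common frame).
#' @param cfg a [pipelineConfig()].
#' @param excludeBarcodes barcodes removed up-front (artifact annotation).
#' @param species passed to [filterGenes()].
#' @return list with `section` (QC-filtered SRT), `raster` (off-tissue
#'   flagged), `transform`, `pairs`, and `mm` (the
#'   [MultimodalDataset-class]).
#' @export
runIntegration <- function(srt, raster, landmarks, cfg = pipelineConfig(),
                           excludeBarcodes = character(),
                           species = "mouse") {
  section <- filterGenes(filterSpots(srt, cfg, excludeBarcodes), species)
  raster <- flagOfftissue(raster)
  transform <- fitSimilarity(landmarks)
  keep <- which(!offTissue(raster))
  msiXY <- applyTransform(transform, pixelCoords(raster)[keep, , drop = FALSE])
  pairs <- pairModalities(msiXY, spotCoords(section), cfg)
  # re-index pairs back to raster pixel indices
  p <- pairs@pairs
  p$msi_pixel_index <- keep[p$msi_pixel_index]
  pairs <- new("PairMap", pairs = p,
               unpaired = c(keep[pairs@unpaired], which(offTissue(raster))),
               max_dist = pairs@max_dist)
  mm <- assembleMultimodal(section, raster, pairs)
  list(section = section, raster = raster, transform = transform,
       pairs = pairs, mm = mm)
}
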