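#' Landmark point pairs
#'
#' A set of corresponding points picked in the MSI raster (source, native
#' units) and on the histology image (target, common-frame pixels), used to
#' fit the section-to-section similarity transform.
#'
#' @param source,target n x 2 matrices of (x, y) coordinates, n >= 2; no
#'   duplicated source points.
#' @return a `landmarkPairs` list (`source`, `target`).
#' @export
landmarkPairs <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) != nrow(target))
    stop("source and target must have equally many points", call. = FALSE)
  if (nrow(source) < 2) stop("need at least 2 landmark pairs", call. = FALSE)
  if (ncol(source) != 2 || ncol(target) != 2)
    stop("landmark coordinates must be two-dimensional", call. = FALSE)
  if (anyDuplicated(source)) stop("duplicated source points", call. = FALSE)
  structure(list(source = unname(source), target = unname(target)),
            class = "landmarkPairs")
}

rotationMatrix <- function(theta, reflection = FALSE) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  if (reflection) R %*% diag(c(1, -1)) else R
}

#' Fit a similarity transform to landmark pairs
#'
#' Closed-form least-squares estimate (orthogonal Procrustes with isotropic
#' scale) of the rotation, scale and translation minimising
#' `sum ||T(source_i) - target_i||^2`. With `allowReflection = FALSE`
#' (default — tissue sections are not mirrored between modalities) the
#' rotation determinant is constrained to +1.
#'
#' @param landmarks a [landmarkPairs()] object (or list with `source`,
#'   `target` matrices).
#' @param allowReflection permit an improper (mirroring) transform.
#' @return a [SimilarityTransform2D-class].
#' @examples
#' src <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
#' tgt <- 2 * src + rep(c(10, -5), each = 4)   # pure scale + translation
#' fitSimilarity(landmarkPairs(src, tgt))
#' @export
fitSimilarity <- function(landmarks, allowReflection = FALSE) {
  S <- landmarks$source; Tg <- landmarks$target
  n <- nrow(S)
  muS <- colMeans(S); muT <- colMeans(Tg)
  Sc <- sweep(S, 2, muS); Tc <- sweep(Tg, 2, muT)
  varS <- sum(Sc^2) / n
  if (varS < 1e-24)
    stop("degenerate landmark configuration: source points coincide",
         call. = FALSE)
  Sigma <- crossprod(Tc, Sc) / n          # 2x2 cross-covariance target~source
  sv <- svd(Sigma)
  d <- sign(det(sv$u) * det(sv$v))
  Dfix <- if (allowReflection) diag(2) else diag(c(1, d))
  R <- sv$u %*% Dfix %*% t(sv$v)
  scale <- sum(diag(diag(sv$d) %*% Dfix)) / varS
  if (scale <= 0)
    stop("fitted scale is non-positive; landmarks are inconsistent",
         call. = FALSE)
  refl <- det(R) < 0
  theta <- atan2(R[2, 1], R[1, 1])
  if (refl) {
    # decompose improper R as rotation %*% diag(1, -1)
    Rp <- R %*% diag(c(1, -1))
    theta <- atan2(Rp[2, 1], Rp[1, 1])
  }
  tr <- muT - scale * as.vector(R %*% muS)
  similarityTransform2D(scale = scale, rotationRad = theta,
                        translation = tr, reflection = refl)
}

transformMatrix <- function(t) t@scale * rotationMatrix(t@rotation_rad, t@reflection)

#' Apply a similarity transform to coordinates
#'
#' Maps points (or the pixel coordinates of a raster) into the common frame.
#' The raster itself is unchanged; only transformed coordinates are returned.
#'
#' @param transform a [SimilarityTransform2D-class].
#' @param x an n x 2 coordinate matrix or an [MSIRaster-class] (whose pixel
#'   coordinates are used).
#' @return n x 2 matrix of transformed (x, y).
#' @export
applyTransform <- function(transform, x) {
  xy <- if (is(x, "MSIRaster")) pixelCoords(x) else as.matrix(x)
  M <- transformMatrix(transform)
  out <- xy %*% t(M)
  out[, 1] <- out[, 1] + transform@translation[1]
  out[, 2] <- out[, 2] + transform@translation[2]
  colnames(out) <- c("x", "y")
  out
}

#' Invert a similarity transform
#' @param transform a [SimilarityTransform2D-class].
#' @return the inverse transform, such that applying both returns the input
#'   to within 1e-9.
#' @export
invertTransform <- function(transform) {
  M <- transformMatrix(transform)
  Minv <- solve(M)
  trInv <- -as.vector(Minv %*% transform@translation)
  refl <- det(Minv) < 0
  sc <- sqrt(abs(det(Minv)))
  Rinv <- Minv / sc
  if (refl) Rinv <- Rinv %*% diag(c(1, -1))
  similarityTransform2D(scale = sc, rotationRad = atan2(Rinv[2, 1], Rinv[1, 1]),
                        translation = trInv, reflection = refl)
}

#' Registration residuals
#' @param transform fitted [SimilarityTransform2D-class].
#' @param landmarks the [landmarkPairs()] it was fitted to.
#' @return list with per-point residual distances and their RMS.
#' @export
registrationResiduals <- function(transform, landmarks) {
  pred <- applyTransform(transform, landmarks$source)
  res <- sqrt(rowSums((pred - landmarks$target)^2))
  list(residuals = res, rms = sqrt(mean(res^2)))
}

#' Pair MSI pixels with RNA spots
#'
#' The cross-modality pairing rule: for each MSI pixel (already mapped into
#' the common frame) find its `cfg$knn_k` nearest RNA spots by Euclidean
#' distance, drop candidates farther than `cfg$max_pair_dist_px`, and keep
#' exactly the closest surviving spot. A spot that is closest for several
#' MSI pixels is reused by each of them; MSI pixels with no candidate within
#' the cutoff stay unpaired and are reported. Exact distance ties are broken
#' towards the lower spot index. Pairing deliberately runs MSI -> RNA:
#' the MSI raster is the sparser point set.
#'
#' @param msiXY n x 2 common-frame coordinates of MSI pixels (from
#'   [applyTransform()]), typically off-tissue-filtered.
#' @param spotXY m x 2 common-frame coordinates of the QC-passing spots.
#' @param cfg a [pipelineConfig()].
#' @return a [PairMap-class].
#' @export
pairModalities <- function(msiXY, spotXY, cfg = pipelineConfig()) {
  msiXY <- as.matrix(msiXY); spotXY <- as.matrix(spotXY)
  if (nrow(spotXY) == 0) stop("empty spot set", call. = FALSE)
  if (nrow(msiXY) == 0) stop("empty MSI pixel set", call. = FALSE)
  k <- min(cfg$knn_k, nrow(spotXY))
  spot2 <- rowSums(spotXY^2)
  nMSI <- nrow(msiXY)
  pairIdx <- integer(nMSI); pairDist <- numeric(nMSI)
  chunk <- 512L
  for (start in seq(1L, nMSI, by = chunk)) {
    ii <- start:min(start + chunk - 1L, nMSI)
    # squared Euclidean distances, chunk x spots
    D2 <- outer(rowSums(msiXY[ii, , drop = FALSE]^2), spot2, `+`) -
      2 * msiXY[ii, , drop = FALSE] %*% t(spotXY)
    D2[D2 < 0] <- 0
    for (j in seq_along(ii)) {
      d <- sqrt(D2[j, ])
      cand <- order(d, seq_along(d))[seq_len(k)]     # ties -> lower index
      cand <- cand[d[cand] <= cfg$max_pair_dist_px]
      if (length(cand)) {
        pairIdx[ii[j]] <- cand[1]
        pairDist[ii[j]] <- d[cand[1]]
      } else pairIdx[ii[j]] <- NA_integer_
    }
  }
  paired <- which(!is.na(pairIdx))
  new("PairMap",
      pairs = data.frame(msi_pixel_index = paired,
                         spot_index = pairIdx[paired],
                         distance_px = pairDist[paired]),
      unpaired = setdiff(seq_len(nMSI), paired),
      max_dist = cfg$max_pair_dist_px)
}

#' Suggest a pairing distance cutoff
#'
#' Otsu's threshold on the 64-bin histogram of nearest-neighbour distances:
#' a data-driven separation between the within-tissue mode and the long
#' distances of non-overlapping regions. Advisory only — the configured
#' `max_pair_dist_px` is what [pairModalities()] enforces.
#'
#' @param distances numeric vector of at least 50 nearest-neighbour
#'   distances.
#' @return suggested cutoff (same units as the input).
#' @export
suggestDistanceCutoff <- function(distances) {
  if (length(distances) < 50)
    stop("need at least 50 distances (got ", length(distances), ")",
         call. = FALSE)
  if (diff(range(distances)) == 0) {
    warning("all distances equal; returning that value")
    return(distances[1])
  }
  nb <- 64L
  brk <- seq(min(distances), max(distances), length.out = nb + 1L)
  h <- graphics::hist(distances, breaks = brk, plot = FALSE)
  counts <- h$counts; mids <- h$mids
  total <- sum(counts)
  cw <- cumsum(counts)
  cm <- cumsum(counts * mids)
  between <- vapply(seq_len(nb - 1L), function(t) {
    w0 <- cw[t] / total; w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(-Inf)
    mu0 <- cm[t] / cw[t]
    mu1 <- (cm[nb] - cm[t]) / (cw[nb] - cw[t])
    w0 * w1 * (mu0 - mu1)^2
  }, numeric(1))
  best <- max(between)
  # empty bins between modes tie the objective exactly; cut mid-plateau
  plateau <- which(between >= best - 1e-9 * abs(best))
  mean(brk[plateau + 1L])
}

#' Assemble the aligned two-modality dataset
#'
#' Subsets both modalities to the paired observations: one column per pair
#' (ascending MSI pixel index), the gene assay from the paired spot (spots
#' reused by several MSI pixels are duplicated column-wise) and the peak
#' assay from the paired pixel. A log-CPM `logcounts` assay is computed for
#' the gene side. The pairing distance bound is re-verified on assembly.
#'
#' @param section QC-filtered [SRTSection-class] whose columns the pairs'
#'   `spot_index` refers to.
#' @param raster [MSIRaster-class] whose columns `msi_pixel_index` refers to.
#' @param pairs a [PairMap-class].
#' @return a [MultimodalDataset-class].
#' @export
assembleMultimodal <- function(section, raster, pairs) {
  p <- pairTable(pairs)
  if (nrow(p) == 0) stop("empty PairMap: nothing to assemble", call. = FALSE)
  if (any(p$spot_index < 1) || any(p$spot_index > ncol(section)))
    stop("spot_index out of range for the section", call. = FALSE)
  if (any(p$msi_pixel_index < 1) || any(p$msi_pixel_index > ncol(raster)))
    stop("msi_pixel_index out of range for the raster", call. = FALSE)
  if (any(p$distance_px > pairs@max_dist + 1e-9))
    stop("pair distance exceeds the configured cutoff", call. = FALSE)
  p <- p[order(p$msi_pixel_index), ]

  genes <- assay(section, "counts")[, p$spot_index, drop = FALSE]
  obsNames <- sprintf("obs%05d", seq_len(nrow(p)))
  colnames(genes) <- obsNames
  logc <- normalizeLogCPM(genes)
  peaks <- assay(raster, "intensities")[, p$msi_pixel_index, drop = FALSE]
  colnames(peaks) <- obsNames
  cd <- colData(section)[p$spot_index, ]
  obsData <- DataFrame(
    barcode = colnames(section)[p$spot_index],
    msi_pixel_index = p$msi_pixel_index,
    spot_index = p$spot_index,
    distance_px = p$distance_px,
    x = cd$x, y = cd$y,
    annotation = cd$annotation,
    row.names = obsNames
  )
  peakSE <- SummarizedExperiment(
    assays = list(intensities = peaks),
    rowData = DataFrame(mz = mzValues(raster), row.names = rownames(peaks)))
  sce <- SingleCellExperiment(
    assays = list(counts = genes, logcounts = logc),
    colData = obsData,
    altExps = list(peaks = peakSE))
  metadata(sce) <- c(metadata(raster)[c("pitch_um", "matrix_name", "polarity")],
                     list(max_pair_dist_px = pairs@max_dist))
  new("MultimodalDataset", sce)
}
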