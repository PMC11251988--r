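#' Configuration for the synthetic paired-data generator
#'
#' Describes a synthetic coronal-section experiment: a hexagonal-offset SRT
#' spot lattice with domain-structured negative-binomial counts, an MSI
#' raster on its own pitch observed in a different (MSI-native) coordinate
#' frame under a known similarity transform, planted peak-gene correlations,
#' and a unilateral lesion depleting one peak in one hemisphere — the
#' structure of a unilateral 6-OHDA dopamine-depletion experiment, with
#' known ground truth.
#'
#' @param nSpotRows,nSpotCols spot lattice size (default 32 x 32, ~1000
#'   spots — the scale of one capture-area region).
#' @param spotPitchPx centre-to-centre spot distance in common-frame pixels
#'   (default 100, i.e. 100 um at 1 px/um).
#' @param nGenes,nPeaks feature counts (defaults 2000 genes, 50 peaks).
#' @param nbDispersion negative-binomial dispersion (`size = 1/dispersion`;
#'   default 0.5, typical spot-level overdispersion).
#' @param nDomains number of spatial expression domains (y-bands crossed
#'   with hemisphere; default 4).
#' @param markerFrac fraction of genes up-shifted (x4) per domain
#'   (default 0.05).
#' @param nMitoGenes genes named `mt-*` with elevated expression
#'   (default 13, the mitochondrial protein-coding complement).
#' @param plantedLinks data.frame with columns `peak`, `gene` (indices) and
#'   `r` (true correlation in (0,1)); default one link, peak 1 <-> gene 1 at
#'   r = 0.8 (a dopamine-Th-like association).
#' @param lesionPeakIndex,lesionDepletion peak depleted in the lesioned
#'   hemisphere and the depletion fraction (defaults: peak 2, 0.85).
#' @param trueTransform the [SimilarityTransform2D-class] mapping MSI-native
#'   coordinates to the common frame; the generator stores MSI pixels in
#'   native units (= inverse-transformed common coordinates). Default:
#'   rotation 0.1 rad, scale 1.25, translation (120, -40).
#' @param msiPitchPx MSI raster pitch in common-frame pixels (default 100;
#'   equal to the spot pitch so the identity-transform case nests pixels
#'   exactly on spots).
#' @param nBackgroundPixels off-tissue pixels ringing the section
#'   (default 100).
#' @param landmarkJitterPx Gaussian jitter of landmark clicks (default 1).
#' @param nLandmarks number of landmark pairs (default 8).
#' @param seed integer; all generators are pure functions of this config.
#' @return a `SynthConfig` list.
#' @export
synthConfig <- function(nSpotRows = 32L, nSpotCols = 32L, spotPitchPx = 100,
                        nGenes = 2000L, nPeaks = 50L, nbDispersion = 0.5,
                        nDomains = 4L, markerFrac = 0.05, nMitoGenes = 13L,
                        plantedLinks = data.frame(peak = 1L, gene = 1L, r = 0.8),
                        lesionPeakIndex = 2L, lesionDepletion = 0.85,
                        trueTransform = similarityTransform2D(
                          scale = 1.25, rotationRad = 0.1,
                          translation = c(120, -40)),
                        msiPitchPx = 100, nBackgroundPixels = 100L,
                        landmarkJitterPx = 1, nLandmarks = 8L, seed = 1L) {
  cfg <- list(n_spot_rows = as.integer(nSpotRows),
              n_spot_cols = as.integer(nSpotCols),
              spot_pitch_px = spotPitchPx, n_genes = as.integer(nGenes),
              n_peaks = as.integer(nPeaks), nb_dispersion = nbDispersion,
              n_domains = as.integer(nDomains), marker_frac = markerFrac,
              n_mito_genes = as.integer(nMitoGenes),
              planted_links = plantedLinks,
              lesion_peak_index = as.integer(lesionPeakIndex),
              lesion_depletion = lesionDepletion,
              true_transform = trueTransform, msi_pitch_px = msiPitchPx,
              n_background_pixels = as.integer(nBackgroundPixels),
              landmark_jitter_px = landmarkJitterPx,
              n_landmarks = as.integer(nLandmarks), seed = as.integer(seed))
  if (cfg$msi_pitch_px <= 0) stop("msiPitchPx must be > 0", call. = FALSE)
  if (cfg$spot_pitch_px <= 0) stop("spotPitchPx must be > 0", call. = FALSE)
  if (nrow(cfg$planted_links)) {
    if (anyDuplicated(cfg$planted_links$gene))
      stop("planted gene indices must be distinct", call. = FALSE)
    if (any(cfg$planted_links$r <= 0) || any(cfg$planted_links$r >= 1))
      stop("planted correlations must lie in (0, 1)", call. = FALSE)
    if (max(cfg$planted_links$gene) > cfg$n_genes ||
        max(cfg$planted_links$peak) > cfg$n_peaks)
      stop("planted link indices exceed feature counts", call. = FALSE)
  }
  if (cfg$lesion_depletion < 0 || cfg$lesion_depletion > 1)
    stop("lesionDepletion must lie in [0, 1]", call. = FALSE)
  class(cfg) <- c("SynthConfig", "list")
  cfg
}

# hexagonal-offset lattice in the common frame: odd rows shifted half a pitch
hexLattice <- function(nRows, nCols, pitch) {
  r <- rep(seq_len(nRows) - 1L, each = nCols)
  c <- rep(seq_len(nCols) - 1L, times = nRows)
  cbind(x = (c + 0.5 * (r %% 2)) * pitch, y = r * pitch * sqrt(3) / 2,
        row = r, col = c)
}

#' Generate a synthetic SRT section
#'
#' Spots on a hexagonal-offset lattice; counts negative-binomial with
#' log-normal baseline gene means; `nDomains` spatial domains (horizontal
#' bands) each up-shifting its own 5\% of genes 4-fold; mitochondrial genes
#' named `mt-*`; hemispheres labelled `intact` (left) / `lesioned` (right)
#' in `annotation`, spatial domains in the extra `region` column.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [synthConfig()].
#' @param replicate replicate index. Replicates model consecutive sections:
#'   they share the latent structure (gene means, domain programs) drawn
#'   from `cfg$seed` and differ only in the sampling noise of the counts.
#' @return an [SRTSection-class].
#' @export
generateSRT <- function(cfg, replicate = 1L) {
  stopifnot(inherits(cfg, "SynthConfig"))
  set.seed(cfg$seed)
  lat <- hexLattice(cfg$n_spot_rows, cfg$n_spot_cols, cfg$spot_pitch_px)
  n <- nrow(lat)
  hemi <- ifelse(lat[, "x"] <= stats::median(lat[, "x"]), "intact", "lesioned")
  band <- cut(lat[, "y"], breaks = cfg$n_domains, labels = FALSE)
  region <- paste0("region", band)

  g <- cfg$n_genes
  ids <- sprintf("gene%04d", seq_len(g))
  if (cfg$n_mito_genes > 0)
    ids[(g - cfg$n_mito_genes + 1L):g] <- paste0("mt-", seq_len(cfg$n_mito_genes))
  base <- stats::rlnorm(g, meanlog = log(0.3), sdlog = 1.2)
  base[grepl("^mt-", ids)] <- stats::runif(cfg$n_mito_genes, 3, 8)
  if (nrow(cfg$planted_links))
    base[cfg$planted_links$gene] <- pmax(base[cfg$planted_links$gene], 2)

  nMark <- max(1L, round(cfg$marker_frac * g))
  pool <- setdiff(sample.int(g), c(which(grepl("^mt-", ids)),
                                   cfg$planted_links$gene))
  markers <- lapply(seq_len(cfg$n_domains), function(d)
    pool[((d - 1L) * nMark + 1L):(d * nMark)])
  fac <- matrix(1, g, cfg$n_domains)
  for (d in seq_len(cfg$n_domains)) fac[markers[[d]], d] <- 4

  if (cfg$n_domains * nMark > length(pool))
    stop("too many marker genes requested for the gene count", call. = FALSE)
  mu <- fac[, band, drop = FALSE] * base      # genes x spots; base recycles by row
  set.seed(cfg$seed + 500L + as.integer(replicate))   # observation noise layer
  counts <- matrix(stats::rnbinom(g * n, mu = mu, size = 1 / cfg$nb_dispersion),
                   g, n)
  sec <- SRTSection(counts, geneIds = ids,
                    barcodes = sprintf("BC%05d", seq_len(n)),
                    spotXY = lat[, c("x", "y")],
                    arrayRC = lat[, c("row", "col")],
                    inTissue = rep(TRUE, n), annotations = hemi)
  colData(sec)$region <- region
  sec@int_metadata$domain_markers <- markers
  sec
}

#' Generate the matched synthetic MSI raster
#'
#' Lays an MSI pixel lattice (same offset-lattice geometry, pitch
#' `msi_pitch_px`) over the tissue in the common frame, plus an off-tissue
#' ring of background pixels, and stores pixel coordinates in MSI-native
#' units (`trueTransform`-inverse of the common frame). For each planted
#' link (p, g, r), peak p at a tissue pixel is r*z + sqrt(1 - r^2)*e,
#' where `z` is the z-scored normalised expression of gene g at the pixel's
#' geometrically nearest spot — so the population correlation with that
#' gene equals r by construction. The lesion peak rides a smooth positive
#' field multiplied by `1 - lesionDepletion` in the lesioned hemisphere;
#' all other peaks are smooth spatial Gaussian-bump fields. Background
#' pixels carry near-zero noise; every peak is shifted non-negative.
#'
#' @param cfg a [synthConfig()].
#' @param srt the [generateSRT()] output for the same config.
#' @param replicate replicate index: replicates share the latent spatial
#'   fields and m/z axis, with independent measurement noise.
#' @return list with elements `raster` ([MSIRaster-class]) and `truth`
#'   (a `GroundTruth` list: `true_transform`, `pixel_common` — true
#'   common-frame pixel coordinates, `nearest_spot` / `nearest_dist` — the
#'   true pairing (NA for background), `off_tissue` mask, `planted_links`
#'   with realized latent fields, and the per-spot `hemisphere` / `region`
#'   labels).
#' @export
generateMSI <- function(cfg, srt, replicate = 1L) {
  stopifnot(inherits(cfg, "SynthConfig"), is(srt, "SRTSection"))
  if (cfg$msi_pitch_px <= 0) stop("msi_pitch_px must be > 0", call. = FALSE)
  set.seed(cfg$seed + 1L)
  spotXY <- spotCoords(srt)
  # tissue lattice: same offset geometry, clipped to the spot bounding box
  nR <- ceiling(max(spotXY[, 2]) / (cfg$msi_pitch_px * sqrt(3) / 2)) + 1L
  nC <- ceiling(max(spotXY[, 1]) / cfg$msi_pitch_px) + 1L
  lat <- hexLattice(nR, nC, cfg$msi_pitch_px)
  inBox <- lat[, "x"] <= max(spotXY[, 1]) + 1e-9 &
           lat[, "y"] <= max(spotXY[, 2]) + 1e-9
  tissueXY <- lat[inBox, c("x", "y"), drop = FALSE]
  nt <- nrow(tissueXY)

  # off-tissue ring: same lattice continued around the box
  pad <- 3L
  latBig <- hexLattice(nR + 2L * pad, nC + 2L * pad, cfg$msi_pitch_px)
  latBig[, "x"] <- latBig[, "x"] - pad * cfg$msi_pitch_px
  latBig[, "y"] <- latBig[, "y"] - pad * cfg$msi_pitch_px * sqrt(3) / 2
  outRing <- latBig[latBig[, "x"] < -1e-9 | latBig[, "y"] < -1e-9 |
                    latBig[, "x"] > max(spotXY[, 1]) + 1e-9 |
                    latBig[, "y"] > max(spotXY[, 2]) + 1e-9, , drop = FALSE]
  nbg <- min(cfg$n_background_pixels, nrow(outRing))
  bgXY <- outRing[sample.int(nrow(outRing), nbg), c("x", "y"), drop = FALSE]

  common <- rbind(tissueXY, bgXY)
  offTissue <- c(rep(FALSE, nt), rep(TRUE, nbg))

  # true pairing: geometrically nearest spot per tissue pixel
  nn <- vapply(seq_len(nt), function(i) {
    d2 <- (spotXY[, 1] - tissueXY[i, 1])^2 + (spotXY[, 2] - tissueXY[i, 2])^2
    j <- which.min(d2)
    c(j, sqrt(d2[j]))
  }, numeric(2))
  nearestSpot <- c(as.integer(nn[1, ]), rep(NA_integer_, nbg))
  nearestDist <- c(nn[2, ], rep(NA_real_, nbg))

  logc <- normalizeLogCPM(srt)
  hemi <- annotations(srt)
  bump <- function(xy) {
    ctr <- xy[sample.int(nrow(xy), 3), , drop = FALSE]
    w <- 0.25 * diff(range(xy[, 1]))
    a <- stats::runif(3, 5, 15)
    rowSums(vapply(1:3, function(k) {
      d2 <- (xy[, 1] - ctr[k, 1])^2 + (xy[, 2] - ctr[k, 2])^2
      a[k] * exp(-d2 / (2 * w^2))
    }, numeric(nrow(xy))))
  }

  # latent structure (smooth fields, m/z axis) is a function of cfg$seed only;
  # the observation noise layer is reseeded per replicate below
  fields <- lapply(seq_len(cfg$n_peaks), function(p) bump(tissueXY))
  mz <- round(150 + cumsum(stats::runif(cfg$n_peaks, 1, 15)), 4)

  set.seed(cfg$seed + 1500L + as.integer(replicate))
  intens <- matrix(0, cfg$n_peaks, nt)
  latentFields <- vector("list", nrow(cfg$planted_links))
  for (p in seq_len(cfg$n_peaks)) {
    li <- which(cfg$planted_links$peak == p)
    if (length(li) == 1) {
      gidx <- cfg$planted_links$gene[li]
      r <- cfg$planted_links$r[li]
      z <- as.vector(scale(logc[gidx, ]))[nearestSpot[seq_len(nt)]]
      latent <- r * z + sqrt(1 - r^2) * stats::rnorm(nt)
      latentFields[[li]] <- latent
      v <- 10 + 3 * latent
    } else if (p == cfg$lesion_peak_index) {
      v <- 8 + fields[[p]] + stats::rnorm(nt, 0, 0.5)
      v <- pmax(v, 0)
      lesioned <- hemi[nearestSpot[seq_len(nt)]] == "lesioned"
      v[lesioned] <- v[lesioned] * (1 - cfg$lesion_depletion)
    } else {
      v <- fields[[p]] + stats::rnorm(nt, 0, 0.5)
    }
    # detector floor: negative excursions clip to zero (a fixed floor, unlike
    # a per-draw min-shift, keeps replicate mean spectra comparable)
    intens[p, ] <- pmax(v, 0)
  }
  bg <- matrix(abs(stats::rnorm(cfg$n_peaks * nbg, 0, 0.05)), cfg$n_peaks, nbg)
  intens <- cbind(intens, bg)
  native <- applyTransform(invertTransform(cfg$true_transform), common)
  raster <- MSIRaster(intens, mz = mz, pixelXY = native, pitchUm = cfg$msi_pitch_px)
  truth <- structure(list(
    true_transform = cfg$true_transform,
    pixel_common = common,
    nearest_spot = nearestSpot,
    nearest_dist = nearestDist,
    off_tissue = offTissue,
    planted_links = cbind(cfg$planted_links,
                          mz = mz[cfg$planted_links$peak],
                          gene_id = rownames(srt)[cfg$planted_links$gene]),
    latent_fields = latentFields,
    hemisphere = hemi,
    region = colData(srt)$region
  ), class = "GroundTruth")
  list(raster = raster, truth = truth)
}

#' Generate landmark pairs from the ground truth
#'
#' Samples `cfg$n_landmarks` tissue pixels; sources are their MSI-native
#' coordinates, targets their true common-frame coordinates plus Gaussian
#' jitter of sd `cfg$landmark_jitter_px` — emulating hand-clicked
#' correspondences.
#'
#' @param cfg a [synthConfig()].
#' @param raster the generated [MSIRaster-class].
#' @param truth the matching `GroundTruth`.
#' @return a [landmarkPairs()] object.
#' @export
generateLandmarks <- function(cfg, raster, truth) {
  set.seed(cfg$seed + 2L)
  tissue <- which(!truth$off_tissue)
  idx <- sample(tissue, min(cfg$n_landmarks, length(tissue)))
  src <- pixelCoords(raster)[idx, , drop = FALSE]
  tgt <- truth$pixel_common[idx, , drop = FALSE] +
    matrix(stats::rnorm(2 * length(idx), 0, cfg$landmark_jitter_px),
           ncol = 2)
  landmarkPairs(src, tgt)
}

#' Generate a complete synthetic paired dataset
#'
#' Convenience wrapper: SRT section, MSI raster + ground truth, landmarks.
#'
#' @param cfg a [synthConfig()].
#' @return list with `srt`, `raster`, `truth`, `landmarks`, `cfg`.
#' @export
generateDataset <- function(cfg = synthConfig()) {
  srt <- generateSRT(cfg)
  msi <- generateMSI(cfg, srt)
  lm <- generateLandmarks(cfg, msi$raster, msi$truth)
  list(srt = srt, raster = msi$raster, truth = msi$truth, landmarks = lm,
       cfg = cfg)
}
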