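# Independent oracles used across tests. These deliberately re-derive results
# from first principles (full distance matrices, exhaustive permutation,
# step-up definition) so they share no code path with the implementation.

# all-pairs pairing oracle: full distance matrix, cutoff, per-pixel argmin
# (ties towards the lower spot index)
bruteForcePair <- function(msiXY, spotXY, cutoff) {
  D <- as.matrix(stats::dist(rbind(msiXY, spotXY)))
  n <- nrow(msiXY)
  D <- D[seq_len(n), -seq_len(n), drop = FALSE]
  out <- lapply(seq_len(n), function(i) {
    d <- D[i, ]
    ok <- which(d <= cutoff)
    if (!length(ok)) return(NULL)
    j <- ok[order(d[ok], ok)][1]
    data.frame(msi_pixel_index = i, spot_index = unname(j),
               distance_px = unname(d[j]))
  })
  do.call(rbind, out)
}

# Benjamini-Hochberg step-up from its definition
bhStepUp <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  qs <- m * p[o] / seq_len(m)
  q[o] <- rev(cummin(rev(qs)))
  pmin(q, 1)
}

# exhaustive two-sided permutation p-value for the rank-sum statistic
permWilcoxP <- function(x, inGroup) {
  r <- rank(x)
  n1 <- sum(inGroup)
  mu <- n1 * (length(x) + 1) / 2
  obs <- abs(sum(r[inGroup]) - mu)
  splits <- utils::combn(length(x), n1)
  stat <- abs(colSums(matrix(r[splits], nrow = n1)) - mu)
  mean(stat >= obs - 1e-9)
}

# Monte-Carlo permutation p-value for a Pearson correlation
permCorP <- function(x, y, nPerm = 10000, seed = 42) {
  set.seed(seed)
  obs <- abs(stats::cor(x, y))
  hits <- sum(vapply(seq_len(nPerm),
                     function(i) abs(stats::cor(x, sample(y))) >= obs - 1e-12,
                     logical(1)))
  (hits + 1) / (nPerm + 1)
}

# exhaustive cosine-kNN oracle over gene features
bruteForceCosineKNN <- function(coords, type, k) {
  cosd <- function(a, b) 1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  genes <- which(type == "gene")
  peaks <- which(type == "peak")
  ids <- rownames(coords)
  do.call(rbind, lapply(peaks, function(p) {
    d <- vapply(genes, function(g) cosd(coords[p, ], coords[g, ]), numeric(1))
    o <- order(d, ids[genes])[seq_len(k)]
    data.frame(peak = ids[p], gene = ids[genes][o],
               cosine_distance = pmax(d[o], 0), rank = seq_len(k))
  }))
}

# small deterministic SRT section for unit fixtures
toySection <- function(counts, pitch = 100) {
  n <- ncol(counts)
  SRTSection(counts,
             spotXY = cbind(seq_len(n) * pitch, rep(0, n)),
             inTissue = rep(TRUE, n))
}

# 6-spot QC boundary fixture: unique-gene counts {10, 50, 49, 200, 200, 200}
# and mitochondrial fractions {0, 0, 0, 0.38, 0.39, 0.10}; only the 50-gene
# spot and the two spots at <= 0.38 mito pass both strict thresholds.
qcBoundaryFixture <- function() {
  nGenes <- 250
  ids <- sprintf("g%03d", seq_len(nGenes))
  ids[nGenes] <- "mt-1"
  cts <- matrix(0L, nGenes, 6, dimnames = list(ids, paste0("s", 1:6)))
  uniq <- c(10, 50, 49, 200, 200, 200)
  # non-mito totals chosen so the mito fraction is exact in integers:
  # 190/(190+310) = 0.38, 195/(195+305) = 0.39, 40/(40+360) = 0.10
  nonMitoTotal <- c(10, 50, 49, 310, 305, 360)
  mtCount <- c(0L, 0L, 0L, 190L, 195L, 40L)
  for (j in 1:6) {
    k <- uniq[j] - (mtCount[j] > 0)          # unique non-mito genes
    cts[seq_len(k), j] <- 1L
    cts[1, j] <- cts[1, j] + (nonMitoTotal[j] - k)
    cts["mt-1", j] <- mtCount[j]
  }
  toySection(cts)
}

# two tight orthogonal feature blocks (genes + peaks copied around a shared
# direction per block); the cosine-kNN graph then splits into two components
orthogonalBlocksEmbedding <- function(seed = 36, nGene = 10, nPeak = 5) {
  set.seed(seed)
  mkBlock <- function(dims, prefix) {
    centre <- rep(0, 10)
    centre[dims] <- abs(rnorm(length(dims), 2))
    base <- matrix(rep(centre, nGene + nPeak), ncol = 10, byrow = TRUE) +
      0.05 * matrix(rnorm((nGene + nPeak) * 10), ncol = 10)
    rownames(base) <- c(sprintf("%s_g%02d", prefix, seq_len(nGene)),
                        sprintf("%s_p%02d", prefix, seq_len(nPeak)))
    base
  }
  coords <- rbind(mkBlock(1:5, "A"), mkBlock(6:10, "B"))
  new("FeatureEmbedding", coords = coords,
      feature_type = rep(rep(c("gene", "peak"), c(nGene, nPeak)), 2))
}

# a MultimodalDataset built directly from matrices via a 1:1 identity pairing
mkMM <- function(genes, peaks, mz = seq_len(nrow(peaks)) * 100 + 0.5) {
  n <- ncol(genes)
  sec <- toySection(genes)
  r <- MSIRaster(peaks, mz = mz, pixelXY = cbind(seq_len(n), 0))
  pm <- new("PairMap",
            pairs = data.frame(msi_pixel_index = seq_len(n),
                               spot_index = seq_len(n),
                               distance_px = rep(0, n)),
            unpaired = integer(), max_dist = 35)
  assembleMultimodal(sec, r, pm)
}

# a compact synthetic config used where full scale is unnecessary
smallSynthConfig <- function(seed = 1, ...) {
  synthConfig(nSpotRows = 12L, nSpotCols = 12L, nGenes = 300L, nPeaks = 8L,
              nMitoGenes = 5L, nBackgroundPixels = 40L, seed = seed, ...)
}
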