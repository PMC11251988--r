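rot <- function(thetaDeg) {
  th <- thetaDeg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# rebuild the 2x2 linear part from the transform's parameters
transformMatrixForTest <- function(t) {
  R <- rot(t@rotation_rad * 180 / pi)
  if (t@reflection) R <- R %*% diag(c(1, -1))
  t@scale * R
}

test_that("similarity fitting recovers identity and a known transform", {
  src <- cbind(c(0, 10, 0), c(0, 0, 10))
  fitId <- fitSimilarity(landmarkPairs(src, src))
  expect_equal(fitId@scale, 1, tolerance = 1e-12)
  expect_equal(fitId@rotation_rad, 0, tolerance = 1e-12)
  expect_equal(fitId@translation, c(0, 0), tolerance = 1e-12)

  src4 <- cbind(c(0, 10, 0, 10), c(0, 0, 10, 10))
  tgt <- t(2 * rot(90) %*% t(src4)) + rep(c(10, -5), each = 4)
  fit <- fitSimilarity(landmarkPairs(src4, tgt))
  expect_equal(fit@scale, 2, tolerance = 1e-8)
  expect_equal(fit@rotation_rad, pi / 2, tolerance = 1e-8)
  expect_equal(fit@translation, c(10, -5), tolerance = 1e-8)
})

test_that("the fitted transform beats 1000 random transforms in residual RMS", {
  set.seed(10)
  src <- matrix(runif(16, 0, 100), 8, 2)
  tgt <- t(1.3 * rot(25) %*% t(src)) + rep(c(5, 7), each = 8) +
    matrix(rnorm(16, 0, 2), 8, 2)
  lm <- landmarkPairs(src, tgt)
  fit <- fitSimilarity(lm)
  rmsFit <- registrationResiduals(fit, lm)$rms
  for (i in 1:1000) {
    rnd <- similarityTransform2D(scale = runif(1, 0.5, 3),
                                 rotationRad = runif(1, -pi, pi),
                                 translation = runif(2, -50, 50))
    expect_gte(registrationResiduals(rnd, lm)$rms, rmsFit)
  }
})

test_that("similarity fitting agrees with a Procrustes reference", {
  skip_if_not_installed("vegan")
  set.seed(11)
  src <- matrix(runif(20, 0, 50), 10, 2)
  tgt <- t(0.8 * rot(-40) %*% t(src)) + rep(c(-3, 12), each = 10) +
    matrix(rnorm(20, 0, 1), 10, 2)
  fit <- fitSimilarity(landmarkPairs(src, tgt))
  ref <- vegan::procrustes(tgt, src, scale = TRUE, symmetric = FALSE)
  expect_equal(fit@scale, ref$scale, tolerance = 1e-6)
  expect_equal(transformMatrixForTest(fit) / fit@scale, unname(t(ref$rotation)),
               tolerance = 1e-6)
  # both reach the same least-squares optimum
  expect_equal(registrationResiduals(fit, landmarkPairs(src, tgt))$rms^2 * 10,
               ref$ss, tolerance = 1e-6)
})

test_that("reflection is refused by default but fit when allowed", {
  set.seed(16)
  src <- matrix(runif(12, 0, 10), 6, 2)  # asymmetric configuration
  tgt <- src %*% diag(c(1, -1))          # pure mirror
  lm <- landmarkPairs(src, tgt)
  noRefl <- fitSimilarity(lm, allowReflection = FALSE)
  expect_false(noRefl@reflection)
  withRefl <- fitSimilarity(lm, allowReflection = TRUE)
  expect_true(withRefl@reflection)
  expect_equal(unname(applyTransform(withRefl, src)), unname(tgt),
               tolerance = 1e-9)
  # the proper-rotation fit cannot reach the mirrored optimum
  expect_gt(registrationResiduals(noRefl, lm)$rms,
            registrationResiduals(withRefl, lm)$rms + 1)

  expect_error(fitSimilarity(landmarkPairs(cbind(c(1, 1 + 1e-15), c(2, 2)),
                                           cbind(c(0, 5), c(0, 5)))),
               "degenerate|duplicated")
})

test_that("transforms apply, compose with their inverse, and translate purely", {
  set.seed(12)
  pts <- matrix(runif(40, -100, 100), 20, 2)
  id <- similarityTransform2D()
  expect_equal(unname(applyTransform(id, pts)), unname(pts))

  shift <- similarityTransform2D(translation = c(5, 5))
  expect_equal(unname(applyTransform(shift, pts)), unname(pts) + 5)

  tr <- similarityTransform2D(scale = 1.7, rotationRad = 0.6,
                              translation = c(-20, 33))
  back <- applyTransform(invertTransform(tr), applyTransform(tr, pts))
  expect_equal(unname(back), unname(pts), tolerance = 1e-9)

  refl <- similarityTransform2D(scale = 0.5, rotationRad = -1.1,
                                translation = c(4, 4), reflection = TRUE)
  back2 <- applyTransform(invertTransform(refl), applyTransform(refl, pts))
  expect_equal(unname(back2), unname(pts), tolerance = 1e-9)
})

test_that("pairing follows the kNN + cutoff + closest-neighbour rule", {
  cfg <- pipelineConfig()
  pm <- pairModalities(rbind(c(0, 0)), rbind(c(3, 4), c(30, 40)), cfg)
  tab <- pairTable(pm)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$spot_index, 1)
  expect_equal(tab$distance_px, 5)

  # cutoff excludes everything -> all pixels reported unpaired
  cfg0 <- pipelineConfig(maxPairDistPx = 1e-9)
  pm0 <- pairModalities(rbind(c(0, 0), c(10, 10)), rbind(c(3, 4)), cfg0)
  expect_equal(nrow(pairTable(pm0)), 0)
  expect_equal(unpairedPixels(pm0), c(1L, 2L))

  # exact tie broken towards the lower spot index; the spot is reused
  pmTie <- pairModalities(rbind(c(0, 0), c(0, 0.5)),
                          rbind(c(0, 1), c(0, -1)), cfg)
  expect_equal(pairTable(pmTie)$spot_index, c(1L, 1L))
})

test_that("pairing equals the brute-force all-pairs oracle on random instances", {
  set.seed(13)
  cfg <- pipelineConfig()
  for (i in 1:100) {
    nM <- sample(20:500, 1)
    nS <- sample(20:500, 1)
    # mixed scales so some instances have dense, some sparse neighbourhoods
    span <- sample(c(100, 300, 1000), 1)
    msiXY <- matrix(runif(2 * nM, 0, span), nM, 2)
    spotXY <- matrix(runif(2 * nS, 0, span), nS, 2)
    got <- pairTable(pairModalities(msiXY, spotXY, cfg))
    want <- bruteForcePair(msiXY, spotXY, cfg$max_pair_dist_px)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("PairMap invariants hold on every output", {
  set.seed(14)
  cfg <- pipelineConfig()
  msiXY <- matrix(runif(400, 0, 500), 200, 2)
  spotXY <- matrix(runif(400, 0, 500), 200, 2)
  pm <- pairModalities(msiXY, spotXY, cfg)
  tab <- pairTable(pm)
  expect_false(anyDuplicated(tab$msi_pixel_index) > 0)
  expect_true(all(tab$distance_px <= cfg$max_pair_dist_px))
  expect_setequal(c(tab$msi_pixel_index, unpairedPixels(pm)), 1:200)
  expect_error(pairModalities(msiXY, matrix(0, 0, 2), cfg), "empty spot")
})

test_that("multimodal assembly duplicates reused spots and validates indices", {
  cts <- matrix(1:12, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  sec <- toySection(cts)
  r <- MSIRaster(matrix(runif(12, 1, 5), 2, 6), mz = c(100.1, 200.2),
                 pixelXY = cbind(1:6, rep(0, 6)))
  pm <- new("PairMap",
            pairs = data.frame(msi_pixel_index = c(5L, 1L, 3L),
                               spot_index = c(2L, 2L, 4L),
                               distance_px = c(1, 2, 3)),
            unpaired = c(2L, 4L, 6L), max_dist = 35)
  mm <- assembleMultimodal(sec, r, pm)
  expect_s4_class(mm, "MultimodalDataset")
  expect_equal(ncol(mm), 3)
  # observation order is ascending MSI pixel index
  expect_equal(SummarizedExperiment::colData(mm)$msi_pixel_index, c(1L, 3L, 5L))
  expect_equal(SummarizedExperiment::colData(mm)$barcode, c("s2", "s4", "s2"))
  genes <- SummarizedExperiment::assay(mm, "counts")
  expect_equal(unname(genes[, 1]), unname(genes[, 3]))  # s2 duplicated
  peaks <- SummarizedExperiment::assay(SingleCellExperiment::altExp(mm, "peaks"),
                                       "intensities")
  expect_equal(ncol(peaks), 3)

  pmEmpty <- new("PairMap", pairs = pm@pairs[0, ], unpaired = 1:6, max_dist = 35)
  expect_error(assembleMultimodal(sec, r, pmEmpty), "empty PairMap")
  pmBad <- new("PairMap",
               pairs = data.frame(msi_pixel_index = 1L, spot_index = 9L,
                                  distance_px = 0), unpaired = integer(),
               max_dist = 35)
  expect_error(assembleMultimodal(sec, r, pmBad), "out of range")
})

test_that("distance-cutoff suggestion splits a bimodal mixture and scales", {
  set.seed(15)
  d <- c(rnorm(500, 10, 2), rnorm(200, 80, 5))
  d <- d[d > 0]
  thr <- suggestDistanceCutoff(d)
  expect_gt(thr, 20)
  expect_lt(thr, 70)
  expect_equal(suggestDistanceCutoff(d * 3), 3 * thr, tolerance = 1e-9)
  expect_warning(thrEq <- suggestDistanceCutoff(rep(7, 60)), "equal")
  expect_equal(thrEq, 7)
  expect_error(suggestDistanceCutoff(1:10), "at least 50")
})
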