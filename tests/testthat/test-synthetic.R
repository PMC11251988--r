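test_that("the SRT generator produces the configured lattice and count model", {
  cfg <- smallSynthConfig(seed = 3)
  srt <- generateSRT(cfg)
  expect_equal(ncol(srt), cfg$n_spot_rows * cfg$n_spot_cols)
  expect_equal(nrow(srt), cfg$n_genes)
  cts <- SummarizedExperiment::assay(srt, "counts")
  expect_true(all(cts >= 0))
  expect_true(all(cts == floor(cts)))
  expect_setequal(unique(annotations(srt)), c("intact", "lesioned"))
  expect_equal(sum(grepl("^mt-", rownames(srt))), cfg$n_mito_genes)
  expect_equal(length(unique(SummarizedExperiment::colData(srt)$region)),
               cfg$n_domains)
  # hemispheres split along x: every intact spot lies left of every lesioned
  xy <- spotCoords(srt)
  expect_lt(max(xy[annotations(srt) == "intact", 1]),
            min(xy[annotations(srt) == "lesioned", 1]) + cfg$spot_pitch_px)
})

test_that("generators are pure functions of config and seed", {
  cfg <- smallSynthConfig(seed = 11)
  a <- generateDataset(cfg)
  b <- generateDataset(cfg)
  expect_identical(SummarizedExperiment::assay(a$srt, "counts"),
                   SummarizedExperiment::assay(b$srt, "counts"))
  expect_identical(SummarizedExperiment::assay(a$raster, "intensities"),
                   SummarizedExperiment::assay(b$raster, "intensities"))
  expect_identical(a$landmarks, b$landmarks)
  expect_false(identical(
    SummarizedExperiment::assay(a$srt, "counts"),
    SummarizedExperiment::assay(generateSRT(smallSynthConfig(seed = 12)), "counts")))
})

test_that("domain marker genes outrank null genes in a Wilcoxon screen", {
  hits <- 0
  for (s in 1:20) {
    cfg <- smallSynthConfig(seed = 100 + s)
    srt <- generateSRT(cfg)
    normed <- normalizeLogCPM(srt)
    tab <- rankMarkers(normed, SummarizedExperiment::colData(srt)$region,
                       pipelineConfig())
    planted <- rownames(srt)[srt@int_metadata$domain_markers[[1]]]
    reg1 <- tab[tab$cluster == "region1", ]
    rk <- rank(reg1$pval)
    isPlanted <- reg1$gene %in% planted
    hits <- hits + (mean(rk[isPlanted]) < mean(rk[!isPlanted]))
  }
  expect_gte(hits, 19)   # planted markers outrank nulls in >= 95% of seeds
})

test_that("planted links realise their target correlation at the pixel level", {
  cfg <- synthConfig(seed = 21)
  srt <- generateSRT(cfg)
  msi <- generateMSI(cfg, srt)
  truth <- msi$truth
  tissue <- !truth$off_tissue
  peakRow <- cfg$planted_links$peak[1]
  intens <- SummarizedExperiment::assay(msi$raster, "intensities")[peakRow, tissue]
  z <- scale(normalizeLogCPM(srt)[cfg$planted_links$gene[1], ])[, 1]
  r <- cor(intens, z[truth$nearest_spot[tissue]])
  expect_gt(r, 0.75)
  expect_lt(r, 0.85)
})

test_that("a full lesion empties the lesioned hemisphere of the lesion peak", {
  cfg <- smallSynthConfig(seed = 22, lesionDepletion = 1)
  srt <- generateSRT(cfg)
  msi <- generateMSI(cfg, srt)
  truth <- msi$truth
  tissue <- which(!truth$off_tissue)
  v <- SummarizedExperiment::assay(msi$raster, "intensities")[cfg$lesion_peak_index, tissue]
  hemi <- truth$hemisphere[truth$nearest_spot[tissue]]
  expect_lt(mean(v[hemi == "lesioned"]), 0.05 * mean(v[hemi == "intact"]))
})

test_that("identity transform with equal pitches nests pixels exactly on spots", {
  cfg <- smallSynthConfig(seed = 23,
                          trueTransform = similarityTransform2D(),
                          landmarkJitterPx = 0)
  srt <- generateSRT(cfg)
  msi <- generateMSI(cfg, srt)
  truth <- msi$truth
  tissue <- !truth$off_tissue
  expect_true(all(truth$nearest_dist[tissue] < 1e-9))
  # native coordinates equal common coordinates under the identity transform
  expect_equal(unname(pixelCoords(msi$raster)[tissue, ]),
               unname(truth$pixel_common[tissue, ]), tolerance = 1e-9)
})

test_that("noiseless landmarks recover the true transform to 1e-8", {
  cfg <- smallSynthConfig(seed = 24, landmarkJitterPx = 0)
  ds <- generateDataset(cfg)
  fit <- fitSimilarity(ds$landmarks)
  tt <- cfg$true_transform
  expect_equal(fit@scale, tt@scale, tolerance = 1e-8)
  expect_equal(fit@rotation_rad, tt@rotation_rad, tolerance = 1e-8)
  expect_equal(fit@translation, tt@translation, tolerance = 1e-6)

  # minimal configuration: 2 landmarks pin down all 4 degrees of freedom
  cfg2 <- smallSynthConfig(seed = 25, landmarkJitterPx = 0, nLandmarks = 2)
  ds2 <- generateDataset(cfg2)
  fit2 <- fitSimilarity(ds2$landmarks)
  expect_equal(fit2@scale, tt@scale, tolerance = 1e-8)
  expect_equal(fit2@rotation_rad, tt@rotation_rad, tolerance = 1e-8)
})

test_that("jittered landmarks keep the mapping error within 2 px RMS", {
  rms <- vapply(1:20, function(s) {
    cfg <- smallSynthConfig(seed = 200 + s)   # jitter 1 px, 8 landmarks
    ds <- generateDataset(cfg)
    fit <- fitSimilarity(ds$landmarks)
    tissue <- !ds$truth$off_tissue
    mapped <- applyTransform(fit, pixelCoords(ds$raster)[tissue, ])
    sqrt(mean(rowSums((mapped - ds$truth$pixel_common[tissue, ])^2)))
  }, numeric(1))
  expect_lt(mean(rms), 2)
  expect_gte(mean(rms <= 2), 0.9)
})

test_that("generator config validation rejects inconsistent settings", {
  expect_error(synthConfig(msiPitchPx = -1), "msiPitchPx")
  expect_error(synthConfig(plantedLinks = data.frame(peak = 1L, gene = 1L, r = 1.2)),
               "\\(0, 1\\)")
  expect_error(synthConfig(plantedLinks = data.frame(peak = c(1L, 2L),
                                                     gene = c(3L, 3L),
                                                     r = c(0.5, 0.6))),
               "distinct")
  expect_error(synthConfig(lesionDepletion = 1.5), "lesionDepletion")
  expect_error(synthConfig(nGenes = 100L, plantedLinks =
                             data.frame(peak = 1L, gene = 200L, r = 0.5)),
               "exceed")
})

test_that("written synthetic data round-trips through the directory readers", {
  cfg <- smallSynthConfig(seed = 26)
  ds <- generateDataset(cfg)
  d <- withr::local_tempdir()
  writeSRTdir(ds$srt, file.path(d, "srt"))
  srt2 <- readSRTdir(file.path(d, "srt"))
  expect_equal(as.matrix(SummarizedExperiment::assay(srt2, "counts")),
               as.matrix(SummarizedExperiment::assay(ds$srt, "counts")),
               ignore_attr = TRUE)
  expect_identical(annotations(srt2), annotations(ds$srt))

  writeMSIcsv(ds$raster, file.path(d, "msi.csv"))
  r2 <- readMSI(file.path(d, "msi.csv"))
  expect_equal(unname(SummarizedExperiment::assay(r2, "intensities")),
               unname(SummarizedExperiment::assay(ds$raster, "intensities")),
               tolerance = 1e-10)
  expect_equal(mzValues(r2), mzValues(ds$raster), tolerance = 1e-4)
})
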