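mkEmbedding <- function(coords, type) {
  new("FeatureEmbedding", coords = coords, feature_type = type)
}

# a MultimodalDataset where one peak duplicates one gene's z-scored profile
dupFeatureMM <- function(n = 100, seed = 30) {
  set.seed(seed)
  genes <- matrix(rpois(40 * n, 10) + 1L, 40, n,
                  dimnames = list(sprintf("g%02d", 1:40), NULL))
  mm0 <- mkMM(genes, matrix(runif(n, 1, 2), 1, n), mz = 500.5)
  z <- scale(SummarizedExperiment::assay(mm0, "logcounts")["g01", ])[, 1]
  # expm1 of the z-profile so that log1p(peak) reproduces it exactly
  peak <- expm1(z - min(z))
  mkMM(genes, rbind(peak), mz = 500.5)
}

test_that("a peak duplicating a gene lands on top of it in the co-embedding", {
  mm <- dupFeatureMM()
  emb <- jointEmbedding(mm, rownames(mm), pipelineConfig(nPCs = 10))
  coords <- emb@coords
  gi <- which(rownames(coords) == "g01")
  pi <- which(emb@feature_type == "peak")
  # identical z-scored columns -> identical embeddings
  expect_equal(coords[gi, ], coords[pi, ], tolerance = 1e-8)
  gr <- peakKNN(emb, pipelineConfig(knnPeaks = 3))
  top <- gr@edges[gr@edges$rank == 1, ]
  expect_equal(top$gene, "g01")
  expect_equal(top$cosine_distance, 0, tolerance = 1e-8)
})

test_that("embeddings of independent white-noise features are near-orthogonal", {
  set.seed(31)
  n <- 2000
  genes <- matrix(rpois(20 * n, 20) + 1L, 20, n,
                  dimnames = list(sprintf("g%02d", 1:20), NULL))
  peaks <- matrix(runif(5 * n, 1, 10), 5, n)
  mm <- mkMM(genes, peaks)
  # full-rank embedding: feature coords then satisfy coords %*% t(coords)
  # = crossprod(X), so embedding cosine ~ sample correlation ~ 1/sqrt(n)
  emb <- jointEmbedding(mm, rownames(mm), pipelineConfig(nPCs = 25))
  a <- emb@coords[rownames(emb@coords) == "g01", ]
  b <- emb@coords[emb@feature_type == "peak", ][1, ]
  cosSim <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_lt(abs(cosSim), 0.15)
})

test_that("the co-embedding is deterministic and observation-order invariant", {
  mm <- dupFeatureMM(n = 60, seed = 32)
  cfg <- pipelineConfig(nPCs = 8)
  e1 <- jointEmbedding(mm, rownames(mm), cfg)
  e2 <- jointEmbedding(mm, rownames(mm), cfg)
  expect_identical(e1@coords, e2@coords)
  set.seed(33)
  perm <- sample(ncol(mm))
  e3 <- jointEmbedding(mm[, perm], rownames(mm), cfg)
  expect_equal(e3@coords, e1@coords, tolerance = 1e-8)
})

test_that("embedding input validation catches bad HVGs and tiny n", {
  mm <- dupFeatureMM(n = 40, seed = 34)
  expect_error(jointEmbedding(mm, c("g01", "nope"), pipelineConfig(nPCs = 5)),
               "nope")
  expect_error(jointEmbedding(mm, rownames(mm), pipelineConfig(nPCs = 50)),
               ">= 50")
  # constant feature is dropped with a warning, not embedded as NaN
  SummarizedExperiment::assay(mm, "logcounts")["g02", ] <- 1
  expect_warning(e <- jointEmbedding(mm, rownames(mm), pipelineConfig(nPCs = 5)),
                 "constant")
  expect_false("g02" %in% rownames(e@coords))
  expect_true(all(is.finite(e@coords)))
})

test_that("peak kNN equals exhaustive cosine search on random embeddings", {
  set.seed(35)
  cfg <- pipelineConfig(knnPeaks = 10)
  for (i in 1:50) {
    coords <- matrix(rnorm(220 * 10), 220, 10)
    rownames(coords) <- c(sprintf("gene%03d", 1:200), sprintf("peak%02d", 1:20))
    type <- c(rep("gene", 200), rep("peak", 20))
    emb <- mkEmbedding(coords, type)
    got <- peakKNN(emb, cfg)@edges
    want <- bruteForceCosineKNN(coords, type, 10)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("peak kNN edge cases: complete graph, zero vectors, missing types", {
  coords <- rbind(diag(4), c(1, 1, 0, 0))
  rownames(coords) <- c(paste0("g", 1:4), "p1")
  type <- c(rep("gene", 4), "peak")
  gr <- peakKNN(mkEmbedding(coords, type), pipelineConfig(knnPeaks = 4))
  expect_equal(nrow(gr@edges), 4)   # knn_peaks = gene count -> complete
  expect_equal(gr@edges$gene[1:2], c("g1", "g2"))  # tie at d=1-1/sqrt(2) broken by id

  bad <- coords; bad[2, ] <- 0
  expect_error(peakKNN(mkEmbedding(bad, type), pipelineConfig()), "g2")
  expect_error(peakKNN(mkEmbedding(coords[1:4, , drop = FALSE],
                                   rep("gene", 4)), pipelineConfig()),
               "no peaks")
})

test_that("spinglass recovers disconnected planted blocks exactly", {
  skip_if_not_installed("mclust")
  # two orthogonal blocks: peaks copied from genes of block A vs block B
  emb <- orthogonalBlocksEmbedding(seed = 36)
  gr <- peakKNN(emb, pipelineConfig(knnPeaks = 10))
  expect_equal(igraph::components(igraph::graph_from_data_frame(
    gr@edges[, c("peak", "gene")], directed = FALSE))$no, 2)
  gr <- detectModules(gr, pipelineConfig(seed = 99))
  comm <- communityLabels(gr)
  truthBlock <- substr(names(comm), 1, 1)
  expect_equal(mclust::adjustedRandIndex(comm, truthBlock), 1.0)
  expect_equal(length(unique(comm)), 2)
})

test_that("module detection is reproducible and handles degenerate graphs", {
  set.seed(37)
  coords <- matrix(rnorm(300), 30, 10)
  rownames(coords) <- c(sprintf("g%02d", 1:20), sprintf("p%02d", 1:10))
  type <- rep(c("gene", "peak"), c(20, 10))
  gr <- peakKNN(mkEmbedding(coords, type), pipelineConfig(knnPeaks = 5))
  c1 <- communityLabels(detectModules(gr, pipelineConfig(seed = 7)))
  c2 <- communityLabels(detectModules(gr, pipelineConfig(seed = 7)))
  expect_identical(c1, c2)

  single <- gr
  single@edges <- gr@edges[1, , drop = FALSE]
  single@nodes <- gr@nodes[gr@nodes$id %in% unlist(single@edges[, c("peak", "gene")]), ]
  cs <- communityLabels(detectModules(single, pipelineConfig()))
  expect_equal(cs[[1]], cs[[2]])

  none <- gr
  none@edges <- gr@edges[0, ]
  expect_warning(out <- detectModules(none, pipelineConfig()), "no edges")
  expect_equal(length(unique(communityLabels(out))), nrow(gr@nodes))
})

test_that("the exported neighbour table is complete, ordered and reversible", {
  set.seed(38)
  coords <- matrix(rnorm(130), 13, 10)
  rownames(coords) <- c(sprintf("g%02d", 1:10), sprintf("p%d", 1:3))
  type <- rep(c("gene", "peak"), c(10, 3))
  gr <- detectModules(peakKNN(mkEmbedding(coords, type),
                              pipelineConfig(knnPeaks = 10)))
  tab <- exportPeakGeneTable(gr)
  expect_equal(nrow(tab), 30)          # 3 peaks x 10 neighbours
  for (p in unique(tab$peak_mz))
    expect_identical(tab$rank[tab$peak_mz == p], 1:10)
  expect_false(any(is.na(tab$community_of_peak)))

  back <- importPeakGeneTable(tab)
  reEx <- exportPeakGeneTable(back)
  expect_equal(reEx[order(reEx$peak_mz, reEx$rank), ],
               tab[order(tab$peak_mz, tab$rank), ],
               ignore_attr = TRUE)
})
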