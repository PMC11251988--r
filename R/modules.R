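#' Joint PCA co-embedding of genes and peaks
#'
#' Builds the observations x features matrix by column-binding z-scored
#' log-normalised HVG expression with z-scored `log1p` peak intensities,
#' then takes an SVD and places each *feature* at its principal-axis
#' coordinates (loading vector scaled by the corresponding singular values).
#' Features that vary together across the tissue land close together —
#' whether they are genes or peaks — which is what the downstream cosine-kNN
#' search exploits. Component signs are fixed by forcing the
#' largest-magnitude loading of each component positive, making repeated
#' runs bit-identical. Constant features cannot be z-scored and are dropped
#' with a warning.
#'
#' @param mm a [MultimodalDataset-class] with at least `cfg$n_pcs`
#'   observations.
#' @param hvgs gene identifiers to embed (subset of `rownames(mm)`),
#'   typically from [selectHVGs()].
#' @param cfg a [pipelineConfig()]; `n_pcs` components are retained.
#' @return a [FeatureEmbedding-class] (genes first, then peaks).
#' @export
jointEmbedding <- function(mm, hvgs, cfg = pipelineConfig()) {
  miss <- setdiff(hvgs, rownames(mm))
  if (length(miss))
    stop("HVG(s) absent from the dataset: ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  n <- ncol(mm)
  if (n < cfg$n_pcs)
    stop("need >= ", cfg$n_pcs, " observations for ", cfg$n_pcs,
         " components (got ", n, ")", call. = FALSE)
  G <- t(assay(mm, "logcounts")[hvgs, , drop = FALSE])        # obs x genes
  P <- t(log1p(assay(altExp(mm, "peaks"), "intensities")))     # obs x peaks
  X <- cbind(G, P)
  type <- c(rep("gene", ncol(G)), rep("peak", ncol(P)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant feature(s) dropped from the embedding")
    type <- type[sds > 0]; X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  X <- scale(X, center = TRUE, scale = sds)
  d <- min(cfg$n_pcs, ncol(X), n - 1L)
  sv <- svd(X, nu = 0, nv = d)
  sing <- sv$d[seq_len(d)]
  V <- sv$v
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(d)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  coords <- V %*% diag(sing, nrow = d)
  rownames(coords) <- colnames(X)
  colnames(coords) <- paste0("PC", seq_len(d))
  new("FeatureEmbedding", coords = coords, feature_type = type)
}

cosineDistance <- function(A, B) {
  # rows of A vs rows of B; 1 - cosine similarity, in [0, 2]
  nA <- sqrt(rowSums(A^2)); nB <- sqrt(rowSums(B^2))
  sim <- (A %*% t(B)) / outer(nA, nB)
  sim[sim > 1] <- 1
  sim[sim < -1] <- -1
  1 - sim
}

#' Cosine k-nearest-gene search per peak
#'
#' For every peak feature, finds the `cfg$knn_peaks` gene features with
#' smallest cosine distance (1 - cosine similarity) in the joint embedding
#' and records them as directed ranked edges. The search is exhaustive, so
#' results are exact nearest neighbours; ties are broken by gene identifier.
#' The search ranges over genes only — the readout is "which genes co-vary
#' with this peak".
#'
#' @param embedding a [FeatureEmbedding-class] with >= 1 peak and >=
#'   `cfg$knn_peaks` genes (with fewer genes, all of them are linked).
#' @param cfg a [pipelineConfig()].
#' @return a [PeakGeneGraph-class].
#' @export
peakKNN <- function(embedding, cfg = pipelineConfig()) {
  coords <- embedding@coords
  type <- embedding@feature_type
  if (!any(type == "peak")) stop("embedding contains no peaks", call. = FALSE)
  if (!any(type == "gene")) stop("embedding contains no genes", call. = FALSE)
  norms <- sqrt(rowSums(coords^2))
  if (any(norms == 0))
    stop("zero-vector embedding for feature '",
         rownames(coords)[which(norms == 0)[1]], "'", call. = FALSE)
  Gc <- coords[type == "gene", , drop = FALSE]
  Pc <- coords[type == "peak", , drop = FALSE]
  k <- min(cfg$knn_peaks, nrow(Gc))
  D <- cosineDistance(Pc, Gc)
  geneIds <- rownames(Gc)
  edges <- do.call(rbind, lapply(seq_len(nrow(Pc)), function(i) {
    o <- order(D[i, ], geneIds)[seq_len(k)]
    data.frame(peak = rownames(Pc)[i], gene = geneIds[o],
               cosine_distance = pmax(D[i, o], 0), rank = seq_len(k))
  }))
  nodes <- data.frame(id = c(geneIds, rownames(Pc)),
                      type = c(rep("gene", nrow(Gc)), rep("peak", nrow(Pc))),
                      community = NA_integer_)
  new("PeakGeneGraph", nodes = nodes, edges = edges, k = as.integer(k))
}

#' Spinglass community detection on the peak-gene graph
#'
#' Labels spatially co-detected modules: groups of peaks and genes that are
#' mutual neighbours in the co-embedding. Edge weights are cosine
#' similarities (`1 - distance`) clipped at 0; the directed kNN graph is
#' symmetrised by maximum weight (the spinglass implementation operates on
#' undirected graphs) and the ferromagnetic Potts-model objective is
#' optimised by simulated annealing, seeded from `cfg$seed` for
#' reproducibility. Detection runs per weakly-connected component; isolated
#' nodes (or a graph with no edges, which triggers a warning) each form
#' their own community.
#'
#' The resolution default is `gamma = 0.5` rather than the textbook 1: the
#' kNN graph is bipartite (edges only run peak -> gene), and for such graphs
#' the configuration-null Potts objective at gamma = 1 is exactly degenerate
#' between one community per connected block and a partition into per-peak
#' stars — with uniform weights both have identical energy, so annealing
#' shatters genuine modules. Halving gamma compensates for the null model's
#' overestimate of expected within-type weight (no gene-gene or peak-peak
#' edges exist to realise it); see the vignette for the derivation.
#'
#' @param graph a [PeakGeneGraph-class] from [peakKNN()].
#' @param cfg a [pipelineConfig()]; `seed` fixes the annealing.
#' @param gamma spinglass resolution parameter (default 0.5; larger values
#'   give smaller, tighter modules).
#' @return the graph with integer community labels filled into its nodes
#'   (retrieve with [communityLabels()]). Labels are arbitrary integers,
#'   stable across runs with the same seed.
#' @export
detectModules <- function(graph, cfg = pipelineConfig(), gamma = 0.5) {
  nodes <- graph@nodes
  ed <- graph@edges
  if (nrow(ed) == 0) {
    warning("graph has no edges; every node is its own community")
    nodes$community <- seq_len(nrow(nodes))
    graph@nodes <- nodes
    return(graph)
  }
  w <- pmax(1 - ed$cosine_distance, 0)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ed$peak, to = ed$gene, weight = w),
    directed = FALSE, vertices = nodes$id)
  # parallel edges (a peak pair sharing reciprocal links) -> max weight
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "max"))
  comp <- igraph::components(g, mode = "weak")
  labels <- integer(igraph::vcount(g))
  nextLabel <- 0L
  haveSeed <- exists(".Random.seed", envir = globalenv())
  oldSeed <- if (haveSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (haveSeed) assign(".Random.seed", oldSeed, envir = globalenv()))
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    # 1-node components are singleton communities; a 2-node component is one
    # community by definition (and the annealer cannot run on 2 vertices)
    if (length(vs) <= 2) {
      labels[vs] <- nextLabel + 1L
      nextLabel <- nextLabel + 1L
      next
    }
    sub <- igraph::induced_subgraph(g, vs)
    if (all(igraph::E(sub)$weight == 0)) {
      labels[vs] <- nextLabel + seq_along(vs)
      nextLabel <- nextLabel + length(vs)
      next
    }
    set.seed(cfg$seed + ci)
    cl <- igraph::cluster_spinglass(sub, weights = igraph::E(sub)$weight,
                                    gamma = gamma,
                                    spins = min(25L, length(vs)))
    m <- igraph::membership(cl)
    labels[vs] <- nextLabel + as.integer(m)
    nextLabel <- nextLabel + max(as.integer(m))
  }
  nodes$community <- labels[match(nodes$id, igraph::V(g)$name)]
  graph@nodes <- nodes
  graph
}

#' Community labels of a PeakGeneGraph
#' @param graph a [PeakGeneGraph-class] after [detectModules()].
#' @return named integer vector (node id -> community).
#' @export
communityLabels <- function(graph) {
  stats::setNames(graph@nodes$community, graph@nodes$id)
}

#' Export the peak-gene neighbour table
#'
#' One row per directed edge: the peak's m/z label, neighbour rank, gene,
#' cosine distance and (when modules have been detected) the community of
#' each endpoint. Rows are ordered by peak then ascending rank.
#'
#' @param graph a [PeakGeneGraph-class].
#' @return data.frame with columns `peak_mz`, `rank`, `gene`,
#'   `cosine_distance`, `community_of_peak`, `community_of_gene`.
#' @seealso [importPeakGeneTable()] for the inverse.
#' @export
exportPeakGeneTable <- function(graph) {
  ed <- graph@edges
  comm <- stats::setNames(graph@nodes$community, graph@nodes$id)
  out <- data.frame(
    peak_mz = ed$peak, rank = ed$rank, gene = ed$gene,
    cosine_distance = ed$cosine_distance,
    community_of_peak = unname(comm[ed$peak]),
    community_of_gene = unname(comm[ed$gene]))
  out[order(out$peak_mz, out$rank), ]
}

#' Rebuild a PeakGeneGraph from an exported table
#' @param table a data.frame from [exportPeakGeneTable()].
#' @return a [PeakGeneGraph-class] with the same edge set.
#' @export
importPeakGeneTable <- function(table) {
  edges <- data.frame(peak = table$peak_mz, gene = table$gene,
                      cosine_distance = table$cosine_distance,
                      rank = table$rank)
  peakIds <- unique(table$peak_mz)
  geneIds <- setdiff(unique(table$gene), peakIds)
  pc <- table$community_of_peak[match(peakIds, table$peak_mz)]
  gc <- table$community_of_gene[match(geneIds, table$gene)]
  nodes <- data.frame(id = c(geneIds, peakIds),
                      type = c(rep("gene", length(geneIds)),
                               rep("peak", length(peakIds))),
                      community = c(gc, pc))
  new("PeakGeneGraph", nodes = nodes, edges = edges,
      k = as.integer(max(table$rank)))
}
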