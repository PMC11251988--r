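#' Spot quality-control filter
#'
#' Removes low-quality spots: those detecting fewer than
#' `cfg$min_genes_per_spot` unique genes, those whose mitochondrial count
#' fraction exceeds `cfg$max_mito_frac` (both thresholds strict, i.e. a spot
#' at exactly 50 genes or exactly 38\% mitochondrial counts is kept), spots
#' outside the tissue, and any explicitly excluded barcodes (e.g. under
#' sectioning artifacts). Mitochondrial genes are recognised by the
#' case-insensitive symbol prefix `mt-`.
#'
#' @param section an [SRTSection-class].
#' @param cfg a [pipelineConfig()].
#' @param excludeBarcodes character vector of barcodes to drop regardless of
#'   the metric filters.
#' @return the filtered [SRTSection-class]; per-criterion removal counts are
#'   recorded in the QC log (`qcLog()`), and spots failing several criteria
#'   are tallied once under each.
#' @export
filterSpots <- function(section, cfg = pipelineConfig(),
                        excludeBarcodes = character()) {
  if (ncol(section) == 0) stop("section has no spots", call. = FALSE)
  cts <- assay(section, "counts")
  nGenes <- Matrix::colSums(cts > 0)
  mito <- grepl("^mt-", rownames(section), ignore.case = TRUE)
  tot <- Matrix::colSums(cts)
  mitoFrac <- ifelse(tot > 0, Matrix::colSums(cts[mito, , drop = FALSE]) / tot, 0)

  failGenes <- nGenes < cfg$min_genes_per_spot
  failMito <- mitoFrac > cfg$max_mito_frac
  failTissue <- !inTissue(section)
  failExcl <- colnames(section) %in% excludeBarcodes
  keep <- !(failGenes | failMito | failTissue | failExcl)

  log <- list(input = ncol(section),
              low_unique_genes = sum(failGenes),
              high_mito_fraction = sum(failMito),
              off_tissue = sum(failTissue),
              excluded_barcode = sum(failExcl),
              retained = sum(keep))
  if (!any(keep))
    stop("all spots removed by QC (",
         paste(names(log), unlist(log), sep = "=", collapse = ", "), ")",
         call. = FALSE)
  out <- section[, keep]
  out@int_metadata$qc_log <- log
  out
}

#' QC log of a filtered section
#' @param section an [SRTSection-class] returned by [filterSpots()].
#' @return named list of removal counts, or `NULL` if never filtered.
#' @export
qcLog <- function(section) section@int_metadata$qc_log

#' Remove confounding gene families
#'
#' Drops haemoglobin genes (`Hba*`/`Hbb*`, `HBA*`/`HBB*`), ribosomal-protein
#' genes (`Rps*`/`Rpl*`) and `Malat1` — families whose expression reflects
#' blood contamination or dominates variance rather than tissue biology.
#' Matching is case-insensitive on the symbol prefix, so the same patterns
#' serve mouse and human symbols.
#'
#' @param section an [SRTSection-class] with gene symbols as identifiers.
#' @param species `"mouse"` or `"human"` (same patterns; kept for interface
#'   clarity and future divergence).
#' @return the filtered section, with the removal count in `qcLog()` under
#'   `genes_removed`.
#' @export
filterGenes <- function(section, species = c("mouse", "human")) {
  species <- match.arg(species)
  drop <- grepl("^Hb[ab]", rownames(section), ignore.case = TRUE) |
    grepl("^Rp[sl]", rownames(section), ignore.case = TRUE) |
    grepl("^Malat1$", rownames(section), ignore.case = TRUE)
  out <- section[!drop, ]
  out@int_metadata$qc_log <- c(section@int_metadata$qc_log,
                               list(genes_removed = sum(drop)))
  out
}

#' Log-CPM normalisation
#'
#' Per-spot library-size normalisation to 10,000 counts followed by
#' `log(1 + x)` — a monotone per-spot transform sufficient for the
#' correlation and embedding stages downstream.
#'
#' @param x an [SRTSection-class] or a genes x spots count matrix.
#' @return a dense numeric matrix of the same dimensions.
#' @export
normalizeLogCPM <- function(x) {
  cts <- if (is(x, "SRTSection")) assay(x, "counts") else x
  tot <- Matrix::colSums(cts)
  if (any(tot == 0)) {
    bc <- colnames(cts)[which(tot == 0)[1]]
    stop("spot with zero total counts: '",
         if (is.null(bc)) which(tot == 0)[1] else bc,
         "'; run filterSpots() first", call. = FALSE)
  }
  out <- as.matrix(cts %*% Matrix::Diagonal(x = 1e4 / tot))
  dimnames(out) <- dimnames(cts)
  log1p(out)
}

#' Select highly variable genes
#'
#' Ranks genes by standardised variance: the variance of the normalised
#' values divided by a fitted mean-variance trend (degree-2 polynomial of
#' log-variance on log-mean over all expressed genes). Deterministic; ties
#' broken by lexicographic gene identifier. Constant genes are never
#' selected while non-constant genes remain.
#'
#' @param normed normalised matrix from [normalizeLogCPM()] (genes x spots),
#'   with gene identifiers as rownames.
#' @param n number of genes to return.
#' @return character vector of `n` gene identifiers, most variable first.
#' @export
selectHVGs <- function(normed, n) {
  if (n > nrow(normed))
    stop("requested ", n, " HVGs but only ", nrow(normed), " genes present",
         call. = FALSE)
  mu <- rowMeans(normed)
  v <- apply(normed, 1, stats::var)
  std <- rep(0, length(v))
  usable <- v > 0 & mu > 0
  lmu <- log(mu[usable])
  # the trend needs a real spread of means; with (near-)identical means the
  # polynomial would chase variance noise, so fall back to a flat trend
  if (sum(usable) >= 10 && diff(range(lmu)) > 0.1) {
    lm_fit <- stats::lm(log(v[usable]) ~ stats::poly(lmu, 2))
    trend <- exp(stats::fitted(lm_fit))
    std[usable] <- v[usable] / trend
  } else {
    std[usable] <- v[usable]
  }
  ids <- rownames(normed)
  ord <- order(-std, ids)
  ids[ord][seq_len(n)]
}

# Vectorised two-sided Wilcoxon rank-sum p-values, one per gene (matrix row),
# group1 vs rest, normal approximation with tie and continuity correction.
wilcoxonVec <- function(normed, inGroup) {
  n <- ncol(normed)
  n1 <- sum(inGroup)
  n2 <- n - n1
  ranks <- t(apply(normed, 1, rank))
  W <- rowSums(ranks[, inGroup, drop = FALSE])
  muW <- n1 * (n + 1) / 2
  # tie correction: sum of (t^3 - t) over tie groups, per gene
  tieTerm <- apply(normed, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  })
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
  z <- pmax(abs(W - muW) - 0.5, 0) / sqrt(pmax(sigma2, .Machine$double.eps))
  p <- 2 * stats::pnorm(-z)
  p[sigma2 <= 0] <- 1  # all-tied gene: no information
  pmin(p, 1)
}

#' Rank cluster marker genes
#'
#' For every cluster and gene, tests in-cluster expression against all other
#' spots with a two-sided Wilcoxon rank-sum test (normal approximation with
#' tie and continuity correction) and applies Bonferroni correction across
#' all genes x clusters. The log2 fold change compares de-logged means:
#' `log2((mean(expm1(in)) + 1e-9) / (mean(expm1(rest)) + 1e-9))`. A gene is
#' a significant marker when `log2fc > cfg$log2fc_min` and
#' `p_adjusted < cfg$padj_max` (both strict).
#'
#' @param normed normalised matrix from [normalizeLogCPM()].
#' @param labels cluster label per spot (character/factor), >= 2 clusters
#'   with >= 3 spots each.
#' @param cfg a [pipelineConfig()].
#' @return data.frame with columns `cluster`, `gene`, `log2fc`, `pval`,
#'   `padj`, `significant`, ordered within cluster by decreasing log2fc.
#' @export
rankMarkers <- function(normed, labels, cfg = pipelineConfig()) {
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(normed))
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 clusters", call. = FALSE)
  if (any(tab < 3))
    stop("cluster(s) with fewer than 3 spots: ",
         paste(names(tab)[tab < 3], collapse = ", "), call. = FALSE)
  expd <- expm1(normed)
  m <- nrow(normed) * length(tab)
  res <- lapply(names(tab), function(cl) {
    inG <- labels == cl
    p <- wilcoxonVec(normed, inG)
    lfc <- log2((rowMeans(expd[, inG, drop = FALSE]) + 1e-9) /
                (rowMeans(expd[, !inG, drop = FALSE]) + 1e-9))
    data.frame(cluster = cl, gene = rownames(normed), log2fc = lfc,
               pval = p, padj = pmin(1, p * m), row.names = NULL)
  })
  out <- do.call(rbind, res)
  out$significant <- out$log2fc > cfg$log2fc_min & out$padj < cfg$padj_max
  out[order(out$cluster, -out$log2fc), ]
}

#' Pseudobulk replicate concordance
#'
#' Collapses each section to a gene pseudobulk profile,
#' `log10(1 + sum of counts per gene)` over the genes shared by all
#' sections (aligned by identifier), and returns the pairwise Pearson
#' correlation matrix — the gene-side concordance statistic for consecutive
#' or replicate sections.
#'
#' @param sections list of [SRTSection-class] objects (>= 2) sharing at
#'   least 100 genes.
#' @return symmetric correlation matrix with unit diagonal, one row/column
#'   per section (named from the list names when present).
#' @export
pseudobulkCorrelation <- function(sections) {
  stopifnot(length(sections) >= 2)
  shared <- Reduce(intersect, lapply(sections, rownames))
  if (length(shared) < 100)
    stop("only ", length(shared), " genes shared across sections (>=100 required)",
         call. = FALSE)
  prof <- vapply(sections, function(s)
    log10(1 + Matrix::rowSums(assay(s, "counts")[shared, , drop = FALSE])),
    numeric(length(shared)))
  r <- stats::cor(prof)
  if (!is.null(names(sections))) dimnames(r) <- list(names(sections), names(sections))
  diag(r) <- 1
  r
}
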