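#' Read a Visium-style SRT directory
#'
#' Expects the standard filtered-matrix layout: a MatrixMarket count matrix
#' (`matrix.mtx`), a gene list (`features.tsv` or `genes.tsv`, first column
#' used as the identifier, kept as given), a `barcodes.tsv`, and a
#' `tissue_positions.csv` with columns
#' `barcode,in_tissue,array_row,array_col,pxl_row_in_fullres,pxl_col_in_fullres`.
#' Spot (x, y) is taken from the full-resolution pixel columns
#' (x = `pxl_col_in_fullres`, y = `pxl_row_in_fullres`). Spots keep the order
#' of the barcode file; out-of-tissue spots are retained but flagged.
#'
#' @param path directory containing the files above.
#' @return an [SRTSection-class].
#' @seealso [writeSRTdir()] for the inverse.
#' @export
readSRTdir <- function(path) {
  findFile <- function(cands) {
    for (f in cands) if (file.exists(file.path(path, f))) return(file.path(path, f))
    stop("missing file in '", path, "': expected one of ",
         paste(cands, collapse = " / "), call. = FALSE)
  }
  mtxFile <- findFile("matrix.mtx")
  geneFile <- findFile(c("features.tsv", "genes.tsv"))
  bcFile <- findFile("barcodes.tsv")
  posFile <- findFile(c("tissue_positions.csv", "tissue_positions_list.csv"))

  counts <- tryCatch(Matrix::readMM(mtxFile), error = function(e)
    stop("malformed MatrixMarket file '", mtxFile, "': ", conditionMessage(e),
         call. = FALSE))
  genes <- utils::read.delim(geneFile, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  barcodes <- utils::read.delim(bcFile, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(counts) != length(genes) || ncol(counts) != length(barcodes))
    stop("matrix dimensions (", nrow(counts), " x ", ncol(counts),
         ") do not match gene/barcode lists (", length(genes), " / ",
         length(barcodes), ")", call. = FALSE)

  pos <- utils::read.csv(posFile, stringsAsFactors = FALSE)
  need <- c("barcode", "in_tissue", "array_row", "array_col",
            "pxl_row_in_fullres", "pxl_col_in_fullres")
  if (!all(need %in% colnames(pos)))
    stop("positions file lacks column(s): ",
         paste(setdiff(need, colnames(pos)), collapse = ", "), call. = FALSE)
  i <- match(barcodes, pos$barcode)
  if (anyNA(i))
    stop("barcode(s) in matrix absent from positions file, e.g. '",
         barcodes[which(is.na(i))[1]], "'", call. = FALSE)
  pos <- pos[i, ]

  SRTSection(
    counts = counts, geneIds = genes, barcodes = barcodes,
    spotXY = cbind(pos$pxl_col_in_fullres, pos$pxl_row_in_fullres),
    arrayRC = cbind(pos$array_row, pos$array_col),
    inTissue = as.logical(pos$in_tissue),
    annotations = if ("annotation" %in% colnames(pos)) pos$annotation else NULL
  )
}

#' Write an SRTSection as a Visium-style directory
#'
#' Inverse of [readSRTdir()]: writes `matrix.mtx`, `features.tsv`,
#' `barcodes.tsv` and `tissue_positions.csv` (with an extra `annotation`
#' column when annotations are present).
#'
#' @param section an [SRTSection-class].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
writeSRTdir <- function(section, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cts <- as(assay(section, "counts"), "CsparseMatrix")
  Matrix::writeMM(cts, file.path(path, "matrix.mtx"))
  writeLines(rownames(section), file.path(path, "features.tsv"))
  writeLines(colnames(section), file.path(path, "barcodes.tsv"))
  cd <- colData(section)
  pos <- data.frame(
    barcode = colnames(section),
    in_tissue = as.integer(cd$in_tissue),
    array_row = cd$array_row, array_col = cd$array_col,
    pxl_row_in_fullres = round(cd$y, 6), pxl_col_in_fullres = round(cd$x, 6)
  )
  if (!all(is.na(cd$annotation))) pos$annotation <- cd$annotation
  utils::write.csv(pos, file.path(path, "tissue_positions.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an MSI peak raster
#'
#' Two on-disk forms are supported: a plain peak-table CSV (`x`, `y`, then one
#' column per peak, headers the m/z values) and continuous-mode imzML (one
#' shared m/z axis; paired `.ibd` next to the XML). Peaks are sorted by
#' ascending m/z; pixel order is preserved from the file. Processed-mode
#' imzML (per-pixel m/z axes, i.e. unpicked profile data) is rejected: peak
#' picking is assumed done upstream in vendor software.
#'
#' @param path CSV or imzML file.
#' @param format `"csv"` or `"imzml"`; guessed from the extension by default.
#' @param pitchUm,matrixName,polarity metadata passed to [MSIRaster()]
#'   (imzML pixel size is read from the file when present).
#' @return an [MSIRaster-class].
#' @export
readMSI <- function(path, format = c("auto", "csv", "imzml"), pitchUm = 100,
                    matrixName = "FMP-10", polarity = "positive") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.imzml$", path, ignore.case = TRUE)) "imzml" else "csv"
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  if (format == "csv")
    readMSIcsv(path, pitchUm, matrixName, polarity)
  else
    readImzML(path, pitchUm, matrixName, polarity)
}

readMSIcsv <- function(path, pitchUm, matrixName, polarity) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3 || !all(tolower(colnames(tab)[1:2]) == c("x", "y")))
    stop("peak-table CSV must start with columns x, y: '", path, "'",
         call. = FALSE)
  mzHdr <- colnames(tab)[-(1:2)]
  mz <- suppressWarnings(as.numeric(sub("^mz_", "", mzHdr)))
  if (anyNA(mz))
    stop("non-numeric m/z column header(s): ",
         paste(utils::head(mzHdr[is.na(mz)], 3), collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab[, 1:2]))
    stop("duplicated pixel coordinates in '", path, "'", call. = FALSE)
  MSIRaster(intensities = t(as.matrix(tab[, -(1:2), drop = FALSE])), mz = mz,
            pixelXY = as.matrix(tab[, 1:2]), pitchUm = pitchUm,
            matrixName = matrixName, polarity = polarity)
}

#' Write an MSI raster as a peak-table CSV
#'
#' Columns `x`, `y`, then one per peak with the m/z (4 decimals) as header.
#'
#' @param raster an [MSIRaster-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMSIcsv <- function(raster, path) {
  xy <- pixelCoords(raster)
  tab <- data.frame(x = round(xy[, 1], 6), y = round(xy[, 2], 6),
                    t(assay(raster, "intensities")), check.names = FALSE)
  colnames(tab)[-(1:2)] <- sprintf("%.4f", mzValues(raster))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- minimal continuous-mode imzML ------------------------------------------
# Layout written/read here: .ibd = 16-byte UUID, then the shared m/z axis
# (float64), then one float64 intensity block per pixel, in spectrum order.
# The XML carries pixel positions and external-array offsets/lengths.

imsAccession <- function(node, acc) {
  v <- xml2::xml_find_first(
    node, sprintf(".//*[local-name()='cvParam'][@accession='%s']", acc))
  if (inherits(v, "xml_missing")) NA_character_ else xml2::xml_attr(v, "value")
}

readImzML <- function(path, pitchUm, matrixName, polarity) {
  doc <- xml2::read_xml(path)
  all_acc <- xml2::xml_attr(
    xml2::xml_find_all(doc, "//*[local-name()='cvParam']"), "accession")
  if ("IMS:1000031" %in% all_acc)
    stop("processed-mode imzML (per-pixel m/z axes) is not supported; ",
         "supply continuous-mode data or a peak-table CSV", call. = FALSE)
  if (!"IMS:1000030" %in% all_acc)
    stop("imzML file does not declare continuous mode: '", path, "'",
         call. = FALSE)
  ibd <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd)) stop("missing .ibd next to '", path, "'", call. = FALSE)

  px <- xml2::xml_find_all(doc, "//*[local-name()='cvParam'][@accession='IMS:1000046']")
  pitch <- if (length(px)) as.numeric(xml2::xml_attr(px[[1]], "value")) else pitchUm

  specs <- xml2::xml_find_all(doc, "//*[local-name()='spectrum']")
  if (!length(specs)) stop("no spectra in '", path, "'", call. = FALSE)
  getArr <- function(sp, which) {
    # arrays are tagged by referenceableParamGroupRef ("mzArray"/"intensityArray")
    bda <- xml2::xml_find_first(sp, sprintf(
      ".//*[local-name()='binaryDataArray'][.//*[local-name()='referenceableParamGroupRef'][@ref='%s']]",
      which))
    c(offset = as.numeric(imsAccession(bda, "IMS:1000102")),
      length = as.numeric(imsAccession(bda, "IMS:1000103")))
  }
  con <- file(ibd, "rb")
  on.exit(close(con))
  mzRef <- getArr(specs[[1]], "mzArray")
  seek(con, mzRef["offset"])
  mz <- readBin(con, "double", n = mzRef["length"], size = 8)
  xy <- matrix(NA_real_, length(specs), 2)
  intens <- matrix(NA_real_, length(mz), length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    xy[i, 1] <- as.numeric(imsAccession(sp, "IMS:1000050"))
    xy[i, 2] <- as.numeric(imsAccession(sp, "IMS:1000051"))
    ia <- getArr(sp, "intensityArray")
    if (ia["length"] != length(mz))
      stop("intensity array length differs from the shared m/z axis at ",
           "spectrum ", i, call. = FALSE)
    seek(con, ia["offset"])
    intens[, i] <- readBin(con, "double", n = ia["length"], size = 8)
  }
  MSIRaster(intensities = pmax(intens, 0), mz = mz, pixelXY = xy,
            pitchUm = pitch, matrixName = matrixName, polarity = polarity)
}

#' Write an MSI raster as continuous-mode imzML
#'
#' Emits a minimal but standard-conforming imzML/ibd pair: a shared 64-bit
#' m/z axis stored once, 64-bit intensity arrays per pixel, pixel positions
#' as integer scan coordinates. Round-trips through [readMSI()].
#'
#' @param raster an [MSIRaster-class]. Pixel coordinates are written as
#'   given (imzML positions are conventionally 1-based integers; non-integer
#'   coordinates survive the round trip but may confuse other readers).
#' @param path output `.imzML` path; the `.ibd` is written alongside.
#' @return `path`, invisibly.
#' @export
writeImzML <- function(raster, path) {
  ibdPath <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibdPath, path)) ibdPath <- paste0(path, ".ibd")
  mz <- mzValues(raster)
  intens <- assay(raster, "intensities")
  xy <- pixelCoords(raster)
  n <- ncol(intens)

  # fixed tag bytes rather than a random UUID: keeps writers free of RNG state
  uuid <- as.raw(c(83, 80, 65, 77, 83, 73, 0:9))
  con <- file(ibdPath, "wb")
  writeBin(uuid, con)
  mzOffset <- 16
  writeBin(as.numeric(mz), con, size = 8)
  intOffsets <- mzOffset + 8 * length(mz) + 8 * length(mz) * (seq_len(n) - 1)
  for (i in seq_len(n)) writeBin(as.numeric(intens[, i]), con, size = 8)
  close(con)

  cv <- function(cvRef, acc, name, value = NULL)
    sprintf('<cvParam cvRef="%s" accession="%s" name="%s"%s/>', cvRef, acc,
            name, if (is.null(value)) "" else sprintf(' value="%s"', value))
  specXml <- vapply(seq_len(n), function(i) paste0(
    sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
            i - 1L, i, length(mz)),
    "<scanList count=\"1\"><scan>",
    cv("IMS", "IMS:1000050", "position x", format(xy[i, 1])),
    cv("IMS", "IMS:1000051", "position y", format(xy[i, 2])),
    "</scan></scanList>",
    '<binaryDataArrayList count="2">',
    '<binaryDataArray encodedLength="0">',
    '<referenceableParamGroupRef ref="mzArray"/>',
    cv("IMS", "IMS:1000102", "external offset", format(mzOffset)),
    cv("IMS", "IMS:1000103", "external array length", format(length(mz))),
    cv("IMS", "IMS:1000104", "external encoded length", format(8 * length(mz))),
    "<binary/></binaryDataArray>",
    '<binaryDataArray encodedLength="0">',
    '<referenceableParamGroupRef ref="intensityArray"/>',
    cv("IMS", "IMS:1000102", "external offset", format(intOffsets[i])),
    cv("IMS", "IMS:1000103", "external array length", format(length(mz))),
    cv("IMS", "IMS:1000104", "external encoded length", format(8 * length(mz))),
    "<binary/></binaryDataArray>",
    "</binaryDataArrayList></spectrum>"), character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="ISO-8859-1"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    "<fileDescription><fileContent>",
    cv("IMS", "IMS:1000030", "continuous"),
    cv("IMS", "IMS:1000080", "universally unique identifier",
       paste0("{", paste(format(uuid), collapse = ""), "}")),
    "</fileContent></fileDescription>",
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    cv("MS", "MS:1000514", "m/z array"),
    cv("MS", "MS:1000523", "64-bit float"),
    cv("IMS", "IMS:1000101", "external data", "true"),
    "</referenceableParamGroup>",
    '<referenceableParamGroup id="intensityArray">',
    cv("MS", "MS:1000515", "intensity array"),
    cv("MS", "MS:1000523", "64-bit float"),
    cv("IMS", "IMS:1000101", "external data", "true"),
    "</referenceableParamGroup></referenceableParamGroupList>",
    "<scanSettingsList count=\"1\"><scanSettings id=\"scan1\">",
    cv("IMS", "IMS:1000046", "pixel size (x)",
       format(metadata(raster)$pitch_um)),
    "</scanSettings></scanSettingsList>",
    '<run id="run1"><spectrumList count="', n, '">',
    paste(specXml, collapse = ""),
    "</spectrumList></run></mzML>")
  writeLines(xml, path)
  invisible(path)
}

#' Read landmark point pairs
#'
#' CSV with columns `source_x`, `source_y` (MSI-native units) and
#' `target_x`, `target_y` (common-frame pixels).
#'
#' @param path CSV file.
#' @return a list with matrices `source` and `target` (n x 2), as consumed
#'   by [fitSimilarity()].
#' @export
readLandmarks <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("source_x", "source_y", "target_x", "target_y")
  if (!all(need %in% colnames(tab)))
    stop("landmark file lacks column(s): ",
         paste(setdiff(need, colnames(tab)), collapse = ", "), call. = FALSE)
  landmarkPairs(as.matrix(tab[, c("source_x", "source_y")]),
                as.matrix(tab[, c("target_x", "target_y")]))
}
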