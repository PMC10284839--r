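#' Read and write the pipeline's file formats
#'
#' Cell tables travel as a single CSV with the mandated header
#' (`cell_id, roi_id, patient_id, group, x, y, area`, then one column per
#' channel; optional `phenotype` and `cn` columns). Channel stacks are
#' multi-page TIFFs (one page per channel) with a sidecar JSON manifest
#' holding the channel names and ROI id. Spillover matrices are CSVs with a
#' channel-name header row and first column. Label maps are single-channel
#' 16-bit TIFFs.
#'
#' @param x object to write.
#' @param path file path (for stacks, path of the TIFF; the manifest is
#'   `<path>.json`).
#' @return the read object, or (invisibly) `path` for writers.
#' @name imcTopo-io
NULL

.metaCols <- c("cell_id", "roi_id", "patient_id", "group", "x", "y", "area")

#' @rdname imcTopo-io
#' @export
writeCellTable <- function(x, path) {
  stopifnot(is(x, "CellTable"))
  cd <- x@cells
  opt <- intersect(c("phenotype", "cn"), names(cd))
  df <- cbind(cd[, c(.metaCols, opt), drop = FALSE],
              as.data.frame(x@exprs, check.names = FALSE))
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname imcTopo-io
#' @export
readCellTable <- function(path) {
  df <- as.data.frame(data.table::fread(path, check.names = FALSE))
  opt <- intersect(c("phenotype", "cn"), names(df))
  chan <- setdiff(names(df), c(.metaCols, opt))
  cells <- df[, c(.metaCols, opt), drop = FALSE]
  cells$roi_id <- as.character(cells$roi_id)
  cells$patient_id <- as.character(cells$patient_id)
  cellTable(cells, as.matrix(df[, chan, drop = FALSE]))
}

#' @rdname imcTopo-io
#' @export
writeChannelStack <- function(x, path) {
  stopifnot(is(x, "ChannelStack"))
  p <- x@pixels
  mx <- max(p, 1)
  pages <- lapply(seq_len(dim(p)[3]), function(i) p[, , i] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(roi_id = x@roiId, channels = x@channelNames, scale = mx),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname imcTopo-io
#' @export
readChannelStack <- function(path) {
  man <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  p <- array(0, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) p[, , i] <- pages[[i]] * man$scale
  channelStack(p, man$channels, man$roi_id)
}

#' @rdname imcTopo-io
#' @export
writeSpillover <- function(x, path) {
  stopifnot(is(x, "SpilloverMatrix"))
  df <- data.frame(channel = rownames(x@S), x@S, check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname imcTopo-io
#' @export
readSpillover <- function(path) {
  df <- as.data.frame(data.table::fread(path, check.names = FALSE))
  S <- as.matrix(df[, -1, drop = FALSE])
  rownames(S) <- df[[1]]
  spilloverMatrix(S)
}

#' @rdname imcTopo-io
#' @export
writeLabelMap <- function(x, path) {
  stopifnot(is(x, "LabelMap"))
  m <- x@labels
  if (max(m) > 65535) stop("more than 65535 objects; cannot write 16-bit TIFF")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname imcTopo-io
#' @export
readLabelMap <- function(path) {
  m <- tiff::readTIFF(path)
  labelMap(matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)))
}
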