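#' CellTable: the per-cell exchange format of the pipeline
#'
#' One row per segmented (or simulated) cell, carrying its position, ROI,
#' patient and group membership, area, and the per-channel marker
#' intensities. Every downstream stage (phenotyping, neighborhoods, spatial
#' statistics, tensors) consumes and annotates a `CellTable`.
#'
#' The on-disk form is a single CSV with the mandated header
#' `cell_id, roi_id, patient_id, group, x, y, area`, then one column per
#' channel; phenotype and CN assignments are appended as columns
#' `phenotype` and `cn` when present (see [readCellTable()] /
#' [writeCellTable()]).
#'
#' @slot cells data.frame with columns `cell_id` (integer, unique within
#'   ROI), `roi_id`, `patient_id`, `group` (`"normal"` or `"disease"`),
#'   `x`, `y` (0-based pixel coordinates), `area` (pixels), and optionally
#'   `phenotype` and `cn` (integer labels).
#' @slot exprs numeric matrix, cells x channels, nonnegative; column names
#'   are the channel names.
#'
#' @param cells,exprs see slots.
#' @param x a `CellTable`.
#' @param value replacement value for the respective accessor.
#' @return `cellTable()` returns a validated `CellTable`.
#' @aliases nCells cellData intensities intensities<- spatialCoords
#'   phenotypes phenotypes<- cnLabels cnLabels<-
#' @export cellTable
#' @exportClass CellTable
setClass("CellTable",
  representation(cells = "data.frame", exprs = "matrix"),
  validity = function(object) {
    cd <- object@cells
    need <- c("cell_id", "roi_id", "patient_id", "group", "x", "y", "area")
    miss <- setdiff(need, names(cd))
    if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
    if (nrow(cd) != nrow(object@exprs))
      return("cells and exprs must have the same number of rows")
    if (nrow(cd)) {
      if (anyDuplicated(paste(cd$roi_id, cd$cell_id)))
        return("(roi_id, cell_id) must be unique")
      if (!all(cd$group %in% c("normal", "disease")))
        return("group must be 'normal' or 'disease'")
      if (any(cd$area < 1)) return("area must be >= 1")
      if (any(object@exprs < 0)) return("intensities must be nonnegative")
    }
    if (is.null(colnames(object@exprs)) && ncol(object@exprs) > 0)
      return("exprs needs channel column names")
    TRUE
  })

cellTable <- function(cells, exprs) {
  cells <- as.data.frame(cells)
  exprs <- as.matrix(exprs)
  new("CellTable", cells = cells, exprs = exprs)
}

#' @rdname CellTable-class
#' @export
setMethod("nCells", "CellTable", function(x) nrow(x@cells))

#' @rdname CellTable-class
#' @export
setMethod("cellData", "CellTable", function(x) x@cells)

#' @rdname CellTable-class
#' @export
setMethod("intensities", "CellTable", function(x) x@exprs)

#' @rdname CellTable-class
#' @export
setMethod("intensities<-", "CellTable", function(x, value) {
  x@exprs <- as.matrix(value); validObject(x); x
})

#' @rdname CellTable-class
#' @export
setMethod("spatialCoords", "CellTable",
  function(x) as.matrix(x@cells[, c("x", "y")]))

#' @rdname channelNames
#' @export
setMethod("channelNames", "CellTable", function(x) colnames(x@exprs))

#' @rdname CellTable-class
#' @export
setMethod("phenotypes", "CellTable", function(x) x@cells$phenotype)

#' @rdname CellTable-class
#' @export
setMethod("phenotypes<-", "CellTable", function(x, value) {
  x@cells$phenotype <- as.integer(value); x
})

#' @rdname CellTable-class
#' @export
setMethod("cnLabels", "CellTable", function(x) x@cells$cn)

#' @rdname CellTable-class
#' @export
setMethod("cnLabels<-", "CellTable", function(x, value) {
  x@cells$cn <- as.integer(value); x
})

setMethod("show", "CellTable", function(object) {
  cd <- object@cells
  cat("CellTable:", nrow(cd), "cells,", ncol(object@exprs), "channels,",
      length(unique(cd$roi_id)), "ROIs,",
      length(unique(cd$patient_id)), "patients\n")
  if (!is.null(cd$phenotype))
    cat("  phenotypes:", length(unique(cd$phenotype)), "clusters\n")
  if (!is.null(cd$cn))
    cat("  neighborhoods:", length(unique(cd$cn)), "CNs\n")
})

#' Subset a CellTable by a logical or integer row index
#' @param x a `CellTable`; @param i row index.
#' @param i row index (logical or integer).
#' @param j,...,drop ignored.
#' @export
setMethod("[", "CellTable", function(x, i, j, ..., drop = FALSE) {
  cellTable(x@cells[i, , drop = FALSE], x@exprs[i, , drop = FALSE])
})

#' Combine two CellTables with identical channels
#' @param x,y `CellTable` objects.
#' @export
setMethod("rbind2", signature("CellTable", "CellTable"), function(x, y) {
  stopifnot(identical(colnames(x@exprs), colnames(y@exprs)))
  cellTable(rbind(x@cells, y@cells), rbind(x@exprs, y@exprs))
})
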