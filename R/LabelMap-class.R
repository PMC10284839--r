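#' LabelMap: labeled objects in one image
#'
#' Integer image in which 0 marks background and `k >= 1` the pixels of
#' object `k`, plus a per-object record of area and centroid. Labels are
#' contiguous `1..K`; centroids are the mean of member pixel coordinates in
#' the package-wide 0-based convention (x = column, y = row).
#'
#' @slot labels integer H x W matrix.
#' @slot objects data.frame with columns `label`, `area`, `x`, `y`.
#' @param labels,objects see slots.
#' @param x a `LabelMap`.
#' @aliases labelMatrix objectTable nObjects
#' @export labelMap
#' @exportClass LabelMap
setClass("LabelMap",
  representation(labels = "matrix", objects = "data.frame"),
  validity = function(object) {
    labs <- object@labels
    K <- nrow(object@objects)
    u <- sort(unique(as.integer(labs[labs > 0])))
    if (length(u) && !identical(u, seq_len(K)))
      return("labels must be contiguous 1..K matching the object table")
    if (K && !identical(object@objects$label, seq_len(K)))
      return("object table labels must be 1..K in order")
    TRUE
  })

labelMap <- function(labels, objects = NULL) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (is.null(objects)) objects <- objectStats(labels)
  new("LabelMap", labels = labels, objects = objects)
}

# Recompute (label, area, centroid) records from a label image.
objectStats <- function(labels) {
  pos <- which(labels > 0, arr.ind = TRUE)
  if (!nrow(pos))
    return(data.frame(label = integer(), area = integer(),
                      x = numeric(), y = numeric()))
  lab <- labels[pos]
  xs <- tapply(pos[, 2] - 1, lab, mean)   # x = column, 0-based
  ys <- tapply(pos[, 1] - 1, lab, mean)
  data.frame(label = as.integer(names(xs)),
             area = as.integer(tabulate(lab)[as.integer(names(xs))]),
             x = as.numeric(xs), y = as.numeric(ys))
}

#' @rdname LabelMap-class
#' @export
setMethod("labelMatrix", "LabelMap", function(x) x@labels)

#' @rdname LabelMap-class
#' @export
setMethod("objectTable", "LabelMap", function(x) x@objects)

#' @rdname LabelMap-class
#' @export
setMethod("nObjects", "LabelMap", function(x) nrow(x@objects))

setMethod("show", "LabelMap", function(object) {
  cat("LabelMap:", nrow(object@objects), "objects on a",
      nrow(object@labels), "x", ncol(object@labels), "grid\n")
})
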