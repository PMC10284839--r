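#' ChannelStack: a multi-channel image for one region of interest
#'
#' A `ChannelStack` holds the pixel data of one scanned ROI as an
#' `H x W x C` array of nonnegative intensities together with the channel
#' (marker) names. Coordinates are 0-based pixels with `x` indexing columns
#' and `y` rows, origin at the top-left corner, consistently across the
#' package.
#'
#' @slot pixels numeric array, height x width x channels, all values >= 0.
#' @slot channelNames character vector of unique channel names, one per
#'   array slice.
#' @slot roiId character scalar identifying the ROI.
#'
#' @param pixels,channelNames,roiId see slots.
#' @param x a `ChannelStack`.
#' @return `channelStack()` returns a validated `ChannelStack`.
#' @examples
#' cs <- channelStack(array(1, c(4, 4, 2)), c("DNA", "CD3"), "roi1")
#' channelNames(cs)
#' dim(pixelArray(cs))
#' @aliases pixelArray roiId
#' @export channelStack
#' @exportClass ChannelStack
setClass("ChannelStack",
  representation(pixels = "array", channelNames = "character",
                 roiId = "character"),
  validity = function(object) {
    p <- object@pixels
    if (length(dim(p)) != 3L) return("pixels must be an H x W x C array")
    if (dim(p)[1] < 1L || dim(p)[2] < 1L) return("H and W must be >= 1")
    if (dim(p)[3] != length(object@channelNames))
      return("number of channel names must match third array dimension")
    if (anyDuplicated(object@channelNames))
      return("channel names must be unique")
    if (any(!is.finite(p)) || any(p < 0))
      return("pixel intensities must be finite and nonnegative")
    TRUE
  })

channelStack <- function(pixels, channelNames, roiId = "roi") {
  if (length(dim(pixels)) == 2L) pixels <- array(pixels, c(dim(pixels), 1L))
  new("ChannelStack", pixels = pixels,
      channelNames = as.character(channelNames), roiId = as.character(roiId))
}

#' @rdname ChannelStack-class
#' @export
setMethod("pixelArray", "ChannelStack", function(x) x@pixels)

#' @rdname ChannelStack-class
#' @export
setMethod("roiId", "ChannelStack", function(x) x@roiId)

#' Channel names of an object
#'
#' @param x a `ChannelStack`, `SpilloverMatrix` or `CellTable`.
#' @param value replacement character vector.
#' @return character vector of channel (marker) names.
#' @export
setMethod("channelNames", "ChannelStack", function(x) x@channelNames)

#' @rdname channelNames
#' @export
setMethod("channelNames<-", "ChannelStack", function(x, value) {
  x@channelNames <- as.character(value); validObject(x); x
})

setMethod("show", "ChannelStack", function(object) {
  d <- dim(object@pixels)
  cat("ChannelStack '", object@roiId, "': ", d[1], " x ", d[2],
      " px, ", d[3], " channels\n", sep = "")
  cat("  channels: ", paste(head(object@channelNames, 8), collapse = ", "),
      if (length(object@channelNames) > 8) ", ..." else "", "\n", sep = "")
})

#' Extract one channel as a matrix
#'
#' @param x a `ChannelStack`.
#' @param channel channel name or index.
#' @return numeric H x W matrix.
#' @export
getChannel <- function(x, channel) {
  stopifnot(is(x, "ChannelStack"))
  if (is.character(channel)) {
    i <- match(channel, x@channelNames)
    if (is.na(i)) stop("unknown channel: ", channel)
  } else i <- as.integer(channel)
  x@pixels[, , i]
}

#' SpilloverMatrix: linear channel crosstalk
#'
#' Row `s`, column `d` of the matrix gives the fraction of true signal in
#' source channel `s` that is detected in channel `d`; the diagonal is
#' exactly 1. Used by [compensate()] to invert the mixing
#' `observed = true %*% S`.
#'
#' @slot S square numeric matrix with unit diagonal, off-diagonal entries in
#'   `[0, 1)`, and channel names as dimnames.
#' @param S numeric matrix; dimnames taken as channel names (or supplied via
#'   `channels`).
#' @param channels optional character vector of channel names.
#' @export spilloverMatrix
#' @exportClass SpilloverMatrix
setClass("SpilloverMatrix", representation(S = "matrix"),
  validity = function(object) {
    S <- object@S
    if (nrow(S) != ncol(S)) return("spillover matrix must be square")
    if (is.null(rownames(S)) || is.null(colnames(S)))
      return("spillover matrix needs channel dimnames")
    if (!identical(rownames(S), colnames(S)))
      return("row and column channel names must match")
    if (any(abs(diag(S) - 1) > 1e-12)) return("diagonal must be exactly 1")
    off <- S[row(S) != col(S)]
    if (any(off < 0 | off >= 1)) return("off-diagonal entries must be in [0,1)")
    if (abs(det(S)) < 1e-12) return("spillover matrix is singular")
    TRUE
  })

spilloverMatrix <- function(S, channels = NULL) {
  S <- as.matrix(S)
  if (!is.null(channels)) dimnames(S) <- list(channels, channels)
  new("SpilloverMatrix", S = S)
}

#' @rdname SpilloverMatrix-class
#' @param x a `SpilloverMatrix`.
#' @export
setMethod("channelNames", "SpilloverMatrix", function(x) rownames(x@S))

#' @rdname SpilloverMatrix-class
#' @export
setMethod("as.matrix", "SpilloverMatrix", function(x) x@S)

setMethod("show", "SpilloverMatrix", function(object) {
  cat("SpilloverMatrix:", nrow(object@S), "channels, max off-diagonal",
      format(max(object@S[row(object@S) != col(object@S)], 0), digits = 3), "\n")
})

#' Identity spillover (no crosstalk) for a set of channels
#' @param channels character vector of channel names.
#' @return a `SpilloverMatrix`.
#' @export
identitySpillover <- function(channels) {
  spilloverMatrix(diag(length(channels)), channels = channels)
}
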