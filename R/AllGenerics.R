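#' @rdname channelNames
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname channelNames
#' @export
setGeneric("channelNames<-", function(x, value) standardGeneric("channelNames<-"))

#' @rdname ChannelStack-class
#' @export
setGeneric("pixelArray", function(x) standardGeneric("pixelArray"))

#' @rdname ChannelStack-class
#' @export
setGeneric("roiId", function(x) standardGeneric("roiId"))

#' @rdname CellTable-class
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname CellTable-class
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))

#' @rdname CellTable-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname CellTable-class
#' @export
setGeneric("intensities<-", function(x, value) standardGeneric("intensities<-"))

#' @rdname CellTable-class
#' @export
setGeneric("spatialCoords", function(x) standardGeneric("spatialCoords"))

#' @rdname CellTable-class
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname CellTable-class
#' @export
setGeneric("phenotypes<-", function(x, value) standardGeneric("phenotypes<-"))

#' @rdname CellTable-class
#' @export
setGeneric("cnLabels", function(x) standardGeneric("cnLabels"))

#' @rdname CellTable-class
#' @export
setGeneric("cnLabels<-", function(x, value) standardGeneric("cnLabels<-"))

#' @rdname LabelMap-class
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname LabelMap-class
#' @export
setGeneric("objectTable", function(x) standardGeneric("objectTable"))

#' @rdname LabelMap-class
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

#' @rdname TuckerModel-class
#' @export
setGeneric("lossTrace", function(x) standardGeneric("lossTrace"))

#' @rdname TuckerModel-class
#' @export
setGeneric("tuckerCore", function(x) standardGeneric("tuckerCore"))

#' @rdname TuckerModel-class
#' @export
setGeneric("tuckerFactors", function(x) standardGeneric("tuckerFactors"))

#' @rdname TuckerModel-class
#' @export
setGeneric("reconstruct", function(x, ...) standardGeneric("reconstruct"))
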