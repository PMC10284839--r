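#' Detect objects by thresholding and 8-connected components
#'
#' Binarizes a single channel at a fixed threshold (or Otsu's threshold,
#' computed on a 256-level histogram) and labels 8-connected foreground
#' components, dropping components smaller than `minArea` pixels and
#' relabeling the survivors contiguously in scan order. An image that is
#' all background after thresholding yields an empty [LabelMap], not an
#' error.
#'
#' @param channel nonnegative numeric matrix (one image channel).
#' @param threshold numeric intensity (pixels strictly above it are
#'   foreground) or `"otsu"`.
#' @param minArea minimum component size in pixels (default 3).
#' @return a [LabelMap].
#' @examples
#' m <- matrix(0, 30, 30); m[4:6, 4:6] <- 1; m[19:21, 19:21] <- 1
#' nObjects(detectObjects(m, threshold = 0.5))
#' @export
detectObjects <- function(channel, threshold = "otsu", minArea = 3L) {
  stopifnot(is.matrix(channel), all(channel >= 0))
  if (identical(threshold, "otsu")) {
    mx <- max(channel)
    threshold <- if (mx == 0) 0 else
      EBImage::otsu(EBImage::Image(channel / mx), range = c(0, 1),
                    levels = 256) * mx
  }
  fg <- channel > threshold
  H <- nrow(fg); W <- ncol(fg)
  nfg <- sum(fg)
  if (nfg == 0) return(labelMap(matrix(0L, H, W)))
  id <- matrix(seq_len(H * W), H, W)
  pairUp <- function(maskA, maskB, idA, idB) {
    sel <- maskA & maskB
    cbind(idA[sel], idB[sel])
  }
  edges <- rbind(
    if (H > 1) pairUp(fg[-H, , drop = FALSE], fg[-1, , drop = FALSE],
                      id[-H, , drop = FALSE], id[-1, , drop = FALSE]),
    if (W > 1) pairUp(fg[, -W, drop = FALSE], fg[, -1, drop = FALSE],
                      id[, -W, drop = FALSE], id[, -1, drop = FALSE]),
    if (H > 1 && W > 1) pairUp(fg[-H, -W, drop = FALSE], fg[-1, -1, drop = FALSE],
                               id[-H, -W, drop = FALSE], id[-1, -1, drop = FALSE]),
    if (H > 1 && W > 1) pairUp(fg[-H, -1, drop = FALSE], fg[-1, -W, drop = FALSE],
                               id[-H, -1, drop = FALSE], id[-1, -W, drop = FALSE]))
  fgIdx <- which(fg)                       # column-major scan order
  vid <- integer(H * W)
  vid[fgIdx] <- seq_len(nfg)
  g <- igraph::make_empty_graph(n = nfg, directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(cbind(vid[edges[, 1]], vid[edges[, 2]])))
  comp <- igraph::components(g)$membership
  # components are numbered by first member in scan order already; enforce it
  first <- tapply(seq_along(comp), comp, min)
  relab <- integer(length(first))
  relab[order(first)] <- seq_along(first)
  comp <- relab[comp]
  labels <- matrix(0L, H, W)
  labels[fgIdx] <- comp
  # drop small components, relabel contiguously
  sizes <- tabulate(comp)
  keep <- which(sizes >= minArea)
  if (length(keep) < length(sizes)) {
    remap <- integer(length(sizes))
    remap[keep] <- seq_along(keep)
    labels[fgIdx] <- remap[comp]
  }
  labelMap(labels)
}

#' Remove membrane objects far from any nucleus
#'
#' Keeps exactly the objects whose centroid lies within `maxDist` pixels
#' (Euclidean) of the nearest nucleus centroid; objects *strictly farther*
#' than the cutoff are removed, so an object at exactly `maxDist` is
#' retained. With no nuclei at all, every object is removed (the nearest
#' distance is infinite). Default cutoff 15 px.
#'
#' @param objects a [LabelMap] of candidate membrane objects.
#' @param nucleiCentroids numeric matrix (or data.frame) with columns
#'   `x`, `y`; may have zero rows.
#' @param maxDist distance cutoff in pixels.
#' @return filtered [LabelMap] with contiguous labels.
#' @export
filterArtifacts <- function(objects, nucleiCentroids, maxDist = 15) {
  stopifnot(is(objects, "LabelMap"))
  obj <- objectTable(objects)
  if (!nrow(obj)) return(objects)
  nucleiCentroids <- as.matrix(as.data.frame(nucleiCentroids)[, c("x", "y")])
  if (!nrow(nucleiCentroids)) {
    keep <- integer(0)
  } else {
    nn <- RANN::nn2(nucleiCentroids, obj[, c("x", "y")], k = 1)
    keep <- which(nn$nn.dists[, 1] <= maxDist)
  }
  labels <- labelMatrix(objects)
  remap <- integer(nrow(obj))
  remap[keep] <- seq_along(keep)
  pos <- labels > 0
  labels[pos] <- remap[labels[pos]]
  labelMap(labels)
}

#' Build cell masks from nuclei and quantify marker intensities
#'
#' Each detected nucleus is dilated by a disk of `dilationRadius` pixels to
#' form its cell mask; pixels claimed by several nuclei are resolved to the
#' nucleus with the nearer centroid (ties to the lower label). Per-cell
#' intensity is the mean of each channel over the cell mask. The emitted
#' [CellTable] uses the nucleus centroid as the cell position and the mask
#' size as the area.
#'
#' @param stack a [ChannelStack] (typically compensated and denoised).
#' @param nuclei a [LabelMap] of nuclei for the same image.
#' @param dilationRadius disk radius in pixels (default 3).
#' @param patientId,group metadata propagated into the table.
#' @return a [CellTable] with one row per nucleus.
#' @export
assignCellsAndQuantify <- function(stack, nuclei, dilationRadius = 3,
                                   patientId = "P01", group = "normal") {
  stopifnot(is(stack, "ChannelStack"), is(nuclei, "LabelMap"))
  labs <- labelMatrix(nuclei)
  d <- dim(stack@pixels)
  if (!identical(dim(labs), d[1:2]))
    stop("nuclei label map does not match the stack dimensions")
  obj <- objectTable(nuclei)
  H <- d[1]; W <- d[2]
  assign <- matrix(0L, H, W)
  bestD <- matrix(Inf, H, W)
  r <- dilationRadius
  pos <- which(labs > 0, arr.ind = TRUE)
  labVec <- labs[pos]
  for (k in seq_len(nrow(obj))) {
    mem <- pos[labVec == k, , drop = FALSE]
    rr <- max(1, min(mem[, 1]) - ceiling(r)):min(H, max(mem[, 1]) + ceiling(r))
    cc <- max(1, min(mem[, 2]) - ceiling(r)):min(W, max(mem[, 2]) + ceiling(r))
    box <- as.matrix(expand.grid(row = rr, col = cc))
    dmem <- crossdist2(box, mem)
    inMask <- sqrt(apply(dmem, 1, min)) <= r
    box <- box[inMask, , drop = FALSE]
    if (!nrow(box)) next
    dcent <- sqrt((box[, 2] - 1 - obj$x[k])^2 + (box[, 1] - 1 - obj$y[k])^2)
    lin <- (box[, 2] - 1L) * H + box[, 1]
    win <- dcent < bestD[lin]              # strict: ties stay with lower label
    assign[lin[win]] <- k
    bestD[lin[win]] <- dcent[win]
  }
  K <- nrow(obj)
  area <- tabulate(assign[assign > 0], nbins = K)
  exprs <- matrix(0, K, d[3], dimnames = list(NULL, stack@channelNames))
  sel <- assign > 0
  lab <- assign[sel]
  for (ci in seq_len(d[3])) {
    v <- stack@pixels[, , ci][sel]
    s <- tapply(v, lab, mean)
    exprs[as.integer(names(s)), ci] <- s
  }
  cellTable(
    data.frame(cell_id = obj$label, roi_id = stack@roiId,
               patient_id = patientId, group = group,
               x = obj$x, y = obj$y, area = pmax(area, 1L)),
    exprs)
}

#' Segment one preprocessed stack into a cell table
#'
#' Convenience wrapper: detect nuclei on the `nucleiChannel`, then build
#' cell masks and quantify all channels.
#'
#' @inheritParams assignCellsAndQuantify
#' @param nucleiChannel channel name holding the nuclear stain.
#' @param threshold,minArea passed to [detectObjects()].
#' @return a [CellTable].
#' @export
segmentStack <- function(stack, nucleiChannel = "DNA", threshold = "otsu",
                         minArea = 3L, dilationRadius = 3,
                         patientId = "P01", group = "normal") {
  nuc <- detectObjects(getChannel(stack, nucleiChannel), threshold, minArea)
  assignCellsAndQuantify(stack, nuc, dilationRadius, patientId, group)
}
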