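#' PhenotypeModel: phenotype clusters of a cohort
#'
#' Output of [clusterPhenotypes()]: the per-cell phenotype label, the
#' cluster-by-marker mean profile (on normalized intensities), the max-min
#' scaled display profile (each marker scaled to `[0, 1]` across clusters,
#' the form shown in cluster heatmaps), and the per-patient cluster
#' frequency table.
#'
#' @slot labels integer per-cell phenotype, contiguous `1..K`.
#' @slot profile numeric matrix clusters x markers (mean normalized
#'   intensity).
#' @slot displayProfile max-min scaled profile, entries in `[0, 1]`.
#' @slot patientFreq numeric matrix patients x clusters; rows sum to 1.
#' @slot graphInfo list with clustering diagnostics (modularity, k used).
#' @export
setClass("PhenotypeModel",
  representation(labels = "integer", profile = "matrix",
                 displayProfile = "matrix", patientFreq = "matrix",
                 graphInfo = "list"),
  validity = function(object) {
    K <- nrow(object@profile)
    if (length(object@labels) &&
        !identical(sort(unique(object@labels)), seq_len(K)))
      return("labels must be contiguous 1..K")
    dp <- object@displayProfile
    if (length(dp) && (min(dp) < -1e-9 || max(dp) > 1 + 1e-9))
      return("display profile entries must be in [0,1]")
    if (nrow(object@patientFreq) &&
        any(abs(rowSums(object@patientFreq) - 1) > 1e-9))
      return("per-patient frequencies must sum to 1")
    TRUE
  })

setMethod("show", "PhenotypeModel", function(object) {
  cat("PhenotypeModel:", nrow(object@profile), "clusters over",
      length(object@labels), "cells; modularity",
      format(object@graphInfo$modularity, digits = 3), "\n")
})

#' @rdname PhenotypeModel-class
#' @param x a `PhenotypeModel`.
#' @param display return the max-min scaled display profile instead of the
#'   raw cluster means.
#' @export
clusterProfile <- function(x, display = FALSE) {
  stopifnot(is(x, "PhenotypeModel"))
  if (display) x@displayProfile else x@profile
}

#' Range-normalize marker intensities to a channel percentile
#'
#' Divides each channel by its `percentile`-th percentile across all cells
#' (linear interpolation between order statistics) and clips to `[0, 1]`.
#' An all-zero channel is left at zero. Default percentile 99.
#'
#' @param cells a [CellTable].
#' @param percentile percentile in `(0, 100]`.
#' @return the [CellTable] with normalized intensities.
#' @export
rangeNormalize <- function(cells, percentile = 99) {
  stopifnot(is(cells, "CellTable"), nCells(cells) >= 1)
  if (percentile <= 0 || percentile > 100)
    stop("percentile must be in (0, 100]")
  ex <- intensities(cells)
  for (j in seq_len(ncol(ex))) {
    q <- quantile(ex[, j], percentile / 100, names = FALSE)
    if (q > 0) ex[, j] <- pmin(ex[, j] / q, 1)
  }
  intensities(cells) <- ex
  cells
}

#' Align per-patient intensity distributions (batch correction)
#'
#' A transparent substitute for mixture-model batch integration: per
#' channel, each patient's values are centred to their median, rescaled so
#' the patient interquartile range matches the pooled cohort's, and shifted
#' to the pooled median; results are re-clamped at zero. A single-patient
#' cohort is returned unchanged. This removes multiplicative per-patient
#' batch factors of the kind the synthetic generator plants; it is *not*
#' equivalent to Harmony-style embedding alignment used in some published
#' pipelines.
#'
#' @param cells a [CellTable] with `patient_id`.
#' @return the [CellTable] with aligned intensities.
#' @export
alignBatches <- function(cells) {
  stopifnot(is(cells, "CellTable"))
  cd <- cellData(cells)
  pats <- unique(cd$patient_id)
  if (length(pats) < 2) return(cells)
  ex <- intensities(cells)
  for (j in seq_len(ncol(ex))) {
    v <- ex[, j]
    m <- median(v)
    iqr <- diff(quantile(v, c(0.25, 0.75), names = FALSE))
    for (p in pats) {
      sel <- cd$patient_id == p
      mp <- median(v[sel])
      ip <- diff(quantile(v[sel], c(0.25, 0.75), names = FALSE))
      sc <- if (ip > 0 && iqr > 0) iqr / ip else 1
      v[sel] <- (v[sel] - mp) * sc + m
    }
    v[v < 0] <- 0
    ex[, j] <- v
  }
  intensities(cells) <- ex
  cells
}

# Jaccard-weighted kNN graph edges, computed in sparse blocks.
.jaccardEdges <- function(idx) {
  n <- nrow(idx); k <- ncol(idx)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(idx),
                            x = 1, dims = c(n, n))
  ei <- rep(seq_len(n), k); ej <- as.vector(idx)
  inter <- numeric(length(ei))
  bs <- 1024L
  for (s in seq(1, n, by = bs)) {
    e <- min(s + bs - 1L, n)
    M <- A[s:e, , drop = FALSE] %*% Matrix::t(A)   # shared-neighbour counts
    rows <- which(ei >= s & ei <= e)
    inter[rows] <- M[cbind(ei[rows] - s + 1L, ej[rows])]
  }
  jac <- inter / (2 * k - inter)
  data.frame(i = ei, j = ej, w = jac)
}

#' Cluster cells into phenotypes on a Jaccard-weighted kNN graph
#'
#' Builds the k-nearest-neighbour graph of cells in normalized marker space
#' (Euclidean), re-weights each edge by the Jaccard overlap of the two
#' cells' neighbour sets, and partitions the graph by seeded
#' modularity-maximizing (Louvain) community detection. Clusters are
#' relabeled `1..K` by decreasing size (ties by smallest member id) so the
#' labeling is deterministic given the seed.
#'
#' @param cells a [CellTable]; intensities should already be
#'   range-normalized (and batch-aligned if needed).
#' @param kNeighbors neighbours for the graph (default 100, clamped to
#'   `nCells - 1`).
#' @param seed integer RNG seed for the community detection.
#' @param resolution modularity resolution of the community detection
#'   (default 1, the conventional modularity objective). Lower values give
#'   coarser partitions; with well-separated populations whose kNN
#'   subgraphs are mutually disconnected, a low resolution (for instance
#'   0.05) returns exactly one cluster per connected component.
#' @return list with the annotated `cells` (phenotype column filled) and
#'   the fitted [PhenotypeModel] as `model`.
#' @export
clusterPhenotypes <- function(cells, kNeighbors = 100L, seed = 1L,
                              resolution = 1) {
  stopifnot(is(cells, "CellTable"), nCells(cells) >= 2)
  if (kNeighbors < 1) stop("kNeighbors must be >= 1")
  kNeighbors <- min(as.integer(kNeighbors), nCells(cells) - 1L)
  ex <- intensities(cells)
  nn <- knnIndices(ex, k = kNeighbors, exclude.self = TRUE)
  edges <- .jaccardEdges(nn$idx)
  edges <- edges[edges$w > 0, ]
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$i, to = edges$j, weight = edges$w),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nCells(cells))))
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "max"))
  comm <- withSeed(seed, igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(comm)[as.character(seq_len(nCells(cells)))]
  labels <- .relabelBySize(as.integer(memb))
  K <- max(labels)
  prof <- t(vapply(seq_len(K), function(k)
    colMeans(ex[labels == k, , drop = FALSE]), numeric(ncol(ex))))
  colnames(prof) <- colnames(ex)
  rownames(prof) <- paste0("PT", seq_len(K))
  disp <- apply(prof, 2, function(v) {
    rng <- max(v) - min(v)
    if (rng == 0) rep(0, length(v)) else (v - min(v)) / rng
  })
  disp <- matrix(disp, nrow = K, dimnames = dimnames(prof))
  cd <- cellData(cells)
  freq <- .freqTable(cd$patient_id, labels, K)
  phenotypes(cells) <- labels
  model <- new("PhenotypeModel", labels = labels, profile = prof,
               displayProfile = disp, patientFreq = freq,
               graphInfo = list(modularity = igraph::modularity(comm),
                                kNeighbors = kNeighbors, seed = seed,
                                resolution = resolution))
  list(cells = cells, model = model)
}

# relabel 1..K by decreasing cluster size; ties by smallest member index
.relabelBySize <- function(labels) {
  sizes <- tabulate(labels)
  firsts <- vapply(seq_along(sizes), function(k) {
    w <- which(labels == k)
    if (length(w)) w[1] else NA_integer_
  }, integer(1))
  o <- order(-sizes, firsts)
  remap <- integer(length(sizes))
  remap[o] <- seq_along(o)
  remap[labels]
}

.freqTable <- function(groupIds, labels, K) {
  ids <- sort(unique(groupIds))
  freq <- t(vapply(ids, function(p) {
    tab <- tabulate(labels[groupIds == p], nbins = K)
    tab / sum(tab)
  }, numeric(K)))
  dimnames(freq) <- list(ids, paste0("C", seq_len(K)))
  freq
}

#' Compare per-ROI phenotype densities between groups
#'
#' Cell density (cells per mm-squared, given the pixel size) is compared
#' rather than frequency, to avoid the dilution effect of heavy immune
#' infiltration: per phenotype, each ROI contributes
#' `count / ROI area`, and the normal and disease ROI density vectors are
#' compared with a two-sided Wilcoxon rank-sum test. No multiplicity
#' correction is applied by default; set `adjust = "BH"` for
#' Benjamini-Hochberg.
#'
#' @param cells a phenotype-annotated [CellTable].
#' @param roiSize numeric c(width, height) of an ROI in pixels.
#' @param pixelSizeUm physical pixel edge in micrometres (default 1).
#' @param adjust p-value adjustment method (default `"none"`).
#' @return data.frame with one row per phenotype: mean density per group,
#'   Wilcoxon `p`, and adjusted `p_adj`.
#' @export
compareDensity <- function(cells, roiSize, pixelSizeUm = 1,
                           adjust = "none") {
  stopifnot(is(cells, "CellTable"))
  labels <- phenotypes(cells)
  if (is.null(labels)) stop("phenotype labels missing; run clusterPhenotypes")
  cd <- cellData(cells)
  if (length(unique(cd$group)) < 2)
    stop("both groups must be represented")
  areaMm2 <- prod(roiSize) * pixelSizeUm^2 / 1e6
  rois <- unique(cd[, c("roi_id", "group")])
  K <- max(labels)
  res <- lapply(seq_len(K), function(k) {
    dens <- vapply(rois$roi_id, function(r)
      sum(cd$roi_id == r & labels == k) / areaMm2, numeric(1))
    dn <- dens[rois$group == "normal"]
    dd <- dens[rois$group == "disease"]
    p <- if (all(c(dn, dd) == c(dn, dd)[1])) 1 else
      suppressWarnings(wilcox.test(dn, dd)$p.value)
    data.frame(phenotype = k, density_normal = mean(dn),
               density_disease = mean(dd), p = p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, method = adjust)
  out
}
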