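#' NeighborhoodModel: cellular neighborhoods (CNs) of a cohort
#'
#' A CN is a cluster of local composition windows: each cell is summarized
#' by the phenotype fractions among itself and its `w` nearest same-ROI
#' neighbours (default 20, so a 21-cell window), and the windows are
#' K-means clustered (default k = 15). Cells inherit the CN of their own
#' window.
#'
#' @slot windowSize neighbours per window (excluding the centre cell).
#' @slot k number of CNs requested.
#' @slot composition numeric matrix cells x phenotypes; rows sum to 1.
#' @slot labels integer per-cell CN in `1..k`.
#' @slot centroids k x phenotypes K-means centroids.
#' @slot abundance CN x phenotype mean composition, column-scaled to
#'   `[0, 1]` for display.
#' @slot patientFreq patients x CN frequency matrix; rows sum to 1.
#' @slot sizes integer CN sizes (empty CNs reported as 0, never dropped).
#' @export
setClass("NeighborhoodModel",
  representation(windowSize = "integer", k = "integer",
                 composition = "matrix", labels = "integer",
                 centroids = "matrix", abundance = "matrix",
                 patientFreq = "matrix", sizes = "integer"),
  validity = function(object) {
    if (nrow(object@composition) &&
        any(abs(rowSums(object@composition) - 1) > 1e-9))
      return("composition rows must sum to 1")
    if (length(object@labels) &&
        (min(object@labels) < 1 || max(object@labels) > object@k))
      return("CN labels must lie in 1..k")
    if (nrow(object@patientFreq) &&
        any(abs(rowSums(object@patientFreq) - 1) > 1e-9))
      return("per-patient CN frequencies must sum to 1")
    TRUE
  })

setMethod("show", "NeighborhoodModel", function(object) {
  cat("NeighborhoodModel:", object@k, "CNs (", sum(object@sizes > 0),
      "occupied ) from", nrow(object@composition), "windows of",
      object@windowSize, "+1 cells\n")
})

#' Neighborhood composition windows
#'
#' For every cell, finds its `w` nearest neighbours within the same ROI by
#' Euclidean distance (exact ties broken by lower cell id) and returns the
#' phenotype composition of the window formed by the centre cell plus those
#' neighbours. ROIs with `<= w` cells use all their cells as the window.
#' Windows never cross ROI boundaries.
#'
#' @param cells a phenotype-annotated [CellTable]; each ROI needs >= 2
#'   cells.
#' @param w neighbours per window (default 20).
#' @param nTypes optionally force the number of phenotype columns (useful
#'   when some phenotype is absent from a subset).
#' @return numeric matrix cells x phenotypes, rows summing to 1, rows in
#'   the order of `cells`.
#' @export
neighborhoodWindows <- function(cells, w = 20L, nTypes = NULL) {
  stopifnot(is(cells, "CellTable"))
  labels <- phenotypes(cells)
  if (is.null(labels)) stop("phenotype labels missing; run clusterPhenotypes")
  cd <- cellData(cells)
  K <- if (is.null(nTypes)) max(labels) else as.integer(nTypes)
  comp <- matrix(0, nCells(cells), K,
                 dimnames = list(NULL, paste0("PT", seq_len(K))))
  for (rid in unique(cd$roi_id)) {
    sel <- which(cd$roi_id == rid)
    if (length(sel) < 2) stop("ROI ", rid, " has fewer than 2 cells")
    xy <- cbind(cd$x[sel], cd$y[sel])
    ww <- min(w, length(sel) - 1L)
    nn <- knnIndices(xy, k = ww, exclude.self = TRUE)
    for (i in seq_along(sel)) {
      members <- c(i, nn$idx[i, ])
      tab <- tabulate(labels[sel[members]], nbins = K)
      comp[sel[i], ] <- tab / length(members)
    }
  }
  comp
}

# K-means++ seeding followed by Lloyd iterations. Used instead of
# stats::kmeans so that empty clusters are reported (not an error) and
# assignment ties break deterministically to the lower cluster index.
.kmeansLloyd <- function(X, k, maxIter = 100L) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    pick <- if (sum(d2) == 0) sample.int(n, 1) else
      sample.int(n, 1, prob = d2)
    centers[j + 1, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[j + 1, ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  assign <- integer(n)
  for (it in seq_len(maxIter)) {
    D <- crossdist2(X, centers)
    newAssign <- max.col(-D, ties.method = "first")
    if (identical(newAssign, assign)) break
    assign <- newAssign
    for (j in seq_len(k)) {
      m <- assign == j
      if (any(m)) centers[j, ] <- colMeans(X[m, , drop = FALSE])
    }
  }
  D <- crossdist2(X, centers)
  list(assign = assign, centers = centers,
       inertia = sum(D[cbind(seq_len(n), assign)]))
}

#' Cluster composition windows into CNs with K-means
#'
#' K-means (k-means++ initialization, Lloyd updates, 10 restarts keeping
#' the best inertia, all seeded) on the window composition rows. Empty
#' clusters are reported in the model's `sizes` slot, never silently
#' dropped.
#'
#' @param composition cells x phenotypes matrix from
#'   [neighborhoodWindows()].
#' @param k number of CNs (default 15).
#' @param seed integer seed.
#' @param nRestarts K-means restarts (default 10).
#' @return list with integer `labels`, matrix `centers`, numeric
#'   `inertia` and integer `sizes` (length k).
#' @export
clusterNeighborhoods <- function(composition, k = 15L, seed = 1L,
                                 nRestarts = 10L) {
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(composition)) stop("k exceeds the number of cells")
  withSeed(seed, {
    best <- NULL
    for (r in seq_len(nRestarts)) {
      fit <- .kmeansLloyd(composition, k)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
    sizes <- tabulate(best$assign, nbins = k)
    if (any(sizes == 0))
      message(sum(sizes == 0), " of ", k, " CNs are empty")
    list(labels = best$assign, centers = best$centers,
         inertia = best$inertia, sizes = sizes)
  })
}

#' Fit the full neighborhood model of a cohort
#'
#' Windows, K-means CNs, display abundances and per-patient CN
#' frequencies in one call.
#'
#' @inheritParams neighborhoodWindows
#' @inheritParams clusterNeighborhoods
#' @return list with the CN-annotated `cells` and the
#'   [NeighborhoodModel] as `model`.
#' @export
fitNeighborhoods <- function(cells, w = 20L, k = 15L, seed = 1L) {
  comp <- neighborhoodWindows(cells, w)
  cl <- clusterNeighborhoods(comp, k, seed)
  K <- ncol(comp)
  abund <- t(vapply(seq_len(k), function(j) {
    m <- cl$labels == j
    if (any(m)) colMeans(comp[m, , drop = FALSE]) else rep(0, K)
  }, numeric(K)))
  # column-scaled for display, as in CN composition heatmaps
  abundScaled <- apply(abund, 2, function(v) {
    rng <- max(v) - min(v)
    if (rng == 0) rep(0, length(v)) else (v - min(v)) / rng
  })
  abundScaled <- matrix(abundScaled, nrow = k,
                        dimnames = list(paste0("CN", seq_len(k)),
                                        colnames(comp)))
  cd <- cellData(cells)
  freq <- .freqTable(cd$patient_id, cl$labels, k)
  colnames(freq) <- paste0("CN", seq_len(k))
  cnLabels(cells) <- cl$labels
  model <- new("NeighborhoodModel", windowSize = as.integer(w),
               k = as.integer(k), composition = comp,
               labels = cl$labels, centroids = cl$centers,
               abundance = abundScaled, patientFreq = freq,
               sizes = as.integer(cl$sizes))
  list(cells = cells, model = model)
}

#' Compare CN abundance between groups
#'
#' Per patient, the frequency of each CN (cells in the CN over the
#' patient's total cells); per CN, a two-sided Wilcoxon rank-sum test
#' between the normal and disease patients' frequencies.
#'
#' @param cells a CN-annotated [CellTable].
#' @param adjust p-value adjustment method (default `"none"`).
#' @return data.frame with per-CN group means and p-values.
#' @export
cnGroupAbundance <- function(cells, adjust = "none") {
  stopifnot(is(cells, "CellTable"))
  labels <- cnLabels(cells)
  if (is.null(labels)) stop("CN labels missing; run fitNeighborhoods")
  cd <- cellData(cells)
  if (length(unique(cd$group)) < 2) stop("both groups must have patients")
  k <- max(labels)
  pats <- unique(cd[, c("patient_id", "group")])
  freq <- .freqTable(cd$patient_id, labels, k)
  grp <- pats$group[match(rownames(freq), pats$patient_id)]
  res <- lapply(seq_len(k), function(j) {
    fn <- freq[grp == "normal", j]
    fd <- freq[grp == "disease", j]
    p <- if (all(c(fn, fd) == c(fn, fd)[1])) 1 else
      suppressWarnings(wilcox.test(fn, fd)$p.value)
    data.frame(cn = j, freq_normal = mean(fn), freq_disease = mean(fd),
               p = p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, method = adjust)
  out
}

#' Voronoi allocation map of one ROI
#'
#' Tessellates the ROI rectangle by the cell centroids and tags each
#' polygon with its cell's CN label, for overlay on the source image. The
#' polygons tile the rectangle exactly.
#'
#' @param cells a CN-annotated [CellTable].
#' @param roi ROI id to map.
#' @param roiSize numeric c(width, height) in pixels.
#' @return list with `polygons` (list of two-column vertex matrices),
#'   integer `cn` per polygon, numeric `area` per polygon, and the
#'   generating `points`.
#' @export
voronoiMap <- function(cells, roi, roiSize) {
  stopifnot(is(cells, "CellTable"))
  labels <- cnLabels(cells)
  if (is.null(labels)) stop("CN labels missing; run fitNeighborhoods")
  cd <- cellData(cells)
  sel <- which(cd$roi_id == roi)
  if (length(sel) < 3)
    stop("ROI ", roi, " has fewer than 3 cells; cannot tessellate")
  x <- cd$x[sel]; y <- cd$y[sel]
  if (svd(cbind(x - mean(x), y - mean(y)))$d[2] < 1e-9)
    stop("cells of ROI ", roi, " are collinear; cannot tessellate")
  dd <- deldir::deldir(x, y, rw = c(0, roiSize[1], 0, roiSize[2]),
                       suppressMsge = TRUE)
  tiles <- deldir::tile.list(dd)
  polys <- lapply(tiles, function(t) cbind(x = t$x, y = t$y))
  areas <- vapply(tiles, function(t) {
    n <- length(t$x)
    abs(sum(t$x * t$y[c(2:n, 1)] - t$x[c(2:n, 1)] * t$y)) / 2
  }, numeric(1))
  gen <- t(vapply(tiles, function(t) c(t$pt[1], t$pt[2]), numeric(2)))
  # deldir fuzzes generator coordinates by ~1e-7; match tiles back to the
  # input cells by nearest neighbour
  ord <- RANN::nn2(cbind(x, y), gen, k = 1)$nn.idx[, 1]
  list(polygons = polys, cn = unname(labels[sel][ord]),
       area = unname(areas), points = cbind(x = x[ord], y = y[ord]))
}
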