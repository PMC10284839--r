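#' InteractionResult: per-ROI interaction/avoidance permutation tests
#'
#' For every ROI and ordered phenotype pair (centre type A, neighbour type
#' B), the observed statistic is the mean, over A cells, of the count of B
#' cells among their spatial neighbours. One-sided empirical p-values
#' against a label-permutation null score interaction (observed high) and
#' avoidance (observed low). [summarizeCohort()] aggregates the per-ROI
#' results into the fraction of significant ROIs per pair and the Pearson
#' correlation of per-ROI type fractions.
#'
#' @slot results data.frame with columns `roi`, `group`, `center`,
#'   `neighbor`, `obs`, `p_int`, `p_avoid`.
#' @slot nPerm,kSpatial test parameters.
#' @slot typeNames phenotype level names tested.
#' @export
setClass("InteractionResult",
  representation(results = "data.frame", nPerm = "integer",
                 kSpatial = "integer", typeNames = "character"),
  validity = function(object) {
    r <- object@results
    if (nrow(r)) {
      pmin_ <- 1 / (object@nPerm + 1)
      if (any(r$p_int < pmin_ - 1e-12 | r$p_int > 1 + 1e-12) ||
          any(r$p_avoid < pmin_ - 1e-12 | r$p_avoid > 1 + 1e-12))
        return("p-values must lie in [1/(n_perm+1), 1]")
    }
    TRUE
  })

setMethod("show", "InteractionResult", function(object) {
  cat("InteractionResult:", length(unique(object@results$roi)), "ROIs,",
      length(object@typeNames), "types,", object@nPerm, "permutations\n")
})

#' @rdname InteractionResult-class
#' @param x an `InteractionResult`.
#' @export
interactionResults <- function(x) {
  stopifnot(is(x, "InteractionResult"))
  x@results
}

#' Directed k-nearest-neighbour spatial graph of one ROI
#'
#' @param coords two-column matrix of cell positions (one ROI).
#' @param kSpatial neighbours per cell (default 20, clamped to `n - 1`);
#'   ties broken by lower cell index, self excluded.
#' @return integer matrix `n x kSpatial` of neighbour row indices.
#' @export
buildSpatialGraph <- function(coords, kSpatial = 20L) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 2)
  k <- min(as.integer(kSpatial), nrow(coords) - 1L)
  knnIndices(coords, k = k, exclude.self = TRUE)$idx
}

#' Permutation test for pairwise interaction and avoidance in one ROI
#'
#' The observed statistic per ordered pair (A, B) is the mean number of B
#' neighbours over A cells on the given spatial graph. The null fixes the
#' positions (and hence the graph) and permutes the phenotype labels
#' within the ROI `nPerm` times. Empirical p-values use the add-one
#' correction `p = (1 + #extreme) / (1 + nPerm)`, so they are valid at
#' finite `nPerm` and never exactly zero: `p_int` counts permutations with
#' statistic `>=` observed, `p_avoid` those `<=` observed. Pairs whose
#' centre type has no cells get `p = 1` for both directions and an
#' `NA` statistic.
#'
#' @param labels integer phenotype labels of the ROI's cells.
#' @param graph neighbour index matrix from [buildSpatialGraph()].
#' @param nTypes number of phenotype levels (pairs are reported for all
#'   levels, present or not).
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#' @return data.frame with `center`, `neighbor`, `obs`, `p_int`,
#'   `p_avoid` for all ordered type pairs.
#' @export
interactionTest <- function(labels, graph, nTypes = max(labels),
                            nPerm = 1000L, seed = 1L) {
  stopifnot(nPerm >= 1)
  n <- length(labels)
  stopifnot(nrow(graph) == n)
  K <- as.integer(nTypes)
  Adj <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(graph)),
                              j = as.vector(graph), x = 1, dims = c(n, n))
  pairStat <- function(lab) {
    L <- Matrix::sparseMatrix(i = seq_len(n), j = lab, x = 1,
                              dims = c(n, K))
    counts <- as.matrix(Adj %*% L)         # cell x type neighbour counts
    nA <- Matrix::colSums(L)
    S <- as.matrix(Matrix::crossprod(L, counts))
    S[nA > 0, ] <- S[nA > 0, ] / nA[nA > 0]
    S[nA == 0, ] <- NA_real_
    S                                       # K x K: centre x neighbour mean
  }
  obs <- pairStat(labels)
  withSeed(seed, {
    ge <- matrix(0L, K, K)
    le <- matrix(0L, K, K)
    for (b in seq_len(nPerm)) {
      Sp <- pairStat(sample(labels))
      ge <- ge + (!is.na(Sp) & !is.na(obs) & Sp >= obs)
      le <- le + (!is.na(Sp) & !is.na(obs) & Sp <= obs)
    }
    pInt <- (1 + ge) / (1 + nPerm)
    pAvoid <- (1 + le) / (1 + nPerm)
    pInt[is.na(obs)] <- 1
    pAvoid[is.na(obs)] <- 1
    data.frame(center = rep(seq_len(K), K),
               neighbor = rep(seq_len(K), each = K),
               obs = as.vector(obs), p_int = as.vector(pInt),
               p_avoid = as.vector(pAvoid))
  })
}

#' Run the interaction test over every ROI of a cohort
#'
#' @param cells a phenotype-annotated [CellTable].
#' @param kSpatial spatial neighbours per cell (default 20).
#' @param nPerm permutations per ROI (default 1000).
#' @param seed base seed; each ROI uses `seed + roi index`.
#' @return an [InteractionResult].
#' @export
testInteractions <- function(cells, kSpatial = 20L, nPerm = 1000L,
                             seed = 1L) {
  stopifnot(is(cells, "CellTable"))
  labels <- phenotypes(cells)
  if (is.null(labels)) stop("phenotype labels missing")
  cd <- cellData(cells)
  K <- max(labels)
  rois <- unique(cd[, c("roi_id", "group")])
  out <- lapply(seq_len(nrow(rois)), function(i) {
    sel <- which(cd$roi_id == rois$roi_id[i])
    g <- buildSpatialGraph(cbind(cd$x[sel], cd$y[sel]), kSpatial)
    r <- interactionTest(labels[sel], g, nTypes = K, nPerm = nPerm,
                         seed = seed + i)
    cbind(roi = rois$roi_id[i], group = rois$group[i], r)
  })
  new("InteractionResult", results = do.call(rbind, out),
      nPerm = as.integer(nPerm), kSpatial = as.integer(kSpatial),
      typeNames = paste0("PT", seq_len(K)))
}

#' Cohort summary of interaction/avoidance results
#'
#' Per group and ordered pair: the fraction of ROIs significant for
#' interaction and for avoidance at level `alpha` (default 0.01), the
#' Pearson correlation of the two types' per-ROI fraction vectors, and a
#' classification (`"interaction"` / `"avoidance"` / `"neither"`) by
#' majority significance across ROIs. A constant fraction vector makes the
#' correlation undefined; it is reported as 0 with `r_defined = FALSE`.
#'
#' @param x an [InteractionResult].
#' @param cells the [CellTable] the tests were run on (for per-ROI type
#'   fractions).
#' @param alpha significance level per ROI (default 0.01).
#' @return data.frame keyed by (group, center, neighbor).
#' @export
summarizeCohort <- function(x, cells, alpha = 0.01) {
  stopifnot(is(x, "InteractionResult"), is(cells, "CellTable"))
  res <- x@results
  labels <- phenotypes(cells)
  cd <- cellData(cells)
  K <- length(x@typeNames)
  out <- list()
  for (g in unique(res$group)) {
    rg <- res[res$group == g, ]
    roiIds <- unique(rg$roi)
    if (length(roiIds) < 2) stop("need >= 2 ROIs per group")
    fracs <- t(vapply(roiIds, function(r) {
      sel <- cd$roi_id == r
      tabulate(labels[sel], nbins = K) / sum(sel)
    }, numeric(K)))
    agg <- aggregate(cbind(sigInt = p_int < alpha, sigAvoid = p_avoid < alpha)
                     ~ center + neighbor, data = rg, FUN = mean)
    agg$r <- NA_real_
    agg$r_defined <- TRUE
    for (i in seq_len(nrow(agg))) {
      a <- fracs[, agg$center[i]]; b <- fracs[, agg$neighbor[i]]
      if (sd(a) == 0 || sd(b) == 0) {
        agg$r[i] <- 0; agg$r_defined[i] <- FALSE
      } else agg$r[i] <- cor(a, b)
    }
    agg$class <- ifelse(agg$sigInt > 0.5, "interaction",
                        ifelse(agg$sigAvoid > 0.5, "avoidance", "neither"))
    out[[g]] <- cbind(group = g, agg)
  }
  do.call(rbind, out)
}
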