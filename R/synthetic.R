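#' TissueSpec: configuration of the synthetic tissue generator
#'
#' Describes a synthetic multiplexed-imaging cohort: how many ROIs and
#' patients, the planted niches (clustered mixtures of cell types), planted
#' pairwise attraction/avoidance, the per-type marker archetypes, noise,
#' per-patient batch factors and channel spillover. [generateCohort()] turns
#' a spec into a [CellTable] plus [GroundTruth]; [rasterize()] renders
#' per-ROI channel stacks for the segmentation stage.
#'
#' Cells are placed by a Neyman-Scott-style clustered point process: each
#' niche scatters parent points uniformly in the ROI and disperses its
#' offspring cells around them with Gaussian spread `clusterSd`. A niche's
#' `props` give the mixing proportions over cell types (optionally distinct
#' per group, as a list with elements `normal` and `disease`), and must sum
#' to 1. Attraction pairs relocate a `strength` fraction of B cells to
#' Gaussian displacements around random A cells; avoidance pairs thin B
#' cells within an exclusion radius `strength * 30` px of any A cell.
#' Expression is `archetype[type] * lognormal(cv) * patient batch factor`,
#' mixed through the spillover matrix.
#'
#' @slot nRois,nPatients counts.
#' @slot roiSize numeric c(width, height) in pixels.
#' @slot cellsPerRoi target cells per ROI (before avoidance thinning).
#' @slot typeNames character vector of cell-type names (>= 2 types).
#' @slot nicheDefs list; each element a list with `props` (named numeric
#'   vector over types, or list(normal=, disease=)), `weight` (share of the
#'   ROI's cells), `clusterSd` (offspring dispersion, px) and
#'   `offspringPerParent`.
#' @slot interactionPairs data.frame(typeA, typeB, mode, strength) with
#'   mode in "attract"/"avoid" and strength in [0, 1].
#' @slot groupAssignment character per patient, "normal" or "disease".
#' @slot archetypes numeric matrix types x channels (must contain a "DNA"
#'   column used for the nuclei channel).
#' @slot noiseCv lognormal coefficient of variation of per-cell expression.
#' @slot batchEffectScale lognormal sigma of the per-patient, per-channel
#'   multiplicative batch factor.
#' @slot spillover a [SpilloverMatrix] over the archetype channels.
#' @slot minSpacing optional hard-core spacing (px) enforced by sequential
#'   thinning; 0 disables.
#' @slot backgroundRate Poisson background rate per pixel for [rasterize()].
#' @slot seed integer; fixes all randomness of the generator.
#' @export tissueSpec
#' @exportClass TissueSpec
setClass("TissueSpec",
  representation(nRois = "integer", roiSize = "numeric",
                 cellsPerRoi = "integer", typeNames = "character",
                 nicheDefs = "list", interactionPairs = "data.frame",
                 nPatients = "integer", groupAssignment = "character",
                 archetypes = "matrix", noiseCv = "numeric",
                 batchEffectScale = "numeric", spillover = "SpilloverMatrix",
                 minSpacing = "numeric", backgroundRate = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (length(object@typeNames) < 2) return("need at least 2 cell types")
    if (length(object@roiSize) != 2 || any(object@roiSize < 8))
      return("roiSize must be c(width, height), each >= 8 px")
    if (object@cellsPerRoi > 0.2 * prod(object@roiSize))
      return("infeasible density: requested cells exceed the pixel grid")
    for (nd in object@nicheDefs) {
      pr <- nd$props
      if (!is.list(pr)) pr <- list(pr)
      for (p in pr) {
        if (any(p < 0) || sum(p) <= 0) return("degenerate niche proportions")
        if (abs(sum(p) - 1) > 1e-9)
          return("niche mixing proportions must sum to 1")
        if (!all(names(p) %in% object@typeNames))
          return("niche proportions name unknown types")
      }
    }
    ip <- object@interactionPairs
    if (nrow(ip)) {
      if (!all(ip$mode %in% c("attract", "avoid")))
        return("interaction mode must be 'attract' or 'avoid'")
      if (any(ip$strength < 0 | ip$strength > 1))
        return("interaction strengths must be in [0, 1]")
    }
    if (length(object@groupAssignment) != object@nPatients)
      return("groupAssignment must have one entry per patient")
    if (!all(object@groupAssignment %in% c("normal", "disease")))
      return("groups must be 'normal' or 'disease'")
    if (!"DNA" %in% colnames(object@archetypes))
      return("archetypes must include a 'DNA' channel")
    if (nrow(object@archetypes) != length(object@typeNames))
      return("archetypes must have one row per type")
    if (!identical(colnames(as.matrix(object@spillover)),
                   colnames(object@archetypes)))
      return("spillover channels must match archetype channels")
    TRUE
  })

setMethod("$", "TissueSpec", function(x, name) slot(x, name))

setMethod("show", "TissueSpec", function(object) {
  cat("TissueSpec:", object@nRois, "ROIs x", object@cellsPerRoi,
      "cells,", length(object@typeNames), "types,",
      length(object@nicheDefs), "niches,", object@nPatients,
      "patients (", sum(object@groupAssignment == "normal"), "normal /",
      sum(object@groupAssignment == "disease"), "disease ), seed",
      object@seed, "\n")
})

#' Default marker archetypes: one dominant marker per type plus DNA
#'
#' Each type expresses its own marker at `high`, all other markers at
#' `base`, and DNA at `dna`; channel names are `M01..Mk` plus `"DNA"`.
#'
#' @param typeNames character vector of type names.
#' @param high,base,dna intensity levels.
#' @return numeric matrix, types x channels.
#' @export
defaultArchetypes <- function(typeNames, high = 10, base = 0.2, dna = 5) {
  k <- length(typeNames)
  markers <- sprintf("M%02d", seq_len(k))
  A <- matrix(base, k, k, dimnames = list(typeNames, markers))
  diag(A) <- high
  cbind(A, DNA = dna)
}

#' Default niche definitions: blocks of types with a dominant share
#'
#' Partitions the types into `nNiches` contiguous blocks; each niche puts
#' `dominance` of its mass uniformly on its own block and the rest uniformly
#' on all other types, giving niches that are separable by their window
#' composition.
#'
#' @param typeNames character vector of type names.
#' @param nNiches number of niches.
#' @param dominance probability mass on the niche's own block.
#' @param clusterSd,offspringPerParent point-process parameters.
#' @return list of niche definitions for [tissueSpec()].
#' @export
defaultNiches <- function(typeNames, nNiches = 3, dominance = 0.85,
                          clusterSd = 25, offspringPerParent = 40) {
  k <- length(typeNames)
  blocks <- split(seq_len(k), cut(seq_len(k), nNiches, labels = FALSE))
  lapply(seq_len(nNiches), function(i) {
    p <- rep((1 - dominance) / max(1, k - length(blocks[[i]])), k)
    p[blocks[[i]]] <- dominance / length(blocks[[i]])
    p <- p / sum(p)
    names(p) <- typeNames
    list(props = p, weight = 1 / nNiches, clusterSd = clusterSd,
         offspringPerParent = offspringPerParent)
  })
}

#' Spillover with constant leakage into the next channel
#' @param channels channel names.
#' @param leak off-diagonal leakage fraction.
#' @return a [SpilloverMatrix].
#' @export
adjacentSpillover <- function(channels, leak = 0.03) {
  C <- length(channels)
  S <- diag(C)
  if (C > 1) for (i in seq_len(C - 1)) S[i, i + 1] <- leak
  spilloverMatrix(S, channels = channels)
}

#' @rdname TissueSpec-class
#' @param nRois,roiSize,cellsPerRoi,nPatients,groupAssignment cohort layout.
#' @param nTypes,typeNames,archetypes,nicheDefs,interactionPairs planted
#'   cellular structure.
#' @param noiseCv,batchEffectScale,spillover,minSpacing,backgroundRate,seed
#'   noise model and determinism. All defaults together describe the
#'   bundled small cohort (12 ROIs of ~500 cells, 17 types, 3 niches, 12
#'   patients half per group).
#' @export
tissueSpec <- function(nRois = 12L, roiSize = c(256, 256), cellsPerRoi = 500L,
                       nTypes = 17L, typeNames = sprintf("CT%02d", seq_len(nTypes)),
                       nicheDefs = defaultNiches(typeNames),
                       interactionPairs = data.frame(typeA = character(),
                         typeB = character(), mode = character(),
                         strength = numeric()),
                       nPatients = 12L,
                       groupAssignment = rep(c("normal", "disease"),
                                             length.out = nPatients),
                       archetypes = defaultArchetypes(typeNames),
                       noiseCv = 0.2, batchEffectScale = 0.15,
                       spillover = adjacentSpillover(colnames(archetypes)),
                       minSpacing = 0, backgroundRate = 0.02, seed = 1L) {
  new("TissueSpec", nRois = as.integer(nRois), roiSize = as.numeric(roiSize),
      cellsPerRoi = as.integer(cellsPerRoi),
      typeNames = as.character(typeNames), nicheDefs = nicheDefs,
      interactionPairs = interactionPairs, nPatients = as.integer(nPatients),
      groupAssignment = as.character(groupAssignment),
      archetypes = archetypes, noiseCv = as.numeric(noiseCv),
      batchEffectScale = as.numeric(batchEffectScale), spillover = spillover,
      minSpacing = as.numeric(minSpacing),
      backgroundRate = as.numeric(backgroundRate), seed = as.integer(seed))
}

#' GroundTruth: planted structure of a synthetic cohort
#'
#' Row-aligned with the emitted [CellTable]: the true type and niche of
#' every cell, the planted interaction pairs, and the pre-spillover
#' expression matrix (after noise and batch factors, before channel
#' mixing) used by the spillover round-trip checks. Niche labels are
#' contiguous integers starting at 0.
#'
#' @slot trueType integer vector (1-based index into `typeNames`).
#' @slot typeNames character.
#' @slot trueNiche integer vector, 0-based contiguous niche labels.
#' @slot pairs data.frame of planted interaction pairs.
#' @slot exprsTrue numeric matrix, cells x channels, pre-spillover.
#' @export groundTruth
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(trueType = "integer", typeNames = "character",
                 trueNiche = "integer", pairs = "data.frame",
                 exprsTrue = "matrix"),
  validity = function(object) {
    if (length(object@trueType) != length(object@trueNiche))
      return("trueType and trueNiche must be the same length")
    if (length(object@trueNiche)) {
      u <- sort(unique(object@trueNiche))
      if (u[1] != 0L || !identical(u, seq_along(u) - 1L))
        return("niche labels must be contiguous integers from 0")
    }
    TRUE
  })

groundTruth <- function(trueType, typeNames, trueNiche, pairs, exprsTrue) {
  new("GroundTruth", trueType = as.integer(trueType), typeNames = typeNames,
      trueNiche = as.integer(trueNiche), pairs = pairs,
      exprsTrue = exprsTrue)
}

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@trueType), "cells,",
      length(unique(object@trueNiche)), "niches,",
      nrow(object@pairs), "planted pairs\n")
})

#' @rdname GroundTruth-class
#' @param x a `GroundTruth`; @param what one of "type", "niche", "exprs".
#' @param what which component to extract.
#' @export
truth <- function(x, what = c("type", "niche", "exprs", "pairs")) {
  stopifnot(is(x, "GroundTruth"))
  switch(match.arg(what), type = x@trueType, niche = x@trueNiche,
         exprs = x@exprsTrue, pairs = x@pairs)
}

# ---- generation ------------------------------------------------------------

# Place one ROI's cells: parents per niche, Gaussian offspring, niche-typed.
.placeRoiCells <- function(spec, group) {
  W <- spec@roiSize[1]; H <- spec@roiSize[2]
  margin <- 3                              # keep nuclei disks inside the grid
  nNiche <- length(spec@nicheDefs)
  w <- vapply(spec@nicheDefs, function(nd) nd$weight, numeric(1))
  w <- w / sum(w)
  counts <- drop(stats::rmultinom(1, spec@cellsPerRoi, w))
  out <- vector("list", nNiche)
  for (k in seq_len(nNiche)) {
    nd <- spec@nicheDefs[[k]]
    nk <- counts[k]
    if (nk == 0) { out[[k]] <- NULL; next }
    opp <- if (is.null(nd$offspringPerParent)) 40 else nd$offspringPerParent
    nPar <- max(1L, round(nk / opp))
    px <- runif(nPar, margin, W - 1 - margin)
    py <- runif(nPar, margin, H - 1 - margin)
    par <- sample.int(nPar, nk, replace = TRUE)
    x <- pmin(pmax(px[par] + rnorm(nk, 0, nd$clusterSd), margin), W - 1 - margin)
    y <- pmin(pmax(py[par] + rnorm(nk, 0, nd$clusterSd), margin), H - 1 - margin)
    pr <- nd$props
    if (is.list(pr)) pr <- pr[[group]]
    pvec <- setNames(rep(0, length(spec@typeNames)), spec@typeNames)
    pvec[names(pr)] <- pr
    type <- sample.int(length(pvec), nk, replace = TRUE, prob = pvec)
    out[[k]] <- data.frame(x = x, y = y, type = type, niche = k - 1L)
  }
  do.call(rbind, out)
}

.applyInteractions <- function(cells, spec) {
  W <- spec@roiSize[1]; H <- spec@roiSize[2]; margin <- 3
  ip <- spec@interactionPairs
  for (i in seq_len(nrow(ip))) {
    a <- match(ip$typeA[i], spec@typeNames)
    b <- match(ip$typeB[i], spec@typeNames)
    ia <- which(cells$type == a); ib <- which(cells$type == b)
    if (!length(ia) || !length(ib)) next
    if (ip$mode[i] == "attract") {
      nMove <- round(ip$strength[i] * length(ib))
      if (nMove == 0) next
      mv <- sample(ib, nMove)
      anchor <- ia[sample.int(length(ia), nMove, replace = TRUE)]
      cells$x[mv] <- pmin(pmax(cells$x[anchor] + rnorm(nMove, 0, 4), margin),
                          W - 1 - margin)
      cells$y[mv] <- pmin(pmax(cells$y[anchor] + rnorm(nMove, 0, 4), margin),
                          H - 1 - margin)
    } else {                               # avoid: hard-core thinning
      r <- ip$strength[i] * 30
      if (r <= 0) next
      nn <- RANN::nn2(cells[ia, c("x", "y")], cells[ib, c("x", "y")], k = 1)
      drop <- ib[nn$nn.dists[, 1] < r]
      if (length(drop)) cells <- cells[-drop, , drop = FALSE]
    }
  }
  cells
}

.thinSpacing <- function(cells, minSpacing) {
  if (minSpacing <= 0 || nrow(cells) < 2) return(cells)
  keep <- logical(nrow(cells))
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_len(nrow(cells))) {
    if (!length(kx) ||
        min((kx - cells$x[i])^2 + (ky - cells$y[i])^2) >= minSpacing^2) {
      keep[i] <- TRUE
      kx <- c(kx, cells$x[i]); ky <- c(ky, cells$y[i])
    }
  }
  cells[keep, , drop = FALSE]
}

#' Generate a ground-truthed synthetic cohort
#'
#' Runs the clustered point process of `spec` for every ROI, applies planted
#' attraction/avoidance and optional hard-core spacing, draws per-cell
#' expression (archetype x lognormal noise x patient batch factor) and mixes
#' it through the spillover matrix. Fully deterministic given `spec@seed`.
#'
#' @param spec a [TissueSpec].
#' @return list with elements `cells` (a [CellTable]) and `truth`
#'   (a [GroundTruth], row-aligned with `cells`).
#' @examples
#' sim <- generateCohort(tissueSpec(nRois = 2, cellsPerRoi = 100, seed = 7))
#' sim$cells
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "TissueSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    patients <- sprintf("P%02d", seq_len(spec@nPatients))
    roiPatient <- rep(seq_len(spec@nPatients), length.out = spec@nRois)
    batch <- matrix(rlnorm(spec@nPatients * ncol(spec@archetypes),
                           0, spec@batchEffectScale),
                    spec@nPatients, ncol(spec@archetypes))
    S <- as.matrix(spec@spillover)
    sdlog <- sqrt(log(1 + spec@noiseCv^2))
    allCells <- vector("list", spec@nRois)
    allTruth <- vector("list", spec@nRois)
    for (r in seq_len(spec@nRois)) {
      p <- roiPatient[r]
      g <- spec@groupAssignment[p]
      cells <- .placeRoiCells(spec, g)
      cells <- .applyInteractions(cells, spec)
      cells <- .thinSpacing(cells, spec@minSpacing)
      n <- nrow(cells)
      if (n < 50)
        stop("ROI ", r, " holds fewer than 50 cells after thinning; ",
             "increase cellsPerRoi or weaken avoidance")
      noise <- matrix(rlnorm(n * ncol(spec@archetypes), -sdlog^2 / 2, sdlog),
                      n, ncol(spec@archetypes))
      eTrue <- spec@archetypes[cells$type, , drop = FALSE] * noise *
        matrix(batch[p, ], n, ncol(spec@archetypes), byrow = TRUE)
      eObs <- eTrue %*% S
      dimnames(eTrue) <- dimnames(eObs) <-
        list(NULL, colnames(spec@archetypes))
      allCells[[r]] <- list(
        meta = data.frame(cell_id = seq_len(n),
                          roi_id = sprintf("ROI%03d", r),
                          patient_id = patients[p], group = g,
                          x = cells$x, y = cells$y, area = 13),
        exprs = eObs)
      allTruth[[r]] <- list(type = cells$type, niche = cells$niche,
                            eTrue = eTrue)
    }
    ct <- cellTable(do.call(rbind, lapply(allCells, `[[`, "meta")),
                    do.call(rbind, lapply(allCells, `[[`, "exprs")))
    gt <- groundTruth(
      unlist(lapply(allTruth, `[[`, "type")), spec@typeNames,
      unlist(lapply(allTruth, `[[`, "niche")), spec@interactionPairs,
      do.call(rbind, lapply(allTruth, `[[`, "eTrue")))
    list(cells = ct, truth = gt)
  })
}

#' Rasterize a synthetic cell table into per-ROI channel stacks
#'
#' The nuclei ("DNA") channel receives a disk of radius 2 px at each cell
#' centroid carrying that cell's DNA intensity; every marker channel
#' receives a disk of radius 3 px scaled by the cell's expression.
#' Overlapping disks add. An additive Poisson background with rate
#' `spec@backgroundRate` is drawn per pixel (seeded from `spec@seed`).
#' Cells whose nuclei lie closer than 4 px (unresolvable at disk radius 2)
#' trigger a warning with their count.
#'
#' @param cells a [CellTable] from [generateCohort()].
#' @param spec the [TissueSpec] that produced it.
#' @param rois optional character vector restricting which ROIs to render.
#' @return named list of [ChannelStack] objects, one per ROI.
#' @export
rasterize <- function(cells, spec, rois = NULL) {
  stopifnot(is(cells, "CellTable"), is(spec, "TissueSpec"))
  W <- spec@roiSize[1]; H <- spec@roiSize[2]
  cd <- cellData(cells); ex <- intensities(cells)
  if (any(cd$x < 0 | cd$x > W - 1 | cd$y < 0 | cd$y > H - 1))
    stop("cell coordinates outside the ROI grid")
  chans <- colnames(ex)
  offN <- diskOffsets(2); offM <- diskOffsets(3)
  roiIds <- if (is.null(rois)) unique(cd$roi_id) else rois
  withSeed(spec@seed + 1L, {
    out <- lapply(roiIds, function(rid) {
      sel <- which(cd$roi_id == rid)
      px <- round(cd$x[sel]); py <- round(cd$y[sel])
      if (length(sel) > 1) {
        nn <- RANN::nn2(cbind(cd$x[sel], cd$y[sel]), k = 2)
        nClose <- sum(nn$nn.dists[, 2] < 4)
        if (nClose > 0)
          warning(rid, ": ", nClose,
                  " cells closer than 4 px; nuclei may be unresolvable",
                  call. = FALSE)
      }
      arr <- array(0, c(H, W, length(chans)))
      for (ci in seq_along(chans)) {
        off <- if (chans[ci] == "DNA") offN else offM
        plane <- matrix(0, H, W)
        for (j in seq_along(sel)) {
          rr <- py[j] + off$dy + 1L; cc <- px[j] + off$dx + 1L
          ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
          idx <- cbind(rr[ok], cc[ok])
          plane[idx] <- plane[idx] + ex[sel[j], ci]
        }
        arr[, , ci] <- plane
      }
      if (spec@backgroundRate > 0)
        arr <- arr + array(rpois(length(arr), spec@backgroundRate), dim(arr))
      channelStack(arr, chans, rid)
    })
    names(out) <- roiIds
    out
  })
}
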