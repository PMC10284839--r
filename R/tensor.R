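#' TissueTensor: patient x CN x cell-type frequency tensor
#'
#' Entry (p, n, t) is the fraction of patient p's cells in CN n that are of
#' phenotype t: each occupied (patient, CN) fibre along the type mode sums
#' to 1, and a (patient, CN) combination with no cells is all-zero. The
#' tensor is built per group so the two groups' tissue organisation can be
#' factored separately.
#'
#' @slot data nonnegative numeric 3-way array with dimnames
#'   (patients, CNs, types).
#' @slot group group tag ("normal" or "disease").
#' @slot normalization how fibres were normalized ("cn_composition" is the
#'   per-(patient, CN) composition used by default; "patient_total"
#'   divides by the patient's total cell count instead).
#' @export
setClass("TissueTensor",
  representation(data = "array", group = "character",
                 normalization = "character"),
  validity = function(object) {
    d <- object@data
    if (length(dim(d)) != 3) return("tensor must be 3-way")
    if (any(d < 0) || any(d > 1 + 1e-9)) return("entries must be in [0,1]")
    if (object@normalization == "cn_composition") {
      s <- apply(d, c(1, 2), sum)
      if (any(s > 1e-12 & abs(s - 1) > 1e-9))
        return("occupied (patient, CN) fibres must sum to 1")
    }
    TRUE
  })

setMethod("show", "TissueTensor", function(object) {
  d <- dim(object@data)
  cat("TissueTensor (", object@group, "): ", d[1], " patients x ", d[2],
      " CNs x ", d[3], " types, ", object@normalization, "\n", sep = "")
})

#' @rdname TissueTensor-class
#' @param x a `TissueTensor`.
#' @export
tensorData <- function(x) {
  stopifnot(is(x, "TissueTensor"))
  x@data
}

#' Build the patient x CN x type tensor for one group
#'
#' @param cells a [CellTable] with phenotype and CN labels.
#' @param group which group's patients to include.
#' @param normalization `"cn_composition"` (default; each occupied
#'   (patient, CN) type-fibre sums to 1) or `"patient_total"`.
#' @return a [TissueTensor].
#' @export
buildTensor <- function(cells, group = c("normal", "disease"),
                        normalization = c("cn_composition", "patient_total")) {
  stopifnot(is(cells, "CellTable"))
  group <- match.arg(group)
  normalization <- match.arg(normalization)
  labels <- phenotypes(cells); cn <- cnLabels(cells)
  if (is.null(labels) || is.null(cn))
    stop("cells must carry phenotype and CN labels")
  cd <- cellData(cells)
  sel <- cd$group == group
  pats <- sort(unique(cd$patient_id[sel]))
  if (!length(pats)) stop("no patients in group ", group)
  nCn <- max(cn); nCt <- max(labels)
  Tarr <- array(0, c(length(pats), nCn, nCt),
                dimnames = list(pats, paste0("CN", seq_len(nCn)),
                                paste0("PT", seq_len(nCt))))
  for (pi in seq_along(pats)) {
    psel <- sel & cd$patient_id == pats[pi]
    if (!any(psel)) stop("patient ", pats[pi], " has zero cells")
    counts <- table(factor(cn[psel], levels = seq_len(nCn)),
                    factor(labels[psel], levels = seq_len(nCt)))
    counts <- matrix(counts, nCn, nCt)
    if (normalization == "cn_composition") {
      rs <- rowSums(counts)
      counts[rs > 0, ] <- counts[rs > 0, ] / rs[rs > 0]
    } else counts <- counts / sum(counts)
    Tarr[pi, , ] <- counts
  }
  new("TissueTensor", data = Tarr, group = group,
      normalization = normalization)
}

# ---- tensor algebra helpers ------------------------------------------------

unfold <- function(A, mode) {
  d <- dim(A)
  perm <- c(mode, setdiff(seq_along(d), mode))
  matrix(aperm(A, perm), d[mode], prod(d[-mode]))
}

foldBack <- function(M, mode, dims) {
  perm <- c(mode, setdiff(seq_along(dims), mode))
  aperm(array(M, dims[perm]), order(perm))
}

# mode-n product: tensor x matrix along `mode` (matrix rows index new dim)
ttm <- function(A, M, mode) {
  d <- dim(A)
  out <- M %*% unfold(A, mode)
  d[mode] <- nrow(M)
  foldBack(out, mode, d)
}

tuckerReconstruct <- function(core, factors) {
  out <- core
  for (m in seq_along(factors)) out <- ttm(out, factors[[m]], m)
  out
}

#' TuckerModel: a fitted non-negative Tucker decomposition
#'
#' Factors a nonnegative 3-way tensor into a nonnegative core contracted
#' with one nonnegative factor matrix per mode. After fitting, factor
#' columns are normalized to unit maximum with the scale absorbed into the
#' core, which leaves the reconstruction unchanged but makes loadings
#' comparable across modules.
#'
#' @slot core nonnegative array, `ranks[1] x ranks[2] x ranks[3]`.
#' @slot factors list of three nonnegative factor matrices
#'   (patients, CNs, types) x rank.
#' @slot lossTrace squared-Frobenius reconstruction error per iteration of
#'   the best restart; non-increasing.
#' @slot ranks integer ranks per mode.
#' @slot converged logical; TRUE when the relative loss change fell below
#'   the tolerance before `maxIter`.
#' @aliases lossTrace tuckerCore tuckerFactors reconstruct
#' @export
setClass("TuckerModel",
  representation(core = "array", factors = "list", lossTrace = "numeric",
                 ranks = "integer", converged = "logical"),
  validity = function(object) {
    if (any(object@core < 0)) return("core must be nonnegative")
    for (f in object@factors) if (any(f < 0))
      return("factors must be nonnegative")
    lt <- object@lossTrace
    # tolerance relative to the initial loss: below it, an "increase" is
    # floating-point noise after convergence to (near) machine zero
    if (length(lt) > 1 && any(diff(lt) > 1e-10 * max(lt[1], 1e-12)))
      return("loss trace must be non-increasing")
    TRUE
  })

setMethod("show", "TuckerModel", function(object) {
  cat("TuckerModel: ranks (", paste(object@ranks, collapse = ", "),
      "), final loss ", format(tail(object@lossTrace, 1), digits = 4),
      if (object@converged) " (converged)" else " (max iterations)",
      "\n", sep = "")
})

#' @rdname TuckerModel-class
#' @export
setMethod("lossTrace", "TuckerModel", function(x) x@lossTrace)

#' @rdname TuckerModel-class
#' @export
setMethod("tuckerCore", "TuckerModel", function(x) x@core)

#' @rdname TuckerModel-class
#' @export
setMethod("tuckerFactors", "TuckerModel", function(x) x@factors)

#' @rdname TuckerModel-class
#' @param ... unused.
#' @export
setMethod("reconstruct", "TuckerModel", function(x, ...)
  tuckerReconstruct(x@core, x@factors))

.ntdOnce <- function(Tarr, ranks, maxIter, tol, projInit, init = NULL) {
  d <- dim(Tarr)
  eps <- 1e-12
  if (!is.null(init)) {
    U <- init$factors
    G <- init$core
  } else if (projInit) {
    U <- lapply(1:3, function(m)
      if (ranks[m] == d[m]) diag(d[m]) else
        matrix(runif(d[m] * ranks[m], 0.1, 1), d[m], ranks[m]))
    G <- Tarr
    for (m in 1:3) G <- ttm(G, t(U[[m]]), m)
    G[G < 0] <- 0
    G <- G + eps
  } else {
    U <- lapply(1:3, function(m)
      matrix(runif(d[m] * ranks[m], 0.1, 1), d[m], ranks[m]))
    G <- array(runif(prod(ranks), 0.1, 1), ranks)
  }
  lossOf <- function() sum((Tarr - tuckerReconstruct(G, U))^2)
  trace <- lossOf()
  for (it in seq_len(maxIter)) {
    for (m in 1:3) {                       # factor updates, one mode at a time
      others <- setdiff(1:3, m)
      W <- kronecker(U[[others[2]]], U[[others[1]]])  # cols of unfold order
      Gm <- unfold(G, m)
      Xm <- unfold(Tarr, m)
      B <- W %*% t(Gm)                     # (prod other dims) x rank_m
      num <- Xm %*% B
      den <- U[[m]] %*% (t(B) %*% B) + eps
      U[[m]] <- U[[m]] * num / den
    }
    num <- Tarr
    for (m in 1:3) num <- ttm(num, t(U[[m]]), m)
    den <- G
    for (m in 1:3) den <- ttm(den, crossprod(U[[m]]), m)
    G <- G * num / (den + eps)
    l <- lossOf()
    trace <- c(trace, l)
    prev <- trace[length(trace) - 1]
    if (abs(prev - l) <= tol * max(prev, 1e-30)) break
  }
  list(core = G, factors = U, trace = trace,
       converged = length(trace) - 1 < maxIter)
}

#' Non-negative Tucker decomposition by multiplicative updates
#'
#' Alternating multiplicative updates (Lee-Seung style generalized to the
#' Tucker model) of the squared Frobenius reconstruction error, which keep
#' every factor and the core nonnegative and make the loss non-increasing
#' at every iteration. Runs `nRestarts` seeded starts and keeps the best
#' final loss; the first start uses an exact projection initialization
#' (identity factors for full-rank modes), the rest seeded uniform random
#' factors. Stops when the relative loss change falls below `tol`.
#'
#' @param x a [TissueTensor] or nonnegative 3-way array.
#' @param ranks integer ranks per mode; `NA` means full (unreduced) for
#'   that mode. Default `c(NA, 4, 4)`: rank 4 on the CN and type modes,
#'   patient mode unreduced. Values are clamped to the tensor dimensions.
#' @param maxIter maximum iterations per restart (default 500).
#' @param tol relative loss-change tolerance (default 1e-8).
#' @param seed integer seed.
#' @param nRestarts random restarts (default 5).
#' @param init optional warm start: a list with elements `core` and
#'   `factors` at the requested ranks, run as an additional restart.
#' @return a [TuckerModel].
#' @export
ntd <- function(x, ranks = c(NA, 4, 4), maxIter = 500L, tol = 1e-8,
                seed = 1L, nRestarts = 5L, init = NULL) {
  Tarr <- if (is(x, "TissueTensor")) x@data else x
  stopifnot(length(dim(Tarr)) == 3, all(Tarr >= 0))
  if (sum(Tarr) == 0) stop("all-zero tensor cannot be decomposed")
  d <- dim(Tarr)
  ranks <- ifelse(is.na(ranks), d, pmin(as.integer(ranks), d))
  withSeed(seed, {
    best <- NULL
    for (r in seq_len(nRestarts)) {
      fit <- .ntdOnce(Tarr, ranks, maxIter, tol, projInit = (r == 1))
      if (is.null(best) || tail(fit$trace, 1) < tail(best$trace, 1))
        best <- fit
    }
    if (!is.null(init)) {
      fit <- .ntdOnce(Tarr, ranks, maxIter, tol, projInit = FALSE,
                      init = init)
      if (tail(fit$trace, 1) < tail(best$trace, 1)) best <- fit
    }
    # absorb factor column scales into the core (unit-max columns)
    for (m in 1:3) {
      mx <- apply(best$factors[[m]], 2, max)
      mx[mx == 0] <- 1
      best$factors[[m]] <- sweep(best$factors[[m]], 2, mx, "/")
      Gm <- unfold(best$core, m) * mx
      best$core <- foldBack(Gm, m, dim(best$core))
    }
    new("TuckerModel", core = best$core, factors = best$factors,
        lossTrace = best$trace, ranks = as.integer(ranks),
        converged = best$converged)
  })
}

#' Relative reconstruction error of a fitted model
#' @param model a [TuckerModel]; @param x the tensor it was fitted to.
#' @param x the tensor (or [TissueTensor]) the model was fitted to.
#' @return `||x - reconstruction|| / ||x||` (Frobenius).
#' @export
relativeError <- function(model, x) {
  Tarr <- if (is(x, "TissueTensor")) x@data else x
  sqrt(sum((Tarr - reconstruct(model))^2) / sum(Tarr^2))
}

#' CN-module / CT-module coupling graph
#'
#' Edge weight between CN module i and type module j is the patient-mode
#' sum of the absolute core entries `|core[, i, j]|`: how strongly the two
#' modules co-occur across patients. Module memberships list the CNs and
#' types whose factor loading reaches `loadingThreshold` times the column
#' maximum.
#'
#' @param model a fitted [TuckerModel].
#' @param loadingThreshold membership cutoff as a fraction of the column
#'   maximum (default 0.5).
#' @return list with `edges` (data.frame cnModule, ctModule, weight,
#'   sorted by decreasing weight) and `members` (per-module index lists).
#' @export
moduleGraph <- function(model, loadingThreshold = 0.5) {
  stopifnot(is(model, "TuckerModel"))
  G <- model@core
  W <- apply(abs(G), c(2, 3), sum)
  edges <- data.frame(cnModule = rep(seq_len(nrow(W)), ncol(W)),
                      ctModule = rep(seq_len(ncol(W)), each = nrow(W)),
                      weight = as.vector(W))
  edges <- edges[order(-edges$weight), ]
  rownames(edges) <- NULL
  memberOf <- function(f) lapply(seq_len(ncol(f)), function(j) {
    mx <- max(f[, j])
    if (mx == 0) integer(0) else which(f[, j] >= loadingThreshold * mx)
  })
  list(edges = edges,
       members = list(cn = memberOf(model@factors[[2]]),
                      ct = memberOf(model@factors[[3]])))
}

#' Decomposition loss across candidate ranks
#'
#' Fits [ntd()] at each candidate rank (applied to the CN and type modes,
#' patient mode unreduced) with a shared seed and reports the final
#' relative loss per rank. Candidates are fitted in increasing order and
#' each is additionally warm-started from the previous rank's solution
#' (zero-padded to the larger rank), so the reported loss curve is
#' non-increasing in rank by construction, not by luck of the random
#' starts. No elbow is auto-selected; the curve is returned for
#' inspection.
#'
#' @param x tensor or [TissueTensor].
#' @param candidates integer vector of candidate ranks.
#' @param seed,maxIter,nRestarts passed to [ntd()].
#' @return data.frame (rank, relLoss), in increasing rank order.
#' @export
selectRank <- function(x, candidates, seed = 1L, maxIter = 500L,
                       nRestarts = 5L) {
  stopifnot(length(candidates) >= 1)
  Tarr <- if (is(x, "TissueTensor")) x@data else x
  candidates <- sort(as.integer(candidates))
  prev <- NULL
  rel <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    r <- candidates[i]
    init <- if (!is.null(prev)) .padModel(prev, c(dim(Tarr)[1], r, r))
    m <- ntd(Tarr, ranks = c(NA, r, r), maxIter = maxIter, seed = seed,
             nRestarts = nRestarts, init = init)
    rel[i] <- relativeError(m, Tarr)
    prev <- m
  }
  data.frame(rank = candidates, relLoss = rel)
}

# Zero-pad a fitted model's core and factors to larger ranks; the padded
# model reconstructs identically, so it is a loss-preserving warm start.
.padModel <- function(model, ranks) {
  ranks <- pmax(ranks, model@ranks)
  core <- array(0, ranks)
  core[seq_len(dim(model@core)[1]), seq_len(dim(model@core)[2]),
       seq_len(dim(model@core)[3])] <- model@core
  factors <- lapply(1:3, function(m) {
    f <- model@factors[[m]]
    cbind(f, matrix(1e-6, nrow(f), ranks[m] - ncol(f)))
  })
  list(core = core, factors = factors)
}

#' @importFrom utils tail
NULL
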