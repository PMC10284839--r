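# Shared fixture builders. Everything is generated in code; no stored data.

# A minimal cohort spec: few ROIs, few types, no interactions.
smallSpec <- function(nRois = 2L, cellsPerRoi = 150L, nTypes = 4L,
                      nPatients = 2L, seed = 1L, ...) {
  tissueSpec(nRois = nRois, cellsPerRoi = cellsPerRoi, nTypes = nTypes,
             nPatients = nPatients, seed = seed, ...)
}

# Single uniform niche over all types (no spatial clustering structure).
uniformNiche <- function(typeNames, clusterSd = 60) {
  p <- rep(1 / length(typeNames), length(typeNames))
  names(p) <- typeNames
  list(list(props = p, weight = 1, clusterSd = clusterSd,
            offspringPerParent = 50))
}

# One ROI of uniformly scattered cells with uniformly random labels: the
# complete-spatial-randomness labeling null for the permutation test.
csrRoi <- function(n, nTypes, size = 200, seed = 1L) {
  withr::with_seed(seed, list(
    xy = cbind(runif(n, 0, size), runif(n, 0, size)),
    labels = sample.int(nTypes, n, replace = TRUE)))
}

# Brute-force mean count of type B among the w nearest neighbours of type
# A cells, by full distance matrix: the oracle for planted attraction.
bruteNeighborCount <- function(xy, labels, a, b, w = 20L) {
  ia <- which(labels == a)
  if (!length(ia)) return(NA_real_)
  D <- as.matrix(dist(xy))
  diag(D) <- Inf
  mean(vapply(ia, function(i) {
    nb <- order(D[i, ])[seq_len(min(w, nrow(xy) - 1))]
    sum(labels[nb] == b)
  }, numeric(1)))
}

# Flood-fill (8-connected) component count: independent oracle for the
# connected-components step.
floodCount <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  count <- 0L
  for (s in which(mask)) {
    if (seen[s]) next
    count <- count + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1L) %% H + 1L; cc <- (cur - 1L) %/% H + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr >= 1 && rr <= H && c2 >= 1 && c2 <= W) {
          j <- (c2 - 1L) * H + rr
          if (mask[j] && !seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
        }
      }
    }
  }
  count
}

# Brute-force zero-padded median filter (9-value sort), the oracle for the
# vectorized implementation.
bruteMedian3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (cc in seq_len(W))
    out[r, cc] <- sort(pad[r:(r + 2), cc:(cc + 2)])[5]
  out
}
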