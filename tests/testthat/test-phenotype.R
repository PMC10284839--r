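mkCells <- function(exprs, patient = "P01", group = "normal",
                    roi = "ROI001") {
  n <- nrow(exprs)
  cellTable(
    data.frame(cell_id = seq_len(n), roi_id = rep_len(roi, n),
               patient_id = rep_len(patient, n),
               group = rep_len(group, n),
               x = runif(n, 0, 100), y = runif(n, 0, 100), area = 10),
    exprs)
}

test_that("range normalization matches an independent percentile oracle", {
  set.seed(1)
  v <- sample(1:1000)                      # values 1..1000, shuffled
  ex <- cbind(M1 = v, M2 = rep(0, 1000))
  ct <- rangeNormalize(mkCells(ex), 99)
  q <- quantile(1:1000, 0.99, names = FALSE)   # independent: type-7 interp
  expect_equal(q, 990.01)
  got <- intensities(ct)[, "M1"]
  expect_equal(got[v == 990], 990 / 990.01, tolerance = 1e-12)
  expect_equal(got[v == 1000], 1)              # clipped
  expect_true(all(got >= 0 & got <= 1))
  expect_true(all(intensities(ct)[, "M2"] == 0))  # zero channel untouched

  # invariant to positive channel rescaling
  ct2 <- rangeNormalize(mkCells(ex * 37), 99)
  expect_equal(intensities(ct2), intensities(ct))

  # a single cell maps to 1 in every nonzero channel
  one <- rangeNormalize(mkCells(cbind(M1 = 5, M2 = 0)), 99)
  expect_equal(unname(intensities(one)[1, ]), c(1, 0))

  expect_error(rangeNormalize(mkCells(ex), 0), "percentile")
})

test_that("batch alignment equalizes per-patient medians", {
  set.seed(2)
  base <- rlnorm(400, 0, 0.4)
  ex <- cbind(M1 = c(base, base * 2))      # patient B doubled
  cd <- data.frame(cell_id = 1:800,
                   roi_id = rep(c("R1", "R2"), each = 400),
                   patient_id = rep(c("PA", "PB"), each = 400),
                   group = "normal", x = runif(800), y = runif(800),
                   area = 10)
  ct <- alignBatches(cellTable(cd, ex))
  v <- intensities(ct)[, 1]
  expect_lt(abs(median(v[1:400]) - median(v[401:800])), 1e-6)

  # identical distributions across patients: unchanged
  ex2 <- cbind(M1 = c(base, base))
  ct2 <- alignBatches(cellTable(cd, ex2))
  expect_equal(intensities(ct2)[, 1], ex2[, 1], tolerance = 1e-9)

  # single patient: identity
  ct3 <- alignBatches(mkCells(cbind(M1 = base)))
  expect_equal(intensities(ct3)[, 1], base)
})

test_that("graph clustering separates well-separated blobs perfectly", {
  set.seed(3)
  n <- 500
  ex <- rbind(cbind(rnorm(n, 0, 1), rnorm(n, 0, 1)),
              cbind(rnorm(n, 10, 1), rnorm(n, 10, 1)))
  colnames(ex) <- c("M1", "M2")
  ex <- ex - min(ex)                       # keep intensities nonnegative
  ct <- mkCells(ex)
  res <- clusterPhenotypes(ct, kNeighbors = 15L, seed = 1L,
                           resolution = 0.05)
  labels <- phenotypes(res$cells)
  expect_equal(max(labels), 2L)
  expect_equal(length(unique(labels[1:n])), 1L)
  expect_equal(length(unique(labels[(n + 1):(2 * n)])), 1L)

  # deterministic given the seed
  res2 <- clusterPhenotypes(ct, kNeighbors = 15L, seed = 1L,
                            resolution = 0.05)
  expect_identical(phenotypes(res2$cells), labels)

  # permuting cell order changes labels only up to relabeling
  perm <- sample(nrow(ex))
  res3 <- clusterPhenotypes(ct[perm], kNeighbors = 15L, seed = 1L,
                            resolution = 0.05)
  ariPkg <- imcTopo:::adjustedRand(labels[perm], phenotypes(res3$cells))
  expect_equal(ariPkg, 1)
  # the package ARI agrees with the established implementation
  expect_equal(ariPkg,
               mclust::adjustedRandIndex(labels[perm],
                                         phenotypes(res3$cells)))
})

test_that("identical cells collapse to one cluster with a sane model", {
  ex <- matrix(1, 50, 2, dimnames = list(NULL, c("M1", "M2")))
  res <- clusterPhenotypes(mkCells(ex), kNeighbors = 10L, seed = 1L)
  expect_equal(max(phenotypes(res$cells)), 1L)
  m <- res$model
  expect_true(all(clusterProfile(m, display = TRUE) >= 0 &
                  clusterProfile(m, display = TRUE) <= 1))
  expect_equal(unname(rowSums(m@patientFreq)), 1)
})

test_that("density comparison reproduces the exact rank-sum p-value", {
  # n = 3 vs 3, complete separation: two-sided exact p = 2/choose(6,3) = 0.1
  mk <- function(dens, group, pat) {
    rows <- lapply(seq_along(dens), function(i) {
      n <- dens[i]
      data.frame(cell_id = seq_len(n),
                 roi_id = sprintf("%s_R%d", group, i),
                 patient_id = pat, group = group,
                 x = runif(n, 0, 50), y = runif(n, 0, 50), area = 10)
    })
    do.call(rbind, rows)
  }
  set.seed(4)
  cd <- rbind(mk(c(1, 2, 3), "normal", "PA"),
              mk(c(10, 11, 12), "disease", "PB"))
  ct <- cellTable(cd, matrix(1, nrow(cd), 1, dimnames = list(NULL, "M1")))
  phenotypes(ct) <- rep(1L, nrow(cd))
  res <- compareDensity(ct, roiSize = c(50, 50))
  expect_equal(res$p, 0.1)

  # identical densities in both groups: degenerate all-tied case, p = 1
  cd2 <- rbind(mk(c(5, 5, 5), "normal", "PA"), mk(c(5, 5, 5), "disease", "PB"))
  ct2 <- cellTable(cd2, matrix(1, nrow(cd2), 1, dimnames = list(NULL, "M1")))
  phenotypes(ct2) <- rep(1L, nrow(cd2))
  expect_equal(compareDensity(ct2, roiSize = c(50, 50))$p, 1)
})

test_that("a planted density drop is detected across ROIs", {
  tn <- c("resident", "other")
  props <- function(r) setNames(c(r, 1 - r), tn)
  nd <- list(list(props = list(normal = props(0.5), disease = props(0.15)),
                  weight = 1, clusterSd = 50, offspringPerParent = 40))
  spec <- tissueSpec(nRois = 30L, cellsPerRoi = 200L, nTypes = 2L,
                     typeNames = tn, nicheDefs = nd, nPatients = 10L,
                     archetypes = defaultArchetypes(tn),
                     roiSize = c(128, 128), seed = 9L)
  sim <- generateCohort(spec)
  ct <- sim$cells
  phenotypes(ct) <- truth(sim$truth, "type")
  res <- compareDensity(ct, roiSize = c(128, 128))
  expect_lt(res$p[res$phenotype == 1], 0.05)
})
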