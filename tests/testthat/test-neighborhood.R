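mkRoi <- function(x, y, types, roi = "R1", patient = "P01",
                  group = "normal") {
  n <- length(x)
  ct <- cellTable(
    data.frame(cell_id = seq_len(n), roi_id = roi, patient_id = patient,
               group = group, x = x, y = y, area = 10),
    matrix(1, n, 1, dimnames = list(NULL, "M1")))
  phenotypes(ct) <- types
  ct
}

test_that("window composition matches hand-enumerated small cases", {
  # 3 cells, types (A, A, B), w = 2: every window is all three cells
  ct <- mkRoi(c(0, 1, 2), c(0, 0, 0), c(1L, 1L, 2L))
  comp <- neighborhoodWindows(ct, w = 2L)
  expect_equal(unname(comp), matrix(rep(c(2 / 3, 1 / 3), each = 3), 3, 2))

  # single-type ROI: every row is one-hot
  ct2 <- mkRoi(runif(10), runif(10), rep(1L, 10))
  comp2 <- neighborhoodWindows(ct2, w = 3L)
  expect_true(all(comp2[, 1] == 1))

  # every row sums to 1 on an arbitrary cohort
  set.seed(5)
  ct3 <- mkRoi(runif(60, 0, 50), runif(60, 0, 50),
               sample(1:3, 60, TRUE))
  expect_equal(unname(rowSums(neighborhoodWindows(ct3, w = 20L))),
               rep(1, 60))
})

test_that("window composition is invariant under rigid motions", {
  set.seed(6)
  n <- 80
  x <- runif(n, 0, 100); y <- runif(n, 0, 100)
  ty <- sample(1:3, n, TRUE)
  comp <- neighborhoodWindows(mkRoi(x, y, ty), w = 10L)
  th <- 0.7
  xr <- cos(th) * x - sin(th) * y + 20
  yr <- sin(th) * x + cos(th) * y - 5
  compR <- neighborhoodWindows(mkRoi(xr, yr, ty), w = 10L)
  expect_equal(comp, compR)
})

test_that("K-means on one-hot compositions attains the exact partition", {
  set.seed(7)
  oneHot <- diag(5)[sample(1:5, 200, TRUE), ]
  cl <- clusterNeighborhoods(oneHot, k = 5L, seed = 1L)
  expect_equal(cl$inertia, 0)
  expect_equal(length(unique(cl$labels)), 5L)

  # k = 1 puts every cell in one CN
  cl1 <- clusterNeighborhoods(oneHot, k = 1L, seed = 1L)
  expect_true(all(cl1$labels == 1L))
  expect_error(clusterNeighborhoods(oneHot, k = 0L), "k")
  # empty clusters are reported, not dropped
  same <- matrix(rep(c(1, 0), each = 50), 50, 2)
  clE <- suppressMessages(clusterNeighborhoods(same, k = 4L, seed = 1L))
  expect_length(clE$sizes, 4L)
  expect_true(any(clE$sizes == 0))
})

test_that("planted niches are recovered by CN clustering", {
  spec <- tissueSpec(nRois = 6L, cellsPerRoi = 400L, nTypes = 10L,
                     nicheDefs = defaultNiches(sprintf("CT%02d", 1:10),
                                               nNiches = 5,
                                               dominance = 0.9,
                                               clusterSd = 10,
                                               offspringPerParent = 80),
                     nPatients = 6L, seed = 31L)
  sim <- generateCohort(spec)
  ct <- sim$cells
  phenotypes(ct) <- truth(sim$truth, "type")
  fit <- fitNeighborhoods(ct, w = 20L, k = 5L, seed = 1L)
  ari <- imcTopo:::adjustedRand(cnLabels(fit$cells),
                                truth(sim$truth, "niche"))
  expect_gte(ari, 0.8)

  # stability across seeds on well-separated niches
  fit2 <- fitNeighborhoods(ct, w = 20L, k = 5L, seed = 99L)
  expect_gte(imcTopo:::adjustedRand(cnLabels(fit$cells),
                                    cnLabels(fit2$cells)), 0.9)

  # per-patient CN frequencies are conserved
  expect_equal(unname(rowSums(fit$model@patientFreq)),
               rep(1, nrow(fit$model@patientFreq)))
})

test_that("CN abundance comparison handles degenerate and planted cases", {
  # identical frequency vectors: p = 1
  set.seed(8)
  cd <- do.call(rbind, lapply(1:4, function(i)
    data.frame(cell_id = 1:40, roi_id = paste0("R", i),
               patient_id = paste0("P", i),
               group = ifelse(i <= 2, "normal", "disease"),
               x = runif(40, 0, 50), y = runif(40, 0, 50), area = 10)))
  ct <- cellTable(cd, matrix(1, 160, 1, dimnames = list(NULL, "M1")))
  cnLabels(ct) <- rep(rep(1:2, each = 20), 4)
  res <- cnGroupAbundance(ct)
  expect_equal(res$p, c(1, 1))
})

test_that("voronoi polygons tile the ROI and respect generators", {
  # 4 cells at the corners of the unit square inside a 2x2 ROI
  ct <- mkRoi(c(0.5, 1.5, 0.5, 1.5), c(0.5, 0.5, 1.5, 1.5),
              rep(1L, 4))
  cnLabels(ct) <- c(1L, 1L, 2L, 2L)
  vm <- voronoiMap(ct, "R1", c(2, 2))
  expect_length(vm$polygons, 4L)
  expect_equal(vm$area, rep(1, 4))         # four congruent quadrants
  expect_equal(sum(vm$area), 4, tolerance = 1e-6)
  expect_equal(vm$cn, c(1L, 1L, 2L, 2L))

  # random ROI: tiling property and nearest-generator spot checks
  set.seed(9)
  n <- 40
  ct2 <- mkRoi(runif(n, 0, 80), runif(n, 0, 60), sample(1:3, n, TRUE))
  cnLabels(ct2) <- sample(1:3, n, TRUE)
  vm2 <- voronoiMap(ct2, "R1", c(80, 60))
  expect_equal(sum(vm2$area), 80 * 60, tolerance = 1e-6)
  for (i in c(1, 7, 20)) {
    poly <- vm2$polygons[[i]]
    cx <- mean(poly[, 1]); cy <- mean(poly[, 2])
    d <- sqrt((vm2$points[, 1] - cx)^2 + (vm2$points[, 2] - cy)^2)
    expect_equal(unname(which.min(d)), i)
  }

  # collinear cells are rejected with the ROI named
  ct3 <- mkRoi(c(1, 2, 3), c(1, 2, 3), rep(1L, 3))
  cnLabels(ct3) <- rep(1L, 3)
  expect_error(voronoiMap(ct3, "R1", c(5, 5)), "collinear")
})
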