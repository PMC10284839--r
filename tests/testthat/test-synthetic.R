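test_that("a fixed seed reproduces the cohort byte for byte", {
  spec <- smallSpec(seed = 7L)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  expect_identical(digest::digest(cellData(a$cells)),
                   digest::digest(cellData(b$cells)))
  expect_identical(a$cells@exprs, b$cells@exprs)
  expect_identical(truth(a$truth, "exprs"), truth(b$truth, "exprs"))
})

test_that("uniform mixing yields multinomial type frequencies", {
  tn <- sprintf("CT%02d", 1:4)
  spec <- tissueSpec(nRois = 5L, cellsPerRoi = 2000L, nTypes = 4L,
                     roiSize = c(512, 512), nicheDefs = uniformNiche(tn),
                     nPatients = 2L, seed = 11L)
  sim <- generateCohort(spec)
  n <- nCells(sim$cells)
  expect_gte(n, 10000)
  freq <- tabulate(truth(sim$truth, "type"), 4) / n
  sigma <- sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(freq - 0.25) < 3 * sigma))
})

test_that("planted attraction raises and avoidance lowers A->B neighbour counts", {
  base <- function(mode, strength, seed = 5L) {
    spec <- smallSpec(nRois = 2L, cellsPerRoi = 400L, nTypes = 4L,
      seed = seed,
      interactionPairs = data.frame(typeA = "CT01", typeB = "CT02",
                                    mode = mode, strength = strength))
    sim <- generateCohort(spec)
    cd <- cellData(sim$cells)
    sel <- cd$roi_id == cd$roi_id[1]
    bruteNeighborCount(cbind(cd$x[sel], cd$y[sel]),
                       truth(sim$truth, "type")[sel], 1, 2)
  }
  expect_gt(base("attract", 0.9), base("avoid", 0.9))
  # monotone in attraction strength (brute-force neighbour oracle)
  counts <- vapply(c(0.1, 0.5, 0.9), function(s) base("attract", s),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("group-specific niche proportions plant group differences", {
  tn <- c("resident", "infiltrating", "other")
  props <- function(r, i) {
    p <- c(r, i, 1 - r - i); names(p) <- tn; p
  }
  nd <- list(list(props = list(normal = props(0.5, 0.05),
                               disease = props(0.05, 0.5)),
                  weight = 1, clusterSd = 40, offspringPerParent = 40))
  spec <- tissueSpec(nRois = 4L, cellsPerRoi = 300L, nTypes = 3L,
                     typeNames = tn, nicheDefs = nd, nPatients = 4L,
                     archetypes = defaultArchetypes(tn), seed = 3L)
  sim <- generateCohort(spec)
  cd <- cellData(sim$cells)
  ty <- truth(sim$truth, "type")
  fr <- function(g, t) mean(ty[cd$group == g] == t)
  expect_gt(fr("normal", 1), fr("disease", 1))
  expect_lt(fr("normal", 2), fr("disease", 2))
})

test_that("infeasible and degenerate specs are rejected", {
  expect_error(tissueSpec(roiSize = c(20, 20), cellsPerRoi = 500L),
               "infeasible density")
  tn <- sprintf("CT%02d", 1:3)
  zero <- setNames(rep(0, 3), tn)
  expect_error(
    tissueSpec(nTypes = 3L, typeNames = tn,
               nicheDefs = list(list(props = zero, weight = 1,
                                     clusterSd = 10)),
               archetypes = defaultArchetypes(tn)),
    "degenerate")
  expect_error(
    smallSpec(interactionPairs = data.frame(typeA = "CT01", typeB = "CT02",
                                            mode = "attract",
                                            strength = 1.5)),
    "strength")
})

test_that("compensating generated expression with the true spillover recovers truth", {
  spec <- smallSpec(seed = 2L)
  sim <- generateCohort(spec)
  rec <- compensate(intensities(sim$cells), spec@spillover)
  expect_lt(max(abs(rec - truth(sim$truth, "exprs"))), 1e-8)
})

test_that("rasterized nuclei are confined to disks at the centroids", {
  tn <- c("A", "B")
  arch <- defaultArchetypes(tn)
  spec <- tissueSpec(nRois = 1L, roiSize = c(40, 40), cellsPerRoi = 1L,
                     nTypes = 2L, typeNames = tn, archetypes = arch,
                     nicheDefs = uniformNiche(tn), nPatients = 1L,
                     backgroundRate = 0, seed = 1L)
  cells <- cellTable(
    data.frame(cell_id = 1L, roi_id = "ROI001", patient_id = "P01",
               group = "normal", x = 10, y = 10, area = 13),
    matrix(c(1, 1, 4), 1, dimnames = list(NULL, c("M01", "M02", "DNA"))))
  st <- rasterize(cells, spec)[[1]]
  dna <- getChannel(st, "DNA")
  nz <- which(dna > 0, arr.ind = TRUE)
  d <- sqrt((nz[, 2] - 1 - 10)^2 + (nz[, 1] - 1 - 10)^2)
  expect_true(all(d <= 2))
  expect_equal(sum(dna > 0), 13)   # disk of radius 2
})

test_that("an ROI with no cells rasterizes to all-zero channels", {
  tn <- c("A", "B")
  spec <- tissueSpec(nRois = 1L, roiSize = c(30, 30), cellsPerRoi = 60L,
                     nTypes = 2L, typeNames = tn,
                     archetypes = defaultArchetypes(tn),
                     nicheDefs = uniformNiche(tn), nPatients = 1L,
                     backgroundRate = 0, seed = 1L)
  empty <- cellTable(
    data.frame(cell_id = integer(), roi_id = character(),
               patient_id = character(), group = character(),
               x = numeric(), y = numeric(), area = numeric()),
    matrix(numeric(), 0, 3,
           dimnames = list(NULL, c("M01", "M02", "DNA"))))
  st <- rasterize(empty, spec, rois = "ROIX")[[1]]
  expect_true(all(pixelArray(st) == 0))
})

test_that("two distant cells give two components in the thresholded nuclei channel", {
  tn <- c("A", "B")
  spec <- tissueSpec(nRois = 1L, roiSize = c(60, 60), cellsPerRoi = 60L,
                     nTypes = 2L, typeNames = tn,
                     archetypes = defaultArchetypes(tn),
                     nicheDefs = uniformNiche(tn), nPatients = 1L,
                     backgroundRate = 0, seed = 1L)
  cells <- cellTable(
    data.frame(cell_id = 1:2, roi_id = "ROI001", patient_id = "P01",
               group = "normal", x = c(10, 40), y = c(10, 10), area = 13),
    matrix(c(1, 1, 1, 1, 4, 4), 2,
           dimnames = list(NULL, c("M01", "M02", "DNA"))))
  st <- rasterize(cells, spec)[[1]]
  expect_equal(floodCount(getChannel(st, "DNA") > 0.5), 2L)
})
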