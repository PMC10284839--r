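test_that("spatial kNN graph follows distances with deterministic ties", {
  # two cells are each other's neighbour
  g <- buildSpatialGraph(cbind(c(0, 1), c(0, 0)), kSpatial = 1L)
  expect_equal(as.vector(g), c(2L, 1L))

  # collinear cells at x = 0, 1, 10 with k = 1
  g3 <- buildSpatialGraph(cbind(c(0, 1, 10), c(0, 0, 0)), kSpatial = 1L)
  expect_equal(as.vector(g3), c(2L, 1L, 2L))

  # out-degree is min(k, n - 1) for every cell
  set.seed(1)
  xy <- cbind(runif(30), runif(30))
  expect_equal(ncol(buildSpatialGraph(xy, kSpatial = 50L)), 29L)
  expect_equal(ncol(buildSpatialGraph(xy, kSpatial = 5L)), 5L)
})

test_that("a single cell type yields the degenerate statistic k", {
  set.seed(2)
  xy <- cbind(runif(40, 0, 50), runif(40, 0, 50))
  g <- buildSpatialGraph(xy, kSpatial = 8L)
  res <- interactionTest(rep(1L, 40), g, nTypes = 1L, nPerm = 50L,
                         seed = 1L)
  expect_equal(res$obs, 8)
  expect_equal(res$p_int, 1)               # all permutations identical
  expect_equal(res$p_avoid, 1)
})

test_that("complete spatial segregation attains the minimal avoidance p-value", {
  set.seed(3)
  n <- 60
  xy <- rbind(cbind(runif(n, 0, 20), runif(n, 0, 20)),
              cbind(runif(n, 500, 520), runif(n, 0, 20)))
  labels <- rep(1:2, each = n)
  g <- buildSpatialGraph(xy, kSpatial = 5L)
  res <- interactionTest(labels, g, nTypes = 2L, nPerm = 100L, seed = 4L)
  pav <- res$p_avoid[res$center == 1 & res$neighbor == 2]
  expect_equal(pav, 1 / 101)
  # and the observed cross-count is zero
  expect_equal(res$obs[res$center == 1 & res$neighbor == 2], 0)
})

test_that("relabeling A and B swaps the ordered-pair results exactly", {
  set.seed(5)
  n <- 80
  xy <- cbind(runif(n, 0, 60), runif(n, 0, 60))
  labels <- sample(1:2, n, replace = TRUE)
  g <- buildSpatialGraph(xy, kSpatial = 6L)
  a <- interactionTest(labels, g, nTypes = 2L, nPerm = 60L, seed = 7L)
  b <- interactionTest(3L - labels, g, nTypes = 2L, nPerm = 60L, seed = 7L)
  pick <- function(r, i, j)
    unlist(r[r$center == i & r$neighbor == j,
             c("obs", "p_int", "p_avoid")], use.names = FALSE)
  expect_equal(pick(a, 1, 2), pick(b, 2, 1))
  expect_equal(pick(a, 2, 2), pick(b, 1, 1))
})

test_that("p-values are reproducible, bounded away from zero, and valid", {
  roi <- csrRoi(100, 3, seed = 11L)
  g <- buildSpatialGraph(roi$xy, kSpatial = 10L)
  a <- interactionTest(roi$labels, g, nTypes = 3L, nPerm = 99L, seed = 2L)
  b <- interactionTest(roi$labels, g, nTypes = 3L, nPerm = 99L, seed = 2L)
  expect_identical(a, b)
  expect_true(all(a$p_int >= 1 / 100))
  expect_true(all(a$p_avoid >= 1 / 100))
  # one-sided p-values overlap: counts of >= and <= exceed n_perm together
  expect_true(all(a$p_int + a$p_avoid >= 1 + 1 / 100))
})

test_that("cohort summary reports fractions, correlations and classes", {
  tn <- c("A", "B", "C")
  # rare centre type with a common attracted neighbour: the satellite
  # configuration the attraction mechanism plants
  nd <- list(list(props = setNames(c(0.2, 0.5, 0.3), tn), weight = 1,
                  clusterSd = 60, offspringPerParent = 50))
  spec <- tissueSpec(nRois = 6L, cellsPerRoi = 250L, nTypes = 3L,
                     typeNames = tn, archetypes = defaultArchetypes(tn),
                     nicheDefs = nd,
                     interactionPairs = data.frame(
                       typeA = "A", typeB = "B", mode = "attract",
                       strength = 0.8),
                     nPatients = 6L, roiSize = c(200, 200), seed = 13L)
  sim <- generateCohort(spec)
  ct <- sim$cells
  phenotypes(ct) <- truth(sim$truth, "type")
  res <- testInteractions(ct, kSpatial = 10L, nPerm = 200L, seed = 1L)
  summ <- summarizeCohort(res, ct, alpha = 0.01)
  expect_true(all(summ$sigInt >= 0 & summ$sigInt <= 1))
  ab <- summ[summ$center == 1 & summ$neighbor == 2, ]
  # planted attraction: majority of ROIs significant in both groups
  expect_true(all(ab$sigInt > 0.5))
  expect_true(all(ab$class == "interaction"))
  expect_true(all(abs(summ$r) <= 1 + 1e-12))
})
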