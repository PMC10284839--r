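mkLabeled <- function(cd, exprs, ph, cn) {
  ct <- cellTable(cd, exprs)
  phenotypes(ct) <- ph
  cnLabels(ct) <- cn
  ct
}

test_that("the frequency tensor counts and normalizes per (patient, CN)", {
  cd <- data.frame(cell_id = 1:8, roi_id = "R1", patient_id = "P01",
                   group = "normal", x = runif(8), y = runif(8), area = 10)
  ex <- matrix(1, 8, 1, dimnames = list(NULL, "M1"))
  # CN1: 3 of type A, 1 of type B; CN3 absent entirely
  ct <- mkLabeled(cd, ex, ph = c(1L, 1L, 1L, 2L, 1L, 2L, 2L, 2L),
                  cn = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L))
  tt <- buildTensor(ct, "normal")
  d <- tensorData(tt)
  expect_equal(unname(d[1, 1, ]), c(0.75, 0.25))
  # every occupied slice sums to 1
  s <- apply(d, c(1, 2), sum)
  expect_true(all(s[s > 0] - 1 < 1e-9))
  expect_error(buildTensor(ct, "disease"), "no patients")
})

test_that("a patient missing a CN contributes an all-zero slice", {
  cd <- data.frame(cell_id = rep(1:4, 2),
                   roi_id = rep(c("R1", "R2"), each = 4),
                   patient_id = rep(c("P01", "P02"), each = 4),
                   group = "normal", x = runif(8), y = runif(8), area = 10)
  ex <- matrix(1, 8, 1, dimnames = list(NULL, "M1"))
  ct <- mkLabeled(cd, ex, ph = rep(1:2, 4),
                  cn = c(1L, 1L, 2L, 2L, 1L, 1L, 1L, 1L))
  d <- tensorData(buildTensor(ct, "normal"))
  expect_true(all(d["P02", 2, ] == 0))
})

test_that("full-rank decomposition reproduces the tensor", {
  set.seed(1)
  Tarr <- array(runif(5 * 4 * 3), c(5, 4, 3))
  fit <- ntd(Tarr, ranks = dim(Tarr), maxIter = 50L, seed = 1L)
  expect_lte(relativeError(fit, Tarr), 1e-6)
})

test_that("a planted rank-1 tensor is recovered", {
  set.seed(2)
  Tarr <- outer(runif(6, 0.2, 1), outer(runif(5, 0.2, 1), runif(4, 0.2, 1)))
  fit <- ntd(Tarr, ranks = c(1, 1, 1), maxIter = 2000L, seed = 3L)
  expect_lte(relativeError(fit, Tarr), 1e-4)
  # core and factors stay nonnegative, factor columns have unit max
  expect_true(all(tuckerCore(fit) >= 0))
  for (f in tuckerFactors(fit)) {
    expect_true(all(f >= 0))
    expect_equal(unname(apply(f, 2, max)), rep(1, ncol(f)))
  }
  # renormalization preserved the reconstruction: final loss matches
  expect_equal(sum((Tarr - reconstruct(fit))^2),
               tail(lossTrace(fit), 1), tolerance = 1e-10)
})

test_that("the loss trace never increases and degenerate input errors", {
  set.seed(3)
  Tarr <- array(runif(6 * 5 * 4), c(6, 5, 4))
  fit <- ntd(Tarr, ranks = c(3, 2, 2), maxIter = 200L, seed = 1L)
  lt <- lossTrace(fit)
  expect_true(all(diff(lt) <= 1e-10 * max(lt[1], 1e-12)))
  expect_error(ntd(array(0, c(2, 2, 2))), "all-zero")
})

test_that("the module graph reads coupling weights off the core", {
  core <- array(0, c(2, 3, 4))
  core[1, 2, 3] <- 5
  model <- new("TuckerModel", core = core,
               factors = list(diag(2), matrix(1, 3, 3), matrix(1, 4, 4)),
               lossTrace = c(1, 0.5), ranks = c(2L, 3L, 4L),
               converged = TRUE)
  mg <- moduleGraph(model)
  nz <- mg$edges[mg$edges$weight > 0, ]
  expect_equal(nrow(nz), 1L)
  expect_equal(nz$cnModule, 2L)
  expect_equal(nz$ctModule, 3L)
  # doubling the core doubles every weight
  model2 <- model; model2@core <- core * 2
  expect_equal(moduleGraph(model2)$edges$weight, mg$edges$weight * 2)
})

test_that("two disjoint planted blocks map to the two dominant module edges", {
  set.seed(4)
  P <- 6; NCN <- 6; NCT <- 8
  u1 <- c(runif(3, 0.5, 1), rep(0, 3)); u2 <- rev(u1)
  v1 <- c(runif(4, 0.5, 1), rep(0, 4)); v2 <- rev(v1)
  w <- runif(P, 0.5, 1)
  Tarr <- outer(w, outer(u1, v1)) + outer(rev(w), outer(u2, v2))
  fit <- ntd(Tarr, ranks = c(P, 2, 2), maxIter = 1000L, seed = 5L)
  expect_lte(relativeError(fit, Tarr), 0.05)
  mg <- moduleGraph(fit)
  # align factor columns to the planted blocks by maximal correlation
  cnBlock <- apply(tuckerFactors(fit)[[2]], 2,
                   function(col) which.max(c(cor(col, u1), cor(col, u2))))
  ctBlock <- apply(tuckerFactors(fit)[[3]], 2,
                   function(col) which.max(c(cor(col, v1), cor(col, v2))))
  top2 <- mg$edges[1:2, ]
  got <- sort(paste0(cnBlock[top2$cnModule], ctBlock[top2$ctModule]))
  expect_equal(got, c("11", "22"))
})

test_that("the loss curve decreases in rank and flags the planted rank", {
  set.seed(5)
  # rank-2 signal plus a small noise floor so the curve plateaus past 2
  Tarr <- outer(runif(6, 0.2, 1), outer(runif(6, 0.2, 1), runif(6, 0.2, 1))) +
    outer(runif(6, 0.2, 1), outer(runif(6, 0.2, 1), runif(6, 0.2, 1))) +
    array(runif(216, 0, 0.02), c(6, 6, 6))
  sr <- selectRank(Tarr, 1:3, seed = 1L, maxIter = 800L, nRestarts = 3L)
  expect_true(all(diff(sr$relLoss) <= 1e-8))
  expect_lt(sr$relLoss[2] / sr$relLoss[1], 0.5)   # sharp drop at rank 2
  expect_gt(sr$relLoss[3] / max(sr$relLoss[2], 1e-12), 0.8)  # then plateau
  # single candidate gives a single-point curve
  expect_equal(nrow(selectRank(Tarr, 2, seed = 1L, maxIter = 100L,
                               nRestarts = 1L)), 1L)
})

test_that("losses agree with an independent reference implementation", {
  oracle <- system.file("oracles", "ntd_reference.py", package = "imcTopo")
  skip_if(oracle == "" || Sys.which("python") == "",
          "python oracle unavailable")
  set.seed(6)
  for (i in 1:3) {
    Tarr <- array(runif(8 * 6 * 5), c(8, 6, 5))
    fit <- ntd(Tarr, ranks = c(4, 3, 2), maxIter = 200L, tol = 0,
               seed = i, nRestarts = 3L)
    rl <- tail(lossTrace(fit), 1)
    spec <- jsonlite::toJSON(list(tensor = Tarr, ranks = c(4, 3, 2),
                                  iters = 200, restarts = 3, seed = i),
                             digits = NA)
    out <- system2("python", oracle, input = as.character(spec),
                   stdout = TRUE)
    pl <- jsonlite::fromJSON(out)$loss
    expect_lt(abs(rl - pl) / pl, 0.05)
  }
})
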