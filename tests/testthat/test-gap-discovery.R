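test_that("a constructed bimodal distance set yields a threshold in the gap", {
  m <- twoBlockMatrix(sizes = c(5, 5), within = c(0.005, 0.03),
                      between = c(0.20, 0.25), seed = 1)
  gd <- geneticDistancesFromMatrix(m)
  scan <- detectBarcodeGap(gd, prior = 0.05, xRel = 1.5)
  expect_false(is.na(scan@gapIndex))
  expect_gt(scan@threshold, 0.03)
  expect_lt(scan@threshold, 0.20)
  # ranked distances are sorted and complete
  expect_false(is.unsorted(scan@ranked))
  expect_length(scan@ranked, choose(10, 2))
})

test_that("no gap is reported for uniform or prior-masked distances", {
  flat <- matrix(0.1, 6, 6); diag(flat) <- 0
  expect_true(is.na(detectBarcodeGap(
    geneticDistancesFromMatrix(flat), prior = 0.01)@threshold))

  # a prior above the barcode gap masks it
  m <- twoBlockMatrix(seed = 2)
  gd <- geneticDistancesFromMatrix(m)
  expect_false(is.na(detectBarcodeGap(gd, prior = 0.05)@gapIndex))
  expect_true(is.na(detectBarcodeGap(gd, prior = 0.30)@gapIndex))
})

test_that("gap detection needs at least three defined pairs", {
  m <- matrix(c(0, 0.1, 0.1, 0), 2, 2)
  expect_error(detectBarcodeGap(geneticDistancesFromMatrix(m), 0.01),
               class = "barcodegap_insufficient_data")
})

test_that("threshold partitioning is single-linkage on defined edges", {
  m <- twoBlockMatrix(sizes = c(4, 6), seed = 3)
  gd <- geneticDistancesFromMatrix(m)
  part <- partitionAtThreshold(gd, 0.1)
  expect_equal(nOtus(part), 2L)
  expect_equal(unname(otuAssignment(part)), rep(c(1L, 2L), c(4, 6)))

  expect_equal(nOtus(partitionAtThreshold(gd, 1)), 1L)       # above max
  expect_equal(nOtus(partitionAtThreshold(gd, 1e-6)), 10L)   # below min

  # undefined entries contribute no edge
  m2 <- matrix(NA_real_, 3, 3); diag(m2) <- 0
  m2[1, 2] <- m2[2, 1] <- 0.01
  gd2 <- geneticDistancesFromMatrix(m2)
  expect_equal(nOtus(partitionAtThreshold(gd2, 0.5)), 2L)
})

test_that("group count is non-increasing in the threshold", {
  gd <- geneticDistances(randomAlignment(12, 150, seed = 41), "P")
  thresholds <- seq(0, 0.8, by = 0.05)
  counts <- vapply(thresholds, function(t) nOtus(partitionAtThreshold(gd, t)),
                   0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("recursion refines the initial partition and splits nested structure", {
  # cluster A = two subclusters whose 0.025-0.055 separation hides inside a
  # smooth geometric ramp of pooled distances (clusters B and C fill the
  # intermediate range), so the pooled scan only sees the ramp-to-0.28 gap;
  # the within-A rescan then exposes the subcluster gap
  grp <- rep(c("A1", "A2", "B", "C"), c(4, 4, 3, 6))
  n <- length(grp)
  geo <- 0.005 * (0.055 / 0.005)^((0:45) / 45)   # 46 smooth small distances
  small <- list(B = geo[13:15], C = geo[16:30])
  m <- matrix(0, n, n)
  aWithin <- geo[1:12]; aBetween <- geo[31:46]
  ai <- bi <- ci <- xi <- 1L
  far <- seq(0.28, 0.30, length.out = 90)
  fi <- 1L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    gi <- grp[i]; gj <- grp[j]
    if (gi == gj || (gi %in% c("A1", "A2") && gj %in% c("A1", "A2"))) {
      if (gi %in% c("A1", "A2") && gi == gj) { v <- aWithin[ai]; ai <- ai + 1L }
      else if (gi %in% c("A1", "A2")) { v <- aBetween[xi]; xi <- xi + 1L }
      else if (gi == "B") { v <- small$B[bi]; bi <- bi + 1L }
      else { v <- small$C[ci]; ci <- ci + 1L }
    } else { v <- far[fi]; fi <- fi + 1L }
    m[i, j] <- m[j, i] <- v
  }
  dimnames(m) <- list(paste0("t", 1:n), paste0("t", 1:n))
  gd <- geneticDistancesFromMatrix(m)

  ini <- abgdInitial(gd, prior = 0.01)
  rec <- abgdRecursive(gd, prior = 0.01)
  expect_equal(nOtus(ini), 3L)          # A pooled, B, C
  expect_equal(nOtus(rec), 4L)          # recursion separates A1 from A2
  recA <- otuAssignment(rec)[grp %in% c("A1", "A2")]
  expect_equal(length(unique(recA)), 2L)
  expect_length(unique(recA[1:4]), 1L)

  # refinement: same recursive group implies same initial group
  a <- otuAssignment(ini); r <- otuAssignment(rec)
  for (g in unique(r)) expect_length(unique(a[r == g]), 1L)
})

test_that("recursive partitions refine initial ones on random matrices", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 12
    m <- matrix(0, n, n)
    v <- runif(n * (n - 1) / 2, 0, 0.4)
    m[upper.tri(m)] <- v
    m <- m + t(m)
    gd <- geneticDistancesFromMatrix(m)
    ini <- abgdInitial(gd, prior = 0.02)
    rec <- abgdRecursive(gd, prior = 0.02)
    a <- otuAssignment(ini); r <- otuAssignment(rec)
    expect_gte(nOtus(rec), nOtus(ini))
    for (g in unique(r)) expect_length(unique(a[r == g]), 1L)
  }
})

test_that("partitions are invariant under sequence reordering", {
  ds <- simulateBarcodes(simulationSpec(4, 5, 500, 0.008, 0.18, seed = 6))
  gd <- geneticDistances(ds@alignment, "K2P")
  set.seed(8)
  perm <- sample(length(alnIds(gd)))
  gdPerm <- gd[perm]
  p1 <- otuAssignment(abgdRecursive(gd, 0.05))
  p2 <- otuAssignment(abgdRecursive(gdPerm, 0.05))
  # same groups up to label renaming
  common <- names(p1)
  expect_equal(outer(p1[common], p1[common], `==`),
               outer(p2[common], p2[common], `==`))
})

test_that("groups too small to rescan are recursion fixed points", {
  # initial partition of size-2 groups: recursion must leave them intact
  m <- twoBlockMatrix(sizes = c(2, 2), within = c(0.005, 0.01),
                      between = c(0.2, 0.25), seed = 9)
  gd <- geneticDistancesFromMatrix(m)
  ini <- abgdInitial(gd, prior = 0.05)
  expect_equal(nOtus(ini), 2L)
  rec <- abgdRecursive(gd, prior = 0.05)
  expect_identical(otuAssignment(rec), otuAssignment(ini))

  # identical sequences always form one group at any prior
  z3 <- geneticDistancesFromMatrix(matrix(0, 3, 3))
  expect_equal(nOtus(abgdInitial(z3, 0.1)), 1L)
  expect_error(
    detectBarcodeGap(geneticDistancesFromMatrix(matrix(0, 2, 2)), 0.1),
    class = "barcodegap_insufficient_data")
})

test_that("the default prior grid is geometric from 0.001 to 0.12", {
  g <- priorGrid()
  expect_length(g, 10L)
  expect_equal(g,
               c(0.001, 0.0017, 0.0029, 0.0049, 0.0084, 0.0143,
                 0.0243, 0.0414, 0.0705, 0.12),
               tolerance = 0.02)
  # constant ratio
  expect_equal(diff(log(g)), rep(log(g[2] / g[1]), 9), tolerance = 1e-12)
  expect_equal(priorGrid(0.01, 0.2, 2), c(0.01, 0.2))
})

test_that("prior sweep reports both partition kinds over the grid", {
  ds <- simulateBarcodes(simulationSpec(4, 5, 500, 0.008, 0.18, seed = 10))
  gd <- geneticDistances(ds@alignment, "K2P")
  sw <- priorSweep(gd, 0.02, 0.3, steps = 4)
  expect_equal(names(sw), c("prior", "n_initial", "n_recursive"))
  expect_equal(nrow(sw), 4L)
  expect_true(all(sw$n_recursive >= sw$n_initial))
  # priors beyond every distance find no gap: single group
  expect_equal(sw$n_initial[sw$prior > 0.25], 1L)
  expect_error(priorSweep(gd, 0.1, 0.05), "pMin < pMax")
})
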