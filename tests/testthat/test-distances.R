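test_that("pair counting under pairwise deletion matches hand counts", {
  pc <- pairCounts("ACGT", "ACGA")
  expect_equal(pc$nValid, 4L)
  expect_equal(pc$nDiff, 1L)
  expect_equal(pc$q, 1 / 4)            # T<->A is a transversion
  expect_equal(pc$p1 + pc$p2, 0)

  pc2 <- pairCounts("AC-T", "AGTT")
  expect_equal(pc2$nValid, 3L)         # columns 1, 2, 4
  expect_equal(pc2$nDiff, 1L)
  expect_equal(pDistance(pc2), 1 / 3)

  pc3 <- pairCounts("ACGTACGT", "ACGTACGT")
  expect_equal(pc3$nDiff, 0L)
  expect_equal(c(pc3$p1, pc3$p2, pc3$q), c(0, 0, 0))

  expect_error(pairCounts("----", "AAAA"), class = "barcodegap_no_overlap")
})

test_that("pair count fields are mutually consistent", {
  for (seed in 1:5) {
    pair <- randomDivergedPair(300, 0.15, seed = seed)
    pc <- pairCounts(pair$x, pair$y)
    expect_equal(pc$p1 + pc$p2 + pc$q, pc$nDiff / pc$nValid, tolerance = 1e-12)
    expect_equal(sum(pc$baseFreqs), 1, tolerance = 1e-12)
    expect_equal(sum(pc$fmat), 1, tolerance = 1e-12)
    expect_equal((rowSums(pc$fmat) + colSums(pc$fmat)) / 2,
                 pc$baseFreqs, tolerance = 1e-12)
    # brute-force mismatch oracle for the p-distance
    expect_equal(pDistance(pc), mean(pair$x != pair$y), tolerance = 1e-12)
  }
})

test_that("K2P closed form matches its formula and the independent oracle", {
  # frozen from -1/2 log((1-2P-Q) sqrt(1-2Q)) at P = 0.1, Q = 0.05
  pc <- list(p1 = 0.1, p2 = 0, q = 0.05)
  expect_equal(k2pDistance(structure(pc, class = "pair_counts")),
               0.1701812, tolerance = 1e-6)
  # zero divergence
  pc0 <- pairCounts("ACGT", "ACGT")
  expect_equal(k2pDistance(pc0), 0)
  # saturation: 1 - 2P - Q <= 0
  expect_true(is.na(k2pDistance(structure(list(p1 = 0.3, p2 = 0, q = 0.45),
                                          class = "pair_counts"))))
  # independent implementation (ape) on random pairs
  for (seed in 1:5) {
    pair <- randomDivergedPair(600, 0.1, seed = seed)
    mine <- k2pDistance(pairCounts(pair$x, pair$y))
    db <- ape::as.DNAbin(rbind(a = tolower(pair$x), b = tolower(pair$y)))
    expect_equal(mine, as.numeric(ape::dist.dna(db, "K80")),
                 tolerance = 1e-10)
  }
})

test_that("TN93 reduces to K2P at equal frequencies and matches ape", {
  pc <- structure(list(p1 = 0.05, p2 = 0.05, q = 0.05,
                       baseFreqs = rep(0.25, 4)), class = "pair_counts")
  expect_equal(tn93Distance(pc), 0.1701812, tolerance = 1e-6)
  pc0 <- pairCounts("ACGT", "ACGT")
  expect_equal(tn93Distance(pc0), 0)
  for (seed in 1:5) {
    pair <- randomDivergedPair(800, 0.12, freqs = c(0.35, 0.15, 0.2, 0.3),
                               seed = seed + 20)
    mine <- tn93Distance(pairCounts(pair$x, pair$y))
    db <- ape::as.DNAbin(rbind(a = tolower(pair$x), b = tolower(pair$y)))
    expect_equal(mine, as.numeric(ape::dist.dna(db, "TN93")),
                 tolerance = 1e-10)
  }
})

test_that("gamma and invariant-site adjustments behave at their limits", {
  pair <- randomDivergedPair(600, 0.1, seed = 31)
  pc <- pairCounts(pair$x, pair$y)
  plain <- k2pDistance(pc)
  # alpha -> Inf restores the uncorrected distance
  expect_equal(k2pDistance(pc, distanceModel("K2P", alpha = 1e6)), plain,
               tolerance = 1e-6)
  expect_equal(tn93Distance(pc, distanceModel("TN93", alpha = 1e6)),
               tn93Distance(pc), tolerance = 1e-6)
  # finite alpha inflates the correction
  expect_gt(k2pDistance(pc, distanceModel("K2P", alpha = 0.5)), plain)
  # gamma ape cross-check
  db <- ape::as.DNAbin(rbind(a = tolower(pair$x), b = tolower(pair$y)))
  expect_equal(k2pDistance(pc, distanceModel("K2P", alpha = 0.7)),
               as.numeric(ape::dist.dna(db, "K80", gamma = 0.7)),
               tolerance = 1e-10)
  # pInv = 0 is a no-op; pInv > 0 inflates
  expect_equal(k2pDistance(pc, distanceModel("K2P", pInv = 0)), plain)
  expect_gt(k2pDistance(pc, distanceModel("K2P", pInv = 0.3)), plain)
})

test_that("GTR estimator recovers known distances and flags saturation", {
  # no divergence: diagonal fmat
  pc0 <- pairCounts("ACGTACGT", "ACGTACGT")
  expect_equal(gtrDistance(pc0), 0)
  # equal-rate (JC-like) simulation at true distance 0.1, long sequences
  set.seed(77)
  L <- 1e5
  dTrue <- 0.1
  pSame <- 0.25 + 0.75 * exp(-4 * dTrue / 3)
  x <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  stay <- runif(L) < pSame
  y <- x
  y[!stay] <- vapply(x[!stay], function(s)
    sample(setdiff(c("A", "C", "G", "T"), s), 1L), "")
  est <- gtrDistance(pairCounts(x, y))
  expect_equal(est, dTrue, tolerance = 0.01)
  # saturated divergence matrix: an eigenvalue <= 0
  f <- matrix(1 / 16, 4, 4)          # complete randomisation
  f[1, 1] <- f[1, 1] - 1e-3; f[1, 2] <- f[1, 2] + 1e-3
  expect_true(is.na(barcodegap:::gtrCore(f)))
})

test_that("distance matrices agree with per-pair computation and ape", {
  aln <- randomAlignment(8, 400, gapProb = 0.05, seed = 13)
  strings <- alnStrings(aln)
  for (modelName in c("P", "K2P", "TN93", "GTR")) {
    gd <- geneticDistances(aln, modelName)
    m <- as.matrix(gd)
    expect_true(isSymmetric(m))
    expect_equal(unname(diag(m)), rep(0, 8))
    # dual route: vectorised matrix vs direct per-pair closed form
    for (pair in list(c(1, 2), c(3, 7), c(5, 8))) {
      pc <- pairCounts(strings[pair[1]], strings[pair[2]])
      direct <- switch(modelName,
        P = pDistance(pc), K2P = k2pDistance(pc),
        TN93 = tn93Distance(pc), GTR = gtrDistance(pc))
      expect_equal(m[pair[1], pair[2]], direct, tolerance = 1e-12)
    }
  }
  # whole-matrix independent oracle
  db <- ape::as.DNAbin(matrix(tolower(as.matrix(aln)), 8,
                              dimnames = list(alnIds(aln), NULL)))
  apeRaw <- as.matrix(ape::dist.dna(db, "raw", pairwise.deletion = TRUE))
  apeK80 <- as.matrix(ape::dist.dna(db, "K80", pairwise.deletion = TRUE))
  expect_equal(as.matrix(geneticDistances(aln, "P")), apeRaw,
               tolerance = 1e-12)
  mine <- as.matrix(geneticDistances(aln, "K2P"))
  ok <- is.finite(apeK80)
  expect_equal(mine[ok], apeK80[ok], tolerance = 1e-12)
})

test_that("distance corrections never fall below the p-distance", {
  aln <- randomAlignment(10, 300, gapProb = 0.1, seed = 17)
  p <- as.matrix(geneticDistances(aln, "P"))
  for (modelName in c("K2P", "TN93", "GTR")) {
    m <- as.matrix(geneticDistances(aln, modelName))
    ok <- !is.na(m)
    expect_true(all(m[ok] >= p[ok] - 1e-9),
                label = paste(modelName, ">= p-distance"))
  }
})

test_that("identical sequences give an all-zero matrix", {
  aln <- barcodeAlignment(c(a = "ACGTACGT", b = "ACGTACGT"))
  for (modelName in c("P", "K2P", "TN93", "GTR"))
    expect_equal(unname(as.matrix(geneticDistances(aln, modelName))),
                 matrix(0, 2, 2))
})

test_that("hand-computed 3-sequence p-distances are reproduced exactly", {
  aln <- barcodeAlignment(c(u = "AAAAAAAAAA", v = "AAAAAAAATT",
                            w = "AAAAA--ATT"))
  m <- as.matrix(geneticDistances(aln, "P"))
  expect_equal(m["u", "v"], 0.2)
  expect_equal(m["u", "w"], 2 / 8)
  expect_equal(m["v", "w"], 0)
})

test_that("non-overlapping pairs are flagged undefined, not zero", {
  aln <- barcodeAlignment(c(a = "AAAA----", b = "----TTTT", c = "AAAATTTT"))
  gd <- geneticDistances(aln, "P")
  expect_false(definedMask(gd)["a", "b"])
  expect_true(is.na(as.matrix(gd)["a", "b"]))
  expect_true(definedMask(gd)["a", "c"])
})

test_that("distance histogram bins and conserves defined pairs", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.01
  m[1, 3] <- m[3, 1] <- 0.02
  m[2, 3] <- m[3, 2] <- 0.30
  h <- distanceHistogram(geneticDistancesFromMatrix(m), 0.1)
  expect_equal(h$count[h$lower == 0], 2L)
  expect_equal(h$count[abs(h$lower - 0.3) < 1e-9], 1L)
  expect_equal(sum(h$count), 3L)

  z <- geneticDistancesFromMatrix(matrix(0, 4, 4))
  hz <- distanceHistogram(z, 0.05)
  expect_equal(sum(hz$count), 6L)            # n(n-1)/2 pairs in bin [0, w)
  expect_equal(hz$count[1], 6L)

  gd <- geneticDistances(randomAlignment(9, 200, seed = 23), "K2P")
  h2 <- distanceHistogram(gd, 0.013)
  expect_equal(sum(h2$count), length(pairwiseDistances(gd)))
})

test_that("distance matrices round-trip through PHYLIP and long TSV", {
  gd <- geneticDistances(randomAlignment(6, 120, seed = 29), "K2P")
  f <- withr::local_tempfile(fileext = ".phy")
  writePhylipDistances(gd, f)
  back <- readPhylipDistances(f, model = gd@model)
  expect_equal(alnIds(back), alnIds(gd))
  expect_equal(as.matrix(back), as.matrix(gd), tolerance = 1e-9)
  expect_identical(definedMask(back), definedMask(gd))

  long <- distancesToLongFormat(gd)
  expect_equal(nrow(long), choose(6, 2))
  expect_setequal(long$model, "K2P")
})
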