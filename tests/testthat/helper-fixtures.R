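# Shared fixture builders; everything is generated in code.

# random gappy alignment as a BarcodeAlignment
randomAlignment <- function(n, L, gapProb = 0.05, seed = 1) {
  withr_seed <- .Random.seed_exists()
  set.seed(seed)
  chars <- matrix(sample(c("A", "C", "G", "T", "-"), n * L, replace = TRUE,
                         prob = c(rep((1 - gapProb) / 4, 4), gapProb)),
                  n, L, dimnames = list(sprintf("s%02d", seq_len(n)), NULL))
  barcodeAlignment(apply(chars, 1, paste, collapse = ""))
}

.Random.seed_exists <- function() exists(".Random.seed", globalenv())

# symmetric matrix with two well-separated blocks of distances
twoBlockMatrix <- function(sizes = c(5, 5), within = c(0.005, 0.03),
                           between = c(0.2, 0.25), seed = 1) {
  set.seed(seed)
  n <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    rng <- if (block[i] == block[j]) within else between
    m[i, j] <- m[j, i] <- runif(1, rng[1], rng[2])
  }
  dimnames(m) <- list(sprintf("q%02d", 1:n), sprintf("q%02d", 1:n))
  m
}

# gap-free pair of sequences with roughly the requested divergence
randomDivergedPair <- function(L = 500, pTarget = 0.1,
                               freqs = c(0.25, 0.25, 0.25, 0.25), seed = 1) {
  set.seed(seed)
  states <- c("A", "C", "G", "T")
  x <- sample(states, L, replace = TRUE, prob = freqs)
  y <- x
  mut <- runif(L) < pTarget
  y[mut] <- sample(states, sum(mut), replace = TRUE)
  list(x = x, y = y)
}

# exhaustive minimum-change count for one site pattern on a 4-taxon tree
# with internal nodes u (tips 1,2) and v (tips 3,4); missing = NA
bruteForceFitch4 <- function(states) {
  det <- c("A", "C", "G", "T")
  best <- Inf
  for (u in det) for (v in det) {
    cost <- (u != v)
    for (k in 1:2) if (!is.na(states[k])) cost <- cost + (states[k] != u)
    for (k in 3:4) if (!is.na(states[k])) cost <- cost + (states[k] != v)
    best <- min(best, cost)
  }
  best
}

# additive distance matrix from a random tree with strictly positive edges
additiveTreeFixture <- function(nTips = 6, seed = 42) {
  set.seed(seed)
  tree <- ape::rtree(nTips, rooted = FALSE)
  tree$edge.length <- runif(length(tree$edge.length), 0.05, 0.3)
  list(tree = tree, d = ape::cophenetic.phylo(tree))
}
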