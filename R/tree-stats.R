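#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (Studier-Keppler criterion, via [ape::nj()]).
#' Negative branch-length estimates are clamped to zero; the number of
#' clamped edges is recorded in the `"clamped"` attribute of the returned
#' tree.
#'
#' @param x a [GeneticDistances-class] with >= 3 sequences and no undefined
#'   entries.
#' @return an unrooted `phylo` tree with non-negative branch lengths and an
#'   integer attribute `clamped`.
#' @export
njTree <- function(x) {
  n <- length(x@ids)
  if (n < 3L) stop("neighbor joining needs at least 3 sequences")
  off <- x@defined | diag(TRUE, n)
  if (!all(off))
    stop("incomplete distance matrix: ",
         sum(!x@defined[upper.tri(x@defined)]),
         " undefined pair(s); NJ requires every entry")
  tree <- ape::nj(stats::as.dist(x@d))
  neg <- tree$edge.length < 0
  tree$edge.length[neg] <- 0
  attr(tree, "clamped") <- sum(neg)
  tree
}

#' Minimum evolution score of a tree
#'
#' The sum of (clamped) branch lengths of a distance tree.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return numeric score (>= 0 for trees from [njTree()]).
#' @export
meScore <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  sum(tree$edge.length)
}

#' Fitch parsimony scores of an alignment on a tree
#'
#' Per site, the Fitch small-parsimony step count `s_i` on the given
#' topology; the per-site minimum `m_i` (number of distinct determinate
#' states minus one) and maximum `g_i` (determinate taxa minus the count of
#' the most frequent state). Sums over sites give the tree length `S`, the
#' lower bound `M` and the upper bound `G`, from which the consistency
#' index `CI = M/S` and retention index `RI = (G-S)/(G-M)` follow (`RI = 1`
#' when `G == M`; `CI = 1` for a homoplasy-free alignment). Gaps, `?`, `N`
#' and ambiguity codes are treated as missing: such leaves constrain
#' nothing at that site. By default all sites are scored; set
#' `informativeOnly = TRUE` to restrict every sum to parsimony-informative
#' sites.
#'
#' @param tree a `phylo` tree whose tips are a subset of the alignment ids.
#' @param aln a [BarcodeAlignment-class].
#' @param informativeOnly restrict the sums to parsimony-informative sites.
#' @return an object of class `parsimony_scores`: list with `treeLength`,
#'   `minSteps`, `maxSteps`, `ci`, `ri`, `perSite` (matrix of s, m, g).
#' @export
fitchScores <- function(tree, aln, informativeOnly = FALSE) {
  tips <- tree$tip.label
  missing <- setdiff(tips, alnIds(aln))
  if (length(missing))
    stop("tree tips absent from alignment: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  sub <- aln[tips]
  chars <- sub@chars
  ## missing semantics: every non-determinate symbol behaves as a free state
  chars[!(chars %in% DETERMINATE_STATES)] <- "-"
  dat <- phangorn::phyDat(chars, type = "DNA")
  perPattern <- phangorn::fitch(tree, dat, site = "site")
  s <- perPattern[attr(dat, "index")]

  counts <- stateCounts(chars)
  nDet <- colSums(counts)
  m <- pmax(colSums(counts > 0L) - 1L, 0L)
  maxCount <- apply(counts, 2L, max)
  g <- ifelse(nDet > 0L, nDet - maxCount, 0L)

  keep <- if (informativeOnly) colSums(counts >= 2L) >= 2L & colSums(counts > 0L) >= 2L
          else rep(TRUE, length(s))
  S <- sum(s[keep]); M <- sum(m[keep]); G <- sum(g[keep])
  ci <- if (S > 0) M / S else 1
  ri <- if (G > M) (G - S) / (G - M) else 1
  structure(list(treeLength = S, minSteps = M, maxSteps = G, ci = ci,
                 ri = ri, perSite = rbind(s = s, m = m, g = g)),
            class = "parsimony_scores")
}

#' @export
print.parsimony_scores <- function(x, ...) {
  cat(sprintf(
    "Fitch parsimony: tree length %d (bounds %d..%d), CI %.3f, RI %.3f\n",
    x$treeLength, x$minSteps, x$maxSteps, x$ci, x$ri))
  invisible(x)
}

#' Uniform random unrooted binary topology
#'
#' Random sequential addition: starting from the unique 3-leaf tree, each
#' further leaf is attached to an edge drawn uniformly at random. Every
#' addition multiplies the number of reachable topologies by the current
#' edge count, so each of the `(2k-5)!!` unrooted binary topologies is
#' produced with equal probability. Consumes the R RNG stream.
#'
#' @param labels tip labels (>= 3).
#' @return an unrooted `phylo` topology without branch lengths.
#' @export
randomTopology <- function(labels) {
  k <- length(labels)
  stopifnot(k >= 3L)
  ## grow an edge list over node ids: tips 1..k, internals k+1, k+2, ...
  nEdge <- 2L * k - 3L
  e1 <- integer(nEdge); e2 <- integer(nEdge)
  e1[1:3] <- k + 1L; e2[1:3] <- 1:3
  used <- 3L
  nextInternal <- k + 2L
  for (leaf in seq_len(k)[-(1:3)]) {
    j <- sample.int(used, 1L)
    v <- nextInternal; nextInternal <- nextInternal + 1L
    b <- e2[j]
    e2[j] <- v                     # split edge (a,b) into (a,v), (v,b)
    used <- used + 1L; e1[used] <- v; e2[used] <- b
    used <- used + 1L; e1[used] <- v; e2[used] <- leaf
  }
  ## orient edges away from the root k+1 (already parent-first by
  ## construction: e1 is always the older endpoint except for split 'b')
  edge <- orientEdges(cbind(e1[1:used], e2[1:used]), root = k + 1L)
  tree <- structure(list(edge = edge, tip.label = as.character(labels),
                         Nnode = k - 2L), class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

orientEdges <- function(edges, root) {
  nb <- split(c(edges[, 2L], edges[, 1L]), c(edges[, 1L], edges[, 2L]))
  out <- matrix(0L, nrow(edges), 2L)
  seen <- root
  frontier <- root
  r <- 0L
  visited <- rep(FALSE, max(edges))
  visited[root] <- TRUE
  while (length(frontier)) {
    nxt <- integer(0)
    for (p in frontier) {
      for (ch in nb[[as.character(p)]]) {
        if (!visited[ch]) {
          visited[ch] <- TRUE
          r <- r + 1L
          out[r, ] <- c(p, ch)
          nxt <- c(nxt, ch)
        }
      }
    }
    frontier <- nxt
  }
  out
}

#' Tree-length skewness (g1) over random topologies
#'
#' Samples `nTrees` uniform random unrooted topologies (seeded), scores the
#' Fitch tree length of the alignment on each, and returns the sample
#' skewness `g1 = m3 / m2^(3/2)` of the length distribution (central
#' moments). Structured data yield strongly left-skewed distributions
#' (`g1 < 0`: few trees much shorter than the mass of random trees —
#' phylogenetic signal); structure-free data give `g1` near 0. A
#' zero-variance distribution is flagged `degenerate` with `g1 = 0`. The
#' caller's RNG state is restored on exit.
#'
#' @param aln a [BarcodeAlignment-class] with >= 4 sequences.
#' @param nTrees number of random topologies (>= 100; default 10000).
#' @param seed integer RNG seed.
#' @return object of class `g1_result`: list with `g1`, `lengths`,
#'   `nTrees`, `seed`, `degenerate`.
#' @export
g1Statistic <- function(aln, nTrees = 10000L, seed = 1L) {
  stopifnot(nTrees >= 100L, nSequences(aln) >= 4L)
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(seed)

  chars <- aln@chars
  chars[!(chars %in% DETERMINATE_STATES)] <- "-"
  dat <- phangorn::phyDat(chars, type = "DNA")
  ids <- alnIds(aln)
  lengths <- vapply(seq_len(nTrees), function(k) {
    phangorn::fitch(randomTopology(ids), dat)
  }, 0)

  m2 <- mean((lengths - mean(lengths))^2)
  degenerate <- m2 == 0
  g1 <- if (degenerate) 0 else mean((lengths - mean(lengths))^3) / m2^1.5
  structure(list(g1 = g1, lengths = lengths, nTrees = as.integer(nTrees),
                 seed = as.integer(seed), degenerate = degenerate),
            class = "g1_result")
}

#' @export
print.g1_result <- function(x, ...) {
  cat(sprintf("g1 = %.4f over %d random topologies (seed %d)%s\n", x$g1,
              x$nTrees, x$seed,
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}
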