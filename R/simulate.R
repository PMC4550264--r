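#' Create a simulation specification
#'
#' @param nSpecies number of species.
#' @param nPerSpecies sequences per species (single count or one per
#'   species).
#' @param seqLen raw (ungapped) sequence length in nt.
#' @param intraD target mean within-species p-distance (>= 0).
#' @param interD target mean between-species p-distance (> `intraD`).
#' @param kappa transition/transversion rate ratio.
#' @param indelRate per-site indel probability on a species-level branch,
#'   in \[0, 0.2\].
#' @param baseFreqs equilibrium base composition (A, C, G, T).
#' @param seed integer RNG seed.
#' @return a [SimulationSpec-class].
#' @export
simulationSpec <- function(nSpecies, nPerSpecies, seqLen, intraD, interD,
                           kappa = 2, indelRate = 0.02,
                           baseFreqs = rep(0.25, 4), seed = 1L) {
  new("SimulationSpec", nSpecies = as.integer(nSpecies),
      nPerSpecies = as.integer(nPerSpecies), seqLen = as.integer(seqLen),
      intraD = as.numeric(intraD), interD = as.numeric(interD),
      kappa = as.numeric(kappa), indelRate = as.numeric(indelRate),
      baseFreqs = as.numeric(baseFreqs), seed = as.integer(seed))
}

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf(
    "SimulationSpec: %d species, %d sequences of %d nt, intra %g / inter %g, kappa %g, indel %g, seed %d\n",
    object@nSpecies, sum(speciesSizes(object)), object@seqLen,
    object@intraD, object@interD, object@kappa, object@indelRate,
    object@seed))
})

speciesSizes <- function(spec) {
  if (length(spec@nPerSpecies) == 1L) rep(spec@nPerSpecies, spec@nSpecies)
  else spec@nPerSpecies
}

#' Simulate a barcode dataset with a known species partition
#'
#' Two-scale star-phylogeny simulator. A root sequence is drawn from
#' `baseFreqs`; species ancestors sit on a star whose branch lengths are
#' calibrated so the expected between-species p-distance equals `interD`;
#' within each species, tips radiate from the ancestor on a star calibrated
#' to a within-species p-distance of `intraD`. Substitutions follow an
#' HKY-type process (ratio `kappa`, composition `baseFreqs`) simulated with
#' [phangorn::simSeq()]. Star phylogenies (rather than birth-death trees)
#' give direct, analytically transparent control of the two divergence
#' scales the barcode-gap principle assumes.
#'
#' Indels are applied after substitution with exact bookkeeping, so the
#' returned alignment is the true homology and degapping it recovers the
#' raw simulated sequences exactly. Indel events hit species-level branches
#' with per-site probability `indelRate` (shared by all members of the
#' species) and tip branches at `indelRate` scaled by relative branch
#' length; event lengths are geometric with mean 3; insertions open a
#' gap column block in all other sequences.
#'
#' The generator self-checks: with `seqLen >= 500` the realised mean
#' within- and between-species p-distances must fall within 25% of
#' `intraD` and `interD`.
#'
#' Identical spec (including seed) gives a bit-identical dataset; the
#' caller's RNG state is untouched.
#'
#' @param spec a [SimulationSpec-class].
#' @return a [SimulatedBarcodes-class].
#' @examples
#' ds <- simulateBarcodes(simulationSpec(5, 6, 600, 0.01, 0.2, seed = 1))
#' ds
#' @export
simulateBarcodes <- function(spec) {
  validObject(spec)
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(spec@seed)

  sizes <- speciesSizes(spec)
  nSp <- spec@nSpecies
  n <- sum(sizes)
  L <- spec@seqLen

  ## calibrate star depths (substitutions/site) so expected p-distances hit
  ## the targets: within-species separation D(intraD); between-species
  ## separation 2*tInter + 2*tIntra = D(interD)
  Q <- hkyRateMatrix(spec@kappa, spec@baseFreqs)
  dIntra <- substDistanceForP(spec@intraD, Q, spec@baseFreqs)
  dInter <- substDistanceForP(spec@interD, Q, spec@baseFreqs)
  tIntra <- dIntra / 2
  tInter <- max((dInter - dIntra) / 2, 0)

  tree <- twoLevelStar(sizes, tInter, tIntra)
  qVec <- c(1, spec@kappa, 1, 1, spec@kappa, 1)   # AC AG AT CG CT GT
  sim <- phangorn::simSeq(tree, l = L, Q = qVec, bf = spec@baseFreqs,
                          type = "DNA")
  raw <- toupper(as.character(sim))[tree$tip.label, , drop = FALSE]

  species <- rep(seq_len(nSp), sizes)
  ids <- sprintf("sp%03d_t%02d", species,
                 unlist(lapply(sizes, seq_len), use.names = FALSE))
  rownames(raw) <- ids

  aligned <- applyIndels(raw, species, spec, tIntra, tInter)

  aln <- new("BarcodeAlignment", chars = aligned,
             descriptions = stats::setNames(rep("", n), ids))
  truth <- newOtuPartition(stats::setNames(species, ids), kind = "truth")
  ds <- new("SimulatedBarcodes", alignment = aln, partition = truth,
            spec = spec)
  selfCheckDivergence(ds)
  ds
}

## HKY rate matrix (rows A,C,G,T), scaled to one expected substitution per
## unit time at equilibrium
hkyRateMatrix <- function(kappa, bf) {
  R <- matrix(1, 4L, 4L)
  R[1L, 3L] <- R[3L, 1L] <- kappa   # A<->G
  R[2L, 4L] <- R[4L, 2L] <- kappa   # C<->T
  Q <- R * rep(bf, each = 4L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q / sum(bf * -diag(Q))
}

## invert the expected-p curve: find D with 1 - sum_i pi_i P_ii(D) == p
substDistanceForP <- function(p, Q, bf) {
  if (p <= 0) return(0)
  eg <- eigen(Q)
  pAt <- function(D) {
    P <- Re(eg$vectors %*% diag(exp(eg$values * D)) %*% solve(eg$vectors))
    1 - sum(bf * diag(P))
  }
  pMaxAsym <- pAt(50)
  if (p >= pMaxAsym) stop("target p-distance ", p, " is unattainable under this model")
  stats::uniroot(function(D) pAt(D) - p, c(1e-9, 50), tol = 1e-10)$root
}

## root -> species ancestors (edge tInter) -> tips (edge tIntra)
twoLevelStar <- function(sizes, tInter, tIntra) {
  nSp <- length(sizes)
  n <- sum(sizes)
  root <- n + 1L
  spNode <- n + 1L + seq_len(nSp)
  parent <- c(rep(root, nSp), spNode[rep(seq_len(nSp), sizes)])
  child <- c(spNode, seq_len(n))
  len <- c(rep(tInter, nSp), rep(tIntra, n))
  tree <- structure(list(edge = cbind(parent, child),
                         edge.length = len,
                         tip.label = paste0("t", seq_len(n)),
                         Nnode = nSp + 1L), class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

## indels: species-level events shared by the species, tip-level events
## private; insertions become private column blocks, deletions become gaps
applyIndels <- function(raw, species, spec, tIntra, tInter) {
  n <- nrow(raw); L <- ncol(raw)
  if (spec@indelRate == 0) return(raw)
  tipRate <- if (tInter > 0) spec@indelRate * tIntra / tInter else spec@indelRate
  nSp <- max(species)

  events <- list()                 # each: owner rows, anchor, type, bases/len
  drawEvents <- function(rate, rows) {
    nEv <- stats::rbinom(1L, L, rate)
    out <- vector("list", nEv)
    for (k in seq_len(nEv)) {
      len <- 1L + stats::rgeom(1L, 1 / 3)          # mean 3
      if (stats::runif(1L) < 0.5) {
        out[[k]] <- list(rows = rows, anchor = sample.int(L, 1L),
                         type = "ins",
                         bases = sample(DETERMINATE_STATES, len, TRUE,
                                        prob = spec@baseFreqs))
      } else {
        start <- sample.int(L, 1L)
        out[[k]] <- list(rows = rows, type = "del",
                         cols = start:min(L, start + len - 1L))
      }
    }
    out
  }
  for (sp in seq_len(nSp))
    events <- c(events, drawEvents(spec@indelRate, which(species == sp)))
  for (i in seq_len(n))
    events <- c(events, drawEvents(tipRate, i))

  ## deletions first: replace deleted characters by '-'
  for (ev in events) {
    if (ev$type == "del") raw[ev$rows, ev$cols] <- "-"
  }
  ## insertions: new column blocks after their anchor column
  ins <- Filter(function(ev) ev$type == "ins", events)
  if (!length(ins)) return(raw)
  pieces <- list(raw[, 0L, drop = FALSE])
  for (a in seq_len(L)) {
    pieces[[length(pieces) + 1L]] <- raw[, a, drop = FALSE]
    for (ev in ins) {
      if (ev$anchor == a) {
        block <- matrix("-", n, length(ev$bases))
        block[ev$rows, ] <- rep(ev$bases, each = length(ev$rows))
        pieces[[length(pieces) + 1L]] <- block
      }
    }
  }
  out <- do.call(cbind, pieces)
  rownames(out) <- rownames(raw)
  out
}

selfCheckDivergence <- function(ds) {
  spec <- ds@spec
  if (spec@seqLen < 500L) return(invisible(ds))
  gd <- geneticDistances(ds@alignment, distanceModel("P"))
  grp <- ds@partition@assignment[gd@ids]
  same <- outer(grp, grp, `==`)[upper.tri(gd@d)]
  vals <- gd@d[upper.tri(gd@d)]
  ok <- !is.na(vals)
  within <- mean(vals[same & ok])
  between <- mean(vals[!same & ok])
  if (spec@intraD > 0 && any(same[ok]) &&
      abs(within - spec@intraD) > 0.25 * spec@intraD)
    stop(sprintf("generator self-check failed: realised within-species p %.4f vs target %.4f",
                 within, spec@intraD))
  if (any(!same[ok]) && abs(between - spec@interD) > 0.25 * spec@interD)
    stop(sprintf("generator self-check failed: realised between-species p %.4f vs target %.4f",
                 between, spec@interD))
  invisible(ds)
}

setMethod("show", "SimulatedBarcodes", function(object) {
  cat("SimulatedBarcodes\n")
  show(object@spec)
  cat(sprintf("  alignment: %d x %d; true partition: %d species\n",
              nSequences(object@alignment), alnLength(object@alignment),
              nOtus(object@partition)))
})

#' Preset emulating the scale of a 290-isolate ITS barcode study
#'
#' A fixed specification of 75 species whose sizes (drawn once, internally
#' seeded) total 290 sequences of 550 nt, within-species divergence 0.012,
#' between-species divergence 0.15, kappa 2, indel rate 0.02 — the scale and
#' divergence structure typical of a culture-collection ITS barcoding
#' campaign (a few hundred isolates in several dozen species, intraspecific
#' K2P distances of order 0.007-0.018, interspecific distances an order of
#' magnitude larger).
#'
#' @param seed RNG seed for the dataset realisation (the species sizes are
#'   part of the fixed preset and do not depend on it).
#' @return a [SimulationSpec-class] totalling exactly 290 sequences.
#' @export
studyEmulationPreset <- function(seed = 1L) {
  nSpecies <- 75L
  total <- 290L
  ## fixed size draw: one seeded multinomial over species, each >= 1
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(290075L)
  sizes <- 1L + as.integer(stats::rmultinom(1L, total - nSpecies,
                                            rep(1 / nSpecies, nSpecies)))
  simulationSpec(nSpecies = nSpecies, nPerSpecies = sizes, seqLen = 550L,
                 intraD = 0.012, interD = 0.15, kappa = 2,
                 indelRate = 0.02, seed = seed)
}

#' Write a simulated dataset to disk
#'
#' Writes the aligned FASTA, a two-column truth TSV (`id`, `species`) and
#' the generating spec as JSON (when the jsonlite package is installed).
#'
#' @param ds a [SimulatedBarcodes-class].
#' @param dir output directory (created if needed).
#' @param stem file name stem.
#' @return invisibly, the paths written.
#' @export
writeSimulatedBarcodes <- function(ds, dir, stem = "simulated") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(stem, ".fasta"))
  truth <- file.path(dir, paste0(stem, "_truth.tsv"))
  writeFastaAlignment(ds@alignment, fasta)
  utils::write.table(
    data.frame(id = names(ds@partition@assignment),
               species = ds@partition@assignment),
    truth, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(fasta, truth)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    spec <- ds@spec
    js <- file.path(dir, paste0(stem, "_spec.json"))
    jsonlite::write_json(
      list(nSpecies = spec@nSpecies, nPerSpecies = speciesSizes(spec),
           seqLen = spec@seqLen, intraD = spec@intraD, interD = spec@interD,
           kappa = spec@kappa, indelRate = spec@indelRate,
           baseFreqs = spec@baseFreqs, seed = spec@seed),
      js, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, js)
  }
  invisible(paths)
}
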