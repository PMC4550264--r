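#' Create a distance model specification
#'
#' @param model one of `"P"`, `"K2P"`, `"TN93"`, `"GTR"`.
#' @param alpha optional gamma shape parameter (> 0); `NULL`/`NA` disables
#'   the gamma rate-heterogeneity adjustment.
#' @param pInv optional proportion of invariable sites in \[0, 1).
#' @param freqMode `"pairwise"` (default) estimates TN93 base frequencies
#'   from each pair's shared determinate sites; `"global"` uses
#'   alignment-wide frequencies.
#' @return a [DistanceModel-class].
#' @examples
#' distanceModel("K2P")
#' distanceModel("TN93", alpha = 0.83, pInv = 0.092)
#' @export
distanceModel <- function(model = c("P", "K2P", "TN93", "GTR"),
                          alpha = NULL, pInv = NULL,
                          freqMode = c("pairwise", "global")) {
  model <- match.arg(toupper(model[1L]), c("P", "K2P", "TN93", "GTR"))
  new("DistanceModel", model = model,
      alpha = if (is.null(alpha)) NA_real_ else as.numeric(alpha),
      pInv = if (is.null(pInv)) NA_real_ else as.numeric(pInv),
      freqMode = match.arg(freqMode))
}

setMethod("show", "DistanceModel", function(object) {
  cat(sprintf("DistanceModel: %s%s%s (%s base frequencies)\n", object@model,
              if (!is.na(object@alpha)) sprintf(" +G(alpha=%g)", object@alpha) else "",
              if (!is.na(object@pInv)) sprintf(" +I(%g)", object@pInv) else "",
              object@freqMode))
})

#' Shared substitution counts for one aligned sequence pair
#'
#' Counts, under pairwise deletion (only sites where both sequences carry a
#' determinate A/C/G/T state), the quantities every distance correction
#' consumes: the number of valid and differing sites, the proportions of
#' A<->G (`p1`) and C<->T (`p2`) transition differences and of transversion
#' differences (`q`), the base composition averaged over the pair's valid
#' sites, and the 4x4 divergence proportion matrix `fmat` (`fmat[x, y]` is
#' the fraction of valid sites with state `x` in the first sequence and `y`
#' in the second).
#'
#' @param s1,s2 aligned sequences: equal-length strings or single-character
#'   vectors from the same alignment.
#' @return an object of class `pair_counts`: a list with elements `nValid`,
#'   `nDiff`, `p1`, `p2`, `q`, `baseFreqs`, `fmat`.
#' @examples
#' pairCounts("AC-T", "AGTT")   # 3 valid sites, 1 difference
#' @export
pairCounts <- function(s1, s2) {
  a <- toSiteChars(s1); b <- toSiteChars(s2)
  if (length(a) != length(b))
    stop("sequences differ in aligned length (", length(a), " vs ",
         length(b), ")")
  valid <- a %in% DETERMINATE_STATES & b %in% DETERMINATE_STATES
  nValid <- sum(valid)
  if (nValid == 0L)
    stop(noOverlapError("sequence pair shares no determinate sites"))
  a <- a[valid]; b <- b[valid]
  nDiff <- sum(a != b)
  p1 <- sum((a == "A" & b == "G") | (a == "G" & b == "A")) / nValid
  p2 <- sum((a == "C" & b == "T") | (a == "T" & b == "C")) / nValid
  q <- nDiff / nValid - p1 - p2
  fmat <- matrix(0, 4L, 4L,
                 dimnames = list(DETERMINATE_STATES, DETERMINATE_STATES))
  tab <- table(factor(a, DETERMINATE_STATES), factor(b, DETERMINATE_STATES))
  fmat[] <- tab / nValid
  baseFreqs <- (rowSums(fmat) + colSums(fmat)) / 2
  structure(list(nValid = nValid, nDiff = nDiff, p1 = p1, p2 = p2, q = q,
                 baseFreqs = baseFreqs, fmat = fmat),
            class = "pair_counts")
}

toSiteChars <- function(s) {
  if (length(s) == 1L && nchar(s) > 1L)
    s <- strsplit(s, "", fixed = TRUE)[[1L]]
  s <- chartr("u", "U", toupper(s))
  chartr("U", "T", s)
}

noOverlapError <- function(msg) {
  structure(class = c("barcodegap_no_overlap", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Observed proportion of differing sites (p-distance)
#'
#' @param counts a `pair_counts` object from [pairCounts()].
#' @return `nDiff / nValid`.
#' @export
pDistance <- function(counts) counts$nDiff / counts$nValid

#' Kimura 2-parameter distance
#'
#' Corrects the observed transition proportion `P = p1 + p2` and
#' transversion proportion `Q` assuming equal base frequencies:
#' `d = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q))`. With a gamma shape `alpha` the
#' rate-heterogeneity form
#' `d = (alpha/2) ((1-2P-Q)^(-1/alpha) + (1-2Q)^(-1/alpha)/2 - 3/2)` is used;
#' with a proportion of invariable sites `pInv = I`, `P` and `Q` are first
#' rescaled by `1/(1-I)` and the result multiplied by `(1-I)`. Saturation
#' (a non-positive logarithm argument) yields `NA`.
#'
#' @param counts a `pair_counts` object from [pairCounts()].
#' @param model a [DistanceModel-class] (only `alpha`/`pInv` are consulted).
#' @return the corrected distance, or `NA` on saturation.
#' @export
k2pDistance <- function(counts, model = distanceModel("K2P")) {
  k2pCore(counts$p1 + counts$p2, counts$q, model@alpha, model@pInv)
}

k2pCore <- function(P, Q, alpha = NA_real_, pInv = NA_real_) {
  scale <- 1
  if (!is.na(pInv)) {
    scale <- 1 - pInv
    P <- P / scale
    Q <- Q / scale
  }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- if (is.na(alpha)) {
    -0.5 * safeLog(w1) - 0.25 * safeLog(w2)
  } else {
    (alpha / 2) * (safePow(w1, -1 / alpha) +
                   0.5 * safePow(w2, -1 / alpha) - 1.5)
  }
  scale * d
}

safeLog <- function(x) log(ifelse(x > 0, x, NA_real_))
safePow <- function(x, p) ifelse(x > 0, x, NA_real_)^p

#' Tamura-Nei (TN93) distance
#'
#' Allows unequal base frequencies, equal transversion rates and distinct
#' purine (A<->G) and pyrimidine (C<->T) transition rates. With
#' `k1 = 2 piA piG / piR`, `k2 = 2 piT piC / piY` and
#' `k3 = 2 (piR piY - piA piG piY / piR - piT piC piR / piY)`:
#' `d = -k1 log(1 - p1/k1 - q/(2 piR)) - k2 log(1 - p2/k2 - q/(2 piY))
#'      - k3 log(1 - q/(2 piR piY))`.
#' Gamma and invariant-site adjustments mirror [k2pDistance()]: each
#' `log(x)` term is replaced by `alpha (1 - x^(-1/alpha))` (which restores
#' the plain logarithm as `alpha -> Inf`), and under `pInv = I` the observed
#' proportions are rescaled by `1/(1-I)` with the result multiplied by
#' `(1-I)`. At equal base frequencies TN93 reduces exactly to K2P.
#'
#' @param counts a `pair_counts` object from [pairCounts()].
#' @param model a [DistanceModel-class] (`alpha`/`pInv` consulted).
#' @param baseFreqs optional base frequencies overriding the pair's own
#'   (used for `freqMode = "global"`).
#' @return the corrected distance, or `NA` on saturation.
#' @export
tn93Distance <- function(counts, model = distanceModel("TN93"),
                         baseFreqs = NULL) {
  bf <- unname(if (is.null(baseFreqs)) counts$baseFreqs else baseFreqs)
  tn93Core(counts$p1, counts$p2, counts$q,
           bf[1L], bf[2L], bf[3L], bf[4L], model@alpha, model@pInv)
}

tn93Core <- function(p1, p2, q, piA, piC, piG, piT,
                     alpha = NA_real_, pInv = NA_real_) {
  piR <- piA + piG
  piY <- piC + piT
  if (any(piR <= 0 | piY <= 0))
    stop("degenerate base composition: purine or pyrimidine frequency is zero")
  scale <- 1
  if (!is.na(pInv)) {
    scale <- 1 - pInv
    p1 <- p1 / scale; p2 <- p2 / scale; q <- q / scale
  }
  k1 <- 2 * piA * piG / piR
  k2 <- 2 * piT * piC / piY
  k3 <- 2 * (piR * piY - piA * piG * piY / piR - piT * piC * piR / piY)
  w1 <- 1 - ifelse(k1 > 0, p1 / k1, ifelse(p1 > 0, Inf, 0)) - q / (2 * piR)
  w2 <- 1 - ifelse(k2 > 0, p2 / k2, ifelse(p2 > 0, Inf, 0)) - q / (2 * piY)
  w3 <- 1 - q / (2 * piR * piY)
  negLog <- if (is.na(alpha)) {
    function(x) -safeLog(x)
  } else {
    function(x) alpha * (safePow(x, -1 / alpha) - 1)
  }
  d <- k1 * negLog(w1) + k2 * negLog(w2) + k3 * negLog(w3)
  scale * d
}

#' General Time Reversible pairwise distance
#'
#' Closed-form pairwise GTR estimator requiring no tree: the divergence
#' proportion matrix is symmetrised, `Fhat = (fmat + t(fmat)) / 2`, `Pi` is
#' the diagonal of its marginal frequencies, and
#' `d = -trace(Pi %*% logm(solve(Pi) %*% Fhat))`
#' with the matrix logarithm taken by eigendecomposition (the similar
#' symmetric matrix `Pi^-1/2 Fhat Pi^-1/2` is decomposed for numerical
#' stability). A singular `Pi` (a base absent from both sequences) or any
#' eigenvalue <= 0 (saturation) yields `NA`. An optional gamma shape applies
#' the `log(x) -> alpha (1 - x^(-1/alpha))` transform to the eigenvalue
#' logarithms; an invariable-site proportion rescales the off-diagonal
#' divergence mass by `1/(1-I)` and multiplies the result by `(1-I)`.
#'
#' @param counts a `pair_counts` object from [pairCounts()].
#' @param model a [DistanceModel-class] (`alpha`/`pInv` consulted).
#' @return the estimated distance, or `NA` when undefined.
#' @export
gtrDistance <- function(counts, model = distanceModel("GTR")) {
  gtrCore(counts$fmat, model@alpha, model@pInv)
}

gtrCore <- function(fmat, alpha = NA_real_, pInv = NA_real_) {
  f <- (fmat + t(fmat)) / 2
  pis <- rowSums(f)
  if (any(pis <= 0)) return(NA_real_)
  scale <- 1
  if (!is.na(pInv) && pInv > 0) {
    ## inflate observed divergence among the variable fraction, keeping the
    ## marginal base frequencies fixed
    scale <- 1 - pInv
    off <- f; diag(off) <- 0
    off <- off / scale
    newDiag <- pis - rowSums(off)
    if (any(newDiag <= 0)) return(NA_real_)  # rescaled divergence saturates
    f <- off; diag(f) <- newDiag
  }
  s <- 1 / sqrt(pis)
  B <- f * outer(s, s)                        # Pi^-1/2 F Pi^-1/2, symmetric
  eig <- eigen(B, symmetric = TRUE)
  if (any(eig$values <= 0)) return(NA_real_)
  lv <- if (is.na(alpha)) log(eig$values)
        else -alpha * (eig$values^(-1 / alpha) - 1)
  ## diag of logm(Pi^-1 F) equals diag of logm(B); d = -sum(pi_i * diag_i)
  diagLog <- as.vector(eig$vectors^2 %*% lv)
  d <- -sum(pis * diagLog)
  scale * max(d, 0)
}
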