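#' Run the full alignment x distance-model comparison
#'
#' Orchestrates the sensitivity analysis: for every combination of input
#' alignment and distance model, builds the distance matrix, sweeps the
#' prior grid for initial and recursive OTU counts, and records a
#' Table-style modal initial count (the most frequent initial-partition
#' size across the prior grid; initial partitions are typically stable
#' across priors). Failures (for instance a fully saturated combination)
#' are captured per cell and never abort the remaining grid. Site summaries
#' are collated per alignment. The whole run is deterministic given its
#' inputs.
#'
#' @param alignments named list of [BarcodeAlignment-class] objects (the
#'   names label the alignment algorithm or source).
#' @param models list of [DistanceModel-class] objects or character model
#'   names.
#' @param pMin,pMax,steps,xRel,window prior-sweep settings, see
#'   [priorSweep()].
#' @return an object of class `comparison_grid`: list with
#'   * `sweep`: `data.frame` (alignment, model, prior, n_initial,
#'     n_recursive) over the full grid;
#'   * `otuTable`: `data.frame` (alignment, model, n_otus) of modal initial
#'     counts, one row per combination;
#'   * `siteSummaries`: per-alignment [siteSummary()] rows;
#'   * `failures`: `data.frame` (alignment, model, message), zero rows when
#'     everything succeeded.
#' @export
runComparison <- function(alignments, models, pMin = 0.001, pMax = 0.12,
                          steps = 10L, xRel = 1.5, window = NULL) {
  stopifnot(length(alignments) >= 1L, length(models) >= 1L)
  if (is.null(names(alignments)) || any(!nzchar(names(alignments))))
    stop("alignments must be a named list")
  models <- lapply(models, function(m)
    if (is.character(m)) distanceModel(m) else m)
  modelNames <- vapply(models, function(m) m@model, "")

  sweepRows <- list(); otuRows <- list(); failRows <- list()
  for (aName in names(alignments)) {
    for (k in seq_along(models)) {
      mName <- modelNames[k]
      cell <- tryCatch({
        gd <- geneticDistances(alignments[[aName]], models[[k]])
        sw <- priorSweep(gd, pMin, pMax, steps, xRel, window)
        list(sweep = sw, modal = modalCount(sw$n_initial))
      }, error = function(e) e)
      if (inherits(cell, "error")) {
        failRows[[length(failRows) + 1L]] <-
          data.frame(alignment = aName, model = mName,
                     message = conditionMessage(cell))
      } else {
        sweepRows[[length(sweepRows) + 1L]] <-
          cbind(data.frame(alignment = aName, model = mName), cell$sweep)
        otuRows[[length(otuRows) + 1L]] <-
          data.frame(alignment = aName, model = mName, n_otus = cell$modal)
      }
    }
  }
  structure(list(
    sweep = rbindOrEmpty(sweepRows,
      c("alignment", "model", "prior", "n_initial", "n_recursive")),
    otuTable = rbindOrEmpty(otuRows, c("alignment", "model", "n_otus")),
    siteSummaries = siteSummaryTable(alignments),
    failures = rbindOrEmpty(failRows, c("alignment", "model", "message"))),
    class = "comparison_grid")
}

modalCount <- function(v) {
  tab <- table(v)
  as.integer(names(tab)[which.max(tab)])
}

rbindOrEmpty <- function(rows, cols) {
  if (length(rows)) do.call(rbind, rows)
  else stats::setNames(data.frame(matrix(nrow = 0L, ncol = length(cols))),
                       cols)
}

#' @export
print.comparison_grid <- function(x, ...) {
  cat(sprintf("comparison_grid: %d alignment(s) x %d model run(s), %d failure(s)\n",
              length(unique(x$sweep$alignment)),
              length(unique(x$sweep$model)), nrow(x$failures)))
  if (nrow(x$otuTable)) {
    cat("modal initial OTU counts:\n")
    print(stats::xtabs(n_otus ~ alignment + model, data = x$otuTable))
  }
  invisible(x)
}

#' Reshape a comparison sweep like an ABGD statistics table
#'
#' Rows are priors, column blocks are alignment x model, values are
#' recursive (or initial) partition counts — the layout used to eyeball
#' the monotone decline of partitions with growing prior.
#'
#' @param grid a `comparison_grid` from [runComparison()].
#' @param which `"n_recursive"` (default) or `"n_initial"`.
#' @return a wide `data.frame`, first column `prior`.
#' @export
sweepTable <- function(grid, which = c("n_recursive", "n_initial")) {
  which <- match.arg(which)
  sw <- grid$sweep
  combo <- paste(sw$alignment, sw$model, sep = ".")
  wide <- stats::reshape(
    data.frame(prior = sw$prior, combo = combo, value = sw[[which]]),
    idvar = "prior", timevar = "combo", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide[order(wide$prior), , drop = FALSE]
}

#' Frequency summary of a metadata column
#'
#' Counts the values of one column of an isolate-metadata table (for
#' instance best-match genus or source type), descending; empty cells and
#' `NA` are grouped as `"(missing)"`. Counts always sum to the number of
#' rows.
#'
#' @param table a `data.frame`, or the path of a delimited text file
#'   (tab-separated by default).
#' @param column name of the column to summarise.
#' @param sep field separator when `table` is a path.
#' @return `data.frame` with columns `value` and `count`, sorted by
#'   decreasing count (ties by value).
#' @export
summarizeMetadata <- function(table, column, sep = "\t") {
  if (is.character(table) && length(table) == 1L)
    table <- utils::read.delim(table, sep = sep, check.names = FALSE,
                               stringsAsFactors = FALSE)
  if (!column %in% names(table))
    stop("column '", column, "' not present; available: ",
         paste(names(table), collapse = ", "))
  v <- as.character(table[[column]])
  v[is.na(v) | !nzchar(trimws(v))] <- "(missing)"
  tab <- base::table(v)   # the 'table' argument shadows base::table here
  out <- data.frame(value = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$value), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(sum(out$count) == length(v))
  out
}
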