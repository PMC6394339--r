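#' Build the discretized gLV regression system
#'
#' Integrating the gLV log-derivative over each sampling interval
#' `[t_k, t_k+1]` with the implicit trapezoid rule turns parameter estimation
#' into linear regression: for taxon i,
#' \deqn{(\ln x_i(t_{k+1}) - \ln x_i(t_k)) / \Delta t_k \approx
#'       r_i + \sum_j \alpha_{ij} (x_j(t_{k+1}) + x_j(t_k)) / 2 .}
#' The shared design matrix holds the trapezoid midpoints; each taxon has its
#' own response vector of per-interval log-difference rates. Dividing by the
#' interval's own `Delta t` (rather than multiplying the right side by it)
#' keeps the design matrix free of `Delta t` under irregular sampling.
#'
#' Intervals where the focal taxon is zero at either endpoint have no defined
#' log-difference; they are dropped from that taxon's response and recorded in
#' `dropped_intervals`. Alternatively `pseudocount = TRUE` adds half the
#' smallest positive abundance in the table to every zero before taking logs.
#'
#' @param table An [abundance_table].
#' @param taxa Taxa to model (default: all).
#' @param window Integer pair `(start, end)` of time-point indices (inclusive,
#'   after sorting by time) delimiting the data used; default all points.
#' @param pseudocount If `TRUE`, replace zeros by half the smallest positive
#'   value in the table instead of dropping intervals.
#' @return An object of class `glv_regression`: list with `taxa`, `design`
#'   (K-by-n midpoint matrix), `responses` (per-taxon named list),
#'   `used_intervals` (per-taxon row indices into `design`),
#'   `dropped_intervals`, `interval_times` (K-by-2 matrix), `dt`, `window`.
#' @examples
#' tab <- abundance_table(0:2, cbind(A = c(1, 2, 4)))
#' sys <- build_regression_system(tab)
#' sys$responses$A       # log-difference rates: log(2), log(2)
#' sys$design            # trapezoid midpoints: 1.5, 3
#' @export
build_regression_system <- function(table, taxa = table$taxa, window = NULL,
                                    pseudocount = FALSE) {
  missing <- setdiff(taxa, table$taxa)
  if (length(missing)) {
    abort_validation(paste0("taxa not present in table: ",
                            paste(missing, collapse = ", ")))
  }
  np <- length(table$times)
  if (is.null(window)) window <- c(1L, np)
  window <- as.integer(window)
  if (length(window) != 2L || window[1] < 1L || window[2] > np ||
      window[1] >= window[2]) {
    abort_validation("window must be (start, end) indices with start < end within the table")
  }
  idx <- window[1]:window[2]
  times <- table$times[idx]
  x <- table$values[idx, taxa, drop = FALSE]
  n <- length(taxa)
  K <- length(times) - 1L

  if (pseudocount && any(x == 0)) {
    pos <- x[x > 0]
    if (length(pos) == 0) abort_validation("all abundances are zero; nothing to model")
    x[x == 0] <- min(pos) / 2
  }

  dt <- diff(times)
  design <- (x[-1L, , drop = FALSE] + x[-(K + 1L), , drop = FALSE]) / 2
  rownames(design) <- NULL

  responses <- used <- dropped <- stats::setNames(vector("list", n), taxa)
  for (i in seq_len(n)) {
    xi <- x[, i]
    ok <- xi[-(K + 1L)] > 0 & xi[-1L] > 0
    used[[i]] <- which(ok)
    dropped[[i]] <- which(!ok)
    responses[[i]] <- (log(xi[-1L][ok]) - log(xi[-(K + 1L)][ok])) / dt[ok]
  }

  structure(list(taxa = taxa, design = design, responses = responses,
                 used_intervals = used, dropped_intervals = dropped,
                 interval_times = cbind(t_k = times[-(K + 1L)], t_k1 = times[-1L]),
                 dt = dt, window = window, pseudocount = pseudocount),
            class = "glv_regression")
}

#' @export
print.glv_regression <- function(x, ...) {
  K <- nrow(x$design)
  nd <- sum(lengths(x$dropped_intervals))
  cat(sprintf("gLV regression system: %d taxa, %d intervals (%d taxon-intervals dropped)\n",
              length(x$taxa), K, nd))
  invisible(x)
}
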