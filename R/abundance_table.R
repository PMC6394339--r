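#' Construct a time-indexed abundance table
#'
#' An `abundance_table` holds longitudinal abundances of a set of taxa: a
#' strictly increasing vector of sampling times (arbitrary units, possibly
#' irregularly spaced) and a nonnegative numeric matrix with one row per time
#' point and one column per taxon. It is the common currency between parameter
#' estimation, simulation and evaluation.
#'
#' @param times Numeric vector of sampling times, strictly increasing.
#' @param values Numeric matrix (or data frame) of abundances;
#'   `nrow(values) == length(times)`, columns named by taxon. All entries must
#'   be finite and `>= 0`.
#' @param taxa Optional character vector of taxon names overriding
#'   `colnames(values)`. Names are whitespace-trimmed and must be unique and
#'   non-empty.
#' @param metadata Optional character vector of per-time-point labels
#'   (length = number of time points).
#' @return An object of class `abundance_table`: a list with elements `times`,
#'   `taxa`, `values` (matrix with `taxa` as column names) and `metadata`.
#' @examples
#' tab <- abundance_table(times = 0:2,
#'                        values = cbind(A = c(1, 2, 4), B = c(5, 4, 3)))
#' tab
#' @export
abundance_table <- function(times, values, taxa = NULL, metadata = NULL) {
  times <- as.numeric(times)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) values <- matrix(values, nrow = length(times))
  storage.mode(values) <- "double"
  if (is.null(taxa)) taxa <- colnames(values)
  if (is.null(taxa)) abort_format("abundance table has no taxon names")
  taxa <- trimws(as.character(taxa))
  if (any(!nzchar(taxa))) abort_format("empty taxon name after whitespace trimming")
  if (anyDuplicated(taxa)) {
    abort_format(paste0("duplicate taxon names: ",
                        paste(unique(taxa[duplicated(taxa)]), collapse = ", ")))
  }
  if (ncol(values) != length(taxa)) {
    abort_validation("number of value columns does not match number of taxa")
  }
  if (nrow(values) != length(times)) {
    abort_validation("number of value rows does not match number of time points")
  }
  if (length(times) == 0L || length(taxa) == 0L) {
    abort_validation("abundance table needs at least one time point and one taxon")
  }
  if (anyNA(times) || any(!is.finite(times))) {
    abort_validation("sampling times must be finite and non-missing")
  }
  dup <- which(diff(times) == 0)
  if (length(dup)) {
    abort_validation(paste0("duplicate sampling times at rows ",
                            paste(unique(c(dup, dup + 1L)), collapse = ", ")))
  }
  ord <- order(times)
  times <- times[ord]
  values <- values[ord, , drop = FALSE]
  if (!is.null(metadata)) metadata <- as.character(metadata)[ord]
  bad <- which(!is.finite(values) | values < 0)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(values))
    abort_validation(sprintf(
      "abundances must be finite and >= 0 (first offence: row %d, taxon '%s')",
      rc[1], taxa[rc[2]]))
  }
  dimnames(values) <- list(NULL, taxa)
  structure(list(times = times, taxa = taxa, values = values,
                 metadata = metadata),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("Abundance table: %d time points x %d taxa\n",
              length(x$times), length(x$taxa)))
  cat(sprintf("  time range: [%g, %g]%s\n", min(x$times), max(x$times),
              if (is_regular_grid(x$times)) " (regular)" else " (irregular)"))
  cat("  taxa:", paste(utils::head(x$taxa, 8), collapse = ", "),
      if (length(x$taxa) > 8) "..." else "", "\n")
  invisible(x)
}

#' Per-taxon summary statistics
#'
#' Mean, median, min, max and fraction of exactly-zero entries for every taxon,
#' across all sampled time points.
#'
#' @param object An [abundance_table].
#' @param ... Unused.
#' @return A data frame with one row per taxon and columns `taxon`, `mean`,
#'   `median`, `min`, `max`, `zero_fraction`.
#' @export
summary.abundance_table <- function(object, ...) {
  v <- object$values
  data.frame(
    taxon = object$taxa,
    mean = colMeans(v),
    median = apply(v, 2, stats::median),
    min = apply(v, 2, min),
    max = apply(v, 2, max),
    zero_fraction = colMeans(v == 0),
    row.names = NULL
  )
}

#' @export
plot.abundance_table <- function(x, taxa = x$taxa, log = FALSE, ...) {
  v <- x$values[, taxa, drop = FALSE]
  if (log) v <- log1p(v)
  graphics::matplot(x$times, v, type = "l", lty = 1, xlab = "time",
                    ylab = if (log) "log(1 + abundance)" else "abundance", ...)
  graphics::legend("topright", legend = taxa, lty = 1,
                   col = seq_along(taxa), cex = 0.7)
  invisible(x)
}

#' Subset an abundance table
#'
#' @param x An [abundance_table].
#' @param taxa Character vector of taxa to keep (original order preserved
#'   as given).
#' @param rows Integer indices of time points to keep.
#' @return An [abundance_table].
#' @export
subset_table <- function(x, taxa = x$taxa, rows = seq_along(x$times)) {
  missing <- setdiff(taxa, x$taxa)
  if (length(missing)) {
    abort_validation(paste0("taxa not present in table: ",
                            paste(missing, collapse = ", ")))
  }
  abundance_table(x$times[rows],
                  x$values[rows, taxa, drop = FALSE],
                  taxa = taxa,
                  metadata = if (!is.null(x$metadata)) x$metadata[rows])
}

is_regular_grid <- function(times, tol = 1e-8) {
  if (length(times) < 3) return(TRUE)
  d <- diff(times)
  max(abs(d - d[1])) <= tol * max(abs(d[1]), 1)
}
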