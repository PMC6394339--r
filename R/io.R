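# File formats: everything is tab-separated UTF-8 text with a mandatory header
# row and '.' as the decimal separator. Lines starting with '#' are comments
# (the synthetic generator records its seed that way). Readers never silently
# drop rows or columns.

#' Read a taxa abundance time series from a TSV file
#'
#' The file must be tab-separated with a header row: one numeric column of
#' sampling times (named `"Time"` by default) and one numeric column per
#' taxon. Rows may appear in any order; they are sorted by time. Negative,
#' missing or non-finite abundances are rejected.
#'
#' @param path Path to the TSV file.
#' @param time_column Name (or 1-based index) of the sampling-time column.
#' @return An [abundance_table].
#' @export
read_abundance_table <- function(path, time_column = "Time") {
  if (!file.exists(path)) abort_io(paste0("file not found: ", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) abort_format("abundance file needs a time column and at least one taxon column")
  if (is.character(time_column)) {
    tc <- match(time_column, trimws(names(df)))
    if (is.na(tc)) {
      abort_format(sprintf("time column '%s' not found (columns: %s)",
                           time_column, paste(names(df), collapse = ", ")))
    }
  } else {
    tc <- as.integer(time_column)
    if (tc < 1 || tc > ncol(df)) abort_format("time column index out of range")
  }
  times <- df[[tc]]
  if (!is.numeric(times)) abort_format("time column is not numeric")
  vals <- df[, -tc, drop = FALSE]
  names(vals) <- names(df)[-tc]  # `[.data.frame` mangles duplicated names
  nonnum <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(nonnum)) {
    abort_format(paste0("non-numeric abundance columns: ",
                        paste(nonnum, collapse = ", ")))
  }
  abundance_table(times, as.matrix(vals))
}

#' Read per-time-point metadata labels
#'
#' Two-column TSV (time, label) matching the sampling times of an abundance
#' table; labels are attached to the table's time points.
#'
#' @param table An [abundance_table].
#' @param path Path to the metadata TSV.
#' @param time_column Name of the time column in the metadata file.
#' @return The table with `metadata` filled in.
#' @export
read_metadata <- function(table, path, time_column = "Time") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) abort_format("metadata file needs a time column and a label column")
  tc <- match(time_column, trimws(names(df)))
  if (is.na(tc)) abort_format(sprintf("time column '%s' not found in metadata", time_column))
  idx <- match(table$times, df[[tc]])
  if (anyNA(idx)) {
    abort_validation(sprintf("metadata missing %d of %d time points",
                             sum(is.na(idx)), length(table$times)))
  }
  table$metadata <- as.character(df[[setdiff(seq_len(ncol(df)), tc)[1]]])[idx]
  table
}

#' Write an abundance table or simulated trajectory to TSV
#'
#' Writes a `Time` column plus one column per taxon at full double precision,
#' so that [read_abundance_table()] round-trips the object.
#'
#' @param x An [abundance_table] or `glv_trajectory`.
#' @param path Output file path.
#' @param comment Optional comment line(s) written as a `#`-prefixed header.
#' @export
write_trajectory <- function(x, path, comment = NULL) {
  if (length(x$taxa) == 0L) abort_validation("cannot write a table with no taxa")
  con <- tryCatch(file(path, "w"), error = function(e) abort_io(conditionMessage(e)),
                  warning = function(w) abort_io(conditionMessage(w)))
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("Time", x$taxa), collapse = "\t"), con)
  rows <- cbind(format_full(x$times),
                matrix(format_full(x$values), nrow = length(x$times)))
  writeLines(apply(rows, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
write_abundance_table <- write_trajectory

#' Read growth-rate and interaction files into a gLV model
#'
#' The growth-rate file is a two-column TSV (taxon, rate); the interaction
#' file is an n-by-n TSV matrix with matching row and column taxon headers.
#' Taxon order is taken from the growth-rate file and the interaction matrix
#' is reordered to match.
#'
#' @param growth_path Path to the growth-rate TSV.
#' @param interaction_path Path to the interaction-matrix TSV.
#' @return A [glv_model] with `method_tag = "user_supplied"`.
#' @export
read_model_files <- function(growth_path, interaction_path) {
  g <- utils::read.delim(growth_path, header = TRUE, sep = "\t",
                         comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(g) < 2) abort_format("growth-rate file must have taxon and rate columns")
  taxa <- trimws(as.character(g[[1]]))
  r <- g[[2]]
  if (!is.numeric(r)) abort_format("growth rates are not numeric")
  m <- utils::read.delim(interaction_path, header = TRUE, sep = "\t",
                         comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE, row.names = 1)
  rn <- trimws(rownames(m)); cn <- trimws(colnames(m))
  if (nrow(m) != ncol(m)) abort_format("interaction matrix is not square")
  mism <- c(setdiff(taxa, rn), setdiff(rn, taxa), setdiff(taxa, cn), setdiff(cn, taxa))
  if (length(mism)) {
    abort_validation(paste0("taxon sets differ between growth and interaction files: ",
                            paste(sort(unique(mism)), collapse = ", ")))
  }
  A <- as.matrix(m)[match(taxa, rn), match(taxa, cn), drop = FALSE]
  storage.mode(A) <- "double"
  glv_model(taxa = taxa, growth_rates = r, interactions = A,
            method_tag = "user_supplied")
}

#' Write a gLV model to growth-rate and interaction files
#'
#' Inverse of [read_model_files()]: values are written at full double
#' precision so the round-trip reproduces the model exactly.
#'
#' @param model A [glv_model].
#' @param growth_path,interaction_path Output paths.
#' @export
write_model_files <- function(model, growth_path, interaction_path) {
  con <- tryCatch(file(growth_path, "w"),
                  error = function(e) abort_io(conditionMessage(e)),
                  warning = function(w) abort_io(conditionMessage(w)))
  writeLines(c("Taxon\tGrowthRate",
               paste(model$taxa, format_full(model$growth_rates), sep = "\t")), con)
  close(con)
  con <- tryCatch(file(interaction_path, "w"),
                  error = function(e) abort_io(conditionMessage(e)),
                  warning = function(w) abort_io(conditionMessage(w)))
  on.exit(close(con))
  writeLines(paste(c("Taxon", model$taxa), collapse = "\t"), con)
  rows <- cbind(model$taxa,
                matrix(format_full(model$interactions), nrow = length(model$taxa)))
  writeLines(apply(rows, 1, paste, collapse = "\t"), con)
  invisible(growth_path)
}
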