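# Input-data exploration: core-taxa filter, Pearson correlation network,
# moving-average smoothing. These operate on raw abundances and are
# visualization/selection aids only — smoothing is never applied before
# parameter estimation.

#' Core taxa of a longitudinal table
#'
#' Core taxa are those detected (nonzero) in most sampled time points:
#' a taxon is core when its fraction of exactly-zero entries is strictly
#' below `max_zero_fraction` (default 0.3, i.e. fewer than 30% zeroes).
#'
#' @param table An [abundance_table].
#' @param max_zero_fraction Exclusive upper bound on the zero fraction.
#' @return Character vector of core taxon names (input order).
#' @examples
#' tab <- abundance_table(1:10, cbind(A = rep(1, 10),
#'                                    B = c(rep(0, 3), rep(1, 7))))
#' core_taxa(tab)  # B has exactly 30% zeros -> excluded
#' @export
core_taxa <- function(table, max_zero_fraction = 0.3) {
  zf <- colMeans(table$values == 0)
  table$taxa[zf < max_zero_fraction]
}

#' Pearson correlation network over core taxa
#'
#' Builds the undirected taxon co-occurrence network: nodes are the core
#' taxa, and an edge joins two taxa when the Pearson correlation of their
#' raw abundance series across all time points reaches the thresholds
#' (`r >= 0.5` or `r <= -0.5` by default). Pairs in which either series is
#' constant have undefined correlation and yield no edge (with a warning).
#'
#' @param table An [abundance_table] with at least 3 time points.
#' @param pos_threshold Minimum positive correlation kept (`> 0`).
#' @param neg_threshold Maximum negative correlation kept (`< 0`).
#' @param max_zero_fraction Passed to [core_taxa()].
#' @return An object of class `glv_network`: list with `nodes` (core taxa)
#'   and `edges` (data frame `from`, `to`, `pearson_r`, with `from < to`
#'   lexicographically).
#' @export
correlation_network <- function(table, pos_threshold = 0.5,
                                neg_threshold = -0.5,
                                max_zero_fraction = 0.3) {
  if (length(table$times) < 3) {
    abort_validation("correlation network needs at least 3 time points")
  }
  if (!(neg_threshold < 0 && pos_threshold > 0)) {
    abort_validation("thresholds must satisfy neg_threshold < 0 < pos_threshold")
  }
  nodes <- core_taxa(table, max_zero_fraction)
  edges <- data.frame(from = character(), to = character(),
                      pearson_r = numeric())
  n_const_pairs <- 0L
  if (length(nodes) >= 2) {
    v <- table$values[, nodes, drop = FALSE]
    sds <- apply(v, 2, stats::sd)
    for (i in 1:(length(nodes) - 1)) {
      for (j in (i + 1):length(nodes)) {
        if (sds[i] == 0 || sds[j] == 0) { n_const_pairs <- n_const_pairs + 1L; next }
        r <- stats::cor(v[, i], v[, j])
        if (r >= pos_threshold || r <= neg_threshold) {
          pair <- sort(c(nodes[i], nodes[j]))
          edges <- rbind(edges, data.frame(from = pair[1], to = pair[2],
                                           pearson_r = r))
        }
      }
    }
  }
  if (n_const_pairs > 0) {
    warning(sprintf("%d pair(s) skipped: constant series have undefined correlation",
                    n_const_pairs), call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "glv_network")
}

#' @export
print.glv_network <- function(x, ...) {
  cat(sprintf("Correlation network: %d core taxa, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) print(transform(x$edges, pearson_r = round(pearson_r, 3)))
  invisible(x)
}

#' Write a correlation network as a TSV edge list or GraphML
#'
#' @param network A `glv_network`.
#' @param path Output path.
#' @param format `"tsv"` (edge list: source, target, pearson_r) or
#'   `"graphml"`.
#' @export
write_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    lines <- c("source\ttarget\tpearson_r",
               if (nrow(network$edges))
                 paste(network$edges$from, network$edges$to,
                       format_full(network$edges$pearson_r), sep = "\t"))
    writeLines(lines, path)
  } else {
    g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                       vertices = data.frame(name = network$nodes))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Centered moving-average smoothing
#'
#' Mean over a centered window of odd width; near the boundaries the window
#' is truncated to the available points, and `window = 1` is the identity.
#' Intended for trend visualisation only.
#'
#' @param x Numeric series.
#' @param window Odd positive integer window width.
#' @return Smoothed series of the same length.
#' @examples
#' moving_average(c(0, 3, 0), 3)  # 1.5 1.0 1.5
#' @export
moving_average <- function(x, window) {
  if (length(window) != 1L || !is.finite(window) || window < 1 ||
      window != round(window) || window %% 2 == 0) {
    abort_validation("window must be an odd integer >= 1")
  }
  if (window == 1) return(as.numeric(x))
  h <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}
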