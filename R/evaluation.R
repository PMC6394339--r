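#' Dynamic time warping distance between two series
#'
#' Plain unconstrained DTW with absolute-difference local cost: the
#' dynamic-programming matrix is initialised with
#' `M[1,1] = |a[1] - b[1]|`, filled with
#' `M[i,j] = |a[i] - b[j]| + min(M[i-1,j], M[i-1,j-1], M[i,j-1])`,
#' and the distance is the final cell `M[m,n]`. Both endpoints are anchored
#' (the warping path runs from `(1,1)` to `(m,n)`); series of unequal length
#' are handled naturally. No warping window or step weighting is applied.
#'
#' @param a,b Non-empty finite numeric series.
#' @return The DTW distance (nonnegative scalar).
#' @examples
#' dtw_distance(c(1, 3), c(2, 2))        # 2
#' dtw_distance(1:3, c(1, 2, 2, 3))      # 0: the repeat is absorbed
#' @export
dtw_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) abort_validation("series must be non-empty")
  if (any(!is.finite(a)) || any(!is.finite(b))) abort_validation("series must be finite")
  m <- length(a); n <- length(b)
  cost <- abs(outer(a, b, "-"))
  D <- matrix(0, m, n)
  D[, 1] <- cumsum(cost[, 1])
  D[1, ] <- cumsum(cost[1, ])
  if (m > 1 && n > 1) {
    for (i in 2:m) {
      for (j in 2:n) {
        D[i, j] <- cost[i, j] + min(D[i - 1L, j], D[i - 1L, j - 1L], D[i, j - 1L])
      }
    }
  }
  D[m, n]
}

#' Min-max scale a series to the unit interval
#'
#' `(x - min) / (max - min)`; a constant series (zero range) maps to all
#' zeros, preserving its flat shape without dividing by zero.
#'
#' @param x Non-empty finite numeric series.
#' @return Series rescaled to `[0, 1]`.
#' @examples
#' scale01(c(2, 4, 6))  # 0.0 0.5 1.0
#' @export
scale01 <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L) abort_validation("series must be non-empty")
  if (any(!is.finite(x))) abort_validation("series must be finite")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' All-vs-all DTW distance matrix over the taxa of a table
#'
#' Each taxon's series is min-max scaled before the pairwise DTW
#' computation (set `scale = FALSE` for raw-scale distances).
#'
#' @param x An [abundance_table] (or `glv_trajectory`).
#' @param scale Min-max scale each series first (default `TRUE`).
#' @return Symmetric zero-diagonal distance matrix with taxon dimnames.
#' @export
dtw_distance_matrix <- function(x, scale = TRUE) {
  series <- lapply(seq_along(x$taxa), function(i) {
    s <- x$values[, i]
    if (scale) scale01(s) else s
  })
  n <- length(series)
  D <- matrix(0, n, n, dimnames = list(x$taxa, x$taxa))
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- dtw_distance(series[[i]], series[[j]])
      }
    }
  }
  D
}

#' Average-linkage dendrogram from a distance matrix
#'
#' Agglomerative clustering of a symmetric distance matrix. Labels are
#' ordered lexicographically before clustering so that ties are broken
#' deterministically (the lexicographically smallest pair merges first).
#'
#' @param dm Symmetric numeric distance matrix with labels as dimnames.
#' @param linkage `"average"` (UPGMA, default), `"complete"` or `"single"`.
#' @return An [stats::hclust] tree.
#' @export
hierarchical_cluster <- function(dm, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  dm <- as.matrix(dm)
  if (nrow(dm) < 2) abort_validation("clustering needs at least 2 labels")
  if (is.null(rownames(dm))) abort_validation("distance matrix must carry labels")
  if (max(abs(dm - t(dm))) > 1e-12 || any(diag(dm) != 0) || any(dm < 0)) {
    abort_validation("distance matrix must be symmetric, nonnegative, zero-diagonal")
  }
  ord <- order(rownames(dm))
  dm <- dm[ord, ord, drop = FALSE]
  stats::hclust(stats::as.dist(dm), method = linkage)
}

#' Serialize a dendrogram as a newick string or file
#'
#' Merge heights become branch lengths (via [ape::as.phylo()]); the leaf
#' ordering is the clustering's canonical order.
#'
#' @param hc An [stats::hclust] tree.
#' @param path Optional output path; when `NULL` the newick string is
#'   returned.
#' @return The newick string, invisibly when written to a file.
#' @export
write_dendrogram <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Score predicted against observed trajectories with DTW
#'
#' For each taxon shared by the two inputs, both series are min-max scaled
#' and their DTW distance computed (observed and predicted grids may have
#' different lengths). The cumulative score is the unweighted sum of the
#' per-taxon distances — the single number used to compare simulations.
#' All-vs-all DTW distance matrices within the observed and within the
#' predicted set, and their average-linkage dendrograms, summarise how well
#' the simulation reproduces the temporal community structure.
#'
#' @param observed An [abundance_table] restricted to the compared window.
#' @param predicted A `glv_trajectory` (or second table) with the same taxa
#'   (any order).
#' @param scale Min-max scale every series before DTW (default `TRUE`).
#' @return An object of class `dtw_report`: list with `per_taxon_distance`,
#'   `cumulative`, `observed_matrix`, `predicted_matrix`, `observed_tree`,
#'   `predicted_tree` (trees are `NULL` for fewer than 2 taxa).
#' @examples
#' tab <- abundance_table(0:3, cbind(A = c(1, 2, 4, 8), B = c(8, 4, 2, 1)))
#' rep <- compare_trajectories(tab, tab)
#' rep$cumulative  # identical inputs: 0
#' @export
compare_trajectories <- function(observed, predicted, scale = TRUE) {
  diff_taxa <- c(setdiff(observed$taxa, predicted$taxa),
                 setdiff(predicted$taxa, observed$taxa))
  if (length(diff_taxa)) {
    abort_validation(paste0("taxa differ between observed and predicted: ",
                            paste(sort(unique(diff_taxa)), collapse = ", ")))
  }
  taxa <- observed$taxa
  per <- vapply(taxa, function(tx) {
    o <- observed$values[, tx]
    p <- predicted$values[, tx]
    if (scale) { o <- scale01(o); p <- scale01(p) }
    dtw_distance(o, p)
  }, numeric(1))
  om <- dtw_distance_matrix(observed, scale = scale)
  pm <- dtw_distance_matrix(subset_table(predicted, taxa), scale = scale)
  ot <- if (length(taxa) >= 2) hierarchical_cluster(om) else NULL
  pt <- if (length(taxa) >= 2) hierarchical_cluster(pm) else NULL
  structure(list(per_taxon_distance = per, cumulative = sum(per),
                 observed_matrix = om, predicted_matrix = pm,
                 observed_tree = ot, predicted_tree = pt),
            class = "dtw_report")
}

#' @export
print.dtw_report <- function(x, ...) {
  cat("DTW evaluation of predicted vs observed trajectories\n")
  cat("  per-taxon distances (scaled series):\n")
  print(round(x$per_taxon_distance, 4))
  cat(sprintf("  cumulative DTW distance: %.4f\n", x$cumulative))
  invisible(x)
}

#' Write the per-taxon DTW table, distance matrices and dendrograms
#'
#' @param report A `dtw_report`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
write_dtw_report <- function(report, dir, prefix = "dtw") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  p <- file.path(dir, paste0(prefix, "_per_taxon.tsv"))
  df_lines <- c("Taxon\tDTW",
                paste(names(report$per_taxon_distance),
                      format_full(report$per_taxon_distance), sep = "\t"),
                paste("CUMULATIVE", format_full(report$cumulative), sep = "\t"))
  writeLines(df_lines, p); paths <- c(paths, p)
  for (which in c("observed", "predicted")) {
    m <- report[[paste0(which, "_matrix")]]
    p <- file.path(dir, paste0(prefix, "_", which, "_matrix.tsv"))
    lines <- c(paste(c("Taxon", colnames(m)), collapse = "\t"),
               apply(cbind(rownames(m), matrix(format_full(m), nrow(m))), 1,
                     paste, collapse = "\t"))
    writeLines(lines, p); paths <- c(paths, p)
    tr <- report[[paste0(which, "_tree")]]
    if (!is.null(tr)) {
      p <- file.path(dir, paste0(prefix, "_", which, "_tree.nwk"))
      write_dendrogram(tr, p); paths <- c(paths, p)
    }
  }
  invisible(paths)
}
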