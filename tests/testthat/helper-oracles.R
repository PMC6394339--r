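# Independent oracles and fixture builders shared across tests.

# --- exhaustive DTW oracle -------------------------------------------------
# All monotone warping paths from (1,1) to (m,n) with steps (1,0),(1,1),(0,1),
# enumerated recursively; the oracle distance is the minimum path cost. The
# path sets depend only on the grid shape, so they are cached per shape and
# stored as index matrices (padded with a zero-cost dummy index) for speed.
.path_cache <- new.env(parent = emptyenv())

enum_warping_paths <- function(m, n) {
  key <- paste(m, n)
  if (!is.null(.path_cache[[key]])) return(.path_cache[[key]])
  res <- list()
  rec <- function(path) {
    last <- path[[length(path)]]
    if (last[1] == m && last[2] == n) {
      res[[length(res) + 1L]] <<- do.call(rbind, path)
      return(invisible())
    }
    for (d in list(c(1L, 0L), c(1L, 1L), c(0L, 1L))) {
      nxt <- last + d
      if (nxt[1] <= m && nxt[2] <= n) rec(c(path, list(nxt)))
    }
  }
  rec(list(c(1L, 1L)))
  L <- max(vapply(res, nrow, 1L))
  P <- t(vapply(res, function(p) {
    lin <- as.integer((p[, 2] - 1L) * m + p[, 1])
    c(lin, rep.int(m * n + 1L, L - length(lin)))   # pad -> dummy zero cost
  }, integer(L)))
  .path_cache[[key]] <- P
  P
}

dtw_oracle <- function(a, b) {
  P <- enum_warping_paths(length(a), length(b))
  cv <- c(abs(outer(a, b, "-")), 0)
  min(rowSums(matrix(cv[P], nrow(P))))
}

# all integer series of length L over the given alphabet, one per row
all_int_series <- function(L, alphabet = 0:2) {
  as.matrix(do.call(expand.grid, rep(list(alphabet), L)))
}

# --- small fixture builders ------------------------------------------------
demo_table <- function() {
  abundance_table(0:4,
                  cbind(A = c(1, 2, 4, 6, 9),
                        B = c(9, 7, 5, 3, 2),
                        C = c(2, 3, 2.5, 3.5, 3)))
}

truth_matrix <- function(model) cbind(r = model$growth_rates, model$interactions)

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
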