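#' Per-FOV exact k-nearest-neighbor graph
#'
#' Builds the neighbor graph every spatial statistic in the package runs
#' on. Neighborhoods never cross FOV boundaries (each FOV is an
#' independently imaged tile; coordinates are only comparable within one),
#' the index cell is excluded from its own neighborhood, and distance ties
#' are broken deterministically by `cell_id`. FOVs with fewer than `k + 1`
#' cells yield truncated neighborhoods (all other cells), flagged per cell;
#' single-cell FOVs are excluded and recorded.
#'
#' @param cells validated cell table.
#' @param k number of neighbors (niche analysis conventionally uses 50,
#'   colocalization 20).
#' @return object of class `knn_graph`: list with `k`, `idx` (n x k global
#'   row indices, `NA`-padded), `dist` (matching Euclidean distances, μm,
#'   nondecreasing within rows), `n_neighbors`, `truncated`, `fov`,
#'   `cell_id`, `excluded_fovs`.
#' @export
build_knn <- function(cells, k = 50) {
  cells <- validate_cells(cells)
  .assert(k >= 1, "k must be >= 1")
  n <- nrow(cells)
  idx <- matrix(NA_integer_, n, k)
  dst <- matrix(NA_real_, n, k)
  n_neighbors <- integer(n)
  excluded <- character(0)
  for (f in unique(cells$fov_id)) {
    w <- which(cells$fov_id == f)
    if (length(w) < 2) {
      excluded <- c(excluded, f)
      next
    }
    res <- .knn_brute_cpp(cells$x_um[w], cells$y_um[w], as.integer(k),
                          as.integer(rank(cells$cell_id[w],
                                          ties.method = "first")))
    kk <- ncol(res$idx)
    idx[w, seq_len(kk)] <- w[res$idx]
    dst[w, seq_len(kk)] <- res$dist
    n_neighbors[w] <- kk
  }
  structure(list(k = k, idx = idx, dist = dst, n_neighbors = n_neighbors,
                 truncated = n_neighbors > 0 & n_neighbors < k,
                 fov = cells$fov_id, cell_id = cells$cell_id,
                 excluded_fovs = excluded),
            class = "knn_graph")
}

#' @export
print.knn_graph <- function(x, ...) {
  cat(sprintf("knn_graph: %d cells, k = %d, %d FOV(s)\n",
              length(x$fov), x$k, length(unique(x$fov))))
  if (any(x$truncated))
    cat(sprintf("  %d cell(s) with truncated neighborhoods\n",
                sum(x$truncated)))
  if (length(x$excluded_fovs))
    cat(sprintf("  excluded single-cell FOV(s): %s\n",
                paste(x$excluded_fovs, collapse = ", ")))
  invisible(x)
}

# counts of a given label among each cell's first `use_k` neighbors
.neighbor_type_count <- function(graph, labels, type, use_k = graph$k) {
  idx <- graph$idx[, seq_len(min(use_k, ncol(graph$idx))), drop = FALSE]
  lab <- labels[idx]
  dim(lab) <- dim(idx)
  rowSums(lab == type, na.rm = TRUE)
}
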