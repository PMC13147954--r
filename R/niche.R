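#' Neighborhood composition matrix
#'
#' Row i is the cell-type histogram of cell i's k nearest neighbors
#' divided by the number of neighbors actually available (the index cell is
#' excluded), so every row sums to 1. Cells in FOVs smaller than `k + 1`
#' use all available neighbors and are flagged via
#' `attr(, "truncated")`.
#'
#' @param graph `knn_graph` built with the niche neighborhood size
#'   (conventionally k = 50).
#' @param labels per-cell type labels aligned with the graph.
#' @return numeric matrix cells x types with `attr(,"truncated")`.
#' @export
neighborhood_composition <- function(graph, labels) {
  .assert(length(labels) == length(graph$fov),
          "labels length does not match graph")
  .assert(all(graph$n_neighbors > 0),
          "graph contains cells with no neighbors (single-cell FOVs): %s",
          paste(graph$excluded_fovs, collapse = ", "))
  types <- sort(unique(labels))
  comp <- matrix(0, length(labels), length(types),
                 dimnames = list(graph$cell_id, types))
  for (t in types)
    comp[, t] <- .neighbor_type_count(graph, labels, t) / graph$n_neighbors
  attr(comp, "truncated") <- graph$truncated
  comp
}

#' Cluster neighborhood compositions into spatial niches
#'
#' k-means (Euclidean) on the composition rows, best of `n_init` restarts
#' by within-cluster sum of squares; niche labels are renumbered by
#' decreasing cluster size so that numbering is stable across runs.
#'
#' @param composition matrix from [neighborhood_composition()].
#' @param K number of niches (the package default elsewhere is 9).
#' @param seed RNG seed.
#' @param n_init number of k-means restarts.
#' @return object of class `niche_assignment`: list with per-cell `labels`
#'   (integers 1..K), `K`, `centroids` (K x types), `sizes`, `inertia`.
#' @export
cluster_niches <- function(composition, K = 9, seed = 1, n_init = 10) {
  .assert(K >= 2, "K must be >= 2")
  .assert(K <= nrow(composition), "K (%d) exceeds number of cells (%d)",
          K, nrow(composition))
  fit <- .with_seed(seed,
    kmeans(composition, centers = K, nstart = n_init, iter.max = 100))
  ord <- order(tabulate(fit$cluster, K), decreasing = TRUE)
  relab <- integer(K)
  relab[ord] <- seq_len(K)
  labels <- relab[fit$cluster]
  structure(list(labels = labels, K = K,
                 centroids = fit$centers[ord, , drop = FALSE],
                 sizes = tabulate(labels, K),
                 inertia = fit$tot.withinss,
                 cell_id = rownames(composition)),
            class = "niche_assignment")
}

#' @export
print.niche_assignment <- function(x, ...) {
  cat(sprintf("niche_assignment: %d cells in %d niches (sizes %s)\n",
              length(x$labels), x$K, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Diagnostics for choosing the number of niches
#'
#' Computes the k-means inertia (elbow) and mean silhouette width for each
#' candidate K; the recommended K maximizes the silhouette. Silhouettes are
#' computed on a random subsample of at most `subsample` cells (the full
#' pairwise distance matrix is quadratic in cells).
#'
#' @inheritParams cluster_niches
#' @param k_range integer vector of candidate K values (all >= 2).
#' @param subsample silhouette subsample size.
#' @return data.frame(K, inertia, silhouette) with
#'   `attr(, "recommended")`.
#' @export
select_k <- function(composition, k_range = 2:12, seed = 1,
                     subsample = 2000) {
  .assert(length(k_range) > 0 && all(k_range >= 2),
          "k_range must be non-empty with all K >= 2")
  n <- nrow(composition)
  sub <- .with_seed(seed, sort(sample(n, min(subsample, n))))
  dsub <- stats::dist(composition[sub, , drop = FALSE])
  rows <- lapply(k_range, function(K) {
    fit <- cluster_niches(composition, K, seed = seed)
    sil <- cluster::silhouette(fit$labels[sub], dsub)
    data.frame(K = K, inertia = fit$inertia,
               silhouette = mean(sil[, "sil_width"]))
  })
  out <- do.call(rbind, rows)
  attr(out, "recommended") <- out$K[which.max(out$silhouette)]
  out
}

#' Niche enrichment by cell type or region
#'
#' Log2 observed/expected composition of each niche:
#' `entry(n, g) = log2(fraction of level-g cells within niche n /
#' marginal fraction of level g)`, with both fractions floored at the
#' pseudo-fraction `1 / (n_cells + 1)` to guard empty combinations.
#' Positive entries mean the level is over-represented in the niche.
#'
#' @param assignment `niche_assignment` (or an integer label vector).
#' @param grouping per-cell grouping labels (cell types or region labels).
#' @param zscore if `TRUE`, additionally row-standardize for heatmap use.
#' @return matrix niches x levels (log2 enrichment), with empty niches as
#'   `NA` rows flagged in `attr(, "empty_niches")`; the z-scored view in
#'   `attr(, "zscore")` when requested.
#' @export
niche_enrichment <- function(assignment, grouping, zscore = FALSE) {
  labels <- if (inherits(assignment, "niche_assignment"))
    assignment$labels else assignment
  .assert(length(labels) == length(grouping),
          "assignment and grouping lengths differ")
  n <- length(labels)
  K <- max(labels)
  pseudo <- 1 / (n + 1)
  tab <- table(factor(labels, levels = seq_len(K)), grouping)
  rs <- rowSums(tab)
  marg <- pmax(colSums(tab) / n, pseudo)
  E <- log2(pmax(sweep(unclass(tab), 1, pmax(rs, 1), "/"), pseudo) /
              rep(marg, each = K))
  rownames(E) <- paste0("niche", seq_len(K))
  empty <- rs == 0
  E[empty, ] <- NA_real_
  attr(E, "empty_niches") <- which(empty)
  if (zscore) {
    z <- t(scale(t(E)))
    attr(E, "zscore") <- z
  }
  E
}

#' Niche abundance per patient, region or FOV
#'
#' Fraction of each grouping unit's cells assigned to each niche; rows sum
#' to 1. Patient-level abundance is the covariate used for survival
#' dichotomization.
#'
#' @param assignment `niche_assignment` (or integer label vector).
#' @param cells aligned cell table.
#' @param level one of `"patient"`, `"region"`, `"fov"`.
#' @return matrix units x niches of fractions.
#' @export
niche_abundance <- function(assignment, cells, level = c("patient",
                                                         "region", "fov")) {
  level <- match.arg(level)
  labels <- if (inherits(assignment, "niche_assignment"))
    assignment$labels else assignment
  .assert(length(labels) == nrow(cells),
          "assignment and cells lengths differ")
  unit <- switch(level, patient = cells$patient_id, region = cells$region,
                 fov = cells$fov_id)
  K <- max(labels)
  tab <- table(unit, factor(labels, levels = seq_len(K)))
  ab <- unclass(tab) / rowSums(tab)
  colnames(ab) <- paste0("niche", seq_len(K))
  ab
}
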