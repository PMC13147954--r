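#' Flag reference cells spatially proximal to a target type
#'
#' Two predicates, both evaluated within the cell's own FOV:
#' \describe{
#'   \item{knn}{proximal iff at least one `target_type` cell appears among
#'     the `threshold` nearest neighbors (e.g. "within 50 spatial
#'     neighbors"); requires `graph` with `k >= threshold`.}
#'   \item{radius}{proximal iff at least one `target_type` cell lies within
#'     `threshold` micrometres (e.g. within 80 μm of a capillary).}
#' }
#'
#' @param cells validated cell table.
#' @param ref_type type whose cells are flagged.
#' @param target_type type whose presence defines proximity.
#' @param mode `"knn"` or `"radius"`.
#' @param threshold neighbor count (knn) or distance in μm (radius).
#' @param graph `knn_graph`, required for knn mode.
#' @return object of class `proximity_flags`: data.frame(cell_id, fov_id,
#'   region, proximal) over all `ref_type` cells, with mode/threshold/type
#'   metadata attached as attributes.
#' @export
proximity_flags <- function(cells, ref_type, target_type,
                            mode = c("knn", "radius"), threshold,
                            graph = NULL) {
  mode <- match.arg(mode)
  cells <- validate_cells(cells)
  .assert(ref_type %in% cells$cell_type,
          "ref_type '%s' absent from cells", ref_type)
  is_ref <- cells$cell_type == ref_type
  if (mode == "knn") {
    .assert(!is.null(graph), "knn mode requires a knn_graph")
    .assert(graph$k >= threshold,
            "graph k (%d) smaller than threshold (%d)", graph$k, threshold)
    .assert(threshold >= 1, "knn threshold must be >= 1")
    prox <- .neighbor_type_count(graph, cells$cell_type, target_type,
                                 use_k = threshold)[is_ref] > 0
  } else {
    .assert(is.numeric(threshold) && threshold > 0,
            "radius threshold must be a positive distance in um")
    prox <- rep(FALSE, sum(is_ref))
    ri <- which(is_ref)
    for (f in unique(cells$fov_id[is_ref])) {
      w <- ri[cells$fov_id[ri] == f]
      tg <- which(cells$fov_id == f & cells$cell_type == target_type)
      prox[match(w, ri)] <- .any_within_radius(
        cells$x_um[w], cells$y_um[w], cells$x_um[tg], cells$y_um[tg],
        threshold)
    }
  }
  out <- data.frame(cell_id = cells$cell_id[is_ref],
                    fov_id = cells$fov_id[is_ref],
                    region = cells$region[is_ref],
                    proximal = prox)
  attr(out, "mode") <- mode
  attr(out, "threshold") <- threshold
  attr(out, "ref_type") <- ref_type
  attr(out, "target_type") <- target_type
  class(out) <- c("proximity_flags", "data.frame")
  out
}

# Vectorized two-sided Wilcoxon rank-sum with normal approximation,
# tie correction and continuity correction, matching
# wilcox.test(exact = FALSE, correct = TRUE). Returns W (group-1 U
# statistic) and p per row of X; rows where the statistic is degenerate
# (all values tied) get p = 1.
.ranksum_rows <- function(X, idx1, idx2) {
  X <- as.matrix(X)
  n1 <- length(idx1)
  n2 <- length(idx2)
  nn <- n1 + n2
  sub <- X[, c(idx1, idx2), drop = FALSE]
  W <- numeric(nrow(sub))
  p <- numeric(nrow(sub))
  for (g in seq_len(nrow(sub))) {
    r <- rank(sub[g, ])
    w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    nt <- table(r)
    sigma <- sqrt((n1 * n2 / 12) *
                    ((nn + 1) - sum(nt^3 - nt) / (nn * (nn - 1))))
    z <- w - n1 * n2 / 2
    if (sigma == 0 || z == 0) {
      W[g] <- w; p[g] <- 1
    } else {
      zz <- (z - sign(z) * 0.5) / sigma
      W[g] <- w
      p[g] <- min(1, 2 * pnorm(-abs(zz)))
    }
  }
  list(W = W, p = p)
}

.wilcox_de_table <- function(normalized, idx1, idx2, label1, label2,
                             gene_subset = NULL, min_group = 20) {
  .assert(length(idx1) >= 2 && length(idx2) >= 2,
          "need >= 2 cells per group (got %d %s, %d %s)",
          length(idx1), label1, length(idx2), label2)
  genes <- rownames(normalized)
  if (!is.null(gene_subset)) {
    miss <- setdiff(gene_subset, genes)
    .assert(length(miss) == 0, "gene(s) absent from matrix: %s",
            paste(miss[1:min(3, length(miss))], collapse = ", "))
    genes <- gene_subset
  }
  X <- normalized[genes, , drop = FALSE]
  ts <- .ranksum_rows(X, idx1, idx2)
  m1 <- Matrix::rowMeans(X[, idx1, drop = FALSE])
  m2 <- Matrix::rowMeans(X[, idx2, drop = FALSE])
  out <- data.frame(gene = genes,
                    mean_group1 = as.numeric(m1),
                    mean_group2 = as.numeric(m2),
                    log2fc = log2((m1 + 1e-9) / (m2 + 1e-9)),
                    statistic = ts$W, p = ts$p,
                    q = p.adjust(ts$p, "BH"),
                    row.names = NULL)
  names(out)[2:3] <- paste0("mean_", c(label1, label2))
  attr(out, "groups") <- setNames(c(length(idx1), length(idx2)),
                                  c(label1, label2))
  attr(out, "small_groups") <- min(length(idx1), length(idx2)) < min_group
  out
}

#' Differential expression between proximal and distal reference cells
#'
#' Per-gene two-sided Wilcoxon rank-sum test on the normalized expression
#' of the reference cells, proximal vs distal to the target type, with
#' Benjamini-Hochberg adjustment across the tested genes. Log2 fold changes
#' are of group means (pseudo 1e-9). Groups smaller than 20 cells are
#' flagged via `attr(, "small_groups")`.
#'
#' @param normalized normalized gene x cell matrix (see
#'   [normalize_counts()]), columns named by cell_id.
#' @param flags `proximity_flags` for the reference type.
#' @param gene_subset optional character vector of genes to test.
#' @return data.frame(gene, mean_proximal, mean_distal, log2fc, statistic,
#'   p, q).
#' @export
proximity_de <- function(normalized, flags, gene_subset = NULL) {
  .assert(inherits(flags, "proximity_flags"),
          "flags must come from proximity_flags()")
  col <- match(flags$cell_id, colnames(normalized))
  .assert(!anyNA(col), "flagged cell(s) absent from normalized matrix")
  i1 <- col[flags$proximal]
  i2 <- col[!flags$proximal]
  .assert(length(i1) > 0 && length(i2) > 0,
          "one group is empty (proximal n = %d, distal n = %d)",
          length(i1), length(i2))
  .wilcox_de_table(normalized, i1, i2, "proximal", "distal", gene_subset)
}

#' Fraction of target cells proximal to a reference, by region
#'
#' Computes, per tissue region, the proportion of cells carrying a
#' proximity flag (e.g. the share of mCAFs lying within 80 μm of a
#' capillary) plus pairwise two-proportion tests between regions.
#'
#' @param flags `proximity_flags` computed with the population of interest
#'   as `ref_type`.
#' @return list with `fractions` data.frame(region, n, n_proximal,
#'   fraction) and `tests` data.frame(region1, region2, p) from
#'   `prop.test`.
#' @export
proximal_fraction <- function(flags) {
  .assert(inherits(flags, "proximity_flags"),
          "flags must come from proximity_flags()")
  regs <- intersect(REGION_LEVELS, unique(flags$region))
  fr <- do.call(rbind, lapply(regs, function(r) {
    w <- flags$region == r
    data.frame(region = r, n = sum(w), n_proximal = sum(flags$proximal[w]),
               fraction = mean(flags$proximal[w]))
  }))
  pairs <- if (length(regs) >= 2) utils::combn(regs, 2) else NULL
  tests <- NULL
  if (!is.null(pairs)) {
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- fr[fr$region == pairs[1, j], ]
      b <- fr[fr$region == pairs[2, j], ]
      p <- tryCatch(suppressWarnings(
        stats::prop.test(c(a$n_proximal, b$n_proximal),
                         c(a$n, b$n))$p.value),
        error = function(e) NA_real_)
      data.frame(region1 = pairs[1, j], region2 = pairs[2, j], p = p)
    }))
  }
  list(fractions = fr, tests = tests)
}
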