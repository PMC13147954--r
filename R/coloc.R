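#' Colocalization quotient between two cell types
#'
#' The colocalization quotient (CLQ) measures the ratio of observed to
#' expected spatial co-occurrence of type `B` around type `A`. Within one
#' FOV of `N` cells,
#' \deqn{CLQ_{A \to B} = \frac{\frac{1}{N_A}\sum_{i \in A} n_{i,B}/k_i}
#'   {N'_B / (N - 1)}}
#' where \eqn{n_{i,B}} counts type-B cells among cell i's \eqn{k_i} nearest
#' neighbors and \eqn{N'_B = N_B - 1} when `A == B` (the index cell cannot
#' be its own neighbor), else \eqn{N_B}. A value of 1 indicates no spatial
#' association, larger values colocalization, smaller values segregation.
#'
#' FOVs with no A cells (or \eqn{N'_B \le 0}) are scored `NA` and excluded
#' from pooling; the pooled CLQ is the mean of per-FOV values weighted by
#' the number of A cells, i.e. the mean of all local CLQs.
#'
#' @param graph `knn_graph` from [build_knn()].
#' @param labels per-cell type labels aligned with the graph.
#' @param A,B cell-type labels (reference and target).
#' @return object of class `clq_result`: list with `A`, `B`, `per_fov`
#'   (fov, clq, n_A, n_B, N), `pooled`, `local` (cell_id, fov, local_clq
#'   for every A cell), `n_null_fovs`.
#' @export
clq_pair <- function(graph, labels, A, B) {
  .assert(length(labels) == length(graph$fov),
          "labels length (%d) does not match graph (%d cells)",
          length(labels), length(graph$fov))
  .assert(A %in% labels, "reference type '%s' absent from labels", A)
  .assert(B %in% labels, "target type '%s' absent from labels", B)
  res <- .clq_stat(graph, labels, A, B, detail = TRUE)
  structure(c(list(A = A, B = B), res), class = "clq_result")
}

.clq_stat <- function(graph, labels, A, B, detail = FALSE) {
  nb_B <- .neighbor_type_count(graph, labels, B)
  fovs <- unique(graph$fov)
  per <- vector("list", length(fovs))
  local_all <- if (detail) vector("list", length(fovs)) else NULL
  for (q in seq_along(fovs)) {
    w <- which(graph$fov == fovs[q])
    N <- length(w)
    isA <- labels[w] == A
    n_A <- sum(isA)
    n_B <- sum(labels[w] == B)
    n_Bp <- n_B - (A == B)
    if (n_A == 0 || n_Bp <= 0 || N < 2 || all(graph$n_neighbors[w] == 0)) {
      per[[q]] <- data.frame(fov = fovs[q], clq = NA_real_, n_A = n_A,
                             n_B = n_B, N = N)
      next
    }
    wa <- w[isA]
    local <- (nb_B[wa] / graph$n_neighbors[wa]) / (n_Bp / (N - 1))
    per[[q]] <- data.frame(fov = fovs[q], clq = mean(local), n_A = n_A,
                           n_B = n_B, N = N)
    if (detail)
      local_all[[q]] <- data.frame(cell_id = graph$cell_id[wa],
                                   fov = fovs[q], local_clq = local)
  }
  per_fov <- do.call(rbind, per)
  ok <- !is.na(per_fov$clq)
  pooled <- if (any(ok)) {
    weighted.mean(per_fov$clq[ok], per_fov$n_A[ok])
  } else NA_real_
  out <- list(per_fov = per_fov, pooled = pooled,
              n_null_fovs = sum(!ok))
  if (detail) out$local <- do.call(rbind, local_all)
  out
}

#' @export
print.clq_result <- function(x, ...) {
  cat(sprintf("CLQ %s -> %s: pooled = %.4f over %d FOV(s) (%d null)\n",
              x$A, x$B, x$pooled, nrow(x$per_fov), x$n_null_fovs))
  invisible(x)
}

#' Per-FOV CLQ of a reference type against every other type
#'
#' Long-format table suited to density plots of per-FOV CLQ values, one
#' distribution per partner type (the classic view of which lineages a
#' reference population, e.g. malignant cells, colocalizes with).
#'
#' @inheritParams clq_pair
#' @param cells validated cell table aligned with `graph`.
#' @param reference_type the reference (A) type.
#' @return data.frame(fov, other_type, clq) with null FOVs dropped; the
#'   number dropped per type is in `attr(, "n_null")`.
#' @export
clq_density <- function(cells, graph, labels = cells$cell_type,
                        reference_type) {
  .assert(reference_type %in% labels,
          "reference type '%s' absent", reference_type)
  others <- setdiff(sort(unique(labels)), reference_type)
  out <- vector("list", length(others))
  n_null <- setNames(integer(length(others)), others)
  for (q in seq_along(others)) {
    s <- .clq_stat(graph, labels, reference_type, others[q])
    keep <- !is.na(s$per_fov$clq)
    out[[q]] <- data.frame(fov = s$per_fov$fov[keep],
                           other_type = others[q],
                           clq = s$per_fov$clq[keep])
    n_null[q] <- s$n_null_fovs
  }
  res <- do.call(rbind, out)
  attr(res, "n_null") <- n_null
  res
}

#' Permutation test for a CLQ pair
#'
#' Shuffles cell-type labels within each FOV (coordinates fixed), which
#' preserves the point pattern and per-FOV type abundances while breaking
#' any label-location association. Two-sided p-value on the pooled CLQ's
#' deviation from 1: `p = (1 + #{|CLQ* - 1| >= |CLQ - 1|}) / (n_perm + 1)`.
#'
#' @inheritParams clq_pair
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed.
#' @return list(clq, p_value, n_perm).
#' @export
clq_permutation <- function(graph, labels, A, B, n_perm = 199, seed = 1) {
  .assert(n_perm >= 99, "n_perm must be >= 99")
  .assert(length(unique(labels)) >= 2,
          "label vector is degenerate (single type)")
  obs <- .clq_stat(graph, labels, A, B)$pooled
  .assert(is.finite(obs), "observed CLQ undefined on every FOV")
  stat <- abs(obs - 1)
  exceed <- 0L
  .with_seed(seed, {
    for (r in seq_len(n_perm)) {
      perm <- as.character(ave(labels, graph$fov, FUN = sample))
      s <- .clq_stat(graph, perm, A, B)$pooled
      if (is.finite(s) && abs(s - 1) >= stat) exceed <- exceed + 1L
    }
  })
  list(clq = obs, p_value = (1 + exceed) / (n_perm + 1), n_perm = n_perm)
}
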