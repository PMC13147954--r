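#' Range-gated ligand-receptor interaction score
#'
#' Mass-action communication score restricted to biologically feasible
#' distances. Within each FOV, eligible receivers are `receiver` cells with
#' at least one `sender` cell within `range_um`; eligible senders are
#' `sender` cells within `range_um` of at least one eligible receiver.
#' With \eqn{\bar L} the 10\%-trimmed mean ligand expression over eligible
#' senders and \eqn{\bar R} the 10\%-trimmed mean receptor expression over
#' eligible receivers, the score is the Hill-type saturation
#' \deqn{score = \bar L \bar R / (K_h + \bar L \bar R) \in [0, 1)}
#' which is 0 iff \eqn{\bar L \bar R = 0} and 0.5 at half-saturation
#' \eqn{\bar L \bar R = K_h}. Sensible defaults for `range_um` are ~30 μm
#' for contact-dependent ligands and ~80 μm for diffusible ones.
#'
#' @param normalized normalized gene x cell matrix, columns named by
#'   cell_id.
#' @param cells validated cell table aligned with the matrix columns.
#' @param ligand,receptor gene names.
#' @param sender,receiver cell-type labels.
#' @param range_um interaction range in micrometres.
#' @param Kh half-saturation constant (> 0).
#' @param trim trimming fraction for the means.
#' @return object of class `lr_score`: list with `per_fov`
#'   data.frame(fov_id, n_senders, n_receivers, L_bar, R_bar, score; `NA`
#'   score when a FOV has no eligible pair) and `pooled` (same statistics
#'   over all eligible cells pooled across FOVs).
#' @export
lr_score <- function(normalized, cells, ligand, receptor, sender, receiver,
                     range_um = 80, Kh = 0.5, trim = 0.1) {
  cells <- validate_cells(cells)
  .assert(range_um > 0, "range_um must be > 0")
  .assert(Kh > 0, "Kh must be > 0")
  for (g in c(ligand, receptor))
    .assert(g %in% rownames(normalized), "gene '%s' absent from matrix", g)
  col <- match(cells$cell_id, colnames(normalized))
  .assert(!anyNA(col), "cells absent from normalized matrix")
  lig <- as.numeric(normalized[ligand, col])
  rec <- as.numeric(normalized[receptor, col])
  fovs <- unique(cells$fov_id)
  per <- vector("list", length(fovs))
  es_all <- rs_all <- integer(0)
  for (q in seq_along(fovs)) {
    w <- which(cells$fov_id == fovs[q])
    sn <- w[cells$cell_type[w] == sender]
    rc <- w[cells$cell_type[w] == receiver]
    elig <- .eligible_pairs(cells$x_um, cells$y_um, sn, rc, range_um)
    if (length(elig$receivers) == 0) {
      per[[q]] <- data.frame(fov_id = fovs[q], n_senders = 0L,
                             n_receivers = 0L, L_bar = NA_real_,
                             R_bar = NA_real_, score = NA_real_)
      next
    }
    L <- mean(lig[elig$senders], trim = trim)
    R <- mean(rec[elig$receivers], trim = trim)
    per[[q]] <- data.frame(fov_id = fovs[q],
                           n_senders = length(elig$senders),
                           n_receivers = length(elig$receivers),
                           L_bar = L, R_bar = R,
                           score = L * R / (Kh + L * R))
    es_all <- c(es_all, elig$senders)
    rs_all <- c(rs_all, elig$receivers)
  }
  pooled <- if (length(rs_all)) {
    L <- mean(lig[es_all], trim = trim)
    R <- mean(rec[rs_all], trim = trim)
    list(L_bar = L, R_bar = R, score = L * R / (Kh + L * R),
         n_senders = length(es_all), n_receivers = length(rs_all))
  } else {
    list(L_bar = NA_real_, R_bar = NA_real_, score = NA_real_,
         n_senders = 0L, n_receivers = 0L)
  }
  structure(list(ligand = ligand, receptor = receptor, sender = sender,
                 receiver = receiver, range_um = range_um, Kh = Kh,
                 per_fov = do.call(rbind, per), pooled = pooled),
            class = "lr_score")
}

# indices of eligible senders/receivers for one FOV (global indices)
.eligible_pairs <- function(x, y, sn, rc, range_um) {
  if (length(sn) == 0 || length(rc) == 0)
    return(list(senders = integer(0), receivers = integer(0)))
  er <- rc[.any_within_radius(x[rc], y[rc], x[sn], y[sn], range_um)]
  if (length(er) == 0)
    return(list(senders = integer(0), receivers = integer(0)))
  es <- sn[.any_within_radius(x[sn], y[sn], x[er], y[er], range_um)]
  list(senders = es, receivers = er)
}

#' @export
print.lr_score <- function(x, ...) {
  cat(sprintf("LR score %s (%s) -> %s (%s), range %g um: pooled = %s\n",
              x$ligand, x$sender, x$receptor, x$receiver, x$range_um,
              format(x$pooled$score, digits = 4)))
  invisible(x)
}

#' Permutation test for a ligand-receptor score
#'
#' Shuffles cell-type labels within each FOV (coordinates and expression
#' fixed) and recomputes the pooled range-gated score; one-sided
#' `p = (1 + #{score* >= score}) / (n_perm + 1)`.
#'
#' @inheritParams lr_score
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed.
#' @return list(score, p_value, n_perm).
#' @export
lr_permutation <- function(normalized, cells, ligand, receptor, sender,
                           receiver, range_um = 80, Kh = 0.5, trim = 0.1,
                           n_perm = 199, seed = 1) {
  .assert(n_perm >= 99, "n_perm must be >= 99")
  cells <- validate_cells(cells)
  .assert(length(unique(cells$cell_type)) >= 2,
          "cell_type vector is degenerate (single type)")
  obs <- lr_score(normalized, cells, ligand, receptor, sender, receiver,
                  range_um, Kh, trim)$pooled$score
  .assert(is.finite(obs), "observed score undefined (no eligible pairs)")
  exceed <- 0L
  .with_seed(seed, {
    for (r in seq_len(n_perm)) {
      perm <- cells
      perm$cell_type <- as.character(ave(cells$cell_type, cells$fov_id,
                                         FUN = sample))
      s <- lr_score(normalized, perm, ligand, receptor, sender, receiver,
                    range_um, Kh, trim)$pooled$score
      if (is.finite(s) && s >= obs) exceed <- exceed + 1L
    }
  })
  list(score = obs, p_value = (1 + exceed) / (n_perm + 1), n_perm = n_perm)
}

#' Per-FOV pseudobulk expression of one cell type
#'
#' Mean normalized expression of the given genes over that type's cells in
#' each FOV; FOVs with fewer than `min_cells` cells of the type yield `NA`
#' rows (reported in `attr(, "n_filtered")`).
#'
#' @inheritParams lr_score
#' @param cell_type type to aggregate.
#' @param genes genes to include (default all).
#' @param min_cells minimum cells of the type per FOV.
#' @return matrix FOVs x genes with `attr(, "n_cells")` and
#'   `attr(, "n_filtered")`.
#' @export
fov_pseudobulk <- function(normalized, cells, cell_type,
                           genes = rownames(normalized), min_cells = 5) {
  cells <- validate_cells(cells)
  .assert(cell_type %in% cells$cell_type,
          "cell_type '%s' absent from cells", cell_type)
  miss <- setdiff(genes, rownames(normalized))
  .assert(length(miss) == 0, "gene(s) absent from matrix: %s",
          paste(miss[1:min(3, length(miss))], collapse = ", "))
  col <- match(cells$cell_id, colnames(normalized))
  fovs <- unique(cells$fov_id)
  out <- matrix(NA_real_, length(fovs), length(genes),
                dimnames = list(fovs, genes))
  ncell <- setNames(integer(length(fovs)), fovs)
  for (f in fovs) {
    w <- which(cells$fov_id == f & cells$cell_type == cell_type)
    ncell[f] <- length(w)
    if (length(w) >= min_cells)
      out[f, ] <- Matrix::rowMeans(
        normalized[genes, col[w], drop = FALSE])
  }
  attr(out, "n_cells") <- ncell
  attr(out, "n_filtered") <- sum(ncell < min_cells)
  out
}

#' Correlation between two per-FOV vectors
#'
#' Pearson (default) or Spearman correlation with pairwise deletion of
#' missing FOVs; requires at least 3 complete pairs. A zero-variance vector
#' yields an `NA` correlation with an explanatory `reason`.
#'
#' @param vec1,vec2 numeric vectors aligned by FOV (names respected when
#'   both are named).
#' @param method `"pearson"` or `"spearman"`.
#' @return list(r, p, n, method, reason).
#' @export
fov_correlation <- function(vec1, vec2, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.null(names(vec1)) && !is.null(names(vec2))) {
    common <- intersect(names(vec1), names(vec2))
    vec1 <- vec1[common]
    vec2 <- vec2[common]
  }
  .assert(length(vec1) == length(vec2), "vectors differ in length")
  ok <- is.finite(vec1) & is.finite(vec2)
  .assert(sum(ok) >= 3, "need >= 3 paired non-missing FOVs (got %d)",
          sum(ok))
  x <- vec1[ok]; y <- vec2[ok]
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = sum(ok), method = method,
                reason = "zero variance in one vector"))
  ct <- cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
       method = method, reason = NULL)
}

#' Signature score per unit
#'
#' Mean of z-scored member genes: each member gene is standardized across
#' units (cells, FOVs or ROIs, i.e. the columns of `mat`), then averaged.
#' Genes missing from the matrix are dropped and reported; at least one
#' member must be present. Constant genes contribute 0.
#'
#' @param mat genes x units numeric matrix (e.g. a pseudobulk transposed,
#'   or the normalized cell matrix).
#' @param gene_set character vector of member genes.
#' @return numeric vector of per-unit scores with
#'   `attr(, "missing_genes")`.
#' @export
signature_score <- function(mat, gene_set) {
  gene_set <- unique(gene_set)
  present <- intersect(gene_set, rownames(mat))
  .assert(length(present) > 0, "no member gene present in the matrix")
  X <- as.matrix(mat[present, , drop = FALSE])
  Z <- t(apply(X, 1, function(v) {
    s <- sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  score <- colMeans(Z)
  attr(score, "missing_genes") <- setdiff(gene_set, present)
  score
}

#' Genes correlated with an anchor gene across samples
#'
#' Pearson screen in the style of bulk-cohort co-expression analysis:
#' returns genes with `r > r_min` and `p < p_max` against the anchor
#' (two-sided), anchor excluded, constant genes excluded (undefined r
#' treated as failure).
#'
#' @param mat genes x samples numeric matrix (>= 10 samples).
#' @param anchor_gene anchor gene name (must not be constant).
#' @param r_min,p_max selection thresholds (defaults follow the common
#'   r > 0.4, p < 0.05 convention).
#' @return data.frame(gene, r, p) sorted by decreasing r.
#' @export
correlated_genes <- function(mat, anchor_gene, r_min = 0.4, p_max = 0.05) {
  .assert(anchor_gene %in% rownames(mat), "anchor '%s' absent", anchor_gene)
  .assert(ncol(mat) >= 10, "need >= 10 samples (got %d)", ncol(mat))
  a <- as.numeric(mat[anchor_gene, ])
  .assert(sd(a) > 0, "anchor gene '%s' is constant", anchor_gene)
  genes <- setdiff(rownames(mat), anchor_gene)
  res <- lapply(genes, function(g) {
    v <- as.numeric(mat[g, ])
    if (sd(v) == 0) return(NULL)
    ct <- cor.test(a, v)
    if (ct$estimate > r_min && ct$p.value < p_max)
      data.frame(gene = g, r = unname(ct$estimate), p = ct$p.value)
    else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(gene = character(0), r = numeric(0), p = numeric(0))
  out[order(-out$r), , drop = FALSE]
}
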