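# fixtures and independent oracles shared across test files

# minimal valid cell table from coordinate/type vectors
make_cells <- function(x, y, type, fov = "F1", region = "T",
                       patient = "P01") {
  n <- length(x)
  fov <- rep_len(fov, n)
  region <- rep_len(region, n)
  patient <- rep_len(patient, n)
  data.frame(cell_id = sprintf("c%05d", seq_len(n)), x_um = x, y_um = y,
             fov_id = fov, core_id = paste(patient, region, sep = "_"),
             patient_id = patient, region = region, cell_type = type)
}

# one CSR FOV with iid labels
make_csr_fov <- function(n = 2000, p_A = 0.3, fov_size = 510,
                         fov = "F1") {
  make_cells(runif(n, 0, fov_size), runif(n, 0, fov_size),
             sample(c("A", "B"), n, TRUE, c(p_A, 1 - p_A)), fov = fov)
}

# constructed sender/receiver layout: per FOV, 2 capillaries at the
# centre, n_pair mCAFs nearby (proximal at the 30 um coupling radius) and
# n_pair mCAFs in a far corner (distal)
make_coupling_layout <- function(n_fov = 20, n_pair = 25) {
  do.call(rbind, lapply(seq_len(n_fov), function(f) {
    cc <- make_cells(
      x = c(250, 260, runif(n_pair, 235, 275), runif(n_pair, 0, 50)),
      y = c(250, 250, runif(n_pair, 235, 275), runif(n_pair, 0, 50)),
      type = c("Capillary", "Capillary", rep("mCAF", 2 * n_pair)),
      fov = sprintf("F%02d", f))
    cc$cell_id <- paste0(sprintf("F%02d", f), cc$cell_id)
    cc
  }))
}

# O(N^2) brute-force kNN oracle: list of neighbour index vectors,
# ties broken by (distance, cell_id)
knn_oracle <- function(cells, k) {
  lapply(seq_len(nrow(cells)), function(i) {
    w <- which(cells$fov_id == cells$fov_id[i])
    w <- setdiff(w, i)
    d <- sqrt((cells$x_um[w] - cells$x_um[i])^2 +
                (cells$y_um[w] - cells$y_um[i])^2)
    w[order(d, cells$cell_id[w])][seq_len(min(k, length(w)))]
  })
}

# direct-formula CLQ oracle (pooled over FOVs, cell-weighted), sharing
# nothing with the package implementation beyond the definition
clq_oracle <- function(cells, A, B, k) {
  nb <- knn_oracle(cells, k)
  per <- lapply(unique(cells$fov_id), function(f) {
    w <- which(cells$fov_id == f)
    N <- length(w)
    aw <- w[cells$cell_type[w] == A]
    nB <- sum(cells$cell_type[w] == B) - (A == B)
    if (length(aw) == 0 || nB <= 0 || N < 2) return(NULL)
    frac <- vapply(aw, function(i)
      mean(cells$cell_type[nb[[i]]] == B), numeric(1))
    c(clq = mean(frac) / (nB / (N - 1)), n_A = length(aw))
  })
  per <- do.call(rbind, per)
  if (is.null(per)) return(NA_real_)
  weighted.mean(per[, "clq"], per[, "n_A"])
}

# product-limit oracle computed step by step from the definition
km_oracle <- function(time, event) {
  s <- 1
  out <- numeric(0)
  for (t in sort(unique(time[event == 1]))) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out[as.character(t)] <- s
  }
  out
}

# hand hypergeometric log-rank tally
logrank_oracle <- function(time, event, group) {
  gA <- group == unique(group)[1]
  U <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    nA <- sum(at_risk & gA)
    d <- sum(time == t & event == 1)
    dA <- sum(time == t & event == 1 & gA)
    U <- U + dA - d * nA / n
    if (n > 1)
      V <- V + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  U^2 / V
}

expr_matrix <- function(values, genes, cells) {
  matrix(values, length(genes), nrow(cells),
         dimnames = list(genes, cells$cell_id))
}
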