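test_that("neighborhood composition matches hand enumeration", {
  # 3 cells (A, A, B), k = 2: A rows see {A, B}, the B row sees {A, A}
  cells <- make_cells(c(0, 1, 2), c(0, 0, 0), c("A", "A", "B"))
  g <- build_knn(cells, 2)
  comp <- neighborhood_composition(g, cells$cell_type)
  expect_equal(unname(comp[1, ]), c(0.5, 0.5))
  expect_equal(unname(comp[2, ]), c(0.5, 0.5))
  expect_equal(unname(comp[3, ]), c(1, 0))
})

test_that("composition rows sum to 1 and one-type FOVs are one-hot", {
  set.seed(31)
  cells <- make_csr_fov(500)
  comp <- neighborhood_composition(build_knn(cells, 20), cells$cell_type)
  expect_equal(unname(rowSums(comp)), rep(1, 500))
  cells1 <- make_cells(runif(40), runif(40), "A")
  comp1 <- neighborhood_composition(build_knn(cells1, 10),
                                    cells1$cell_type)
  expect_true(all(comp1 == 1))
})

test_that("relabelling cell types permutes composition columns", {
  set.seed(32)
  cells <- make_csr_fov(300)
  g <- build_knn(cells, 10)
  comp <- neighborhood_composition(g, cells$cell_type)
  swapped <- ifelse(cells$cell_type == "A", "B", "A")
  comp2 <- neighborhood_composition(g, swapped)
  expect_equal(unname(comp2[, "B"]), unname(comp[, "A"]))
  expect_equal(unname(comp2[, "A"]), unname(comp[, "B"]))
})

test_that("two well-separated niches with disjoint mixtures are
           recovered perfectly", {
  # find the first seed satisfying the precondition: both niches
  # realized (cluster counts are Poisson) and centres well separated
  specs <- list(niche_spec("left", c(A = 0.5, B = 0.5), radius_um = 5,
                           clusters_per_fov = 1, cells_per_cluster = 100),
                niche_spec("right", c(C = 0.5, D = 0.5), radius_um = 5,
                           clusters_per_fov = 1, cells_per_cluster = 100))
  fov <- NULL
  for (s in 1:50) {
    cand <- plant_niche_pattern(2000, specs, seed = s)
    if (setequal(unique(cand$niche), c("left", "right"))) {
      ctr <- aggregate(cand[, c("x_um", "y_um")],
                       list(niche = cand$niche), median)
      if (min(dist(ctr[, -1])) > 300) { fov <- cand; break }
    }
  }
  stopifnot(!is.null(fov))
  cells <- make_cells(fov$x_um, fov$y_um, fov$cell_type)
  comp <- neighborhood_composition(build_knn(cells, 50), cells$cell_type)
  a <- cluster_niches(comp, 2, seed = 1)
  expect_equal(mclust::adjustedRandIndex(a$labels, fov$niche), 1)
})

test_that("clustering is deterministic given the seed and renumbers by
           size", {
  set.seed(34)
  comp <- matrix(runif(600), 200, 3)
  a1 <- cluster_niches(comp, 4, seed = 9)
  a2 <- cluster_niches(comp, 4, seed = 9)
  expect_identical(a1$labels, a2$labels)
  expect_true(all(diff(a1$sizes) <= 0))
  expect_error(cluster_niches(comp, 300, seed = 1), "exceeds")
})

test_that("select_k diagnostics peak at the planted K", {
  cfg3 <- cohort_config(
    n_patients = 2,
    niche_specs = list(
      niche_spec("A", c(Malignant = 0.9, T.NK = 0.1), radius_um = 20,
                 cells_per_cluster = 100, clusters_per_fov = 2),
      niche_spec("B", c(mCAF = 0.5, Cholangiocyte = 0.5), radius_um = 20,
                 cells_per_cluster = 100, clusters_per_fov = 2),
      niche_spec("C", c(T.NK = 0.5, Myeloid = 0.5), radius_um = 20,
                 cells_per_cluster = 100, clusters_per_fov = 1)),
    background_rate = 10, outcome_niche = "B", seed = 3)
  co <- generate_cohort(cfg3)
  comp <- neighborhood_composition(build_knn(co$cells, 50),
                                   co$cells$cell_type)
  sk <- select_k(comp, 2:6, seed = 1)
  expect_equal(attr(sk, "recommended"), 3)
  # inertia is nonincreasing in K on this well-separated layout
  expect_true(all(diff(sk$inertia) <= 1e-8))
  expect_error(select_k(comp, 1:3, seed = 1), "K >= 2")
})

test_that("niche enrichment behaves at both extremes", {
  # a niche of only type X: strong positive for X, negative elsewhere
  labels <- rep(1:2, each = 500)
  grouping <- c(rep("X", 500), rep(c("Y", "Z"), 250))
  E <- niche_enrichment(labels, grouping)
  expect_equal(E[1, "X"], log2(1 / 0.5))
  expect_lt(E[1, "Y"], -5)
  # independent grouping concentrates near 0
  set.seed(35)
  E0 <- niche_enrichment(sample(1:3, 12000, TRUE),
                         sample(letters[1:5], 12000, TRUE))
  expect_lt(max(abs(E0)), 0.2)
})

test_that("planted boundary-restricted niche is most enriched in B", {
  co <- generate_cohort(cohort_config(seed = 6))
  # use the planted labels directly: CD8_CD4_DCs only occurs in B FOVs
  lab <- as.integer(factor(co$truth$niche))
  E <- niche_enrichment(lab, co$cells$region)
  row <- which(levels(factor(co$truth$niche)) == "CD8_CD4_DCs")
  expect_equal(colnames(E)[which.max(E[row, ])], "B")
})

test_that("niche abundance sums to 1 and matches the planted truth", {
  co <- generate_cohort(cohort_config(seed = 8))
  lab <- as.integer(factor(co$truth$niche))
  ab <- niche_abundance(lab, co$cells, "patient")
  expect_equal(unname(rowSums(ab)), rep(1, nrow(ab)))
  # truth-label abundance of the outcome niche equals a direct tally
  oc <- which(levels(factor(co$truth$niche)) == co$config$outcome_niche)
  direct <- tapply(co$truth$niche == co$config$outcome_niche,
                   co$cells$patient_id, mean)
  expect_equal(unname(ab[, oc]), unname(as.numeric(direct)))
  # abundance recomputed from the clustered assignment tracks the truth
  comp <- neighborhood_composition(build_knn(co$cells, 50),
                                   co$cells$cell_type)
  a <- cluster_niches(comp, 9, seed = 1)
  best <- which.max(vapply(seq_len(9), function(kk)
    sum(a$labels == kk & co$truth$niche == co$config$outcome_niche),
    numeric(1)))
  ab_hat <- niche_abundance(a, co$cells, "patient")
  expect_lt(max(abs(ab_hat[, best] - ab[, oc])), 0.05)
  # single-niche degenerate case
  ab1 <- niche_abundance(rep(1L, nrow(co$cells)), co$cells, "region")
  expect_true(all(ab1 == 1))
})
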