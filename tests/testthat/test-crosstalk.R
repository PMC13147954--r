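test_that("radius proximity respects the threshold geometry exactly", {
  cells <- make_cells(c(0, 79, 200, 281), c(0, 0, 0, 0),
                      c("mCAF", "Capillary", "mCAF", "Capillary"))
  fl <- proximity_flags(cells, "mCAF", "Capillary", mode = "radius",
                        threshold = 80)
  expect_equal(fl$proximal, c(TRUE, FALSE))  # 79 um in, 81 um out
  # no target cells in the FOV -> all distal
  only <- make_cells(1:4, rep(0, 4), "mCAF")
  fl0 <- proximity_flags(only, "mCAF", "Capillary", mode = "radius",
                         threshold = 80)
  expect_false(any(fl0$proximal))
  expect_error(proximity_flags(cells, "Ghost", "Capillary",
                               mode = "radius", threshold = 80), "absent")
})

test_that("radius proximity is geometrically symmetric", {
  set.seed(41)
  cells <- make_cells(runif(200, 0, 300), runif(200, 0, 300),
                      sample(c("mCAF", "Capillary"), 200, TRUE))
  fa <- proximity_flags(cells, "mCAF", "Capillary", mode = "radius",
                        threshold = 60)
  fb <- proximity_flags(cells, "Capillary", "mCAF", mode = "radius",
                        threshold = 60)
  # any proximal mCAF implies at least one proximal capillary and the
  # pairwise predicate agrees with a direct distance check
  d <- as.matrix(dist(cells[, c("x_um", "y_um")]))
  is_m <- cells$cell_type == "mCAF"
  direct <- apply(d[is_m, !is_m, drop = FALSE] <= 60, 1, any)
  expect_equal(unname(fa$proximal), unname(direct))
  direct_b <- apply(d[!is_m, is_m, drop = FALSE] <= 60, 1, any)
  expect_equal(unname(fb$proximal), unname(direct_b))
})

test_that("knn and radius proximity agree on a constructed layout", {
  # 1 capillary + 3 mCAF in a tight clump (all within 30 um and within
  # each cell's 3 nearest neighbours), plus a far clump with no capillary
  cells <- make_cells(c(0, 5, 10, 15, 500, 505, 510),
                      rep(0, 7),
                      c("Capillary", rep("mCAF", 3), rep("mCAF", 3)))
  g <- build_knn(cells, 3)
  f_knn <- proximity_flags(cells, "mCAF", "Capillary", mode = "knn",
                           threshold = 3, graph = g)
  f_rad <- proximity_flags(cells, "mCAF", "Capillary", mode = "radius",
                           threshold = 30)
  expect_equal(f_knn$proximal, f_rad$proximal)
  expect_equal(f_rad$proximal, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("rank-sum machinery matches the stats::wilcox.test oracle", {
  set.seed(42)
  X <- matrix(rnbinom(60 * 50, size = 2, mu = 3), 60)
  o <- spatialTME:::.ranksum_rows(X, 1:22, 23:50)
  ref <- apply(X, 1, function(v)
    wilcox.test(v[1:22], v[23:50], exact = FALSE,
                correct = TRUE)$p.value)
  expect_equal(o$p, unname(ref), tolerance = 1e-12)
})

test_that("identical groups yield p = 1 everywhere and no discoveries", {
  set.seed(43)
  # 1 capillary, 20 proximal mCAFs, 20 distal mCAFs
  cells <- make_cells(c(0, runif(20, 1, 40), runif(20, 200, 240)),
                      rep(0, 41), c("Capillary", rep("mCAF", 40)))
  fl <- proximity_flags(cells, "mCAF", "Capillary", mode = "radius",
                        threshold = 50)
  stopifnot(sum(fl$proximal) == 20, sum(!fl$proximal) == 20)
  # distal cells get exactly the proximal cells' expression profile
  X <- expr_matrix(0, paste0("g", 1:10), cells)
  vals <- matrix(rpois(10 * 20, 5), 10)
  X[, fl$cell_id[fl$proximal]] <- vals
  X[, fl$cell_id[!fl$proximal]] <- vals
  de <- proximity_de(X, fl)
  expect_true(all(de$p == 1))
  expect_false(any(de$q < 0.05))
  expect_true(all(de$q >= de$p))
})

test_that("the planted coupling is recovered with controlled error", {
  set.seed(44)
  cells <- make_coupling_layout(n_fov = 20)
  gm <- default_gene_model()
  gm$low_count_frac <- 0
  ex <- sample_expression(cells, gm, default_coupling_spec(gm),
                          seed = 45)
  fl <- proximity_flags(cells, "mCAF", "Capillary", mode = "radius",
                        threshold = 30)
  # generator truth and analysis flags coincide
  expect_equal(unname(fl$proximal),
               unname(ex$proximal[match(fl$cell_id, cells$cell_id)]))
  de <- proximity_de(normalize_counts(ex$counts), fl)
  disc <- de$gene[de$q < 0.05]
  expect_gt(mean(ex$planted_de %in% disc), 0.8)
  # planted genes rise in the proximal group
  expect_true(all(de$log2fc[de$gene %in% ex$planted_de] > 0))
  # DE output is invariant to gene order
  de2 <- proximity_de(normalize_counts(ex$counts)[rev(rownames(ex$counts)), ],
                      fl)
  expect_equal(de2[match(de$gene, de2$gene), "p"], de$p)
})

test_that("proximal fractions recover a planted region-dependent
           coupling", {
  set.seed(46)
  # T and B FOVs: mCAFs packed around capillaries; N FOVs: far away
  mk_region <- function(region, coupled, f) {
    off <- if (coupled) runif(20, -20, 20) else runif(20, 150, 200)
    cc <- make_cells(c(250, 250 + off), c(250, 250 + off),
                     c("Capillary", rep("mCAF", 20)),
                     fov = paste0(region, f), region = region)
    cc$cell_id <- paste0(region, f, cc$cell_id)
    cc
  }
  cells <- rbind(mk_region("T", TRUE, 1), mk_region("T", TRUE, 2),
                 mk_region("B", TRUE, 1), mk_region("N", FALSE, 1),
                 mk_region("N", FALSE, 2))
  fl <- proximity_flags(cells, "mCAF", "Capillary", mode = "radius",
                        threshold = 80)
  pf <- proximal_fraction(fl)
  fr <- setNames(pf$fractions$fraction, pf$fractions$region)
  expect_gt(fr["T"], fr["N"])
  expect_gt(fr["B"], fr["N"])
  # all-proximal degenerate case
  fl$proximal[] <- TRUE
  expect_true(all(proximal_fraction(fl)$fractions$fraction == 1))
})

test_that("correlated_genes screens by r and p with planted correlates", {
  set.seed(47)
  n <- 200
  anchor <- rnorm(n)
  mat <- rbind(NOTCH3 = anchor,
               t(sapply(1:20, function(i)
                 0.6 * anchor + sqrt(1 - 0.36) * rnorm(n))),
               t(sapply(1:100, function(i) rnorm(n))),
               CONST = rep(1, n))
  rownames(mat) <- c("NOTCH3", paste0("COR", 1:20), paste0("RND", 1:100),
                     "CONST")
  res <- correlated_genes(mat, "NOTCH3", r_min = 0.4, p_max = 0.05)
  expect_gte(sum(paste0("COR", 1:20) %in% res$gene), 18)
  expect_lte(sum(grepl("^RND", res$gene)), 5)
  expect_false("NOTCH3" %in% res$gene)
  expect_false("CONST" %in% res$gene)
  # exact copy of the anchor is returned with r = 1
  mat2 <- rbind(mat, COPY = anchor)
  res2 <- correlated_genes(mat2, "NOTCH3")
  expect_equal(res2$r[res2$gene == "COPY"], 1)
  expect_error(correlated_genes(mat, "CONST"), "constant")
})

test_that("signature scores are z-score means with degenerate cases", {
  set.seed(48)
  mat <- matrix(rnorm(5 * 30), 5, 30,
                dimnames = list(paste0("g", 1:5), NULL))
  s1 <- signature_score(mat, "g1")
  expect_equal(unname(s1), unname(scale(mat["g1", ])[, 1]),
               ignore_attr = TRUE)
  # duplicated member collapses to the same single-gene score
  expect_equal(signature_score(mat, c("g1", "g1")), s1)
  expect_error(signature_score(mat, "absent"), "no member")
  expect_equal(attr(signature_score(mat, c("g1", "zz")),
                    "missing_genes"), "zz")
})
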