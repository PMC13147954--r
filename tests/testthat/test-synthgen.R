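test_that("niche planting honours degenerate and deterministic cases", {
  # radius 0: every member sits exactly on its cluster center
  fov <- plant_niche_pattern(
    500, list(niche_spec("n1", c(A = 1), radius_um = 0,
                         clusters_per_fov = 3, cells_per_cluster = 20)),
    seed = 71)
  # members collapse onto at most 3 centers (up to the anti-collision
  # jitter of 1e-6 um)
  rounded <- unique(paste(round(fov$x_um, 3), round(fov$y_um, 3)))
  expect_lte(length(rounded), 3)
  # identical seed -> identical coordinates
  fov2 <- plant_niche_pattern(
    500, list(niche_spec("n1", c(A = 1), radius_um = 0,
                         clusters_per_fov = 3, cells_per_cluster = 20)),
    seed = 71)
  expect_identical(fov$x_um, fov2$x_um)
  expect_identical(fov$y_um, fov2$y_um)
  # coordinates never leave the FOV
  big <- plant_niche_pattern(
    100, list(niche_spec("n1", c(A = 1), radius_um = 80,
                         clusters_per_fov = 5, cells_per_cluster = 50)),
    background_rate = 20, background_mixture = c(A = 1), seed = 72)
  expect_true(all(big$x_um >= 0 & big$x_um <= 100))
  expect_true(all(big$y_um >= 0 & big$y_um <= 100))
  # no two cells share identical coordinates
  expect_false(any(duplicated(paste(big$x_um, big$y_um))))
  # empty FOV is an explicit error naming the FOV
  expect_error(
    plant_niche_pattern(100, list(), background_rate = 0,
                        fov_id = "P01_T_F1", seed = 73),
    "P01_T_F1")
})

test_that("expression sampling respects the gene model", {
  set.seed(74)
  cells <- make_cells(runif(200, 0, 100), runif(200, 0, 100),
                      sample(c("Capillary", "mCAF", "Malignant"), 200,
                             TRUE))
  gm <- default_gene_model()
  gm$low_count_frac <- 0
  ex <- sample_expression(cells, gm, coupling = NULL, seed = 75)
  # ligand has zero mean outside senders -> zero counts there
  expect_true(all(ex$counts["DLL4",
                            cells$cell_type != "Capillary"] == 0))
  # per-cell totals concentrate near the target
  expect_lt(abs(mean(Matrix::colSums(ex$counts)) - gm$total_target) /
              gm$total_target, 0.2)
  # unknown cell type is reported by name
  bad <- cells
  bad$cell_type[1] <- "Klingon"
  expect_error(sample_expression(bad, gm), "Klingon")
})

test_that("a zero effect size leaves proximal and distal receivers
           exchangeable", {
  set.seed(76)
  cells <- make_coupling_layout(n_fov = 20)
  gm <- default_gene_model()
  gm$low_count_frac <- 0
  cp <- default_coupling_spec(gm)
  cp$log2fc <- 0
  ex <- sample_expression(cells, gm, cp, seed = 77)
  prox <- ex$proximal
  dist <- ex$receiver & !ex$proximal
  prog <- as.numeric(Matrix::colSums(ex$counts[cp$receptor_program, ]))
  p <- wilcox.test(prog[prox], prog[dist])$p.value
  expect_gt(p, 0.01)
})

test_that("the planted log2 fold change is recovered empirically", {
  set.seed(78)
  cells <- make_coupling_layout(n_fov = 20)  # 500 proximal / 500 distal
  gm <- default_gene_model()
  gm$low_count_frac <- 0
  ex <- sample_expression(cells, gm, default_coupling_spec(gm),
                          seed = 79)
  prox <- ex$proximal
  dist <- ex$receiver & !ex$proximal
  expect_gte(sum(prox), 450)
  expect_gte(sum(dist), 450)
  lfc <- mean(log2(
    Matrix::rowMeans(ex$counts[ex$planted_de, prox]) /
      Matrix::rowMeans(ex$counts[ex$planted_de, dist])))
  expect_lt(abs(lfc - 1), 0.2)
})

test_that("survival attachment follows its hazard model", {
  # censoring rate 1: everyone censored
  sv <- attach_survival(setNames(runif(20), sprintf("P%02d", 1:20)),
                        list(baseline_hazard = 0.02, beta = 1,
                             censoring_rate = 1, admin_months = 120),
                        seed = 80)
  expect_true(all(sv$event == 0))
  expect_true(all(sv$time_months > 0))
  expect_error(
    attach_survival(c(P1 = 0.5), list(baseline_hazard = -1, beta = 0,
                                      censoring_rate = 0)),
    "positive")
  # beta = 0: log-rank p over repeated cohorts is uniform
  set.seed(81)
  spec0 <- list(baseline_hazard = 0.02, beta = 0, censoring_rate = 0.2,
                admin_months = 120)
  ps <- replicate(200, {
    sv <- attach_survival(setNames(runif(40), sprintf("P%02d", 1:40)),
                          spec0)
    logrank_test(sv$time_months, sv$event,
                 dichotomize(sv$abundance))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  # beta = log(2.5): the high-abundance arm dies sooner nearly always
  set.seed(82)
  spec1 <- list(baseline_hazard = 0.02, beta = log(2.5),
                censoring_rate = 0, admin_months = Inf)
  shorter <- replicate(100, {
    ab <- setNames(rep(c(0, 1), each = 30), sprintf("P%02d", 1:60))
    sv <- attach_survival(ab, spec1)
    median(sv$time_months[sv$abundance == 1]) <
      median(sv$time_months[sv$abundance == 0])
  })
  expect_gte(mean(shorter), 0.9)
})

test_that("cohort generation composes the layers coherently", {
  co <- generate_cohort(cohort_config(seed = 83))
  # all nine planted niche labels are present
  expect_setequal(setdiff(unique(co$truth$niche), "background"),
                  vapply(co$config$niche_specs, `[[`, "", "name"))
  # coordinates inside the FOV, hierarchy consistent
  expect_true(all(co$cells$x_um >= 0 & co$cells$x_um <= 510))
  key <- unique(co$cells[, c("fov_id", "core_id", "patient_id",
                             "region")])
  expect_equal(anyDuplicated(key$fov_id), 0)
  # realized transcript totals near the target
  expect_lt(abs(mean(Matrix::colSums(co$counts)) - 800) / 800, 0.2)
  # truth proximal flags equal the radius-mode analysis predicate
  fl <- proximity_flags(co$cells, co$config$coupling$receiver,
                        co$config$coupling$sender, mode = "radius",
                        threshold = co$config$coupling$radius_um)
  expect_equal(unname(fl$proximal),
               co$truth$proximal[match(fl$cell_id, co$truth$cell_id)])
})

test_that("region-shifted CAF composition is realized in the patterns", {
  # spec-scale check on the pattern layer: 20 seeds x 30 FOVs per region
  specs <- default_niche_specs()
  mixes <- default_region_mixtures()
  ok <- vapply(1:20, function(s) {
    set.seed(900 + s)
    frac <- vapply(c("T", "N"), function(reg) {
      types <- unlist(lapply(1:30, function(f)
        plant_niche_pattern(510, specs, region = reg,
                            background_rate = 20,
                            background_mixture =
                              mixes[[reg]])$cell_type))
      mean(types == "mCAF")
    }, numeric(1))
    frac["T"] > frac["N"]
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("identical config and seed reproduce the dataset byte for
           byte", {
  cfg <- cohort_config(n_patients = 2, seed = 84)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1$cells, co2$cells)
  expect_identical(co1$counts, co2$counts)
  expect_identical(co1$survival, co2$survival)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(co1, d1)
  write_cohort(co2, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})
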