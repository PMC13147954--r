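#' Configuration of a synthetic spatial cohort
#'
#' Bundles and validates every parameter of the generator. Defaults define
#' the package's reference study conditions: 6 patients, 2 tumor + 1
#' boundary + 1 normal FOV each, 510 μm square FOVs, nine planted niches,
#' region-shifted CAF composition, the capillary-to-mCAF DLL4/NOTCH
#' coupling and survival tied to the abundance of the mCAFs_Chola niche
#' (per-patient cluster-intensity factors spread over
#' `outcome_niche_factors` create an abundance gradient).
#'
#' @param n_patients number of patients.
#' @param fovs_per_patient named integer vector of FOV counts per region.
#' @param fov_size FOV side length in μm.
#' @param cell_types named list of per-region baseline type proportions
#'   for background cells (each sums to 1).
#' @param niche_specs list of [niche_spec()] objects.
#' @param background_rate expected background cells per FOV, single value
#'   or named by region.
#' @param gene_model see [default_gene_model()].
#' @param coupling see [default_coupling_spec()]; `NULL` disables the
#'   coupling.
#' @param survival_spec see [default_survival_spec()].
#' @param outcome_niche niche whose per-patient abundance drives survival.
#' @param outcome_niche_factors per-patient multipliers on the outcome
#'   niche's cluster intensity (default an even gradient 0.5..1.5).
#' @param seed RNG seed; identical config + seed reproduce the dataset
#'   byte for byte.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 6,
                          fovs_per_patient = c(T = 2, B = 1, N = 1),
                          fov_size = 510,
                          cell_types = default_region_mixtures(),
                          niche_specs = default_niche_specs(),
                          background_rate = c(T = 20, B = 20, N = 40),
                          gene_model = default_gene_model(),
                          coupling = default_coupling_spec(gene_model),
                          survival_spec = default_survival_spec(),
                          outcome_niche = "mCAFs_Chola",
                          outcome_niche_factors = NULL,
                          seed = 1) {
  .assert(n_patients >= 1, "n_patients must be >= 1")
  .assert(fov_size > 0, "fov_size must be > 0")
  .assert(all(names(fovs_per_patient) %in% REGION_LEVELS),
          "fovs_per_patient must be named by region (T/B/N)")
  for (r in names(cell_types)) {
    .assert(abs(sum(cell_types[[r]]) - 1) < 1e-8,
            "region %s baseline proportions sum to %g, not 1",
            r, sum(cell_types[[r]]))
    .assert(all(names(cell_types[[r]]) %in%
                  colnames(gene_model$mean_matrix)),
            "region %s baseline mixture uses types absent from gene model", r)
  }
  if (!is.null(coupling)) {
    .assert(coupling$radius_um < fov_size,
            "coupling radius (%g) must be smaller than fov_size (%g)",
            coupling$radius_um, fov_size)
    .assert(is.finite(coupling$log2fc), "coupling log2fc must be finite")
  }
  .assert(survival_spec$baseline_hazard > 0,
          "baseline hazard must be positive")
  .assert(is.finite(survival_spec$beta), "survival beta must be finite")
  if (is.null(outcome_niche_factors))
    outcome_niche_factors <- if (n_patients == 1) 1 else
      seq(0.5, 1.5, length.out = n_patients)
  .assert(length(outcome_niche_factors) == n_patients,
          "need one outcome_niche_factor per patient")
  structure(list(n_patients = n_patients,
                 fovs_per_patient = fovs_per_patient, fov_size = fov_size,
                 cell_types = cell_types, niche_specs = niche_specs,
                 background_rate = background_rate,
                 gene_model = gene_model, coupling = coupling,
                 survival_spec = survival_spec,
                 outcome_niche = outcome_niche,
                 outcome_niche_factors = outcome_niche_factors,
                 seed = seed),
            class = "cohort_config")
}

#' Plant a Matern-style niche point pattern in one FOV
#'
#' For each niche spec, cluster centers are drawn uniformly in the FOV
#' (Poisson count at the spec's per-region intensity), member cells as
#' isotropic Gaussian offspring around their center (sd = `radius_um`,
#' clamped to the FOV), and member types from the niche mixture.
#' Background cells follow a homogeneous Poisson process with types from
#' `background_mixture`. Coincident coordinates are jittered by 1e-6 μm so
#' no two cells tie in neighbor searches.
#'
#' @param fov_size FOV side (μm).
#' @param niche_specs list of [niche_spec()] objects.
#' @param region region label selecting each spec's cluster intensity
#'   (`NULL` uses the first/scalar intensity).
#' @param background_rate expected background cell count.
#' @param background_mixture named type proportions for background cells.
#' @param niche_factors optional named multipliers on specific niches'
#'   cluster intensities.
#' @param fov_id label used in error messages.
#' @param seed optional seed (`NULL` continues the current RNG stream).
#' @return data.frame(x_um, y_um, cell_type, niche) where `niche` is the
#'   planted label or `"background"`.
#' @export
plant_niche_pattern <- function(fov_size, niche_specs, region = NULL,
                                background_rate = 0,
                                background_mixture = NULL,
                                niche_factors = NULL, fov_id = "FOV",
                                seed = NULL) {
  .with_seed(seed, {
    parts <- vector("list", length(niche_specs) + 1)
    for (q in seq_along(niche_specs)) {
      sp <- niche_specs[[q]]
      lam <- sp$clusters_per_fov
      if (!is.null(names(lam)) && !is.null(region)) lam <- lam[[region]]
      lam <- lam[1]
      if (!is.null(niche_factors) && sp$name %in% names(niche_factors))
        lam <- lam * niche_factors[[sp$name]]
      n_clust <- rpois(1, lam)
      if (n_clust == 0) next
      cx <- runif(n_clust, 0, fov_size)
      cy <- runif(n_clust, 0, fov_size)
      sizes <- rpois(n_clust, sp$cells_per_cluster)
      total <- sum(sizes)
      if (total == 0) next
      cen <- rep(seq_len(n_clust), sizes)
      x <- pmin(pmax(cx[cen] + rnorm(total, 0, sp$radius_um), 0), fov_size)
      y <- pmin(pmax(cy[cen] + rnorm(total, 0, sp$radius_um), 0), fov_size)
      parts[[q]] <- data.frame(
        x_um = x, y_um = y,
        cell_type = sample(names(sp$mixture), total, replace = TRUE,
                           prob = sp$mixture),
        niche = sp$name)
    }
    n_bg <- if (background_rate > 0) rpois(1, background_rate) else 0L
    if (n_bg > 0) {
      .assert(!is.null(background_mixture),
              "background cells requested without a background mixture")
      parts[[length(niche_specs) + 1]] <- data.frame(
        x_um = runif(n_bg, 0, fov_size), y_um = runif(n_bg, 0, fov_size),
        cell_type = sample(names(background_mixture), n_bg, replace = TRUE,
                           prob = background_mixture),
        niche = "background")
    }
    out <- do.call(rbind, parts)
    .assert(!is.null(out) && nrow(out) > 0,
            "empty FOV '%s': planted density too low", fov_id)
    dup <- duplicated(paste(out$x_um, out$y_um))
    while (any(dup)) {
      # jitter inward so coordinates stay inside the FOV
      inward <- ifelse(out$x_um[dup] < fov_size / 2, 1, -1)
      out$x_um[dup] <- out$x_um[dup] + inward * runif(sum(dup), 0, 1e-6)
      dup <- duplicated(paste(out$x_um, out$y_um))
    }
    rownames(out) <- NULL
    out
  })
}

#' Sample negative-binomial expression for a cell table
#'
#' Each cell's mean vector is its type's column of the gene model's mean
#' matrix, rescaled so expected totals equal `total_target`. When a
#' coupling is given, receiver cells lying within the coupling radius of
#' at least one sender (within their FOV) have the receptor-program means
#' multiplied by `2^log2fc` — the planted differential-expression truth.
#' A `low_count_frac` share of cells is downscaled to
#' `low_count_target` expected transcripts (planted QC failures). Counts
#' are NB(mu, size = dispersion).
#'
#' @param cells validated cell table (needs `cell_id`, coordinates,
#'   `fov_id`, `cell_type`).
#' @param gene_model see [default_gene_model()].
#' @param coupling see [default_coupling_spec()]; `NULL` for none.
#' @param seed optional seed (`NULL` continues the current stream).
#' @return list with `counts` (sparse genes x cells), `planted_de`
#'   (receptor program genes, or `character(0)`), `proximal` (per-cell
#'   logical: receiver within coupling radius of a sender), `receiver`
#'   (per-cell logical) and `low_count` (per-cell logical).
#' @export
sample_expression <- function(cells, gene_model = default_gene_model(),
                              coupling = NULL, seed = NULL) {
  M <- gene_model$mean_matrix
  unknown <- setdiff(unique(cells$cell_type), colnames(M))
  .assert(length(unknown) == 0, "cell type(s) missing from gene model: %s",
          paste(unknown, collapse = ", "))
  .with_seed(seed, {
    n <- nrow(cells)
    Ms <- sweep(M, 2, colSums(M), "/") * gene_model$total_target
    MU <- Ms[, cells$cell_type, drop = FALSE]
    proximal <- rep(FALSE, n)
    receiver <- rep(FALSE, n)
    planted_de <- character(0)
    if (!is.null(coupling)) {
      receiver <- cells$cell_type == coupling$receiver
      for (f in unique(cells$fov_id[receiver])) {
        w <- which(receiver & cells$fov_id == f)
        sn <- which(cells$fov_id == f & cells$cell_type == coupling$sender)
        proximal[w] <- .any_within_radius(cells$x_um[w], cells$y_um[w],
                                          cells$x_um[sn], cells$y_um[sn],
                                          coupling$radius_um)
      }
      if (any(proximal)) {
        MU[coupling$receptor_program, proximal] <-
          MU[coupling$receptor_program, proximal] * 2^coupling$log2fc
      }
      planted_de <- coupling$receptor_program
    }
    low <- runif(n) < gene_model$low_count_frac
    if (any(low))
      MU[, low] <- MU[, low] *
        (gene_model$low_count_target / gene_model$total_target)
    counts <- matrix(rnbinom(length(MU), size = gene_model$dispersion,
                             mu = as.numeric(MU)),
                     nrow = nrow(MU),
                     dimnames = list(rownames(M), cells$cell_id))
    list(counts = as(Matrix::Matrix(counts, sparse = TRUE),
                     "CsparseMatrix"),
         planted_de = planted_de, proximal = proximal,
         receiver = receiver, low_count = low)
  })
}

#' Attach exponential survival to patient-level niche abundance
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(beta * abundance)`; independent random censoring
#' targets `censoring_rate` (exponential censoring calibrated at the
#' baseline hazard; `censoring_rate >= 1` censors everyone), plus
#' administrative censoring at `admin_months`.
#'
#' @param abundance named numeric in \[0, 1\], one entry per patient.
#' @param spec see [default_survival_spec()].
#' @param seed optional seed.
#' @return data.frame(patient_id, time_months, event, abundance).
#' @export
attach_survival <- function(abundance, spec = default_survival_spec(),
                            seed = NULL) {
  .assert(spec$baseline_hazard > 0, "baseline hazard must be positive")
  .assert(all(abundance >= 0 & abundance <= 1),
          "abundance must lie in [0, 1]")
  n <- length(abundance)
  ids <- names(abundance) %||% sprintf("P%02d", seq_len(n))
  .with_seed(seed, {
    lam <- spec$baseline_hazard * exp(spec$beta * abundance)
    t_event <- rexp(n, lam)
    rate <- spec$censoring_rate
    cens <- if (rate <= 0) {
      rep(Inf, n)
    } else if (rate < 1) {
      rexp(n, spec$baseline_hazard * rate / (1 - rate))
    } else {
      t_event * runif(n)  # certain censoring, strictly before the event
    }
    admin <- spec$admin_months %||% Inf
    data.frame(patient_id = ids,
               time_months = pmin(t_event, cens, admin),
               event = as.integer(t_event <= pmin(cens, admin)),
               abundance = unname(abundance), row.names = NULL)
  })
}

#' Generate a complete synthetic spatial cohort
#'
#' Composes [plant_niche_pattern()], [sample_expression()] and
#' [attach_survival()] over patients x regions x FOVs, recording all
#' ground truth: per-cell planted niche, per-cell proximal flag, the
#' planted DE gene list, planted low-count cells, and patient-level
#' outcome-niche abundance. Fully deterministic given the config's seed.
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: list with `cells`,
#'   `counts`, `truth` (data.frame cell_id/niche/proximal/receiver/
#'   low_count plus `attr(,"planted_de")`), `survival`, `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  .assert(inherits(config, "cohort_config"),
          "config must come from cohort_config()")
  set.seed(config$seed)
  patients <- sprintf("P%02d", seq_len(config$n_patients))
  parts <- list()
  for (pi in seq_along(patients)) {
    fac <- setNames(config$outcome_niche_factors[pi], config$outcome_niche)
    for (region in names(config$fovs_per_patient)) {
      bg <- config$background_rate
      if (!is.null(names(bg))) bg <- bg[[region]]
      for (f in seq_len(config$fovs_per_patient[[region]])) {
        fov_id <- sprintf("%s_%s_F%d", patients[pi], region, f)
        df <- plant_niche_pattern(config$fov_size, config$niche_specs,
                                  region = region, background_rate = bg,
                                  background_mixture =
                                    config$cell_types[[region]],
                                  niche_factors = fac, fov_id = fov_id)
        df$fov_id <- fov_id
        df$core_id <- sprintf("%s_%s", patients[pi], region)
        df$patient_id <- patients[pi]
        df$region <- region
        parts[[length(parts) + 1]] <- df
      }
    }
  }
  cells <- do.call(rbind, parts)
  cells$cell_id <- sprintf("cell%06d", seq_len(nrow(cells)))
  niche_truth <- cells$niche
  cells <- cells[, c("cell_id", "x_um", "y_um", "fov_id", "core_id",
                     "patient_id", "region", "cell_type")]
  cells <- validate_cells(cells)
  expr <- sample_expression(cells, config$gene_model, config$coupling)
  truth <- data.frame(cell_id = cells$cell_id, niche = niche_truth,
                      proximal = expr$proximal, receiver = expr$receiver,
                      low_count = expr$low_count)
  attr(truth, "planted_de") <- expr$planted_de
  ab <- tapply(niche_truth == config$outcome_niche, cells$patient_id, mean)
  abundance <- setNames(as.numeric(ab), names(ab))[patients]
  survival <- attach_survival(abundance, config$survival_spec)
  structure(list(cells = cells, counts = expr$counts, truth = truth,
                 survival = survival, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d cells, %d genes, %d patients, ",
                     "%d FOVs\n  planted niches: %s\n"),
              nrow(x$cells), nrow(x$counts), x$config$n_patients,
              length(unique(x$cells$fov_id)),
              paste(setdiff(unique(x$truth$niche), "background"),
                    collapse = ", ")))
  invisible(x)
}

#' Write a synthetic cohort to a dataset directory
#'
#' Standard dataset layout (see [write_dataset()]) plus `truth.tsv`,
#' `truth_genes.tsv` (planted DE genes) and the config echoed as
#' `config.yaml`.
#'
#' @param cohort `synthetic_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  write_dataset(cohort$cells, cohort$counts, dir,
                survival = cohort$survival[, c("patient_id", "time_months",
                                               "event")])
  write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(attr(cohort$truth, "planted_de"),
             file.path(dir, "truth_genes.tsv"))
  cfg <- cohort$config
  echo <- list(n_patients = cfg$n_patients,
               fovs_per_patient = as.list(cfg$fovs_per_patient),
               fov_size = cfg$fov_size, seed = cfg$seed,
               outcome_niche = cfg$outcome_niche,
               niches = vapply(cfg$niche_specs, `[[`, "", "name"),
               coupling = if (is.null(cfg$coupling)) NULL else
                 cfg$coupling[c("ligand", "sender", "receiver",
                                "radius_um", "log2fc")])
  yaml::write_yaml(echo, file.path(dir, "config.yaml"))
  invisible(dir)
}
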