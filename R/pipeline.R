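#' Configuration for an end-to-end pipeline run
#'
#' Exactly one of `simulate` (a [cohort_config()]) or `dataset` (a
#' directory readable by [read_dataset()]) must be given. Stage parameters
#' carry the package's conventional defaults: QC at 20 transcripts, CLQ at
#' k = 20, niches at k = 50 with K = 9, crosstalk on the DLL4 -> NOTCH3
#' capillary-to-mCAF axis at an 80 μm diffusible range, immune
#' infiltration over T/NK, B/Plasma and Myeloid cells. Every stochastic
#' stage derives its seed from `seed` and its stage name, so adding or
#' removing a stage never shifts another stage's randomness.
#'
#' @param simulate optional [cohort_config()].
#' @param dataset optional dataset directory.
#' @param stages character vector of stages to run, in pipeline order.
#' @param seed global seed.
#' @param qc,normalize,clq,niche,crosstalk,outcomes per-stage parameter
#'   lists; any omitted entry keeps its default.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, dataset = NULL,
                            stages = c("qc", "knn", "clq", "niche",
                                       "crosstalk", "outcomes"),
                            seed = 1,
                            qc = list(), normalize = list(), clq = list(),
                            niche = list(), crosstalk = list(),
                            outcomes = list()) {
  .assert(xor(is.null(simulate), is.null(dataset)),
          "exactly one of simulate/dataset must be given")
  if (!is.null(simulate))
    .assert(inherits(simulate, "cohort_config"),
            "simulate must be a cohort_config")
  defaults <- list(
    qc = list(min_transcripts = 20),
    normalize = list(target_total = 500, pseudo = 1),
    clq = list(reference_type = "Malignant", k = 20, n_perm = 0),
    niche = list(k = 50, K = 9),
    crosstalk = list(ligand = "DLL4", receptor = "NOTCH3",
                     sender = "Capillary", receiver = "mCAF",
                     range_um = 80, proximity_mode = "radius",
                     proximity_threshold = 80, Kh = 0.5),
    outcomes = list(immune_types = c("T.NK", "B.Plasma", "Myeloid")))
  merge1 <- function(d, u) { d[names(u)] <- u; d }
  structure(list(simulate = simulate, dataset = dataset, stages = stages,
                 seed = seed,
                 qc = merge1(defaults$qc, qc),
                 normalize = merge1(defaults$normalize, normalize),
                 clq = merge1(defaults$clq, clq),
                 niche = merge1(defaults$niche, niche),
                 crosstalk = merge1(defaults$crosstalk, crosstalk),
                 outcomes = merge1(defaults$outcomes, outcomes)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes qc -> knn -> clq -> niche -> crosstalk -> outcomes on a
#' simulated or loaded dataset, writing TSV/JSON artifacts under
#' `out_dir` and returning a machine-readable report (also written as
#' `report.json`) with per-stage row counts, echoed parameters, warnings
#' and artifact checksums. A stage failure aborts with the stage name; the
#' partial report is attached to the error condition.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return the report, invisibly (class `pipeline_report`).
#' @export
run_pipeline <- function(config, out_dir) {
  .assert(inherits(config, "pipeline_config"),
          "config must come from pipeline_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(stages = list(), params = config[
    c("qc", "normalize", "clq", "niche", "crosstalk", "outcomes")],
    seed = config$seed, warnings = character(0))
  tsv <- function(x, name) {
    write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = !is.null(rownames(x)) &&
                  !identical(rownames(x), as.character(seq_len(nrow(x)))))
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      cond <- simpleError(sprintf("stage '%s' failed: %s", name,
                                  conditionMessage(e)))
      cond$partial_report <- report
      stop(cond)
    })
  }

  # input
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- .derive_seed(config$seed, "simulate")
    cohort <- run_stage("simulate", function() generate_cohort(sim_cfg))
    cells <- cohort$cells
    counts <- cohort$counts
    survival_tab <- cohort$survival
    report$stages$simulate <- list(n_cells = nrow(cells),
                                   n_genes = nrow(counts))
  } else {
    ds <- run_stage("load", function() read_dataset(config$dataset))
    cells <- ds$cells
    counts <- ds$counts
    survival_tab <- ds$survival
    report$stages$load <- list(n_cells = nrow(cells),
                               n_genes = nrow(counts))
  }

  normalized <- NULL
  graph_clq <- graph_niche <- NULL
  assignment <- NULL
  has <- function(s) s %in% config$stages

  if (has("qc")) {
    res <- run_stage("qc", function()
      qc_filter_cells(cells, counts, config$qc$min_transcripts))
    cells <- res$cells
    counts <- res$counts
    tsv(res$report, "qc_report.tsv")
    report$stages$qc <- list(n_cells = nrow(cells),
                             min_transcripts = config$qc$min_transcripts)
  }
  normalized <- normalize_counts(counts, config$normalize$target_total,
                                 config$normalize$pseudo)

  if (has("knn") || has("clq") || has("niche") || has("crosstalk")) {
    graph_niche <- run_stage("knn", function()
      build_knn(cells, config$niche$k))
    graph_clq <- if (config$clq$k == config$niche$k) graph_niche else
      run_stage("knn", function() build_knn(cells, config$clq$k))
    report$stages$knn <- list(k_niche = config$niche$k,
                              k_clq = config$clq$k,
                              n_truncated = sum(graph_niche$truncated),
                              excluded_fovs = graph_niche$excluded_fovs)
  }

  if (has("clq")) {
    run_stage("clq", function() {
      dens <- clq_density(cells, graph_clq, cells$cell_type,
                          config$clq$reference_type)
      tsv(dens, "clq.tsv")
      report$stages$clq <<- list(n_rows = nrow(dens),
                                 reference = config$clq$reference_type,
                                 n_null = sum(attr(dens, "n_null")))
      if (config$clq$n_perm >= 99) {
        others <- unique(dens$other_type)
        ps <- lapply(others, function(t)
          clq_permutation(graph_clq, cells$cell_type,
                          config$clq$reference_type, t,
                          n_perm = config$clq$n_perm,
                          seed = .derive_seed(config$seed,
                                              paste0("clq_", t))))
        perm <- data.frame(other_type = others,
                           clq = vapply(ps, `[[`, 0, "clq"),
                           p = vapply(ps, `[[`, 0, "p_value"))
        tsv(perm, "clq_permutation.tsv")
      }
    })
  }

  if (has("niche")) {
    run_stage("niche", function() {
      comp <- neighborhood_composition(graph_niche, cells$cell_type)
      assignment <<- cluster_niches(comp, config$niche$K,
                                    seed = .derive_seed(config$seed,
                                                        "niche"))
      tsv(data.frame(cell_id = cells$cell_id, niche = assignment$labels),
          "niche_labels.tsv")
      tsv(as.data.frame(niche_enrichment(assignment, cells$cell_type)),
          "niche_enrichment_type.tsv")
      tsv(as.data.frame(niche_enrichment(assignment, cells$region)),
          "niche_enrichment_region.tsv")
      tsv(as.data.frame(niche_abundance(assignment, cells, "patient")),
          "niche_abundance_patient.tsv")
      report$stages$niche <<- list(K = assignment$K,
                                   sizes = assignment$sizes,
                                   n_truncated = sum(graph_niche$truncated))
    })
  }

  if (has("crosstalk")) {
    run_stage("crosstalk", function() {
      ct <- config$crosstalk
      flags <- proximity_flags(cells, ct$receiver, ct$sender,
                               mode = ct$proximity_mode,
                               threshold = ct$proximity_threshold,
                               graph = graph_niche)
      tsv(as.data.frame(flags), "proximity_flags.tsv")
      de <- proximity_de(normalized, flags)
      tsv(de, "proximity_de.tsv")
      pf <- proximal_fraction(flags)
      tsv(pf$fractions, "proximal_fraction.tsv")
      lr <- lr_score(normalized, cells, ct$ligand, ct$receptor,
                     ct$sender, ct$receiver, ct$range_um, ct$Kh)
      tsv(lr$per_fov, "lr_score.tsv")
      pbL <- fov_pseudobulk(normalized, cells, ct$sender, ct$ligand)
      pbR <- fov_pseudobulk(normalized, cells, ct$receiver, ct$receptor)
      fc <- tryCatch(fov_correlation(pbL[, 1], pbR[, 1]),
                     error = function(e) list(r = NA, p = NA, n = 0))
      jsonlite::write_json(
        list(lr_pooled = lr$pooled,
             fov_correlation = fc[c("r", "p", "n")]),
        file.path(out_dir, "crosstalk_summary.json"), auto_unbox = TRUE,
        digits = NA, null = "null")
      report$stages$crosstalk <<- list(
        n_flagged = nrow(flags), n_proximal = sum(flags$proximal),
        n_de_genes = nrow(de), lr_score = lr$pooled$score,
        fov_correlation_r = fc$r)
    })
  }

  if (has("outcomes")) {
    run_stage("outcomes", function() {
      strata <- immune_fraction(cells, config$outcomes$immune_types)
      tsv(strata, "fov_strata.tsv")
      out <- list(n_high = sum(strata$stratum == "high"),
                  n_low = sum(strata$stratum == "low"))
      ct <- config$crosstalk
      de <- tryCatch(infiltration_de(normalized, cells, ct$receiver,
                                     strata),
                     error = function(e) NULL)
      if (!is.null(de)) tsv(de, "infiltration_de.tsv")
      if (!is.null(survival_tab) && !is.null(assignment)) {
        ab <- niche_abundance(assignment, cells, "patient")
        # follow the inferred niche most enriched for the receiver type
        enr <- niche_enrichment(assignment, cells$cell_type)
        target_niche <- which.max(enr[, ct$receiver])
        cov <- ab[match(survival_tab$patient_id, rownames(ab)),
                  target_niche]
        if (length(unique(cov)) > 1 && sum(survival_tab$event) >= 1) {
          grp <- dichotomize(cov)
          km <- rbind(cbind(km_curve(
                        survival_tab$time_months[grp == "high"],
                        survival_tab$event[grp == "high"]), group = "high"),
                      cbind(km_curve(
                        survival_tab$time_months[grp == "low"],
                        survival_tab$event[grp == "low"]), group = "low"))
          tsv(km, "km_curves.tsv")
          lr_test <- logrank_test(survival_tab$time_months,
                                  survival_tab$event, grp)
          jsonlite::write_json(
            list(niche = unname(target_niche), logrank = lr_test),
            file.path(out_dir, "survival_summary.json"),
            auto_unbox = TRUE, digits = NA)
          out$logrank_p <- lr_test$p
          out$survival_niche <- unname(target_niche)
        }
      }
      report$stages$outcomes <<- out
    })
  }

  arts <- sort(setdiff(list.files(out_dir), "report.json"))
  report$artifacts <- as.list(setNames(
    unname(tools::md5sum(file.path(out_dir, arts))), arts))
  class(report) <- "pipeline_report"
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report; stages:", paste(names(x$stages), collapse = ", "),
      "\n")
  invisible(x)
}
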