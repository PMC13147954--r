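# Default study conditions for the synthetic cohort generator.
#
# The generator emulates an imaging-based spatial transcriptomics cohort of
# hepatocellular carcinoma tissue: square FOVs of 510 um, ~500-600 cells
# per FOV, per-cell transcript totals near 800 (the platform's reported
# medians are 797/829), region labels T (tumor core) / B (invasive
# boundary) / N (adjacent normal), nine planted spatial niches, a
# capillary-DLL4 -> mCAF-NOTCH3-program coupling, and survival linked to
# the abundance of a stromal niche.

#' Default cell-type vocabulary of the generator
#'
#' The eight parenchymal/immune lineages of a liver tumor panel with the
#' fibroblast compartment split into matrix (mCAF) and inflammatory (iCAF)
#' polarization states and the endothelial compartment represented by its
#' capillary/LSEC population.
#' @return character vector of type labels.
#' @export
default_cell_types <- function() {
  c("Malignant", "Hepatocyte", "Cholangiocyte", "Capillary", "mCAF",
    "iCAF", "T.NK", "B.Plasma", "Myeloid")
}

#' Default background composition per region
#'
#' Baseline cell-type proportions of the non-niche (background) cells in
#' each region. Tumor cores are malignant-dominated, normal parenchyma is
#' hepatocyte-dominated, and the CAF polarization is region-shifted: the
#' mCAF share is higher in T/B than in N, the iCAF share the reverse.
#' @return named list `T`/`B`/`N` of proportion vectors summing to 1.
#' @export
default_region_mixtures <- function() {
  list(
    T = c(Malignant = 0.65, Capillary = 0.10, mCAF = 0.08, T.NK = 0.07,
          Myeloid = 0.05, iCAF = 0.02, Cholangiocyte = 0.02,
          B.Plasma = 0.005, Hepatocyte = 0.005),
    B = c(Malignant = 0.30, Hepatocyte = 0.20, T.NK = 0.15, mCAF = 0.10,
          Myeloid = 0.10, Capillary = 0.05, iCAF = 0.05,
          Cholangiocyte = 0.03, B.Plasma = 0.02),
    N = c(Hepatocyte = 0.60, Capillary = 0.12, iCAF = 0.08, T.NK = 0.08,
          Myeloid = 0.06, Cholangiocyte = 0.03, B.Plasma = 0.02,
          mCAF = 0.01))
}

#' Construct a planted-niche specification
#'
#' A niche is planted as a Matern-style cluster: parent centers uniform in
#' the FOV, member cells as isotropic Gaussian offspring around each
#' center, member types drawn from the niche's mixture.
#'
#' @param name niche label written into the truth table.
#' @param mixture named proportions over cell types (sums to 1).
#' @param radius_um Gaussian offspring standard deviation in μm.
#' @param clusters_per_fov expected cluster count per FOV, a single number
#'   or a vector named by region (`T`, `B`, `N`); 0 suppresses the niche
#'   in that region.
#' @param cells_per_cluster expected member cells per cluster.
#' @return list of class `niche_spec`.
#' @export
niche_spec <- function(name, mixture, radius_um = 35,
                       clusters_per_fov = c(T = 1, B = 1, N = 1),
                       cells_per_cluster = 55) {
  .assert(abs(sum(mixture) - 1) < 1e-8,
          "mixture for '%s' sums to %g, not 1", name, sum(mixture))
  .assert(radius_um >= 0, "radius_um must be >= 0")
  .assert(all(clusters_per_fov >= 0) && cells_per_cluster > 0,
          "cluster intensities must be nonnegative")
  structure(list(name = name, mixture = mixture, radius_um = radius_um,
                 clusters_per_fov = clusters_per_fov,
                 cells_per_cluster = cells_per_cluster),
            class = "niche_spec")
}

#' Default planted niches
#'
#' Nine niches mirroring the recurrent composition states of an HCC
#' microenvironment: malignant-capillary and capillary-CAF niches, a pure
#' SPINK1-like malignant state, an immune-rich iCAF niche confined to
#' normal tissue, a T/DC niche confined to the invasive boundary, an
#' outcome-linked mCAF-cholangiocyte niche, plus Treg-, B/plasma- and
#' neutrophil-like niches.
#' @return list of nine `niche_spec` objects.
#' @export
default_niche_specs <- function() {
  list(
    niche_spec("Malignant_Capi",
               c(Malignant = 0.50, Capillary = 0.40, Myeloid = 0.10),
               radius_um = 20, cells_per_cluster = 100,
               clusters_per_fov = c(T = 1.6, B = 0.4, N = 0)),
    niche_spec("Capi_CAFs",
               c(Capillary = 0.35, mCAF = 0.30, iCAF = 0.25,
                 Hepatocyte = 0.10),
               radius_um = 20, cells_per_cluster = 100,
               clusters_per_fov = c(T = 0.8, B = 0.8, N = 0)),
    niche_spec("Malignant_SPINK1",
               c(Malignant = 0.95, T.NK = 0.05),
               radius_um = 20, cells_per_cluster = 100,
               clusters_per_fov = c(T = 1.2, B = 0, N = 0)),
    niche_spec("iCAFs_Immune",
               c(iCAF = 0.40, T.NK = 0.20, Myeloid = 0.20,
                 B.Plasma = 0.20),
               radius_um = 20, cells_per_cluster = 100,
               clusters_per_fov = c(T = 0, B = 0.8, N = 1.2)),
    niche_spec("CD8_CD4_DCs",
               c(T.NK = 0.45, Myeloid = 0.45, B.Plasma = 0.10),
               radius_um = 20, cells_per_cluster = 100,
               clusters_per_fov = c(T = 0, B = 1.6, N = 0)),
    niche_spec("mCAFs_Chola",
               c(mCAF = 0.55, Cholangiocyte = 0.45),
               radius_um = 20, cells_per_cluster = 100,
               clusters_per_fov = c(T = 1.2, B = 0.4, N = 0)),
    niche_spec("Tregs",
               c(T.NK = 0.90, Myeloid = 0.10),
               radius_um = 20, cells_per_cluster = 100,
               clusters_per_fov = c(T = 0.4, B = 0.4, N = 0.4)),
    niche_spec("B_Plasma",
               c(B.Plasma = 0.85, T.NK = 0.15),
               radius_um = 20, cells_per_cluster = 100,
               clusters_per_fov = c(T = 0, B = 0.4, N = 0.8)),
    niche_spec("Nphs",
               c(Myeloid = 0.90, T.NK = 0.10),
               radius_um = 20, cells_per_cluster = 100,
               clusters_per_fov = c(T = 0.4, B = 0.4, N = 0.8)))
}

#' Default gene model
#'
#' A compact CosMx-like panel: six marker genes per lineage (mean 25 in the
#' own type), the capillary-exclusive ligand DLL4, a 30-gene
#' NOTCH/ECM receptor program expressed by mCAFs (the planted
#' differential-expression target of the spatial coupling), 20
#' housekeeping genes and 200 neutral filler genes. The fillers keep the
#' receptor program a realistically small share (~1%) of receiver totals,
#' as in kilo-plex panels, so that per-cell normalization does not turn a
#' planted up-regulation into spurious down-shifts of unrelated genes. Negative-binomial
#' counts (dispersion = `size` parameter, default 2) with per-type mean
#' vectors rescaled so expected per-cell totals hit `total_target`
#' (default 800 transcripts, near the platform's reported medians). A
#' `low_count_frac` share of cells is planted as segmentation-failure-like
#' low-count cells for QC testing.
#'
#' @return list with `mean_matrix` (genes x types), `dispersion`,
#'   `total_target`, `low_count_frac`, `low_count_target`, `signatures`,
#'   `program`.
#' @export
default_gene_model <- function() {
  signatures <- list(
    Malignant = c("SPINK1", "GPC3", "AFP", "AKR1B10", "MDK", "S100A10"),
    Hepatocyte = c("ALB", "APOA1", "TTR", "TF", "CYP2E1", "HP"),
    Cholangiocyte = c("KRT19", "KRT7", "EPCAM", "SOX9", "CFTR", "ANXA4"),
    Capillary = c("PECAM1", "CD34", "VWF", "ENG", "CLDN5", "AQP1"),
    mCAF = c("COL1A1", "COL1A2", "COL3A1", "ACTA2", "TAGLN", "MYH11"),
    iCAF = c("CXCL12", "PDGFRA", "C3", "C7", "CFD", "IGF1"),
    T.NK = c("CD3D", "CD3E", "TRAC", "NKG7", "GNLY", "IL7R"),
    B.Plasma = c("MS4A1", "CD79A", "IGHG1", "IGHA1", "MZB1", "JCHAIN"),
    Myeloid = c("CD68", "CD14", "LYZ", "AIF1", "C1QA", "FCGR3A"))
  program <- c("NOTCH3", "HES1", "HEY1", "HEY2", "HEYL", "FN1", "COL4A1",
               "COL4A2", "COL5A3", "COL5A1", "COL6A1", "COL6A2", "COL6A3",
               "SPARC", "LUM", "BGN", "FBN1", "FBLN1", "MMP2", "TIMP1",
               "LOX", "LOXL1", "POSTN", "THBS1", "THBS2", "SULF1", "VCAN",
               "EDNRA", "PDGFC", "ANGPT2")
  housekeeping <- c("ACTB", "GAPDH", "B2M", "RPL13A", "RPS18", "EEF1A1",
                    "TUBB", "UBC", "PPIA", "TPT1", "RPL10", "RPS6",
                    "RPL41", "RPS27", "RPLP1", "FAU", "NACA", "BTF3",
                    "SERF2", "OAZ1")
  fillers <- sprintf("NC%03d", 1:200)
  types <- default_cell_types()
  genes <- c(unlist(signatures, use.names = FALSE), "DLL4", program,
             housekeeping, fillers)
  M <- matrix(0.5, length(genes), length(types),
              dimnames = list(genes, types))
  for (t in names(signatures)) M[signatures[[t]], t] <- 25
  M["DLL4", ] <- 0
  M["DLL4", "Capillary"] <- 15
  M[program, ] <- 0.5
  M[program, "mCAF"] <- 0.25
  M[housekeeping, ] <- 8
  M[fillers, ] <- 2
  list(mean_matrix = M, dispersion = 2, total_target = 800,
       low_count_frac = 0.05, low_count_target = 5,
       signatures = signatures, program = program)
}

#' Default spatial coupling
#'
#' Capillary senders express the ligand DLL4; mCAF receivers within the
#' coupling radius of at least one sender express the 30-gene receptor
#' program at `2^log2fc` times its baseline mean. The 30 μm radius models
#' a contact-dependent (juxtacrine Notch) interaction.
#' @param gene_model gene model supplying the receptor program.
#' @return list with ligand, sender, receptor_program, receiver,
#'   radius_um, log2fc.
#' @export
default_coupling_spec <- function(gene_model = default_gene_model()) {
  list(ligand = "DLL4", sender = "Capillary",
       receptor_program = gene_model$program, receiver = "mCAF",
       radius_um = 30, log2fc = 1)
}

#' Default survival model
#'
#' Exponential event times with hazard
#' `baseline_hazard * exp(beta * abundance)` (months), random independent
#' censoring at approximately `censoring_rate`, and administrative
#' censoring at 120 months.
#' @return list with baseline_hazard, beta, censoring_rate, admin_months.
#' @export
default_survival_spec <- function() {
  list(baseline_hazard = 0.02, beta = 3, censoring_rate = 0.2,
       admin_months = 120)
}
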