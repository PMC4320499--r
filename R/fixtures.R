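#' Curated core plasma-cell signaling network
#'
#' A hand-curated signed network covering the pathway fragments the four
#' shipped patient case studies exercise: the p53--PTEN/IGFBP3--AKT--NFkB
#' axis and its BCL2/BIRC3 survival output; PI3K/mTORC1 signaling with
#' TSC1--RHEB control; the MEK/ERK--AP1 proliferative arm under RXRA
#' restraint; TGF-beta/SMAD and FOXO1 induction of the CDKN1A cell-cycle
#' brake on the cyclin D1--CDK4/6 checkpoint and E2F; CUL1/proteasome
#' degradation control of CTNNB1, NOTCH1, NFKBIA and CDKN1A; IL6--JAK--STAT
#' signaling into MCL1, BCL2 and cyclin D1; hedgehog (SHH--SMO) and NOTCH
#' (DLL4--NOTCH1) proliferative inputs; receptor tyrosine kinases (MET,
#' IGF1R, FGFR1) feeding PI3K and MEK; and the intrinsic apoptosis chain
#' (BBC3 -| BCL2/MCL1 -| CASP9 -> CASP3 -> cleaved PARP1, with BIRC3
#' restraining CASP3, a constitutive APAF1 apoptosome drive on CASP9 and
#' the caspase-3 -> caspase-9 feedback amplification that makes apoptotic
#' commitment switch-like: the cascade stays off while either BCL2 or MCL1
#' holds CASP9, and fires once both clamps are released). Phospho-forms are
#' not distinguished (one activity per node) and "cleaved PARP1" is a node
#' activated by CASP3.
#'
#' Topology and signs follow the case-study pathway descriptions; weights
#' and Hill parameters are curation choices (documented defaults, with
#' per-node ceilings below 1 so that copy-number amplification has
#' headroom).
#'
#' @return a validated [NetworkModel-class].
#' @export
mmCoreNetwork <- function() {
  g <- 0.6   # default ceiling for gene products: amplification headroom
  N <- function(id, kind = "gene_product", basal = 0.5, x_max = g,
                hill_n = 1.4, hill_k = 0.3,
                biomarker = FALSE, marker_groups = "")
    data.frame(id = id, kind = kind, basal = basal, x_max = x_max,
               hill_n = hill_n, hill_k = hill_k,
               biomarker = biomarker, marker_groups = marker_groups,
               stringsAsFactors = FALSE)
  nodes <- rbind(
    N("TP53", basal = 0.55, biomarker = TRUE),
    N("PTEN", biomarker = TRUE),
    N("IGFBP3"),
    N("BBC3", biomarker = TRUE, marker_groups = "apoptosis"),
    N("RB1", basal = 0.55),
    N("FOXO1", basal = 0.55),
    N("PI3K", hill_n = 1.2, hill_k = 0.05),
    N("AKT1", hill_n = 3.026414062, hill_k = 0.3746749437, biomarker = TRUE),
    N("NFkB", kind = "complex", x_max = 1, hill_n = 1.30525753,
      hill_k = 0.1859096067, biomarker = TRUE),
    N("NFKBIA", basal = 0.6),
    N("TJP2"),
    N("RXRA"),
    N("MEK", hill_n = 2.876455669, hill_k = 0.7),
    N("ERK", biomarker = TRUE),
    N("AP1", kind = "complex", x_max = 1),
    N("MET", kind = "gene_product", basal = 0.35),
    N("IGF1R", basal = 0.35),
    N("FGFR1", basal = 0.35),
    N("IL6", kind = "ligand", basal = 0.3),
    N("JAK2", hill_n = 5.751575883, hill_k = 0.4324545432),
    N("JAK3", hill_n = 5.751575883, hill_k = 0.4324545432),
    N("STAT3", hill_n = 1.33922359, hill_k = 0.11448306, biomarker = TRUE),
    N("STAT5", hill_n = 1.33922359, hill_k = 0.11448306, biomarker = TRUE),
    N("SHH", kind = "ligand", basal = 0.25),
    N("SMO"),
    N("DLL4", kind = "ligand", basal = 0.25),
    N("NOTCH1"),
    N("CTNNB1", basal = 0.55, biomarker = TRUE),
    N("CUL1"),
    N("proteasome", kind = "process", basal = 0.9, x_max = 1,
      hill_n = 1.914641066, hill_k = 0.5337785978),
    N("TSC1", basal = 0.55),
    N("RHEB", basal = 0.6),
    N("mTORC1", kind = "complex", x_max = 1, hill_n = 4.893262296,
      hill_k = 0.6593367452, biomarker = TRUE),
    N("TGFBR1"),
    N("SMAD", kind = "complex", x_max = 1),
    N("CDKN1A", biomarker = TRUE),
    N("CCND1", hill_n = 1.2, hill_k = 0.0639276518, biomarker = TRUE),
    N("CCND1_CDK46", kind = "complex", x_max = 1, hill_n = 2,
      hill_k = 0.4663758379, biomarker = TRUE,
      marker_groups = "proliferation"),
    N("E2F", biomarker = TRUE, marker_groups = "proliferation"),
    N("BCL2", hill_n = 4.514502405, hill_k = 0.05, biomarker = TRUE,
      marker_groups = "survival"),
    N("MCL1", hill_n = 2.23698349, hill_k = 0.1610250129, biomarker = TRUE,
      marker_groups = "survival"),
    N("BIRC3", biomarker = TRUE, marker_groups = "survival"),
    # apoptosome scaffold: constitutive CASP9 drive gated by the clamps
    N("APAF1", basal = 0.9, x_max = 1),
    # caspases start low (basal sets the initial condition only) and keep
    # apoptosis off until both survival clamps release CASP9
    N("CASP9", basal = 0.2, x_max = 1, hill_n = 3.828651697,
      hill_k = 0.3758290974, biomarker = TRUE, marker_groups = "apoptosis"),
    N("CASP3", basal = 0.2, x_max = 1, hill_n = 3.297783844,
      hill_k = 0.1441076739, biomarker = TRUE, marker_groups = "apoptosis"),
    N("cPARP1", basal = 0.2, x_max = 1, biomarker = TRUE,
      marker_groups = "apoptosis"))

  E <- function(source, target, sign = "activating", weight = 1,
                mechanism = "signaling", cofactor = NA_character_)
    data.frame(source = source, target = target, sign = sign,
               weight = weight, mechanism = mechanism, cofactor = cofactor,
               stringsAsFactors = FALSE)
  edges <- rbind(
    E("TP53", "PTEN", weight = 0.9, mechanism = "transcriptional"),
    E("TP53", "IGFBP3", weight = 0.9, mechanism = "transcriptional"),
    E("TP53", "BBC3", weight = 0.8, mechanism = "transcriptional"),
    E("PTEN", "AKT1", "inhibiting", 0.7),
    E("IGFBP3", "AKT1", "inhibiting", 0.3),
    E("PI3K", "AKT1", weight = 0.95),
    E("MET", "PI3K", weight = 0.5),
    E("IGF1R", "PI3K", weight = 0.5),
    E("FGFR1", "PI3K", weight = 0.5),
    E("MET", "MEK", weight = 0.5),
    E("IGF1R", "MEK", weight = 0.5),
    E("FGFR1", "MEK", weight = 0.5),
    E("MEK", "ERK", weight = 0.9),
    E("ERK", "AP1", weight = 0.9),
    E("RXRA", "AP1", "inhibiting", 0.5),
    E("AP1", "CCND1", weight = 0.95, mechanism = "transcriptional"),
    E("AP1", "CDKN1A", "inhibiting", 0.15, mechanism = "transcriptional"),
    E("CTNNB1", "CCND1", weight = 0.3, mechanism = "transcriptional"),
    E("NOTCH1", "CCND1", weight = 0.25, mechanism = "transcriptional"),
    E("SMO", "CCND1", weight = 0.25, mechanism = "transcriptional"),
    E("STAT5", "CCND1", weight = 0.2557003959, mechanism = "transcriptional"),
    E("mTORC1", "CCND1", weight = 0.1656766027),
    E("CCND1", "CCND1_CDK46", weight = 1),
    E("CDKN1A", "CCND1_CDK46", "inhibiting", 0.95),
    E("CCND1_CDK46", "E2F", weight = 0.95),
    E("RB1", "E2F", "inhibiting", 0.75),
    E("TGFBR1", "SMAD", weight = 0.9),
    E("SMAD", "CDKN1A", weight = 0.844165706, mechanism = "transcriptional"),
    E("FOXO1", "CDKN1A", weight = 0.5, mechanism = "transcriptional"),
    E("AKT1", "FOXO1", "inhibiting", 0.6),
    E("TSC1", "RHEB", "inhibiting", 0.8),
    E("RHEB", "mTORC1", weight = 0.8),
    E("AKT1", "mTORC1", weight = 0.6),
    E("AKT1", "NFkB", weight = 0.6588839593),
    E("TJP2", "NFkB", "inhibiting", 0.3),
    E("NFKBIA", "NFkB", "inhibiting", 0.95),
    E("CUL1", "NFKBIA", "inhibiting", 0.5468657113, "degradation",
      "proteasome"),
    E("CUL1", "CTNNB1", "inhibiting", 0.6, "degradation", "proteasome"),
    E("CUL1", "NOTCH1", "inhibiting", 0.4, "degradation", "proteasome"),
    E("CUL1", "CDKN1A", "inhibiting", 0.9482878946, "degradation",
      "proteasome"),
    E("CUL1", "BBC3", "inhibiting", 0.929870664, "degradation", "proteasome"),
    E("NFkB", "BCL2", weight = 0.5869690731, mechanism = "transcriptional"),
    E("NFkB", "BIRC3", weight = 0.6, mechanism = "transcriptional"),
    E("STAT5", "BCL2", weight = 0.5890684831, mechanism = "transcriptional"),
    E("STAT3", "MCL1", weight = 0.95, mechanism = "transcriptional"),
    # cap-dependent translation of MCL1
    E("mTORC1", "MCL1", weight = 0.3345909974),
    # ERK-mediated MCL1 stabilization
    E("ERK", "MCL1", weight = 0.474150894),
    E("IL6", "JAK2", weight = 0.9),
    E("IL6", "JAK3", weight = 0.9),
    E("JAK2", "STAT3", weight = 0.8),
    E("JAK3", "STAT3", weight = 0.6),
    E("JAK2", "STAT5", weight = 0.7),
    E("JAK3", "STAT5", weight = 0.7),
    E("SHH", "SMO", weight = 0.8),
    E("DLL4", "NOTCH1", weight = 0.6),
    E("BBC3", "BCL2", "inhibiting", 0.3709131702),
    E("APAF1", "CASP9", weight = 0.7348159747),
    E("CASP3", "CASP9", weight = 0.95),  # feedback amplification
    E("BCL2", "CASP9", "inhibiting", 0.8319963003),
    E("MCL1", "CASP9", "inhibiting", 0.9048462271),
    E("CASP9", "CASP3", weight = 1),
    E("BIRC3", "CASP3", "inhibiting", 0.15),
    E("CASP3", "cPARP1", weight = 1))

  networkModel(nodes, edges, name = "mm-plasma-cell-core", version = "1")
}

#' Packaged drug library
#'
#' Six small-molecule agents used across the case studies: BEZ235 (dual
#' PI3K/mTORC1 inhibitor), ABT-199 (BCL2 mimetic, inhibits BCL2 function
#' without lowering its level), sirolimus (mTORC1), trametinib (MEK; often
#' described as an ERK-pathway inhibitor -- it targets the MEK node, which
#' feeds ERK), bortezomib (proteasome) and tofacitinib (JAK2/JAK3). Doses
#' are ec50-relative with ec50 = 1 and Hill coefficient 1.
#'
#' @return named list of [DrugSpec-class].
#' @export
mmDrugLibrary <- function() {
  lib <- list(
    drugSpec("BEZ235", c("PI3K", "mTORC1")),
    drugSpec("ABT-199", "BCL2"),
    drugSpec("sirolimus", "mTORC1"),
    drugSpec("trametinib", "MEK"),
    drugSpec("bortezomib", "proteasome"),
    drugSpec("tofacitinib", c("JAK2", "JAK3")))
  stats::setNames(lib, vapply(lib, function(d) d@name, ""))
}

#' Paths to packaged fixture files
#'
#' @param name one of the packaged fixture file names, e.g.
#'   \code{"gene_annotation.tsv"}, \code{"patient1_aberrations.tsv"},
#'   \code{"mm_core_network.json"}, \code{"drug_library.tsv"},
#'   \code{"cytoband_order.tsv"}.
#' @return absolute file path.
#' @export
fixturePath <- function(name) {
  system.file("extdata", name, package = "AvatarScreen", mustWork = TRUE)
}

#' Build a case-study avatar from the packaged fixtures
#'
#' Reads the packaged annotation and the requested patient's aberration
#' table and resolves them against the core network's gene set.
#'
#' @param patient integer 1--4.
#' @param model the network model (defaults to [mmCoreNetwork()]).
#' @return an [AvatarSpec-class].
#' @export
caseStudyAvatar <- function(patient, model = mmCoreNetwork()) {
  stopifnot(patient %in% 1:4)
  ann <- readGeneAnnotation(fixturePath("gene_annotation.tsv"), "tsv")
  ab <- readAberrations(fixturePath(sprintf("patient%d_aberrations.tsv",
                                            patient)))
  buildAvatar(ab, ann, networkGenes(model),
              patientId = sprintf("patient%d", patient))
}
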