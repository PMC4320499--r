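#' @import methods
NULL

ABERRATION_KINDS <- c("copy_gain", "copy_loss", "monosomy", "trisomy",
                      "translocation_amplification", "mutation_gof",
                      "mutation_lof")
SCOPE_TYPES <- c("whole_chromosome", "interval", "cytoband_range", "gene")
ZYGOSITIES <- c("heterozygous", "homozygous", "unspecified")
NODE_KINDS <- c("gene_product", "complex", "ligand", "process")
EDGE_SIGNS <- c("activating", "inhibiting")
EDGE_MECHANISMS <- c("signaling", "transcriptional", "degradation")
MARKER_GROUPS <- c("proliferation", "survival", "apoptosis")
DRUG_CLASSES <- c("small_molecule", "biologic")
DRUG_ACTIONS <- c("inhibit", "activate")

#' Signed signaling network model
#'
#' Container for a curated signed, mechanism-annotated interaction graph.
#' Nodes carry normalized-Hill parameters (basal activity, activity ceiling
#' \code{x_max}, Hill exponent and half-activation constant) plus biomarker
#' annotation; edges carry a sign, a weight in (0, 1], a mechanism
#' (\code{signaling}, \code{transcriptional} or \code{degradation}) and, for
#' degradation edges, a cofactor node (e.g. the proteasome) whose functional
#' activity gates the degradation.
#'
#' @slot nodes data.frame with columns \code{id}, \code{kind}, \code{basal},
#'   \code{x_max}, \code{hill_n}, \code{hill_k}, \code{biomarker} (logical),
#'   \code{marker_groups} (semicolon-separated subset of
#'   proliferation/survival/apoptosis, \code{""} for none).
#' @slot edges data.frame with columns \code{source}, \code{target},
#'   \code{sign}, \code{weight}, \code{mechanism}, \code{cofactor}
#'   (\code{NA} unless mechanism is degradation).
#' @slot name,version character scalars identifying the curation.
#' @seealso [networkModel()], [validateNetwork()], [readNetwork()]
#' @export
setClass("NetworkModel",
         representation(nodes = "data.frame", edges = "data.frame",
                        name = "character", version = "character"))

setValidity("NetworkModel", function(object) {
  needed_n <- c("id", "kind", "basal", "x_max", "hill_n", "hill_k",
                "biomarker", "marker_groups")
  needed_e <- c("source", "target", "sign", "weight", "mechanism", "cofactor")
  if (!all(needed_n %in% names(object@nodes)))
    return("nodes table lacks required columns")
  if (!all(needed_e %in% names(object@edges)))
    return("edges table lacks required columns")
  if (anyDuplicated(object@nodes$id))
    return("node ids must be unique")
  TRUE
})

#' Patient simulation avatar
#'
#' The perturbation set ("trigger file") that transitions the control network
#' into a patient-specific disease state, with optional subclone variants.
#'
#' @slot patientId character label.
#' @slot perturbations data.frame with columns \code{gene},
#'   \code{direction} (\code{knockdown}/\code{overexpress}) and
#'   \code{magnitude} (expression-scale factor; in (0,1) for knockdown,
#'   > 1 for overexpression).
#' @slot clones named list of alternative perturbation data.frames; a
#'   regimen's patient-level efficacy is the minimum across clones.
#' @slot coverageReport character vector of resolved genes excluded because
#'   they are absent from the network model's gene set.
#' @seealso [buildAvatar()]
#' @export
setClass("AvatarSpec",
         representation(patientId = "character", perturbations = "data.frame",
                        clones = "list", coverageReport = "character"))

setValidity("AvatarSpec", function(object) {
  p <- object@perturbations
  if (!all(c("gene", "direction", "magnitude") %in% names(p)))
    return("perturbations need columns gene/direction/magnitude")
  if (anyDuplicated(p$gene))
    return("a gene may appear only once in a perturbation list")
  bad <- (p$direction == "knockdown" & !(p$magnitude > 0 & p$magnitude < 1)) |
         (p$direction == "overexpress" & !(p$magnitude > 1))
  if (any(bad))
    return(sprintf("magnitude out of range for %s",
                   paste(p$gene[bad], collapse = ", ")))
  TRUE
})

#' Simulation configuration
#'
#' Time units are arbitrary; only the ratio horizon/tau matters. Defaults
#' equilibrate the untreated network for 50,000 time units and continue for
#' 100,000 units after triggers (perturbations and/or drugs) are applied.
#'
#' @slot preTriggerHorizon,postTriggerHorizon integration horizons (> 0).
#' @slot tau first-order node time constant.
#' @slot convergenceEps steady-state residual threshold on max |dx/dt|.
#' @slot relTol,absTol solver tolerances passed to [deSolve::lsoda()].
#' @slot seed integer seed used only by randomized modules.
#' @export
setClass("SimulationConfig",
         representation(preTriggerHorizon = "numeric",
                        postTriggerHorizon = "numeric",
                        tau = "numeric", convergenceEps = "numeric",
                        relTol = "numeric", absTol = "numeric",
                        seed = "integer"),
         prototype(preTriggerHorizon = 50000, postTriggerHorizon = 1e5,
                   tau = 100, convergenceEps = 1e-6,
                   relTol = 1e-8, absTol = 1e-10, seed = 1L))

setValidity("SimulationConfig", function(object) {
  if (object@preTriggerHorizon <= 0 || object@postTriggerHorizon <= 0)
    return("horizons must be positive")
  if (object@convergenceEps <= 0) return("convergenceEps must be positive")
  TRUE
})

#' Network state at a time point
#'
#' @slot activities named numeric vector of node activities, each within
#'   \code{[0, x_max]} of its node.
#' @slot time simulation time of the snapshot.
#' @slot converged TRUE iff \code{residual < convergenceEps}.
#' @slot residual max |dx/dt| at the snapshot.
#' @export
setClass("SystemState",
         representation(activities = "numeric", time = "numeric",
                        converged = "logical", residual = "numeric"))

#' Sampled trajectory
#'
#' @slot times strictly increasing sample times.
#' @slot states matrix (time x node) of activities.
#' @export
setClass("Trajectory",
         representation(times = "numeric", states = "matrix"))

setValidity("Trajectory", function(object) {
  if (length(object@times) != nrow(object@states))
    return("times and states disagree in length")
  if (is.unsorted(object@times, strictly = TRUE))
    return("times must be strictly increasing")
  TRUE
})

#' Drug specification
#'
#' @slot name drug label.
#' @slot targets data.frame with columns \code{node} and \code{action}
#'   (\code{inhibit} or \code{activate}); at least one target.
#' @slot drugClass \code{small_molecule} or \code{biologic}; governs the
#'   default screening dose (55\% vs 95\% target manipulation).
#' @slot ec50 dose giving half-maximal target occupancy (dose units are
#'   arbitrary, ec50-relative).
#' @slot hillCoeff occupancy-curve Hill coefficient (>= 1).
#' @export
setClass("DrugSpec",
         representation(name = "character", targets = "data.frame",
                        drugClass = "character", ec50 = "numeric",
                        hillCoeff = "numeric"))

setValidity("DrugSpec", function(object) {
  if (nrow(object@targets) < 1) return("a drug needs at least one target")
  if (!all(c("node", "action") %in% names(object@targets)))
    return("targets need columns node/action")
  if (!all(object@targets$action %in% DRUG_ACTIONS))
    return("unknown target action")
  if (!object@drugClass %in% DRUG_CLASSES) return("unknown drug class")
  if (object@ec50 <= 0) return("ec50 must be positive")
  if (object@hillCoeff < 1) return("hillCoeff must be >= 1")
  TRUE
})

#' Drug applied at a dose
#'
#' @slot drug a [DrugSpec-class].
#' @slot dose nonnegative dose in ec50-relative units; interpreted as a
#'   physiological post-ADME concentration at the target.
#' @export
setClass("DrugApplication",
         representation(drug = "DrugSpec", dose = "numeric"))

setValidity("DrugApplication", function(object) {
  if (object@dose < 0) return("dose must be nonnegative")
  TRUE
})

#' Biomarker weighting for the tumor relative growth index
#'
#' @slot proliferation,survival,apoptosis named numeric weight vectors
#'   (names are node ids); each group nonempty, weights normalized to sum
#'   to one at construction.
#' @slot alpha mixing coefficient between proliferation and survival in
#'   \code{rgi = (alpha P + (1 - alpha) S) (1 - A)}.
#' @export
setClass("MarkerConfig",
         representation(proliferation = "numeric", survival = "numeric",
                        apoptosis = "numeric", alpha = "numeric"))

setValidity("MarkerConfig", function(object) {
  for (g in MARKER_GROUPS) {
    w <- slot(object, g)
    if (length(w) == 0) return(sprintf("marker group '%s' is empty", g))
    if (is.null(names(w)) || any(!nzchar(names(w))))
      return("marker weights must be named by node id")
    if (any(w <= 0)) return("marker weights must be positive")
  }
  if (object@alpha < 0 || object@alpha > 1) return("alpha must be in [0,1]")
  TRUE
})
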