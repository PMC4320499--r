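#' Construct a network model
#'
#' Missing node columns are filled with the documented curation defaults
#' (kind \code{gene_product}, basal 0.5, \code{x_max} 1.0, Hill exponent 1.4,
#' half-activation 0.5, no biomarker annotation); missing edge columns with
#' sign \code{activating}, weight 1.0, mechanism \code{signaling} and no
#' cofactor.
#'
#' @param nodes data.frame with at least an \code{id} column.
#' @param edges data.frame with at least \code{source} and \code{target}.
#' @param name,version identifying labels.
#' @param check if TRUE (default), [validateNetwork()] violations raise an
#'   error.
#' @return a [NetworkModel-class].
#' @export
networkModel <- function(nodes, edges, name = "unnamed", version = "0",
                         check = TRUE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(nodes$id)) stopf("nodes need an 'id' column")
  n <- nrow(nodes)
  fill <- function(df, col, default) {
    if (is.null(df[[col]])) df[[col]] <- rep(default, nrow(df))
    df
  }
  nodes <- fill(nodes, "kind", "gene_product")
  nodes <- fill(nodes, "basal", 0.5)
  nodes <- fill(nodes, "x_max", 1.0)
  nodes <- fill(nodes, "hill_n", 1.4)
  nodes <- fill(nodes, "hill_k", 0.5)
  nodes <- fill(nodes, "biomarker", FALSE)
  nodes <- fill(nodes, "marker_groups", "")
  nodes$basal <- as.numeric(nodes$basal)
  nodes$x_max <- as.numeric(nodes$x_max)
  nodes$hill_n <- as.numeric(nodes$hill_n)
  nodes$hill_k <- as.numeric(nodes$hill_k)
  nodes$biomarker <- as.logical(nodes$biomarker)
  nodes$marker_groups[is.na(nodes$marker_groups)] <- ""
  if (nrow(edges)) {
    if (is.null(edges$source) || is.null(edges$target))
      stopf("edges need 'source' and 'target' columns")
    edges <- fill(edges, "sign", "activating")
    edges <- fill(edges, "weight", 1.0)
    edges <- fill(edges, "mechanism", "signaling")
    edges <- fill(edges, "cofactor", NA_character_)
    edges$weight <- as.numeric(edges$weight)
    edges$cofactor <- as.character(edges$cofactor)
  } else {
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), weight = numeric(),
                        mechanism = character(), cofactor = character(),
                        stringsAsFactors = FALSE)
  }
  model <- new("NetworkModel",
               nodes = nodes[, c("id", "kind", "basal", "x_max", "hill_n",
                                 "hill_k", "biomarker", "marker_groups")],
               edges = edges[, c("source", "target", "sign", "weight",
                                 "mechanism", "cofactor"), drop = FALSE],
               name = name, version = version)
  if (check) {
    v <- validateNetwork(model)
    if (length(v)) stopf("invalid network model:\n  %s",
                         paste(v, collapse = "\n  "))
  }
  model
}

#' Construct a simulation configuration
#'
#' @param preTriggerHorizon,postTriggerHorizon,tau,convergenceEps,relTol,absTol,seed
#'   see [SimulationConfig-class].
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(preTriggerHorizon = 50000,
                             postTriggerHorizon = 100000,
                             tau = 100, convergenceEps = 1e-6,
                             relTol = 1e-8, absTol = 1e-10, seed = 1L) {
  new("SimulationConfig", preTriggerHorizon = preTriggerHorizon,
      postTriggerHorizon = postTriggerHorizon, tau = tau,
      convergenceEps = convergenceEps, relTol = relTol, absTol = absTol,
      seed = as.integer(seed))
}

#' Construct a drug specification
#'
#' @param name drug label.
#' @param targets character vector of target node ids, or a data.frame with
#'   columns \code{node} and \code{action}.
#' @param action default action applied when \code{targets} is a character
#'   vector.
#' @param drugClass \code{small_molecule} or \code{biologic}.
#' @param ec50,hillCoeff occupancy-curve parameters.
#' @return a [DrugSpec-class].
#' @export
drugSpec <- function(name, targets, action = "inhibit",
                     drugClass = "small_molecule", ec50 = 1, hillCoeff = 1) {
  if (is.character(targets))
    targets <- data.frame(node = targets, action = action,
                          stringsAsFactors = FALSE)
  new("DrugSpec", name = name, targets = targets, drugClass = drugClass,
      ec50 = ec50, hillCoeff = hillCoeff)
}

#' Apply a drug at a dose
#' @param drug a [DrugSpec-class].
#' @param dose nonnegative dose (ec50-relative units).
#' @return a [DrugApplication-class].
#' @export
drugApplication <- function(drug, dose) {
  new("DrugApplication", drug = drug, dose = dose)
}

#' Construct a biomarker weighting
#'
#' Weights in each group are normalized to sum to one.
#'
#' @param proliferation,survival,apoptosis named numeric weight vectors.
#' @param alpha proliferation/survival mixing coefficient in [0, 1].
#' @return a [MarkerConfig-class].
#' @export
markerConfig <- function(proliferation, survival, apoptosis, alpha = 0.5) {
  norm <- function(w) w / sum(w)
  new("MarkerConfig", proliferation = norm(proliferation),
      survival = norm(survival), apoptosis = norm(apoptosis), alpha = alpha)
}

#' Construct an avatar directly from a perturbation table
#'
#' Most users build avatars from aberration calls via [buildAvatar()]; this
#' low-level constructor is for hand-specified or deserialized triggers.
#'
#' @param patientId label.
#' @param perturbations data.frame(gene, direction, magnitude).
#' @param clones named list of alternative perturbation data.frames.
#' @param coverageReport genes dropped for lack of model coverage.
#' @return an [AvatarSpec-class].
#' @export
avatarSpec <- function(patientId, perturbations = NULL, clones = list(),
                       coverageReport = character()) {
  if (is.null(perturbations))
    perturbations <- data.frame(gene = character(), direction = character(),
                                magnitude = numeric(),
                                stringsAsFactors = FALSE)
  perturbations <- as.data.frame(perturbations, stringsAsFactors = FALSE)
  rownames(perturbations) <- NULL
  new("AvatarSpec", patientId = patientId, perturbations = perturbations,
      clones = clones, coverageReport = coverageReport)
}

#' @describeIn NetworkModel-class compact display
#' @param object a NetworkModel
#' @export
setMethod("show", "NetworkModel", function(object) {
  cat(sprintf("NetworkModel '%s' (v%s): %d nodes, %d edges\n",
              object@name, object@version, nrow(object@nodes),
              nrow(object@edges)))
  mk <- object@nodes$marker_groups
  cat(sprintf("  biomarkers: %d; marker-group members: %d\n",
              sum(object@nodes$biomarker), sum(nzchar(mk))))
})

#' @describeIn AvatarSpec-class compact display
#' @param object an AvatarSpec
#' @export
setMethod("show", "AvatarSpec", function(object) {
  cat(sprintf("AvatarSpec '%s': %d perturbations, %d clone(s), %d uncovered gene(s)\n",
              object@patientId, nrow(object@perturbations),
              length(object@clones), length(object@coverageReport)))
})

#' @describeIn SystemState-class compact display
#' @param object a SystemState
#' @export
setMethod("show", "SystemState", function(object) {
  cat(sprintf("SystemState at t=%g: %d nodes, residual %.3g (%s)\n",
              object@time, length(object@activities), object@residual,
              if (object@converged) "converged" else "NOT converged"))
})

#' @describeIn DrugSpec-class compact display
#' @param object a DrugSpec
#' @export
setMethod("show", "DrugSpec", function(object) {
  cat(sprintf("DrugSpec %s [%s]: %s (ec50=%g, h=%g)\n", object@name,
              object@drugClass,
              paste(sprintf("%s %s", object@targets$action,
                            object@targets$node), collapse = ", "),
              object@ec50, object@hillCoeff))
})

# ---- accessors ------------------------------------------------------------

#' Accessors for core objects
#'
#' Slot access for the package's S4 classes.
#'
#' @param x the object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
networkNodes <- function(x) x@nodes

#' @rdname accessors
#' @export
networkEdges <- function(x) x@edges

#' @rdname accessors
#' @export
networkGenes <- function(x) x@nodes$id

#' @rdname accessors
#' @export
perturbations <- function(x) x@perturbations

#' @rdname accessors
#' @export
coverageReport <- function(x) x@coverageReport

#' @rdname accessors
#' @export
patientId <- function(x) x@patientId

#' @rdname accessors
#' @export
clones <- function(x) x@clones

#' @rdname accessors
#' @export
activities <- function(x) x@activities

#' @rdname accessors
#' @export
isConverged <- function(x) x@converged

#' @rdname accessors
#' @export
residual <- function(x) x@residual

#' @rdname accessors
#' @export
drugName <- function(x) x@name

#' @rdname accessors
#' @export
drugTargets <- function(x) x@targets
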