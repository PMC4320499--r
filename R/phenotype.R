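#' Default biomarker weighting
#'
#' Equal weights within each family: proliferation is read from the
#' cyclin D1-CDK4/6 checkpoint complex and E2F; survival from BCL2, MCL1
#' and BIRC3; apoptosis from the caspase cascade (CASP9, CASP3), Puma
#' (BBC3) and cleaved PARP1. The mixing coefficient between proliferation
#' and survival defaults to 0.5.
#'
#' @param alpha mixing coefficient in [0, 1].
#' @return a [MarkerConfig-class].
#' @export
defaultMarkerConfig <- function(alpha = 0.5) {
  markerConfig(
    proliferation = c(CCND1_CDK46 = 1, E2F = 1),
    survival = c(BCL2 = 1, MCL1 = 1, BIRC3 = 1),
    apoptosis = c(CASP9 = 1, CASP3 = 1, BBC3 = 1, cPARP1 = 1),
    alpha = alpha)
}

#' Functional outputs of a state under drug action
#'
#' A drug acts on a node's functional output, not its level: a BCL2 mimetic
#' suppresses BCL2 function while the BCL2 "level" readout is unchanged.
#' Inhibitors sharing a target combine by dose additivity, matching the
#' simulator. Phenotype scores and biomarker reports are computed on these
#' outputs.
#'
#' @param state a [SystemState-class].
#' @param applications list of [DrugApplication-class] in force.
#' @return named numeric vector of functional outputs.
#' @export
functionalOutputs <- function(state, applications = list()) {
  out <- state@activities
  act <- combinedDrugAction(applications)
  for (node in intersect(names(act$keep), names(out)))
    out[node] <- out[node] * act$keep[node]
  for (node in intersect(names(act$boost), names(out)))
    out[node] <- min(1, out[node] * act$boost[node])
  out
}

#' Tumor relative growth index
#'
#' Group scores P (proliferation), S (survival) and A (apoptosis) are
#' weighted means of the member nodes' functional outputs; the index is
#' \code{rgi = (alpha P + (1 - alpha) S) * (1 - A)}, so apoptotic
#' convergence annihilates growth multiplicatively.
#'
#' @param state a [SystemState-class].
#' @param markers a [MarkerConfig-class].
#' @param applications drugs in force (see [functionalOutputs()]).
#' @return list with \code{P}, \code{S}, \code{A}, \code{rgi}.
#' @export
computeRGI <- function(state, markers = defaultMarkerConfig(),
                       applications = list()) {
  out <- functionalOutputs(state, applications)
  score <- function(w) {
    miss <- setdiff(names(w), names(out))
    if (length(miss)) stopf("marker node(s) missing from state: %s",
                            paste(miss, collapse = ", "))
    sum(w * out[names(w)]) / sum(w)
  }
  P <- score(markers@proliferation)
  S <- score(markers@survival)
  A <- score(markers@apoptosis)
  list(P = P, S = S, A = A,
       rgi = (markers@alpha * P + (1 - markers@alpha) * S) * (1 - A))
}

#' Viability endpoint
#'
#' The proliferation/survival mixture \code{alpha P + (1 - alpha) S} without
#' the apoptosis factor; a plotting convention mirroring relative-growth
#' readouts.
#'
#' @inheritParams computeRGI
#' @return numeric scalar in [0, 1].
#' @export
viabilityIndex <- function(state, markers = defaultMarkerConfig(),
                           applications = list()) {
  r <- computeRGI(state, markers, applications)
  markers@alpha * r$P + (1 - markers@alpha) * r$S
}

#' Treatment efficacy on the relative growth index
#'
#' \code{100 (1 - rgi_treated / rgi_reference)}. A reference rgi of zero
#' (no growth to reduce) yields an efficacy of 0 by convention.
#'
#' @param treated,reference [SystemState-class] objects sharing the marker
#'   config.
#' @param markers a [MarkerConfig-class].
#' @param applications drugs in force in the treated state.
#' @param referenceApplications drugs in force in the reference state
#'   (normally none).
#' @return percent reduction (can be negative if growth increases).
#' @export
efficacy <- function(treated, reference, markers = defaultMarkerConfig(),
                     applications = list(), referenceApplications = list()) {
  rT <- computeRGI(treated, markers, applications)$rgi
  rR <- computeRGI(reference, markers, referenceApplications)$rgi
  if (rR == 0) return(0)
  100 * (1 - rT / rR)
}

#' Per-biomarker change versus a reference state
#'
#' Percent change of each node's functional output versus the reference;
#' nodes whose reference output is zero are reported as absolute changes and
#' flagged.
#'
#' @param treated,reference [SystemState-class] objects.
#' @param nodes node ids to report.
#' @param applications drugs in force in the treated state.
#' @return data.frame with columns \code{node}, \code{delta}
#'   (percent, or absolute where flagged) and \code{absolute} (logical).
#' @export
biomarkerReport <- function(treated, reference, nodes,
                            applications = list()) {
  outT <- functionalOutputs(treated, applications)
  outR <- functionalOutputs(reference)
  miss <- setdiff(nodes, names(outT))
  if (length(miss)) stopf("node(s) missing from state: %s",
                          paste(miss, collapse = ", "))
  ref <- outR[nodes]
  absFlag <- ref == 0
  delta <- ifelse(absFlag, outT[nodes] - ref,
                  100 * (outT[nodes] - ref) / ref)
  data.frame(node = nodes, delta = unname(delta),
             absolute = unname(absFlag), stringsAsFactors = FALSE)
}
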