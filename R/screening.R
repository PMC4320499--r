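# every perturbation variant of an avatar: the primary list plus any clones
avatarVariants <- function(avatar) {
  v <- c(list(primary = avatar@perturbations), avatar@clones)
  lapply(v, function(p) avatarSpec(avatar@patientId, p))
}

# disease baselines for each variant, computed once
variantBaselines <- function(model, avatar, config) {
  lapply(avatarVariants(avatar), function(av)
    controlAndDiseaseStates(model, av, config))
}

# worst-clone efficacy of a set of applications across variants
worstCloneEfficacy <- function(model, avatar, apps, baselines, config,
                               markers) {
  vars <- avatarVariants(avatar)
  effs <- vapply(seq_along(vars), function(i) {
    drugEfficacy(model, vars[[i]], apps, baselines[[i]]$disease, config,
                 markers)
  }, 0)
  min(effs)
}

#' Single-agent drug screen
#'
#' Evaluates every library drug at its default screening dose (55\% target
#' manipulation for small molecules, 95\% for biologics) on the avatar.
#' With clones present, a drug's efficacy is its worst-clone efficacy.
#' Drugs exceeding 30\% reduction of the relative growth index are
#' shortlisted. Per-drug simulation failures are reported in the
#' \code{failure} column and do not abort the screen.
#'
#' @param model a [NetworkModel-class].
#' @param avatar an [AvatarSpec-class].
#' @param library list of [DrugSpec-class] (nonempty).
#' @param config a [SimulationConfig-class].
#' @param markers a [MarkerConfig-class].
#' @return data.frame sorted by efficacy descending with columns
#'   \code{drug}, \code{dose}, \code{efficacy_pct}, \code{shortlisted},
#'   \code{failure}.
#' @export
singleAgentScreen <- function(model, avatar, library,
                              config = simulationConfig(),
                              markers = defaultMarkerConfig()) {
  if (!length(library)) stopf("drug library is empty")
  baselines <- variantBaselines(model, avatar, config)
  rows <- lapply(library, function(drug) {
    app <- defaultScreeningDose(drug)
    eff <- tryCatch(worstCloneEfficacy(model, avatar, list(app), baselines,
                                       config, markers),
                    error = function(e) e)
    if (inherits(eff, "error"))
      data.frame(drug = drug@name, dose = app@dose, efficacy_pct = NA_real_,
                 shortlisted = FALSE, failure = conditionMessage(eff),
                 stringsAsFactors = FALSE)
    else
      data.frame(drug = drug@name, dose = app@dose, efficacy_pct = eff,
                 shortlisted = eff > 30, failure = NA_character_,
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$efficacy_pct), -Inf, out$efficacy_pct),
                   out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bliss and highest-single-agent synergy scores
#'
#' For fractional effects in [0, 1]: Bliss excess is
#' \code{E_ab - (E_a + E_b - E_a E_b)} (supra-additivity beyond independent
#' action); HSA excess is \code{E_ab - max(E_a, E_b)}. A combination is
#' dominated by one agent when its HSA excess falls below \code{delta}, and
#' synergistic when its Bliss excess is positive and it is not dominated.
#'
#' @param eA,eB,eAB fractional single-agent and combination effects in
#'   [0, 1].
#' @param delta dominance margin on the HSA excess (default 0.05).
#' @return list with \code{bliss_excess}, \code{hsa_excess},
#'   \code{dominated}, \code{synergistic}.
#' @export
synergyScores <- function(eA, eB, eAB, delta = 0.05) {
  vals <- c(eA, eB, eAB)
  if (any(vals < 0 | vals > 1))
    stopf("effects must be fractions in [0, 1]")
  bliss <- eAB - (eA + eB - eA * eB)
  hsa <- eAB - max(eA, eB)
  dominated <- hsa < delta
  list(bliss_excess = bliss, hsa_excess = hsa, dominated = dominated,
       synergistic = bliss > 0 && !dominated)
}

#' Exhaustive pairwise combination screen at ICxx doses
#'
#' Each agent is dosed at its own ICxx on the avatar (default IC20, the
#' design that lets low single-agent concentrations combine to exceed IC50
#' efficacy); drugs whose ICxx is unreachable are skipped for that level and
#' listed in the \code{skipped} attribute. Pair effects are worst-clone
#' fractional efficacies; records carry Bliss/HSA scores, the dominance
#' flag, and a shortlist flag (synergistic with combined effect above 0.5).
#'
#' @inheritParams singleAgentScreen
#' @param anchor optional drug name; all pairs must include it.
#' @param xxLevels subset of \code{c(15, 20, 30)} (default 20).
#' @param delta dominance margin passed to [synergyScores()].
#' @return data.frame sorted by (shortlisted desc, bliss_excess desc) with
#'   one row per pair and level; attribute \code{skipped} records drugs
#'   without a reachable ICxx.
#' @export
combinationScreen <- function(model, avatar, library, anchor = NULL,
                              xxLevels = 20, config = simulationConfig(),
                              markers = defaultMarkerConfig(),
                              delta = 0.05) {
  if (!all(xxLevels %in% c(15, 20, 30)))
    stopf("xxLevels must be drawn from {15, 20, 30}")
  if (length(library) < 2 && is.null(anchor))
    stopf("combination screen needs at least two drugs or an anchor")
  nm <- vapply(library, function(d) d@name, "")
  names(library) <- nm
  if (!is.null(anchor) && !anchor %in% nm)
    stopf("anchor drug '%s' is not in the library", anchor)
  baselines <- variantBaselines(model, avatar, config)
  primary <- baselines[["primary"]]

  skipped <- data.frame(drug = character(), xx = numeric(),
                        reason = character(), stringsAsFactors = FALSE)
  rows <- list()
  for (xx in xxLevels) {
    ic <- lapply(library, function(drug)
      findICxx(model, avatar, drug, xx, config, markers,
               baseline = primary))
    ok <- vapply(ic, `[[`, TRUE, "reachable")
    for (d in nm[!ok])
      skipped <- rbind(skipped, data.frame(
        drug = d, xx = xx,
        reason = sprintf("IC%d unreachable (max efficacy %.1f%%)", xx,
                         ic[[d]]$efficacy_pct), stringsAsFactors = FALSE))
    usable <- nm[ok]
    if (length(usable) < 2) next
    pairs <- t(utils::combn(usable, 2))
    if (!is.null(anchor)) {
      if (!anchor %in% usable) next
      keep <- pairs[, 1] == anchor | pairs[, 2] == anchor
      pairs <- pairs[keep, , drop = FALSE]
    }
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, 1]; b <- pairs[i, 2]
      appA <- drugApplication(library[[a]], ic[[a]]$dose)
      appB <- drugApplication(library[[b]], ic[[b]]$dose)
      eA <- worstCloneEfficacy(model, avatar, list(appA), baselines, config,
                               markers) / 100
      eB <- worstCloneEfficacy(model, avatar, list(appB), baselines, config,
                               markers) / 100
      eAB <- worstCloneEfficacy(model, avatar, list(appA, appB), baselines,
                                config, markers) / 100
      clamp <- function(x) min(max(x, 0), 1)
      sc <- synergyScores(clamp(eA), clamp(eB), clamp(eAB), delta)
      rows[[length(rows) + 1L]] <- data.frame(
        drug_a = a, drug_b = b, xx = xx,
        dose_a = ic[[a]]$dose, dose_b = ic[[b]]$dose,
        E_a = eA, E_b = eB, E_ab = eAB,
        bliss_excess = sc$bliss_excess, hsa_excess = sc$hsa_excess,
        dominated = sc$dominated, synergistic = sc$synergistic,
        shortlisted = sc$synergistic && eAB > 0.5,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(drug_a = character(), drug_b = character(), xx = numeric(),
               dose_a = numeric(), dose_b = numeric(), E_a = numeric(),
               E_b = numeric(), E_ab = numeric(), bliss_excess = numeric(),
               hsa_excess = numeric(), dominated = logical(),
               synergistic = logical(), shortlisted = logical(),
               stringsAsFactors = FALSE)
  out <- out[order(-out$shortlisted, -out$bliss_excess, out$drug_a,
                   out$drug_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
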