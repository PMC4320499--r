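#' Normalized Hill activation function
#'
#' \code{x^n (k^n + 1) / (x^n + k^n)}, clipped to [0, 1]. Normalized so that
#' an input at full activity (x = 1) transmits 1 and the half-activation
#' point sits at \code{k} on the unnormalized curve.
#'
#' @param x input activity (vector ok).
#' @param n Hill exponent (>= 1).
#' @param k half-activation constant in (0, 1).
#' @return transmitted activity in [0, 1].
#' @export
hillActivation <- function(x, n = 1.4, k = 0.5) {
  xn <- pmax(x, 0)^n
  kn <- k^n
  pmin(pmax(xn * (kn + 1) / (xn + kn), 0), 1)
}

# Precompute index structures for the ODE right-hand side.
compileModel <- function(model) {
  nd <- model@nodes
  ed <- model@edges
  n <- nrow(nd)
  idx <- stats::setNames(seq_len(n), nd$id)
  act <- ed$sign == "activating"
  cofIdx <- rep(0L, nrow(ed))
  hasCof <- !is.na(ed$cofactor) & nzchar(ed$cofactor)
  cofIdx[hasCof] <- idx[ed$cofactor[hasCof]]
  list(n = n, ids = nd$id, idx = idx,
       basal = nd$basal, xmax = nd$x_max,
       hillN = nd$hill_n, kn = nd$hill_k^nd$hill_n,
       actSrc = unname(idx[ed$source[act]]), actTgt = unname(idx[ed$target[act]]),
       actW = ed$weight[act],
       inhSrc = unname(idx[ed$source[!act]]), inhTgt = unname(idx[ed$target[!act]]),
       inhW = ed$weight[!act], inhCof = cofIdx[!act],
       hasActivators = seq_len(n) %in% idx[ed$target[act]])
}

# Per-node drug action from a list of DrugApplications. Inhibitors hitting
# the same node are combined by dose additivity (Loewe): normalized doses
# add and the effective Hill coefficient is the dose-weighted mean, so a
# drug combined with a copy of itself behaves as a doubled dose rather than
# as two independent blocks. Activating actions multiply (1 + f) boosts.
combinedDrugAction <- function(applications) {
  rows <- do.call(rbind, lapply(applications, function(app) {
    d <- app@drug
    data.frame(node = d@targets$node, action = d@targets$action,
               u = app@dose / d@ec50, h = d@hillCoeff,
               f = fractionalInhibition(app@dose, d@ec50, d@hillCoeff),
               stringsAsFactors = FALSE)
  }))
  keep <- numeric(0)
  boost <- numeric(0)
  if (!is.null(rows) && nrow(rows)) {
    ir <- rows[rows$action == "inhibit" & rows$u > 0, , drop = FALSE]
    for (node in unique(ir$node)) {
      g <- ir[ir$node == node, , drop = FALSE]
      z <- sum(g$u)
      h <- sum(g$u * g$h) / z
      keep[node] <- 1 - z^h / (z^h + 1)
    }
    ar <- rows[rows$action != "inhibit" & rows$f > 0, , drop = FALSE]
    for (node in unique(ar$node))
      boost[node] <- prod(1 + ar$f[ar$node == node])
  }
  list(keep = keep, boost = boost)
}

# multiplier on each node's functional output from a list of DrugApplications
drugMultipliers <- function(cm, drugs) {
  for (app in drugs) {
    miss <- setdiff(app@drug@targets$node, cm$ids)
    if (length(miss))
      stopf("drug %s targets node %s absent from the model",
            app@drug@name, miss[1])
  }
  inhKeep <- rep(1, cm$n)   # surviving fraction of function
  actBoost <- rep(1, cm$n)
  act <- combinedDrugAction(drugs)
  inhKeep[cm$idx[names(act$keep)]] <- act$keep
  actBoost[cm$idx[names(act$boost)]] <- act$boost
  list(keep = inhKeep, boost = actBoost)
}

# ceiling vector after expression-scale perturbations, capped at 1
effectiveXmax <- function(cm, perturbations) {
  xhat <- cm$xmax
  if (!is.null(perturbations) && nrow(perturbations)) {
    miss <- setdiff(perturbations$gene, cm$ids)
    if (length(miss))
      stopf("perturbed gene(s) absent from the model: %s",
            paste(miss, collapse = ", "))
    i <- cm$idx[perturbations$gene]
    xhat[i] <- pmin(1, cm$xmax[i] * perturbations$magnitude)
  }
  xhat
}

# functional output of each node given state x and drug multipliers;
# activating drug boosts are capped at the node ceiling
nodeOutputs <- function(cm, x, mult) {
  out <- x * mult$keep
  b <- mult$boost != 1
  if (any(b)) out[b] <- pmin(out[b] * mult$boost[b], cm$xmax[b])
  out
}

makeRHS <- function(cm, xhat, mult, tau) {
  function(t, x, parms) {
    out <- nodeOutputs(cm, x, mult)
    phi <- {
      xn <- pmax(out, 0)^cm$hillN
      pmin(pmax(xn * (cm$kn + 1) / (xn + cm$kn), 0), 1)
    }
    u <- cm$basal
    if (length(cm$actSrc)) {
      p <- prodByGroup(1 - cm$actW * phi[cm$actSrc], cm$actTgt, cm$n)
      u[cm$hasActivators] <- 1 - p[cm$hasActivators]
    }
    D <- rep(1, cm$n)
    if (length(cm$inhSrc)) {
      cof <- ifelse(cm$inhCof > 0L, phi[pmax(cm$inhCof, 1L)], 1)
      D <- prodByGroup(pmax(1 - cm$inhW * phi[cm$inhSrc] * cof, 0),
                       cm$inhTgt, cm$n)
    }
    list((u * D * xhat - x) / tau)
  }
}

#' Integrate network dynamics
#'
#' Runs the normalized-Hill ODE system: each node relaxes with time constant
#' \code{tau} toward \code{u * D * x_max_eff}, where the activation drive
#' \code{u} merges activators noisy-OR style (basal activity when a node has
#' no activators), the inhibition factor \code{D} multiplies
#' \code{1 - w * phi(out)} terms (degradation edges additionally gated by
#' their cofactor's transmitted activity), and a node's functional output
#' \code{out} is its state scaled by any drug action on it. Perturbations
#' rescale the node ceiling (capped at 1).
#'
#' Without \code{initialState} the system first equilibrates for
#' \code{preTriggerHorizon} from the basal start with no triggers, then runs
#' \code{postTriggerHorizon} with perturbations and drugs applied. With
#' \code{initialState} (e.g. a disease steady state) only the post-trigger
#' phase is run.
#'
#' @param model a validated [NetworkModel-class].
#' @param perturbations data.frame(gene, direction, magnitude) or an
#'   [AvatarSpec-class] (its main perturbation list is used), or NULL.
#' @param drugs list of [DrugApplication-class].
#' @param config a [SimulationConfig-class].
#' @param initialState optional [SystemState-class] to continue from.
#' @param trajectory if TRUE, sample 200 time points per phase.
#' @return list with \code{state} ([SystemState-class]) and
#'   \code{trajectory} ([Trajectory-class] or NULL). Non-convergence is
#'   reported via the state's \code{converged} flag, not an error.
#' @export
integrateNetwork <- function(model, perturbations = NULL, drugs = list(),
                             config = simulationConfig(),
                             initialState = NULL, trajectory = FALSE) {
  if (methods::is(perturbations, "AvatarSpec"))
    perturbations <- perturbations@perturbations
  cm <- compileModel(model)
  noDrug <- list(keep = rep(1, cm$n), boost = rep(1, cm$n))
  mult <- drugMultipliers(cm, drugs)
  xhat <- effectiveXmax(cm, perturbations)

  samples <- function(h) if (trajectory) seq(0, h, length.out = 201L) else c(0, h)
  times <- numeric(0); states <- NULL; t0 <- 0

  if (is.null(initialState)) {
    x0 <- cm$basal * cm$xmax
    rhs1 <- makeRHS(cm, cm$xmax, noDrug, config@tau)
    sol1 <- deSolve::lsoda(x0, samples(config@preTriggerHorizon), rhs1,
                           rtol = config@relTol, atol = config@absTol)
    x0 <- sol1[nrow(sol1), -1]
    if (trajectory) { times <- sol1[, 1]; states <- sol1[, -1, drop = FALSE] }
    t0 <- config@preTriggerHorizon
  } else {
    x0 <- initialState@activities[cm$ids]
    if (anyNA(x0)) stopf("initial state lacks node(s): %s",
                         paste(cm$ids[is.na(x0)], collapse = ", "))
    t0 <- initialState@time
  }

  rhs2 <- makeRHS(cm, xhat, mult, config@tau)
  sol2 <- deSolve::lsoda(unname(x0), samples(config@postTriggerHorizon), rhs2,
                         rtol = config@relTol, atol = config@absTol)
  xT <- sol2[nrow(sol2), -1]
  if (any(!is.finite(xT)))
    stopf("non-finite state for node %s", cm$ids[which(!is.finite(xT))[1]])
  if (trajectory) {
    keep <- -1L  # drop duplicated t=0 sample of phase 2
    times <- c(times, t0 + sol2[keep, 1])
    states <- rbind(states, sol2[keep, -1, drop = FALSE])
  }
  res <- max(abs(rhs2(t0 + config@postTriggerHorizon, xT, NULL)[[1]]))
  state <- new("SystemState",
               activities = stats::setNames(as.numeric(xT), cm$ids),
               time = t0 + config@postTriggerHorizon,
               converged = res < config@convergenceEps, residual = res)
  traj <- NULL
  if (trajectory) {
    colnames(states) <- cm$ids
    traj <- new("Trajectory", times = as.numeric(times), states = states)
  }
  list(state = state, trajectory = traj)
}

#' Control and disease steady states
#'
#' Equilibrates the untreated network to its control (normal-physiology)
#' steady state, then continues with the avatar's triggers to the disease
#' steady state. An empty avatar leaves the system at the control state.
#'
#' @param model a [NetworkModel-class].
#' @param avatar an [AvatarSpec-class].
#' @param config a [SimulationConfig-class].
#' @return list with \code{control} and \code{disease}
#'   ([SystemState-class] each).
#' @export
controlAndDiseaseStates <- function(model, avatar,
                                    config = simulationConfig()) {
  ctrl <- integrateNetwork(model, NULL, list(), config)$state
  dis <- integrateNetwork(model, avatar@perturbations, list(), config,
                          initialState = ctrl)$state
  list(control = ctrl, disease = dis)
}

#' Treated steady state
#'
#' Continues from a disease steady state with the avatar's triggers kept on
#' and drugs applied for a further post-trigger horizon.
#'
#' @param model,config as in [integrateNetwork()].
#' @param avatar an [AvatarSpec-class] (or perturbation data.frame).
#' @param drugs list of [DrugApplication-class].
#' @param diseaseState the disease [SystemState-class] to continue from.
#' @return a [SystemState-class].
#' @export
treatedState <- function(model, avatar, drugs, diseaseState,
                         config = simulationConfig()) {
  integrateNetwork(model, avatar, drugs, config,
                   initialState = diseaseState)$state
}

#' Export a trajectory as TSV
#'
#' @param traj a [Trajectory-class].
#' @param path output path (columns: time, one per node).
#' @export
writeTrajectory <- function(traj, path) {
  writeTsv(data.frame(time = traj@times, traj@states,
                      check.names = FALSE), path)
  invisible(path)
}
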