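# Shared helpers: independent steady-state oracle, small hand-built
# fixtures, and convenience constructors used across the test files.

# Independent fixed-point oracle for the normalized-Hill steady state
# (no drugs). Iterates x <- u(x) * D(x) * xhat from the basal start; on
# acyclic fixtures this converges to the same steady state the ODE relaxes
# to, giving an oracle that shares no code with the solver path.
fpOracle <- function(model, perturbations = NULL,
                     tol = 1e-12, maxit = 100000L) {
  nd <- model@nodes
  ed <- model@edges
  idx <- stats::setNames(seq_len(nrow(nd)), nd$id)
  xhat <- nd$x_max
  if (!is.null(perturbations) && nrow(perturbations)) {
    i <- idx[perturbations$gene]
    xhat[i] <- pmin(1, nd$x_max[i] * perturbations$magnitude)
  }
  phi <- function(x) {
    xn <- pmax(x, 0)^nd$hill_n
    kn <- nd$hill_k^nd$hill_n
    pmin(pmax(xn * (kn + 1) / (xn + kn), 0), 1)
  }
  act <- ed$sign == "activating"
  x <- nd$basal * nd$x_max
  for (it in seq_len(maxit)) {
    ph <- phi(x)
    u <- nd$basal
    D <- rep(1, nrow(nd))
    for (t in unique(ed$target[act])) {
      j <- which(act & ed$target == t)
      u[idx[[t]]] <- 1 - prod(1 - ed$weight[j] * ph[idx[ed$source[j]]])
    }
    for (t in unique(ed$target[!act])) {
      j <- which(!act & ed$target == t)
      cof <- vapply(j, function(jj) {
        cf <- ed$cofactor[jj]
        if (!is.na(cf) && nzchar(cf)) ph[idx[[cf]]] else 1
      }, 0)
      D[idx[[t]]] <- prod(pmax(1 - ed$weight[j] * ph[idx[ed$source[j]]] * cof,
                               0))
    }
    xn <- u * D * xhat
    if (max(abs(xn - x)) < tol) break
    x <- xn
  }
  stats::setNames(x, nd$id)
}

# Linear chain n1 -> n2 -> ... -> nk with curation defaults.
chainModel <- function(k = 2, sign = "activating", weight = 1) {
  ids <- paste0("n", seq_len(k))
  networkModel(
    data.frame(id = ids, stringsAsFactors = FALSE),
    data.frame(source = ids[-k], target = ids[-1], sign = sign,
               weight = weight, stringsAsFactors = FALSE),
    name = "chain", version = "test")
}

# Bare state constructor for phenotype-level tests.
sysState <- function(activities) {
  new("SystemState", activities = activities, time = 0,
      converged = TRUE, residual = 0)
}

# Acyclic single-path fixture: a driver feeding one relay that drives the
# three marker sinks (apoptosis restrained by the relay). Used for sham
# combinations, dose-response monotonicity and ICxx self-consistency.
pathFixture <- function() {
  nodes <- data.frame(
    id = c("DRV", "RELAY", "PRO", "SUR", "APO"),
    x_max = c(0.4, 1, 1, 1, 1),
    basal = c(0.5, 0.5, 0.5, 0.5, 0.8),
    biomarker = c(FALSE, FALSE, TRUE, TRUE, TRUE),
    marker_groups = c("", "", "proliferation", "survival", "apoptosis"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    source = c("DRV", "RELAY", "RELAY", "RELAY"),
    target = c("RELAY", "PRO", "SUR", "APO"),
    sign = c("activating", "activating", "activating", "inhibiting"),
    weight = c(0.9, 0.9, 0.9, 0.8),
    stringsAsFactors = FALSE)
  networkModel(nodes, edges, name = "single-path", version = "test")
}

pathMarkers <- function() {
  markerConfig(proliferation = c(PRO = 1), survival = c(SUR = 1),
               apoptosis = c(APO = 1))
}

pathAvatar <- function() {
  avatarSpec("path-patient",
             data.frame(gene = "DRV", direction = "overexpress",
                        magnitude = 2.5, stringsAsFactors = FALSE))
}

# Fast solver configuration for small fixtures (same steady states as the
# default configuration; only the horizon/tau ratio matters).
fastConfig <- function() {
  simulationConfig(preTriggerHorizon = 5000, postTriggerHorizon = 10000,
                   tau = 10)
}

# Write a small text fixture to a temp file and return its path.
writeTemp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
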