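#' Synthetic scenario specification
#'
#' Parameters for the random network / avatar / drug-library generator used
#' to benchmark every pipeline stage without patient data.
#'
#' @param nNodes number of nodes (>= 3).
#' @param edgeDensity probability scale for extra parents per node, in
#'   (0, 1]; 0 is rejected (the graph could not be connected).
#' @param fractionInhibiting probability that an internal edge inhibits.
#' @param nPerturbations total avatar perturbations (driver plus
#'   distractor knockdowns).
#' @param plantedDriver optional node id to force as the driver; by default
#'   the generator picks the hub whose hyperactivation most increases the
#'   relative growth index.
#' @param nFeedback number of extra feedback edges (default 0: acyclic).
#' @param seed integer seed; fixed seed implies full reproducibility.
#' @return list of class \code{ScenarioSpec}.
#' @export
scenarioSpec <- function(nNodes = 12, edgeDensity = 0.3,
                         fractionInhibiting = 0.2, nPerturbations = 3,
                         plantedDriver = NULL, nFeedback = 0, seed = 1L) {
  if (nNodes < 3) stopf("nNodes must be >= 3")
  if (edgeDensity <= 0 || edgeDensity > 1)
    stopf("edgeDensity must be in (0, 1]: a zero-density graph is disconnected")
  if (fractionInhibiting < 0 || fractionInhibiting > 1)
    stopf("fractionInhibiting must be in [0, 1]")
  structure(list(nNodes = nNodes, edgeDensity = edgeDensity,
                 fractionInhibiting = fractionInhibiting,
                 nPerturbations = nPerturbations,
                 plantedDriver = plantedDriver, nFeedback = nFeedback,
                 seed = as.integer(seed)),
            class = "ScenarioSpec")
}

#' Generate a random signed network
#'
#' Preferential-attachment construction (hub-dominated, as signaling
#' networks are): nodes are added in order and each connects to one or more
#' earlier nodes chosen proportionally to their out-degree, giving a
#' connected DAG; optional feedback edges are added afterwards. The last
#' three nodes are kept as sinks and assigned the proliferation, survival
#' and apoptosis marker groups (cycling over any further sinks). Edges into
#' apoptosis sinks inhibit (survival signaling restrains death); edges into
#' the growth sinks activate; internal edges inhibit with probability
#' \code{fractionInhibiting}. Non-sink ceilings are 0.4 so that
#' amplification (x2.5) has headroom.
#'
#' @param spec a [scenarioSpec()].
#' @return a validated [NetworkModel-class].
#' @export
randomNetwork <- function(spec) {
  set.seed(spec$seed)
  n <- spec$nNodes
  ids <- sprintf("n%02d", seq_len(n))
  sinks <- ids[(n - 2):n]
  internal <- setdiff(ids, sinks)
  outdeg <- stats::setNames(rep(0, n), ids)
  edges <- NULL
  for (i in 2:n) {
    pool <- if (ids[i] %in% sinks) internal else ids[seq_len(i - 1)]
    pool <- setdiff(pool, sinks)
    if (!length(pool)) pool <- ids[1]
    extra <- stats::rbinom(1, max(length(pool) - 1, 0), spec$edgeDensity)
    k <- min(1 + extra, length(pool))
    w <- (outdeg[pool] + 1) / sum(outdeg[pool] + 1)
    parents <- sample(pool, k, prob = w)
    outdeg[parents] <- outdeg[parents] + 1
    edges <- rbind(edges, data.frame(source = parents, target = ids[i],
                                     stringsAsFactors = FALSE))
  }
  groups <- rep(c("proliferation", "survival", "apoptosis"),
                length.out = length(sinks))
  grp <- stats::setNames(groups, sinks)
  sgn <- function(src, tgt) {
    if (tgt %in% sinks) {
      if (grp[[tgt]] == "apoptosis") "inhibiting" else "activating"
    } else if (stats::runif(1) < spec$fractionInhibiting) "inhibiting"
    else "activating"
  }
  edges$sign <- mapply(sgn, edges$source, edges$target)
  edges$weight <- round(stats::runif(nrow(edges), 0.6, 1), 3)
  if (spec$nFeedback > 0) {
    for (f in seq_len(spec$nFeedback)) {
      tgt <- sample(internal[-1], 1)
      later <- internal[match(tgt, internal) < match(internal, internal)]
      if (!length(later)) next
      src <- sample(later, 1)
      edges <- rbind(edges, data.frame(source = src, target = tgt,
                                       sign = "inhibiting",
                                       weight = 0.5,
                                       stringsAsFactors = FALSE))
    }
  }
  nodes <- data.frame(id = ids,
                      x_max = ifelse(ids %in% sinks, 1, 0.4),
                      biomarker = ids %in% sinks,
                      marker_groups = ifelse(ids %in% sinks, grp[ids], ""),
                      stringsAsFactors = FALSE)
  networkModel(nodes, edges,
               name = sprintf("synthetic-seed%d", spec$seed), version = "1")
}

#' Marker configuration derived from a model's annotations
#'
#' Equal weights over each marker group's members as tagged in the model.
#'
#' @param model a [NetworkModel-class] whose nodes carry marker groups.
#' @param alpha mixing coefficient.
#' @return a [MarkerConfig-class].
#' @export
markerConfigFromModel <- function(model, alpha = 0.5) {
  pick <- function(g) {
    m <- markerNodes(model, g)
    if (!length(m)) stopf("model has no '%s' marker nodes", g)
    stats::setNames(rep(1, length(m)), m)
  }
  markerConfig(pick("proliferation"), pick("survival"), pick("apoptosis"),
               alpha = alpha)
}

#' Planted-driver benchmark scenario
#'
#' Generates a random network, plants a dominant lesion (hyperactivation of
#' one hub, magnitude 2.5) plus mild distractor knockdowns (0.7), and builds
#' a drug library with one inhibitor per hub including the driver. Unless
#' forced via the spec, the driver is the hub whose lone hyperactivation
#' most increases the disease relative growth index over control -- the
#' generator's operational definition of the profile's dominant lesion,
#' audited per seed.
#'
#' @param spec a [scenarioSpec()].
#' @param config simulation configuration used for the audit.
#' @return list with \code{model}, \code{avatar} ([AvatarSpec-class]),
#'   \code{library}, \code{markers}, \code{driver} (node id) and
#'   \code{driverDrug} (library name of the planted driver's inhibitor).
#' @export
plantedDriverScenario <- function(spec, config = simulationConfig()) {
  model <- randomNetwork(spec)
  set.seed(spec$seed + 1L)
  nd <- model@nodes
  ed <- model@edges
  outdeg <- table(factor(ed$source, levels = nd$id))
  sinks <- nd$id[nzchar(nd$marker_groups)]
  hubs <- setdiff(names(sort(outdeg[outdeg >= 1], decreasing = TRUE)), sinks)
  hubs <- utils::head(hubs, 6)
  markers <- markerConfigFromModel(model)
  driver <- spec$plantedDriver
  if (is.null(driver)) {
    ctrl <- integrateNetwork(model, NULL, list(), config)$state
    rgiCtrl <- computeRGI(ctrl, markers)$rgi
    gain <- vapply(hubs, function(h) {
      p <- data.frame(gene = h, direction = "overexpress", magnitude = 2.5)
      st <- integrateNetwork(model, p, list(), config,
                             initialState = ctrl)$state
      computeRGI(st, markers)$rgi - rgiCtrl
    }, 0)
    driver <- hubs[which.max(gain)]
  } else if (!driver %in% nd$id) {
    stopf("plantedDriver '%s' absent from the generated network", driver)
  }
  distractorPool <- setdiff(setdiff(nd$id, sinks), driver)
  nDis <- min(max(spec$nPerturbations - 1, 0), length(distractorPool))
  distractors <- sample(distractorPool, nDis)
  pert <- rbind(
    data.frame(gene = driver, direction = "overexpress", magnitude = 2.5,
               stringsAsFactors = FALSE),
    if (nDis) data.frame(gene = distractors, direction = "knockdown",
                         magnitude = 0.7, stringsAsFactors = FALSE))
  pert <- pert[order(pert$gene), ]
  avatar <- avatarSpec(sprintf("synthetic-seed%d", spec$seed), pert)
  lib <- lapply(union(hubs, driver), function(h)
    drugSpec(paste0("inh_", h), h))
  names(lib) <- vapply(lib, function(d) d@name, "")
  list(model = model, avatar = avatar, library = lib, markers = markers,
       driver = driver, driverDrug = paste0("inh_", driver))
}

#' Write a synthetic scenario to disk
#'
#' Emits the network (JSON dialect), avatar trigger file (TSV) and drug
#' library (TSV) so generated scenarios round-trip through the standard
#' formats.
#'
#' @param scenario output of [plantedDriverScenario()].
#' @param dir output directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
writeScenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(network = file.path(dir, "network.json"),
             avatar = file.path(dir, "avatar.tsv"),
             library = file.path(dir, "drug_library.tsv"))
  writeNetwork(scenario$model, paths["network"])
  writeAvatar(scenario$avatar, paths["avatar"])
  writeDrugLibrary(scenario$library, paths["library"])
  invisible(paths)
}
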