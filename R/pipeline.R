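#' Read a pipeline run configuration
#'
#' YAML with keys: \code{paths} (annotation, aberrations, network, library),
#' optional \code{patient_id}, optional \code{simulation} (any
#' [SimulationConfig-class] field), optional \code{screening}
#' (\code{anchor}, \code{icxx}, \code{delta}), optional \code{markers}
#' (named weight maps \code{proliferation}/\code{survival}/\code{apoptosis}
#' and \code{alpha}) and \code{outdir}.
#'
#' @param path YAML file.
#' @return a named list (the run configuration).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  yaml::read_yaml(path)
}

runConfigSimulation <- function(rc) {
  s <- rc$simulation %||% list()
  simulationConfig(
    preTriggerHorizon = s$preTriggerHorizon %||% 50000,
    postTriggerHorizon = s$postTriggerHorizon %||% 100000,
    tau = s$tau %||% 100,
    convergenceEps = s$convergenceEps %||% 1e-6,
    relTol = s$relTol %||% 1e-8,
    absTol = s$absTol %||% 1e-10,
    seed = s$seed %||% 1L)
}

runConfigMarkers <- function(rc) {
  m <- rc$markers
  if (is.null(m)) return(defaultMarkerConfig())
  markerConfig(unlist(m$proliferation), unlist(m$survival),
               unlist(m$apoptosis), alpha = m$alpha %||% 0.5)
}

#' Run the end-to-end personalization pipeline
#'
#' Reads annotation, aberrations, network and drug library; builds the
#' avatar; equilibrates control and disease states; runs the single-agent
#' and pairwise combination screens; and writes a ranked-regimen report.
#' Single agents are labelled \code{sensitive} (shortlisted, efficacy >
#' 30\%), \code{resistant} (< 10\%) or \code{intermediate} otherwise.
#' Outputs are deterministic (no timestamps); a manifest records input
#' hashes, the configuration, the seed and the package version, plus a
#' completeness marker per stage so partial runs are auditable.
#'
#' @param runConfig a list as from [readRunConfig()], or a YAML path.
#' @return invisibly, a list with the main in-memory results and
#'   \code{files} (paths written).
#' @export
runPipeline <- function(runConfig) {
  if (is.character(runConfig)) runConfig <- readRunConfig(runConfig)
  rc <- runConfig
  paths <- rc$paths
  for (p in c("annotation", "aberrations", "network", "library")) {
    if (is.null(paths[[p]]) || !file.exists(paths[[p]]))
      stopf("stage input: missing %s file '%s'", p, paths[[p]] %||% "")
  }
  outdir <- rc$outdir %||% "avatar-screen-output"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  config <- runConfigSimulation(rc)
  markers <- runConfigMarkers(rc)
  files <- character()
  manifest <- list(
    package = "AvatarScreen",
    version = as.character(utils::packageVersion("AvatarScreen")),
    inputs = lapply(paths, function(p) unname(tools::md5sum(p))),
    seed = config@seed,
    config = rc,
    stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(complete = FALSE,
                                       error = conditionMessage(e))
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(complete = TRUE)
    res
  }
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    files <<- c(files, path)
    path
  }

  model <- stage("network", {
    m <- readNetwork(paths$network)
    v <- validateNetwork(m)
    if (length(v)) stopf("network invalid: %s", paste(v, collapse = "; "))
    m
  })
  annotation <- stage("annotation",
                      readGeneAnnotation(paths$annotation, "tsv"))
  aberrations <- stage("aberrations", readAberrations(paths$aberrations))
  library <- stage("library", readDrugLibrary(paths$library))
  avatar <- stage("avatar",
                  buildAvatar(aberrations, annotation, networkGenes(model),
                              patientId = rc$patient_id %||% "patient"))
  emit("avatar.tsv", function(p) writeAvatar(avatar, p))

  states <- stage("simulate", controlAndDiseaseStates(model, avatar, config))
  stateTsv <- function(st) function(p)
    writeTsv(data.frame(node = names(st@activities),
                        activity = unname(st@activities)), p)
  emit("control_state.tsv", stateTsv(states$control))
  emit("disease_state.tsv", stateTsv(states$disease))

  screen <- stage("screen",
                  singleAgentScreen(model, avatar, library, config, markers))
  screen$label <- ifelse(screen$shortlisted, "sensitive",
                         ifelse(!is.na(screen$efficacy_pct) &
                                  screen$efficacy_pct < 10, "resistant",
                                "intermediate"))
  emit("single_agent_screen.tsv", function(p) writeTsv(screen, p))

  sc <- rc$screening %||% list()
  combos <- stage("combos",
                  combinationScreen(model, avatar, library,
                                    anchor = sc$anchor,
                                    xxLevels = sc$icxx %||% 20,
                                    config = config, markers = markers,
                                    delta = sc$delta %||% 0.05))
  emit("combination_screen.tsv", function(p) writeTsv(combos, p))

  deltaNodes <- model@nodes$id[model@nodes$biomarker]
  topCombo <- if (nrow(combos)) combos[1, ] else NULL
  deltas <- NULL
  if (!is.null(topCombo)) {
    apps <- list(drugApplication(library[[topCombo$drug_a]], topCombo$dose_a),
                 drugApplication(library[[topCombo$drug_b]], topCombo$dose_b))
    st <- treatedState(model, avatar, apps, states$disease, config)
    deltas <- biomarkerReport(st, states$disease, deltaNodes, apps)
    emit("biomarker_deltas.tsv", function(p) writeTsv(deltas, p))
  }

  ranked <- list(
    patient = avatar@patientId,
    single_agents = screen[, c("drug", "dose", "efficacy_pct", "label")],
    combinations = combos,
    top_combination = if (!is.null(topCombo))
      list(drugs = c(topCombo$drug_a, topCombo$drug_b),
           doses = c(topCombo$dose_a, topCombo$dose_b),
           efficacy_pct = 100 * topCombo$E_ab,
           synergistic = topCombo$synergistic) else NULL)
  emit("ranked_regimens.json", function(p)
    jsonlite::write_json(ranked, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null"))
  emit("report.txt", function(p) {
    con <- file(p, "w"); on.exit(close(con))
    writeLines(c(
      sprintf("Patient: %s", avatar@patientId),
      sprintf("Perturbations: %d; uncovered genes: %d",
              nrow(avatar@perturbations), length(avatar@coverageReport)),
      "",
      "Single-agent screen (default screening doses):",
      sprintf("  %-12s eff %6.1f%%  %s", screen$drug, screen$efficacy_pct,
              screen$label),
      "",
      if (!is.null(topCombo))
        sprintf("Top combination: %s + %s (IC%d each), efficacy %.1f%%%s",
                topCombo$drug_a, topCombo$drug_b, topCombo$xx,
                100 * topCombo$E_ab,
                if (topCombo$synergistic) ", synergistic" else "")
      else "No combination records."), con)
  })
  emit("manifest.json", function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                         na = "null"))
  invisible(list(avatar = avatar, states = states, screen = screen,
                 combos = combos, deltas = deltas, files = files))
}
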