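#' Fractional target manipulation at a dose
#'
#' Hill occupancy: \code{dose^h / (dose^h + ec50^h)}; strictly increasing in
#' dose and bounded below 1.
#'
#' @param dose nonnegative dose (vector ok).
#' @param ec50 half-maximal dose (> 0).
#' @param hillCoeff Hill coefficient (>= 1).
#' @return fraction in [0, 1).
#' @export
fractionalInhibition <- function(dose, ec50, hillCoeff = 1) {
  if (any(dose < 0)) stopf("dose must be nonnegative")
  dh <- dose^hillCoeff
  dh / (dh + ec50^hillCoeff)
}

# dose achieving a given fractional manipulation (inverse Hill)
doseForFraction <- function(fraction, ec50, hillCoeff = 1) {
  ec50 * (fraction / (1 - fraction))^(1 / hillCoeff)
}

#' Default screening dose of a drug
#'
#' Small molecules are screened at a physiological dose manipulating the
#' target moderately, by 55\% (the middle of the 50--60\% design band);
#' biologics (antibody-like agents) at 95\%, comfortably above the 90\%
#' inhibition such agents achieve. The dose is found by inverting the
#' drug's own occupancy curve, so the achieved manipulation is exact for
#' any ec50 and Hill coefficient.
#'
#' @param drug a [DrugSpec-class].
#' @return a [DrugApplication-class] at the class-specific dose.
#' @export
defaultScreeningDose <- function(drug) {
  target <- if (drug@drugClass == "biologic") 0.95 else 0.55
  drugApplication(drug, doseForFraction(target, drug@ec50, drug@hillCoeff))
}

#' Default dose grid for dose-response studies
#'
#' Thirteen log-spaced doses spanning 1/16 to 256 times the drug's ec50,
#' preceded by dose zero.
#'
#' @param drug a [DrugSpec-class].
#' @return numeric vector of ascending doses.
#' @export
defaultDoseGrid <- function(drug) c(0, drug@ec50 * 2^seq(-4, 8))

#' Dose-response of a single agent on an avatar
#'
#' Efficacy is the percent reduction of the tumor relative growth index
#' versus the untreated disease steady state, evaluated at each dose.
#'
#' @param model a [NetworkModel-class].
#' @param avatar an [AvatarSpec-class].
#' @param drug a [DrugSpec-class].
#' @param doses ascending dose grid (default [defaultDoseGrid()]).
#' @param config a [SimulationConfig-class].
#' @param markers a [MarkerConfig-class].
#' @param baseline optional precomputed control/disease list from
#'   [controlAndDiseaseStates()] to avoid re-equilibration.
#' @return data.frame with columns \code{dose} and \code{efficacy_pct}.
#' @export
doseResponse <- function(model, avatar, drug, doses = defaultDoseGrid(drug),
                         config = simulationConfig(),
                         markers = defaultMarkerConfig(),
                         baseline = NULL) {
  if (is.unsorted(doses, strictly = TRUE)) stopf("doses must be strictly increasing")
  if (is.null(baseline))
    baseline <- controlAndDiseaseStates(model, avatar, config)
  eff <- vapply(doses, function(d) {
    drugEfficacy(model, avatar, list(drugApplication(drug, d)),
                 baseline$disease, config, markers)
  }, 0)
  data.frame(dose = doses, efficacy_pct = eff)
}

# efficacy (% rgi reduction vs disease) of a set of drug applications
drugEfficacy <- function(model, avatar, apps, diseaseState, config, markers) {
  if (length(apps) && all(vapply(apps, function(a) a@dose == 0, TRUE)))
    return(0)
  st <- treatedState(model, avatar, apps, diseaseState, config)
  efficacy(st, diseaseState, markers, applications = apps)
}

#' Inhibitory-concentration (ICxx) dose by bisection
#'
#' Finds the dose at which the drug reduces the relative growth index by
#' \code{xx} percent versus the untreated disease state. The bracket is
#' grown by doubling from ec50/16 until the efficacy crosses \code{xx}
#' (up to 2^16 times ec50); bisection then refines until the recomputed
#' efficacy is within 0.5 percentage points of \code{xx} or the bracket is
#' below 1e-4 relative width.
#'
#' @inheritParams doseResponse
#' @param xx target efficacy percent in (0, 100).
#' @return list with \code{dose} (NA if unreachable), \code{efficacy_pct}
#'   at that dose, and \code{reachable}.
#' @export
findICxx <- function(model, avatar, drug, xx, config = simulationConfig(),
                     markers = defaultMarkerConfig(), baseline = NULL) {
  if (xx <= 0 || xx >= 100) stopf("xx must be in (0, 100)")
  if (is.null(baseline))
    baseline <- controlAndDiseaseStates(model, avatar, config)
  effAt <- function(d) drugEfficacy(model, avatar,
                                    list(drugApplication(drug, d)),
                                    baseline$disease, config, markers)
  lo <- 0; eLo <- 0
  hi <- drug@ec50 / 16; eHi <- effAt(hi)
  while (eHi < xx && hi < drug@ec50 * 2^16) {
    lo <- hi; eLo <- eHi
    hi <- hi * 2; eHi <- effAt(hi)
  }
  if (eHi < xx)
    return(list(dose = NA_real_, efficacy_pct = eHi, reachable = FALSE))
  repeat {
    mid <- (lo + hi) / 2
    eMid <- effAt(mid)
    if (abs(eMid - xx) < 0.5 || (hi - lo) / max(hi, .Machine$double.eps) < 1e-4)
      return(list(dose = mid, efficacy_pct = eMid, reachable = TRUE))
    if (eMid < xx) lo <- mid else hi <- mid
  }
}

#' Read / write a drug library
#'
#' TSV with header columns \code{name}, \code{class}, \code{targets}
#' (semicolon-separated node ids), \code{actions} (semicolon-separated,
#' recycled if a single value), \code{ec50}, \code{hill}. A JSON array of
#' objects with the same fields is accepted too.
#'
#' @param path file path (.tsv or .json by extension).
#' @return list of [DrugSpec-class], named by drug.
#' @export
readDrugLibrary <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    df <- as.data.frame(raw, stringsAsFactors = FALSE)
    df$targets <- vapply(raw$targets, paste, "", collapse = ";")
    df$actions <- vapply(raw$actions, paste, "", collapse = ";")
  } else {
    df <- readTsv(path)
  }
  need <- c("name", "class", "targets", "actions", "ec50", "hill")
  if (!all(need %in% names(df)))
    stopf("drug library needs columns %s", paste(need, collapse = "/"))
  lib <- lapply(seq_len(nrow(df)), function(i) {
    tg <- strsplit(df$targets[i], ";", fixed = TRUE)[[1]]
    ac <- strsplit(df$actions[i], ";", fixed = TRUE)[[1]]
    if (length(ac) == 1) ac <- rep(ac, length(tg))
    drugSpec(df$name[i],
             data.frame(node = tg, action = ac, stringsAsFactors = FALSE),
             drugClass = df$class[i], ec50 = as.numeric(df$ec50[i]),
             hillCoeff = as.numeric(df$hill[i]))
  })
  stats::setNames(lib, df$name)
}

#' @rdname readDrugLibrary
#' @param library list of [DrugSpec-class].
#' @export
writeDrugLibrary <- function(library, path) {
  df <- do.call(rbind, lapply(library, function(d) {
    data.frame(name = d@name, class = d@drugClass,
               targets = paste(d@targets$node, collapse = ";"),
               actions = paste(d@targets$action, collapse = ";"),
               ec50 = d@ec50, hill = d@hillCoeff, stringsAsFactors = FALSE)
  }))
  writeTsv(df, path)
  invisible(path)
}
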