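#' Magnitude policy for expression-scale perturbations
#'
#' The source studies specify the direction of change (gain -> overexpress,
#' loss -> knockdown) but not its size; this policy supplies the
#' expression-scale factors. Defaults: heterozygous (or unspecified) loss
#' 0.5, homozygous loss 0.05 (near-null but nonzero for numerical
#' robustness), trisomy / heterozygous gain 1.5, amplification / homozygous
#' gain 2.5; classified mutations map to the homozygous extremes
#' (loss-of-function 0.05, gain-of-function 2.5).
#'
#' @param lossHet,lossHom,gainHet,gainHom scale factors.
#' @return a function \code{(kind, zygosity) -> magnitude}.
#' @export
magnitudePolicy <- function(lossHet = 0.5, lossHom = 0.05,
                            gainHet = 1.5, gainHom = 2.5) {
  function(kind, zygosity) {
    hom <- zygosity == "homozygous"
    unname(switch(kind,
      copy_loss = if (hom) lossHom else lossHet,
      monosomy = lossHet,
      mutation_lof = lossHom,
      copy_gain = if (hom) gainHom else gainHet,
      trisomy = gainHet,
      translocation_amplification = gainHom,
      mutation_gof = gainHom,
      stopf("unrecognized aberration kind '%s'", kind)))
  }
}

#' @rdname magnitudePolicy
#' @export
defaultMagnitudePolicy <- function() magnitudePolicy()

#' Build a patient simulation avatar
#'
#' Resolves aberrations to (gene, direction) calls, keeps the genes covered
#' by the network model's gene set as perturbations of the "trigger file",
#' and reports the rest as uncovered. When one gene receives both up and
#' down calls the default is to fail loudly; \code{tiePolicy = "drop"}
#' discards the gene instead. Repeated same-direction calls keep the most
#' severe magnitude.
#'
#' @param aberrations an \code{AberrationSet} from [readAberrations()].
#' @param annotation \code{GRanges} from [readGeneAnnotation()].
#' @param modelGeneSet nonempty character vector, typically
#'   [networkGenes()] of the model.
#' @param policy magnitude policy from [magnitudePolicy()].
#' @param patientId label.
#' @param cloneAberrations optional named list of aberration tables, one per
#'   subclone; each is built with the same policy and stored in
#'   \code{clones}.
#' @param tiePolicy \code{"error"} (default) or \code{"drop"} for genes with
#'   conflicting directions.
#' @param bandTable band-order table for cytoband scopes.
#' @return an [AvatarSpec-class].
#' @export
buildAvatar <- function(aberrations, annotation, modelGeneSet,
                        policy = defaultMagnitudePolicy(),
                        patientId = "patient", cloneAberrations = NULL,
                        tiePolicy = c("error", "drop"),
                        bandTable = cytobandOrder()) {
  tiePolicy <- match.arg(tiePolicy)
  if (!length(modelGeneSet)) stopf("modelGeneSet must be nonempty")
  resolved <- resolveGenes(aberrations, annotation, bandTable)
  pert <- resolvedToPerturbations(resolved, policy, tiePolicy)
  covered <- pert$gene %in% modelGeneSet
  cl <- list()
  if (!is.null(cloneAberrations)) {
    cl <- lapply(cloneAberrations, function(ab) {
      r <- resolveGenes(ab, annotation, bandTable)
      p <- resolvedToPerturbations(r, policy, tiePolicy)
      p[p$gene %in% modelGeneSet, , drop = FALSE]
    })
  }
  avatarSpec(patientId,
             perturbations = pert[covered, , drop = FALSE],
             clones = cl,
             coverageReport = sort(unique(pert$gene[!covered])))
}

resolvedToPerturbations <- function(resolved, policy, tiePolicy) {
  empty <- data.frame(gene = character(), direction = character(),
                      magnitude = numeric(), stringsAsFactors = FALSE)
  if (!nrow(resolved)) return(empty)
  resolved$magnitude <- mapply(policy, resolved$kind, resolved$zygosity)
  out <- lapply(split(resolved, resolved$gene), function(g) {
    if (length(unique(g$change)) > 1) {
      if (tiePolicy == "error")
        stopf("conflicting up/down calls for gene %s (no tie policy configured)",
              g$gene[1])
      return(NULL)
    }
    sev <- which.max(abs(log(g$magnitude)))
    data.frame(gene = g$gene[1],
               direction = if (g$change[1] == "down") "knockdown" else "overexpress",
               magnitude = g$magnitude[sev], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize / deserialize the trigger file
#'
#' The trigger file is a TSV with columns \code{gene}, \code{direction},
#' \code{magnitude}; clones, when present, are written as extra files
#' suffixed by clone name next to \code{path}.
#'
#' @param avatar an [AvatarSpec-class].
#' @param path output TSV path.
#' @return \code{writeAvatar}: \code{path}, invisibly. \code{readAvatar}:
#'   an [AvatarSpec-class] (without clones).
#' @export
writeAvatar <- function(avatar, path) {
  writeTsv(avatar@perturbations, path)
  for (nm in names(avatar@clones)) {
    writeTsv(avatar@clones[[nm]],
             sub("(\\.[^.]+)?$", sprintf("_clone-%s\\1", nm), path))
  }
  invisible(path)
}

#' @rdname writeAvatar
#' @param patientId label for the read avatar.
#' @export
readAvatar <- function(path, patientId = basename(path)) {
  df <- readTsv(path)
  df$magnitude <- as.numeric(df$magnitude)
  avatarSpec(patientId, df)
}
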