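#' Validate a network model
#'
#' Checks the full invariant table and returns violations instead of
#' raising: unique node ids; kinds/signs/mechanisms from the documented
#' vocabularies; basal (a fraction of \code{x_max}) in [0, 1] and
#' \code{x_max} in (0, 1]; Hill exponent
#' >= 1 and half-activation in (0, 1); edge weights in (0, 1]; edge
#' endpoints present; cofactor set if and only if the mechanism is
#' degradation, with the cofactor an existing node distinct from the edge
#' target; marker-group members flagged as biomarkers.
#'
#' @param model a [NetworkModel-class].
#' @return character vector of human-readable violations; empty if valid.
#' @export
validateNetwork <- function(model) {
  nd <- model@nodes
  ed <- model@edges
  v <- character()
  add <- function(cond, fmt, ...) {
    if (any(cond)) v <<- c(v, sprintf(fmt, ...))
    invisible(NULL)
  }
  dup <- nd$id[duplicated(nd$id)]
  add(length(dup) > 0, "duplicate node id: %s", unique(dup))
  add(!nd$kind %in% NODE_KINDS, "node %s: unknown kind '%s'",
      nd$id[!nd$kind %in% NODE_KINDS], nd$kind[!nd$kind %in% NODE_KINDS])
  bad <- nd$basal < 0 | nd$basal > 1
  add(bad, "node %s: basal outside [0,1]", nd$id[bad])
  bad <- nd$x_max <= 0 | nd$x_max > 1
  add(bad, "node %s: x_max outside (0,1]", nd$id[bad])
  bad <- nd$hill_n < 1
  add(bad, "node %s: hill_n < 1", nd$id[bad])
  bad <- nd$hill_k <= 0 | nd$hill_k >= 1
  add(bad, "node %s: hill_k outside (0,1)", nd$id[bad])
  grs <- strsplit(nd$marker_groups, ";", fixed = TRUE)
  bad <- vapply(grs, function(g) any(!g %in% MARKER_GROUPS), TRUE)
  add(bad, "node %s: unknown marker group", nd$id[bad])
  bad <- nzchar(nd$marker_groups) & !nd$biomarker
  add(bad, "node %s: marker-group member not flagged as biomarker", nd$id[bad])

  if (nrow(ed)) {
    lab <- sprintf("%s->%s", ed$source, ed$target)
    add(!ed$source %in% nd$id, "edge %s: dangling source", lab[!ed$source %in% nd$id])
    add(!ed$target %in% nd$id, "edge %s: dangling target", lab[!ed$target %in% nd$id])
    add(!ed$sign %in% EDGE_SIGNS, "edge %s: unknown sign", lab[!ed$sign %in% EDGE_SIGNS])
    add(!ed$mechanism %in% EDGE_MECHANISMS, "edge %s: unknown mechanism",
        lab[!ed$mechanism %in% EDGE_MECHANISMS])
    bad <- ed$weight <= 0 | ed$weight > 1
    add(bad, "edge %s: weight outside (0,1]", lab[bad])
    hasCof <- !is.na(ed$cofactor) & nzchar(ed$cofactor)
    bad <- hasCof & ed$mechanism != "degradation"
    add(bad, "edge %s: cofactor on non-degradation edge", lab[bad])
    bad <- !hasCof & ed$mechanism == "degradation"
    add(bad, "edge %s: degradation edge lacks a cofactor", lab[bad])
    bad <- hasCof & !ed$cofactor %in% nd$id
    add(bad, "edge %s: cofactor absent from node set", lab[bad])
    bad <- hasCof & ed$cofactor == ed$target
    add(bad, "edge %s: degradation edge with its own target as cofactor", lab[bad])
  }
  v
}

#' Read / write network models
#'
#' The JSON dialect stores \code{name}, \code{version}, a \code{nodes} array
#' and an \code{edges} array whose fields mirror the [NetworkModel-class]
#' tables (node \code{marker_groups} as a JSON array). \code{readNetwork}
#' followed by \code{writeNetwork} is the identity on this dialect.
#'
#' @param path file path.
#' @param model a [NetworkModel-class].
#' @return \code{readNetwork} returns a validated [NetworkModel-class];
#'   \code{writeNetwork} returns \code{path} invisibly.
#' @export
readNetwork <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                            simplifyVector = TRUE)
  nodes <- as.data.frame(raw$nodes, stringsAsFactors = FALSE)
  if (!is.null(nodes$marker_groups) && is.list(nodes$marker_groups)) {
    nodes$marker_groups <- vapply(nodes$marker_groups,
                                  function(g) paste(g, collapse = ";"), "")
  }
  edges <- as.data.frame(raw$edges, stringsAsFactors = FALSE)
  networkModel(nodes, edges, name = raw$name %||% "unnamed",
               version = as.character(raw$version %||% "0"))
}

#' @rdname readNetwork
#' @export
writeNetwork <- function(model, path) {
  nodes <- model@nodes
  nodes$marker_groups <- lapply(strsplit(nodes$marker_groups, ";", fixed = TRUE),
                                function(g) g[nzchar(g)])
  obj <- list(name = model@name, version = model@version,
              nodes = nodes, edges = model@edges)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Import a SIF-like interaction table
#'
#' Three tab-separated columns \code{source}, \code{relation}, \code{target};
#' relation \code{activates}/\code{inhibits} (optionally
#' \code{degrades:<cofactor>}). Node parameters come from \code{nodeParams}
#' (a data.frame keyed by \code{id}) or the curation defaults.
#'
#' @param path SIF file path.
#' @param nodeParams optional data.frame of per-node parameter overrides.
#' @param name,version model labels.
#' @return a [NetworkModel-class].
#' @export
readSIF <- function(path, nodeParams = NULL, name = basename(path),
                    version = "0") {
  raw <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE,
                           col.names = c("source", "relation", "target"))
  rel <- raw$relation
  sign <- ifelse(grepl("^activates$", rel), "activating",
          ifelse(grepl("^(inhibits|degrades)", rel), "inhibiting", NA))
  if (anyNA(sign))
    stopf("unknown SIF relation(s): %s",
          paste(unique(rel[is.na(sign)]), collapse = ", "))
  mech <- ifelse(grepl("^degrades", rel), "degradation", "signaling")
  cof <- ifelse(mech == "degradation", sub("^degrades:", "", rel),
                NA_character_)
  ids <- unique(c(raw$source, raw$target, cof[!is.na(cof)]))
  nodes <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (!is.null(nodeParams)) {
    nodes <- merge(nodes, nodeParams, by = "id", all.x = TRUE, sort = FALSE)
    for (col in setdiff(names(nodeParams), "id"))
      if (anyNA(nodes[[col]])) {
        def <- c(kind = "gene_product", basal = 0.5, x_max = 1, hill_n = 1.4,
                 hill_k = 0.5, biomarker = FALSE, marker_groups = "")[col]
        nodes[[col]][is.na(nodes[[col]])] <- def
      }
  }
  edges <- data.frame(source = raw$source, target = raw$target, sign = sign,
                      mechanism = mech, cofactor = cof,
                      stringsAsFactors = FALSE)
  networkModel(nodes, edges, name = name, version = version)
}

#' Convert to an igraph / export GraphML
#'
#' @param model a [NetworkModel-class].
#' @return \code{asIgraph}: an [igraph::igraph] with node and edge attributes.
#' @export
asIgraph <- function(model) {
  igraph::graph_from_data_frame(
    d = model@edges[, c("source", "target", "sign", "weight", "mechanism")],
    directed = TRUE,
    vertices = model@nodes)
}

#' @rdname asIgraph
#' @param path output file for \code{writeGraphML}.
#' @export
writeGraphML <- function(model, path) {
  igraph::write_graph(asIgraph(model), path, format = "graphml")
  invisible(path)
}

#' Query edges and paths
#'
#' \code{hasEdge} tests for a direct edge with the given sign;
#' \code{hasPath} tests directed reachability (any signs).
#'
#' @param model a [NetworkModel-class].
#' @param source,target node ids.
#' @param sign optional sign filter for \code{hasEdge}.
#' @return logical scalar.
#' @export
hasEdge <- function(model, source, target, sign = NULL) {
  ed <- model@edges
  hit <- ed$source == source & ed$target == target
  if (!is.null(sign)) hit <- hit & ed$sign == sign
  any(hit)
}

#' @rdname hasEdge
#' @export
hasPath <- function(model, source, target) {
  g <- asIgraph(model)
  if (!source %in% model@nodes$id || !target %in% model@nodes$id) return(FALSE)
  d <- igraph::distances(g, v = source, to = target, mode = "out")
  is.finite(d[1, 1])
}

#' Marker nodes of a group
#'
#' Node ids tagged with the given marker group (\code{"proliferation"},
#' \code{"survival"} or \code{"apoptosis"}).
#'
#' @param model a [NetworkModel-class].
#' @param group marker group name.
#' @return character vector of node ids.
#' @export
markerNodes <- function(model, group) {
  hit <- vapply(strsplit(model@nodes$marker_groups, ";", fixed = TRUE),
                function(g) group %in% g, TRUE)
  model@nodes$id[hit]
}
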