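#' Build the social cognitive map by matrix addition
#'
#' Aggregates a collection of individual maps into a social cognitive map
#' (SCM). Nodes carry the number of maps citing them (`citation_count`) and
#' the corresponding `frequency` (`citation_count / R`). Ordered node pairs
#' carry the number of maps with a positive (`pos_count`) and negative
#' (`neg_count`) edge, their sum `occurrence`, and the net signed weight
#' `weight_sum = pos_count - neg_count` — equal to the entrywise sum of the
#' individual signed adjacency matrices padded to the union node set.
#' Positive and negative tallies are kept separately so that ambivalent
#' links (judged positive by some respondents and negative by others) remain
#' first-class rather than collapsing to their net sign.
#'
#' @param collection A [map_collection()] at a common level.
#' @return Object of class `social_map` with fields `R`, `level`, `nodes`
#'   (data frame `node`, `citation_count`, `frequency`), `edges` (data frame
#'   `source`, `target`, `pos_count`, `neg_count`, `occurrence`,
#'   `weight_sum`) and `catalog`.
#' @export
build_social_map <- function(collection) {
  maps <- collection$maps
  all_nodes <- sort(unique(unlist(lapply(maps, `[[`, "nodes"))))
  citation <- as.numeric(table(factor(
    unlist(lapply(maps, function(m) unique(m$nodes))), levels = all_nodes)))
  ed <- do.call(rbind, lapply(unname(maps), `[[`, "edges"))
  if (is.null(ed) || nrow(ed) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        pos_count = integer(), neg_count = integer(),
                        occurrence = integer(), weight_sum = integer(),
                        stringsAsFactors = FALSE)
  } else {
    key <- paste(ed$source, ed$target, sep = "\r")
    pos <- tapply(ed$sign > 0, key, sum)
    neg <- tapply(ed$sign < 0, key, sum)
    pair <- do.call(rbind, strsplit(names(pos), "\r", fixed = TRUE))
    edges <- data.frame(
      source = pair[, 1], target = pair[, 2],
      pos_count = as.integer(pos), neg_count = as.integer(neg),
      stringsAsFactors = FALSE
    )
    edges$occurrence <- edges$pos_count + edges$neg_count
    edges$weight_sum <- edges$pos_count - edges$neg_count
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(
    list(R = collection$R, level = collection$level,
         nodes = data.frame(node = all_nodes, citation_count = citation,
                            frequency = citation / collection$R,
                            stringsAsFactors = FALSE),
         edges = edges, catalog = collection$catalog),
    class = "social_map"
  )
}

#' @export
print.social_map <- function(x, ...) {
  cat("<social_map> aggregate of ", x$R, " maps (level '", x$level, "'): ",
      nrow(x$nodes), " nodes, ", nrow(x$edges), " link records\n", sep = "")
  invisible(x)
}

#' Apply display thresholds to a social map
#'
#' Keeps nodes cited by strictly more than `node_freq_min` of respondents
#' and link records occurring in strictly more than `edge_occ_min` maps
#' whose endpoints both survive. Strict inequality matches display
#' conventions such as "cited by >10% of the respondents" and "cited by >10
#' respondents": a node at exactly the threshold is removed. Counts of
#' survivors are unchanged; raising a threshold can only remove material.
#'
#' @param scm A `social_map`.
#' @param node_freq_min Frequency threshold in \[0, 1\] (default 0).
#' @param edge_occ_min Occurrence threshold (count, default 0).
#' @return A filtered `social_map` (same `R`).
#' @export
filter_social_map <- function(scm, node_freq_min = 0, edge_occ_min = 0) {
  if (node_freq_min < 0 || edge_occ_min < 0) {
    stop_repmap("thresholds must be >= 0")
  }
  scm$nodes <- scm$nodes[scm$nodes$frequency > node_freq_min, , drop = FALSE]
  keep <- scm$edges$occurrence > edge_occ_min &
    scm$edges$source %in% scm$nodes$node &
    scm$edges$target %in% scm$nodes$node
  scm$edges <- scm$edges[keep, , drop = FALSE]
  rownames(scm$nodes) <- rownames(scm$edges) <- NULL
  scm
}

#' Aggregate maps separately per respondent group
#'
#' Builds one social map per label (stakeholder group or cluster). The
#' groups partition the collection, so the groups' weight matrices sum
#' entrywise to the full social map's weight matrix.
#'
#' @param collection A [map_collection()].
#' @param labels Named vector (names = respondent ids) of group labels
#'   covering every respondent.
#' @return Named list of `social_map` objects.
#' @export
group_social_maps <- function(collection, labels) {
  unlabeled <- setdiff(names(collection$maps), names(labels))
  if (length(unlabeled)) {
    stop_repmap("unlabeled respondent(s): ",
                paste(unlabeled, collapse = ", "))
  }
  labs <- as.character(labels[names(collection$maps)])
  out <- lapply(split(unname(collection$maps), labs), function(maps) {
    sub <- map_collection(maps, catalog = collection$catalog)
    build_social_map(sub)
  })
  out
}

#' Extract the focal subgraph around chosen components
#'
#' Keeps the focal components plus every component adjacent to them (in
#' either direction) through link records occurring in strictly more than
#' `edge_occ_min` maps; only links incident to the focal set and passing the
#' threshold are kept (1-hop, direction-agnostic neighborhood). Focal
#' components may be given directly or as type labels resolved through the
#' social map's catalog.
#'
#' @param scm A `social_map`.
#' @param focal Character vector of focal node ids (must be present).
#' @param focal_types Character vector of type labels; members present in
#'   the social map are added to the focal set.
#' @param edge_occ_min Occurrence threshold (strict, default 0).
#' @return A `social_map` restricted to the focal neighborhood.
#' @export
focus_subgraph <- function(scm, focal = NULL, focal_types = NULL,
                           edge_occ_min = 0) {
  focal <- as.character(focal %||% character())
  missing_nodes <- setdiff(focal, scm$nodes$node)
  if (length(missing_nodes)) {
    stop_repmap("focal node(s) absent from social map: ",
                paste(missing_nodes, collapse = ", "))
  }
  if (!is.null(focal_types)) {
    if (is.null(scm$catalog)) {
      stop_repmap("focal_types require a catalog on the social map")
    }
    units <- catalog_units(scm$catalog,
                           if (scm$level == "type") "type" else "component")
    members <- units$id[units$type %in% focal_types]
    focal <- union(focal, intersect(members, scm$nodes$node))
  }
  if (!length(focal)) stop_repmap("empty focal set")
  keep <- scm$edges$occurrence > edge_occ_min &
    (scm$edges$source %in% focal | scm$edges$target %in% focal)
  edges <- scm$edges[keep, , drop = FALSE]
  nodes <- union(focal, unique(c(edges$source, edges$target)))
  scm$nodes <- scm$nodes[scm$nodes$node %in% nodes, , drop = FALSE]
  scm$edges <- edges
  rownames(scm$nodes) <- rownames(scm$edges) <- NULL
  scm
}

#' Convert a social map to an igraph object
#'
#' Vertices carry `citation_count`, `frequency` and (when a catalog is
#' available) `type` and `category`; edges carry `pos_count`, `neg_count`,
#' `occurrence`, `weight_sum`, a display `color` (green net-positive, red
#' net-negative, grey ambivalent) and `penwidth` proportional to occurrence.
#'
#' @param scm A `social_map`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(scm) {
  vertices <- scm$nodes
  names(vertices)[1] <- "name"
  if (!is.null(scm$catalog) && scm$level %in% c("component", "type")) {
    units <- catalog_units(scm$catalog, scm$level)
    vertices$type <- units$type[match(vertices$name, units$id)]
    vertices$category <- units$category[match(vertices$name, units$id)]
  }
  edges <- scm$edges
  if (nrow(edges)) {
    edges$color <- ifelse(edges$weight_sum > 0, "green",
                          ifelse(edges$weight_sum < 0, "red", "grey"))
    edges$penwidth <- edges$occurrence
  } else {
    edges$color <- character(0)
    edges$penwidth <- integer(0)
  }
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
}

#' Export a social map to GraphML
#' @param scm A `social_map`.
#' @param path Output path.
#' @export
write_social_map_graphml <- function(scm, path) {
  igraph::write_graph(as_igraph(scm), path, format = "graphml")
  invisible(path)
}

#' Export a social map to DOT
#'
#' Edge attributes `color` (green positive / red negative) and `penwidth`
#' (proportional to occurrence) follow the usual rendering of social
#' cognitive maps.
#'
#' @param scm A `social_map`.
#' @param path Output path.
#' @export
write_social_map_dot <- function(scm, path) {
  igraph::write_graph(as_igraph(scm), path, format = "dot")
  invisible(path)
}
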