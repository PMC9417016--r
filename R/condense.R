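#' Condense a cognitive map to a coarser level
#'
#' Collapses a map's nodes through the catalog (raw labels to components, or
#' components to types), then re-tallies edges between the condensed nodes.
#' For every ordered pair of distinct condensed nodes, all finer edges
#' between their preimages are counted as positive and negative tallies; the
#' resulting edge carries `sign(pos - neg)` (majority sign wins). Pairs with
#' exactly cancelling tallies become `conflict_edges` (sign 0) excluded from
#' the signed edge set and from link counts but retained for reporting.
#' Edges whose endpoints condense to the same node (would-be self-loops) are
#' dropped and counted in `n_dropped_self_loops` — an artifact of merging,
#' not respondent intent.
#'
#' Condensing a map to its own level is the identity, which makes
#' condensation idempotent at a fixed level.
#'
#' @param map A [cognitive_map()].
#' @param catalog A [condensation_catalog()] resolving the map's labels.
#' @param level Target level, `"component"` or `"type"`.
#' @return A [cognitive_map()] at the requested level.
#' @export
condense_map <- function(map, catalog, level = c("component", "type")) {
  level <- match.arg(level)
  if (map$level == level) return(map)
  if (level_index(map$level) > level_index(level)) {
    stop_repmap("map level '", map$level, "' is coarser than requested '",
                level, "'")
  }
  img <- resolve_labels(map$nodes, catalog, map$level, level)
  new_nodes <- unique(unname(img))

  # tally signed edges plus any carried-over conflict counts
  tallies <- data.frame(
    source = unname(img[map$edges$source]),
    target = unname(img[map$edges$target]),
    pos = as.integer(map$edges$sign > 0),
    neg = as.integer(map$edges$sign < 0),
    stringsAsFactors = FALSE
  )
  if (nrow(map$conflict_edges)) {
    tallies <- rbind(tallies, data.frame(
      source = unname(img[map$conflict_edges$source]),
      target = unname(img[map$conflict_edges$target]),
      pos = map$conflict_edges$pos_count,
      neg = map$conflict_edges$neg_count,
      stringsAsFactors = FALSE
    ))
  }
  dropped <- 0L
  edges <- empty_edges(); conflicts <- empty_conflicts()
  if (nrow(tallies)) {
    loop <- tallies$source == tallies$target
    dropped <- as.integer(sum(tallies$pos[loop] + tallies$neg[loop]))
    tallies <- tallies[!loop, , drop = FALSE]
  }
  if (nrow(tallies)) {
    key <- paste(tallies$source, tallies$target, sep = "\r")
    pos <- tapply(tallies$pos, key, sum)
    neg <- tapply(tallies$neg, key, sum)
    pair <- do.call(rbind, strsplit(names(pos), "\r", fixed = TRUE))
    net <- as.integer(sign(pos - neg))
    keep <- net != 0L
    edges <- data.frame(source = pair[keep, 1], target = pair[keep, 2],
                        sign = net[keep], stringsAsFactors = FALSE)
    conflicts <- data.frame(source = pair[!keep, 1], target = pair[!keep, 2],
                            pos_count = as.integer(pos[!keep]),
                            neg_count = as.integer(neg[!keep]),
                            stringsAsFactors = FALSE)
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    conflicts <- conflicts[order(conflicts$source, conflicts$target), ,
                           drop = FALSE]
  }
  cognitive_map(map$respondent_id, nodes = new_nodes, edges = edges,
                respondent_group = map$respondent_group, level = level,
                conflict_edges = conflicts,
                n_dropped_self_loops = map$n_dropped_self_loops + dropped)
}

#' Condense every map in a collection
#'
#' @param collection A [map_collection()] with a catalog.
#' @param level Target level, `"component"` or `"type"`.
#' @param catalog Catalog override (defaults to the collection's).
#' @return A [map_collection()] at the requested level.
#' @export
condense_collection <- function(collection, level = c("component", "type"),
                                catalog = NULL) {
  level <- match.arg(level)
  catalog <- catalog %||% collection$catalog
  if (is.null(catalog)) stop_repmap("no catalog available for condensation")
  maps <- lapply(unname(collection$maps), condense_map,
                 catalog = catalog, level = level)
  map_collection(maps, catalog = catalog)
}

#' Audit a condensation step
#'
#' Per respondent: node and edge counts before/after, nodes and edges merged
#' away, sign conflicts produced, and dropped would-be self-loops. At the
#' collection level: unique component counts before and after. Totals of the
#' per-respondent table equal the sums of its rows by construction.
#'
#' @param before,after [map_collection()]s over the same respondents,
#'   `after` being the condensed one.
#' @return List with `per_respondent` (data frame), `unique_before`,
#'   `unique_after` (counts of unique node labels across maps).
#' @export
condensation_report <- function(before, after) {
  if (!setequal(names(before$maps), names(after$maps))) {
    stop_repmap("collections cover different respondents")
  }
  ids <- names(before$maps)
  rows <- lapply(ids, function(id) {
    b <- before$maps[[id]]; a <- after$maps[[id]]
    data.frame(
      respondent_id = id,
      nodes_before = length(b$nodes), nodes_after = length(a$nodes),
      nodes_merged = length(b$nodes) - length(a$nodes),
      edges_before = nrow(b$edges), edges_after = nrow(a$edges),
      edges_merged = nrow(b$edges) - nrow(a$edges),
      conflicts = nrow(a$conflict_edges) - nrow(b$conflict_edges),
      dropped_self_loops = a$n_dropped_self_loops - b$n_dropped_self_loops,
      stringsAsFactors = FALSE
    )
  })
  list(
    per_respondent = do.call(rbind, rows),
    unique_before = length(unique(unlist(lapply(before$maps, `[[`, "nodes")))),
    unique_after = length(unique(unlist(lapply(after$maps, `[[`, "nodes"))))
  )
}
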