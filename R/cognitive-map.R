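#' Construct an individual cognitive map
#'
#' A cognitive map is one respondent's signed directed concept graph: nodes
#' are the system components the respondent cited, edges are perceived causal
#' links with sign +1 (positive influence) or -1 (negative influence). Maps
#' exist at one of three condensation levels (`raw` verbatim labels,
#' `component`, `type`). Isolated nodes are allowed: citing a component is a
#' datum even when it is unlinked.
#'
#' `conflict_edges` records ordered pairs whose positive and negative tallies
#' cancelled exactly during condensation; they carry sign 0 and are excluded
#' from the signed edge set and from link counts, but retained for reporting.
#'
#' @param respondent_id Respondent identifier (string).
#' @param nodes Character vector of node labels (unique).
#' @param edges Data frame with columns `source`, `target`, `sign`
#'   (sign in -1/+1), or `NULL` for an edgeless map.
#' @param respondent_group One of [RESPONDENT_GROUPS].
#' @param level One of `"raw"`, `"component"`, `"type"`.
#' @param conflict_edges Data frame with columns `source`, `target`,
#'   `pos_count`, `neg_count` (equal, positive counts), or `NULL`.
#' @param n_dropped_self_loops Count of raw edges dropped because their
#'   endpoints condensed to the same node.
#' @return Object of class `cognitive_map`.
#' @export
cognitive_map <- function(respondent_id, nodes = character(), edges = NULL,
                          respondent_group = "other", level = "raw",
                          conflict_edges = NULL, n_dropped_self_loops = 0L) {
  respondent_id <- as.character(respondent_id)
  if (length(respondent_id) != 1L || !nzchar(respondent_id)) {
    stop_repmap("respondent_id must be a single non-empty string")
  }
  if (!respondent_group %in% RESPONDENT_GROUPS) {
    stop_repmap("unknown respondent_group '", respondent_group, "'")
  }
  if (!level %in% MAP_LEVELS) stop_repmap("unknown level '", level, "'")
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    stop_repmap("duplicate node label(s): ",
                paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- empty_edges()
  } else {
    edges <- as.data.frame(edges)[c("source", "target", "sign")]
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    edges$sign <- as.integer(edges$sign)
    if (!all(edges$sign %in% c(-1L, 1L))) {
      stop_repmap("edge sign outside {-1, +1}")
    }
    bad <- setdiff(c(edges$source, edges$target), nodes)
    if (length(bad)) {
      stop_repmap("edge endpoint(s) not in node set: ",
                  paste(unique(bad), collapse = ", "))
    }
    if (any(edges$source == edges$target)) {
      loops <- unique(edges$source[edges$source == edges$target])
      stop_repmap("self-loop(s) on node(s): ", paste(loops, collapse = ", "))
    }
    key <- paste(edges$source, edges$target, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- edges[duplicated(key), , drop = FALSE]
      stop_repmap("more than one edge for ordered pair(s): ",
                  paste(unique(paste0("(", dup$source, ",", dup$target, ")")),
                        collapse = ", "))
    }
    rownames(edges) <- NULL
  }
  if (is.null(conflict_edges) || nrow(conflict_edges) == 0L) {
    conflict_edges <- empty_conflicts()
  } else {
    conflict_edges <- as.data.frame(conflict_edges)[
      c("source", "target", "pos_count", "neg_count")]
    conflict_edges$source <- as.character(conflict_edges$source)
    conflict_edges$target <- as.character(conflict_edges$target)
    conflict_edges$pos_count <- as.integer(conflict_edges$pos_count)
    conflict_edges$neg_count <- as.integer(conflict_edges$neg_count)
    if (!all(conflict_edges$pos_count == conflict_edges$neg_count) ||
        any(conflict_edges$pos_count < 1L)) {
      stop_repmap("conflict edges must have equal, positive pos/neg counts")
    }
    bad <- setdiff(c(conflict_edges$source, conflict_edges$target), nodes)
    if (length(bad)) {
      stop_repmap("conflict edge endpoint(s) not in node set: ",
                  paste(unique(bad), collapse = ", "))
    }
    rownames(conflict_edges) <- NULL
  }
  structure(
    list(respondent_id = respondent_id,
         respondent_group = respondent_group,
         level = level,
         nodes = nodes,
         edges = edges,
         conflict_edges = conflict_edges,
         n_dropped_self_loops = as.integer(n_dropped_self_loops)),
    class = "cognitive_map"
  )
}

#' @export
print.cognitive_map <- function(x, ...) {
  cat("<cognitive_map> respondent ", x$respondent_id, " (",
      x$respondent_group, "), level ", x$level, ": ",
      length(x$nodes), " nodes, ", nrow(x$edges), " signed edges",
      if (nrow(x$conflict_edges)) paste0(", ", nrow(x$conflict_edges),
                                         " conflict pairs") else "",
      "\n", sep = "")
  invisible(x)
}

#' Bundle cognitive maps into a collection
#'
#' A map collection holds maps that are all at the same condensation level,
#' optionally together with the condensation catalog that resolves their
#' node labels.
#'
#' @param maps List of [cognitive_map()] objects.
#' @param catalog Optional [condensation_catalog()].
#' @return Object of class `map_collection` with fields `maps` (named by
#'   respondent id), `catalog`, `level`, `R`.
#' @export
map_collection <- function(maps, catalog = NULL) {
  if (!length(maps)) stop_repmap("no maps")
  if (!all(vapply(maps, inherits, logical(1), "cognitive_map"))) {
    stop_repmap("all elements must be cognitive_map objects")
  }
  ids <- vapply(maps, `[[`, character(1), "respondent_id")
  if (anyDuplicated(ids)) {
    stop_repmap("duplicate respondent_id(s): ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  levels <- unique(vapply(maps, `[[`, character(1), "level"))
  if (length(levels) != 1L) {
    stop_repmap("maps at mixed levels: ", paste(levels, collapse = ", "))
  }
  structure(
    list(maps = stats::setNames(maps, ids), catalog = catalog,
         level = levels, R = length(maps)),
    class = "map_collection"
  )
}

#' @export
print.map_collection <- function(x, ...) {
  cat("<map_collection> ", x$R, " maps at level '", x$level, "'",
      if (!is.null(x$catalog)) " (with catalog)" else "", "\n", sep = "")
  invisible(x)
}

#' Validate a map collection
#'
#' Reporting operation: lists node labels unresolvable in the catalog at the
#' collection's level, self-loops, conflicting duplicate edges, and duplicate
#' respondent ids. The collection is flagged valid iff the report is empty.
#' Accepts either a `map_collection` or a bare list of maps (so problems the
#' constructors reject can still be reported on).
#'
#' @param collection A `map_collection`, or a list of [cognitive_map()]s.
#' @param catalog Catalog to resolve against (defaults to the collection's).
#' @return List with `valid` (logical) and `issues` (data frame with columns
#'   `respondent_id`, `issue`, `detail`).
#' @export
validate_collection <- function(collection, catalog = NULL) {
  if (inherits(collection, "map_collection")) {
    maps <- unname(collection$maps)
    catalog <- catalog %||% collection$catalog
  } else {
    maps <- collection
  }
  issues <- list()
  add <- function(id, issue, detail) {
    issues[[length(issues) + 1L]] <<- data.frame(
      respondent_id = id, issue = issue, detail = detail,
      stringsAsFactors = FALSE)
  }
  ids <- vapply(maps, `[[`, character(1), "respondent_id")
  for (dup in unique(ids[duplicated(ids)])) {
    add(dup, "duplicate_respondent", "respondent id used by several maps")
  }
  for (m in maps) {
    loops <- m$edges$source[m$edges$source == m$edges$target]
    for (l in unique(loops)) add(m$respondent_id, "self_loop", l)
    if (!is.null(catalog)) {
      mapping <- catalog_mapping(catalog, m$level, m$level)
      keys <- if (m$level == "raw") normalize_label(m$nodes) else m$nodes
      for (lab in unique(m$nodes[!keys %in% names(mapping)])) {
        add(m$respondent_id, "unresolvable_label", lab)
      }
    }
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(respondent_id = character(), issue = character(),
               detail = character(), stringsAsFactors = FALSE)
  list(valid = nrow(issues) == 0L, issues = issues)
}
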