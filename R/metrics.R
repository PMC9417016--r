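#' Structural metrics of one cognitive map
#'
#' Computes the nine active variables used for respondent ordination:
#' number of components (nodes, isolated ones included), number of links
#' (signed edges; sign-0 conflict pairs are excluded), map density, and the
#' proportion of the map's components in each of the six categories.
#' Density follows the directed, no-self-loop convention
#' `D = L / (N (N - 1))` (0 when fewer than two nodes).
#'
#' @param map A [cognitive_map()] at component or type level.
#' @param catalog A [condensation_catalog()] providing categories.
#' @return One-row data frame with columns `n_components`, `n_links`,
#'   `density`, `prop_biophysical`, `prop_social`, `prop_ecosystem_service`,
#'   `prop_ecosystem_disservice`, `prop_positive_action`,
#'   `prop_negative_action`.
#' @export
map_metrics <- function(map, catalog) {
  if (!map$level %in% c("component", "type")) {
    stop_repmap("metrics require a condensed (component- or type-level) map")
  }
  units <- catalog_units(catalog, map$level)
  cat_of <- stats::setNames(units$category, units$id)
  node_cat <- cat_of[map$nodes]
  if (anyNA(node_cat)) {
    stop_repmap("node(s) without category in catalog: ",
                paste(map$nodes[is.na(node_cat)], collapse = ", "))
  }
  n <- length(map$nodes)
  l <- nrow(map$edges)
  props <- as.numeric(table(factor(node_cat, levels = CATEGORIES))) /
    max(n, 1L)
  out <- data.frame(
    n_components = n,
    n_links = l,
    density = if (n >= 2) l / (n * (n - 1)) else 0,
    stringsAsFactors = FALSE
  )
  out[c("prop_biophysical", "prop_social", "prop_ecosystem_service",
        "prop_ecosystem_disservice", "prop_positive_action",
        "prop_negative_action")] <- as.list(props)
  out
}

#' Degree centrality of every node in a map
#'
#' Degree centrality in the fuzzy-cognitive-map convention: the sum of the
#' absolute weights of a node's incoming and outgoing edges (with signed
#' unit edges this is in-degree + out-degree). Isolated nodes score 0. Nodes
#' are ranked within the map by descending score, ties receiving their
#' average rank so that input order cannot create artifacts.
#'
#' @param map A [cognitive_map()].
#' @param measure `"degree"` (default) or `"betweenness"` (directed
#'   betweenness on the unsigned graph, exposed as an alternative).
#' @return Data frame with columns `node`, `centrality`, `rank`
#'   (1 = most central), `rel_rank` (`rank / n_components`).
#' @export
node_centrality <- function(map, measure = c("degree", "betweenness")) {
  measure <- match.arg(measure)
  n <- length(map$nodes)
  if (measure == "degree") {
    score <- as.numeric(
      table(factor(c(map$edges$source, map$edges$target),
                   levels = map$nodes)))
  } else {
    g <- igraph::graph_from_data_frame(
      map$edges[c("source", "target")], directed = TRUE,
      vertices = data.frame(name = map$nodes))
    score <- as.numeric(igraph::betweenness(g, directed = TRUE))
  }
  rk <- rank(-score, ties.method = "average")
  data.frame(node = map$nodes, centrality = score, rank = rk,
             rel_rank = rk / n, stringsAsFactors = FALSE)
}

#' Per-respondent metrics table
#'
#' One row per respondent with the nine active metrics of [map_metrics()]
#' plus the respondent's stakeholder group (used downstream as a
#' supplementary variable, never as an active one).
#'
#' @param collection A [map_collection()] at component or type level.
#' @param catalog Catalog override (defaults to the collection's).
#' @return Data frame with columns `respondent_id`, `group`, then the nine
#'   metrics in fixed order.
#' @export
metrics_table <- function(collection, catalog = NULL) {
  catalog <- catalog %||% collection$catalog
  if (is.null(catalog)) stop_repmap("no catalog available for metrics")
  rows <- lapply(unname(collection$maps), function(m) {
    cbind(data.frame(respondent_id = m$respondent_id,
                     group = m$respondent_group,
                     stringsAsFactors = FALSE),
          map_metrics(m, catalog))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[c("respondent_id", "group", METRIC_COLUMNS)]
}

#' Component accumulation (saturation) curve
#'
#' Sampling saturation diagnostic: for each k in 1..R, the mean (over random
#' respondent orderings) of the number of unique components cited by the
#' first k respondents. A plateau indicates that additional respondents
#' contribute no new components. The curve is monotone nondecreasing and its
#' endpoint always equals the total number of unique components.
#'
#' @param collection A [map_collection()].
#' @param n_permutations Number of random orderings (>= 1).
#' @param seed Integer seed for the permutations.
#' @return Data frame with columns `k`, `mean_components`, `sd_components`.
#' @export
accumulation_curve <- function(collection, n_permutations = 100, seed = 1) {
  if (n_permutations < 1) stop_repmap("n_permutations must be >= 1")
  node_sets <- lapply(collection$maps, `[[`, "nodes")
  R <- collection$R
  counts <- with_local_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      ord <- sample.int(R)
      seen <- character(0)
      vapply(ord, function(j) {
        seen <<- union(seen, node_sets[[j]])
        length(seen)
      }, numeric(1))
    }, numeric(R))
  })
  counts <- matrix(counts, nrow = R)
  data.frame(
    k = seq_len(R),
    mean_components = rowMeans(counts),
    sd_components = apply(counts, 1, stats::sd)
  )
}
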