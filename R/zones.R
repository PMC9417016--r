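#' Citation frequency of every component
#'
#' Frequency of citation — the share of respondents whose map contains the
#' component — indicates the level of agreement between respondents on each
#' component of the system.
#'
#' @param collection A [map_collection()].
#' @return Named numeric vector (names = component ids, values in (0, 1\]).
#' @export
component_frequency <- function(collection) {
  counts <- table(unlist(lapply(collection$maps,
                                function(m) unique(m$nodes))))
  freq <- as.numeric(counts) / collection$R
  stats::setNames(freq, names(counts))[order(names(counts))]
}

#' Median within-map centrality rank of every component
#'
#' For each component, the median — over exactly the maps citing it — of its
#' within-map degree-centrality rank (1 = most central, ties averaged),
#' indicating how important citing respondents perceive the component to be.
#' In `relative` mode ranks are divided by each map's size before taking the
#' median, which compensates for map sizes varying severalfold between
#' respondents.
#'
#' @param collection A [map_collection()].
#' @param mode `"raw"` (default) or `"relative"`.
#' @return Named numeric vector of median ranks.
#' @export
median_centrality_rank <- function(collection, mode = c("raw", "relative")) {
  mode <- match.arg(mode)
  per_map <- lapply(collection$maps, function(m) {
    ct <- node_centrality(m)
    stats::setNames(if (mode == "raw") ct$rank else ct$rel_rank, ct$node)
  })
  all_ranks <- split(
    unlist(unname(per_map)),
    unlist(lapply(per_map, names))
  )
  out <- vapply(all_ranks, stats::median, numeric(1))
  out[order(names(out))]
}

#' Classify components into the four zones of a social representation
#'
#' The centrality-frequency method crosses two indicators: citation
#' frequency (agreement between respondents) and median centrality rank
#' (perceived importance). The quadrant rule assigns each component to one
#' of the four zones of the structural approach:
#' high frequency and high centrality -> `core`; high frequency, low
#' centrality -> `first_periphery`; low frequency, high centrality ->
#' `contrasting` (elements known to few respondents but central to them);
#' low frequency, low centrality -> `second_periphery`.
#'
#' "High frequency" means `frequency >= freq_cut`; "high centrality" means
#' `median_rank <= rank_cut` (small rank = central). Ties at a cut go to the
#' high/central side. Cuts given as `"median"` resolve to the median of the
#' corresponding values over all classified components; the resolved cuts
#' are stored in the result for auditability.
#'
#' @param freq Named numeric vector from [component_frequency()].
#' @param rank Named numeric vector from [median_centrality_rank()], over
#'   the same components.
#' @param freq_cut Proportion, or `"median"` (default).
#' @param rank_cut Rank value, or `"median"` (default).
#' @param mode Ranking mode recorded in the output (`"raw"` or
#'   `"relative"`).
#' @return Object of class `zone_table`: data frame with columns
#'   `component`, `frequency`, `median_rank`, `zone`, and attributes
#'   `freq_cut`, `rank_cut`, `rank_mode`.
#' @export
classify_zones <- function(freq, rank, freq_cut = "median",
                           rank_cut = "median", mode = "raw") {
  if (!setequal(names(freq), names(rank))) {
    stop_repmap("frequency and rank cover different components")
  }
  rank <- rank[names(freq)]
  fc <- if (identical(freq_cut, "median")) stats::median(freq) else
    as.numeric(freq_cut)
  rc <- if (identical(rank_cut, "median")) stats::median(rank) else
    as.numeric(rank_cut)
  high_freq <- freq >= fc
  central <- rank <= rc
  zone <- ifelse(high_freq & central, "core",
          ifelse(high_freq & !central, "first_periphery",
          ifelse(!high_freq & central, "contrasting", "second_periphery")))
  out <- data.frame(component = names(freq), frequency = unname(freq),
                    median_rank = unname(rank), zone = unname(zone),
                    stringsAsFactors = FALSE)
  out <- out[order(out$component), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("zone_table", "data.frame"),
            freq_cut = fc, rank_cut = rc, rank_mode = mode)
}

#' Full centrality-frequency zoning of a collection
#'
#' Convenience wrapper chaining [component_frequency()],
#' [median_centrality_rank()] and [classify_zones()].
#'
#' @param collection A [map_collection()] at component or type level.
#' @param freq_cut,rank_cut Passed to [classify_zones()].
#' @param rank_mode Passed to [median_centrality_rank()].
#' @param min_citations Drop components cited by fewer maps than this before
#'   classification (default 1: single-citation components are classified
#'   like any other, their median rank being that one rank).
#' @return A `zone_table`.
#' @export
representation_zones <- function(collection, freq_cut = "median",
                                 rank_cut = "median",
                                 rank_mode = c("raw", "relative"),
                                 min_citations = 1) {
  rank_mode <- match.arg(rank_mode)
  freq <- component_frequency(collection)
  keep <- names(freq)[freq * collection$R >= min_citations]
  freq <- freq[keep]
  rk <- median_centrality_rank(collection, mode = rank_mode)[keep]
  classify_zones(freq, rk, freq_cut = freq_cut, rank_cut = rank_cut,
                 mode = rank_mode)
}

#' Summarize a zone table by zone and component type
#'
#' Per zone: component count; per zone and type: count and mean citation
#' frequency of member components. Zone counts always sum to the number of
#' classified components (the zones partition them).
#'
#' @param table A `zone_table`.
#' @param catalog A [condensation_catalog()] resolving components to types.
#' @param level Level of the table's component ids (`"component"` or
#'   `"type"`).
#' @return List with `zone_counts` (named integer vector over [ZONES]) and
#'   `by_type` (data frame `zone`, `type`, `n`, `mean_frequency`).
#' @export
zone_summary <- function(table, catalog, level = "component") {
  units <- catalog_units(catalog, level)
  type_of <- stats::setNames(units$type, units$id)
  ty <- type_of[table$component]
  if (anyNA(ty)) {
    stop_repmap("component(s) not resolvable to a type: ",
                paste(table$component[is.na(ty)], collapse = ", "))
  }
  zone_counts <- stats::setNames(
    as.integer(table(factor(table$zone, levels = ZONES))), ZONES)
  key <- paste(table$zone, ty, sep = "\r")
  n <- tapply(table$frequency, key, length)
  mf <- tapply(table$frequency, key, mean)
  pair <- do.call(rbind, strsplit(names(n), "\r", fixed = TRUE))
  by_type <- data.frame(zone = pair[, 1], type = pair[, 2],
                        n = as.integer(n), mean_frequency = as.numeric(mf),
                        stringsAsFactors = FALSE)
  by_type <- by_type[order(match(by_type$zone, ZONES), by_type$type), ,
                     drop = FALSE]
  rownames(by_type) <- NULL
  list(zone_counts = zone_counts, by_type = by_type)
}

#' Compare two zone tables
#'
#' For each zone, the components shared between two classifications (for
#' example, the representations of two respondent clusters), with overlap
#' fractions relative to each table's zone.
#'
#' @param a,b `zone_table` objects.
#' @return Data frame with columns `zone`, `n_a`, `n_b`, `n_shared`,
#'   `frac_a` (`n_shared / n_a`), `frac_b`; the shared component sets are
#'   attached as the `shared` attribute (named list by zone).
#' @export
compare_zone_tables <- function(a, b) {
  shared_sets <- list()
  rows <- lapply(ZONES, function(z) {
    in_a <- a$component[a$zone == z]
    in_b <- b$component[b$zone == z]
    shared <- intersect(in_a, in_b)
    shared_sets[[z]] <<- shared
    data.frame(zone = z, n_a = length(in_a), n_b = length(in_b),
               n_shared = length(shared),
               frac_a = if (length(in_a)) length(shared) / length(in_a)
                        else NA_real_,
               frac_b = if (length(in_b)) length(shared) / length(in_b)
                        else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "shared") <- shared_sets
  out
}
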