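#' Default pipeline configuration
#'
#' A pipeline configuration is a plain list (readable from YAML or JSON via
#' [read_pipeline_config()]) naming either input files or a generator spec,
#' display thresholds, zoning and clustering settings, and a seed. Display
#' thresholds default to the conventional strict cut-offs: nodes cited by
#' >10% of respondents, social-map links cited by >10 respondents, focal-map
#' links cited by >2 respondents.
#'
#' @param input Either `list(generator = list(seed = ...))` to simulate, or
#'   `list(files = list(edges = ..., catalog = ..., metadata = ...))`.
#' @param level Analysis level (`"component"` or `"type"`).
#' @param node_freq_min,edge_occ_min Display thresholds for the social map.
#' @param focal_edge_occ_min Occurrence threshold for focal subgraphs.
#' @param focal Character vector of focal components (optional).
#' @param focal_types Character vector of focal type labels (optional).
#' @param freq_cut,rank_cut,rank_mode Zoning settings
#'   (see [representation_zones()]).
#' @param retain,k,test Clustering settings (see [hcpc()],
#'   [compare_clusters()]).
#' @param n_permutations Accumulation-curve permutations.
#' @param seed Pipeline seed.
#' @return A named list.
#' @export
pipeline_config <- function(input = list(generator = list(seed = 42)),
                            level = "component",
                            node_freq_min = 0.10, edge_occ_min = 10,
                            focal_edge_occ_min = 2,
                            focal = NULL, focal_types = NULL,
                            freq_cut = "median", rank_cut = "median",
                            rank_mode = "raw",
                            retain = 0.8, k = "auto", test = "student",
                            n_permutations = 100, seed = 42) {
  list(input = input, level = level,
       node_freq_min = node_freq_min, edge_occ_min = edge_occ_min,
       focal_edge_occ_min = focal_edge_occ_min,
       focal = focal, focal_types = focal_types,
       freq_cut = freq_cut, rank_cut = rank_cut, rank_mode = rank_mode,
       retain = retain, k = k, test = test,
       n_permutations = n_permutations, seed = seed)
}

#' Read a pipeline configuration from YAML or JSON
#' @param path Configuration file path (`.yaml`/`.yml` or `.json`).
#' @return A configuration list with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- pipeline_config()
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
}

#' Run the full analysis pipeline
#'
#' Drives every stage end to end: load or generate the maps, validate,
#' condense to the analysis level, compute the metrics table and saturation
#' curve, build and filter the social cognitive map, classify representation
#' zones, run PCA + hierarchical clustering and the cluster comparison,
#' aggregate per-cluster group maps, compare the clusters' zone tables, and
#' extract focal subgraphs. All artifacts are written under `out_dir`; the
#' run is a pure function of (inputs, configuration, seed), so repeated runs
#' produce identical files.
#'
#' @param config Configuration list from [pipeline_config()] /
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results
#'   (`collection`, `metrics`, `scm`, `zones`, `pca`, `clusters`,
#'   `comparison`, `truth` when simulated) and `files` (paths written).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv(df, path)
    files <<- c(files, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_repmap("pipeline stage '", name, "' failed: ",
                  conditionMessage(e))
    })
  }

  truth <- NULL
  collection <- stage("input", {
    if (!is.null(config$input$generator)) {
      gen_args <- config$input$generator
      gen_args$seed <- gen_args$seed %||% config$seed
      gcfg <- do.call(generator_config, gen_args)
      sim <- generate_collection(gcfg)
      truth <- sim$truth
      sim$collection
    } else if (!is.null(config$input$files)) {
      f <- config$input$files
      catalog <- read_catalog(f$catalog)
      metadata <- if (!is.null(f$metadata)) read_metadata(f$metadata)
      read_edge_list(f$edges, metadata = metadata,
                     level = f$level %||% "raw", catalog = catalog)
    } else {
      stop_repmap("no maps")
    }
  })

  stage("validate", {
    report <- validate_collection(collection)
    if (!report$valid) {
      emit(report$issues, "validation_issues.tsv")
      stop_repmap("collection failed validation (",
                  nrow(report$issues), " issue(s))")
    }
  })

  before <- collection
  collection <- stage("condense", {
    if (level_index(collection$level) < level_index(config$level)) {
      condense_collection(collection, level = config$level)
    } else collection
  })
  if (!identical(before$level, collection$level)) {
    rep_cond <- condensation_report(before, collection)
    emit(rep_cond$per_respondent, "condensation_report.tsv")
  }

  metrics <- stage("metrics", metrics_table(collection))
  emit(metrics, "metrics.tsv")
  curve <- stage("accumulation", accumulation_curve(
    collection, n_permutations = config$n_permutations, seed = config$seed))
  emit(curve, "accumulation_curve.tsv")

  scm <- stage("scm", build_social_map(collection))
  emit(scm$nodes, "scm_nodes.tsv")
  emit(scm$edges, "scm_edges.tsv")
  scm_filtered <- filter_social_map(scm, node_freq_min = config$node_freq_min,
                                    edge_occ_min = config$edge_occ_min)
  emit(scm_filtered$nodes, "scm_filtered_nodes.tsv")
  emit(scm_filtered$edges, "scm_filtered_edges.tsv")
  files <- c(files,
             write_social_map_graphml(
               scm_filtered, file.path(out_dir, "scm_filtered.graphml")),
             write_social_map_dot(
               scm_filtered, file.path(out_dir, "scm_filtered.dot")))

  zones <- stage("zones", representation_zones(
    collection, freq_cut = config$freq_cut, rank_cut = config$rank_cut,
    rank_mode = config$rank_mode))
  ztab <- as.data.frame(zones)
  if (!is.null(collection$catalog)) {
    units <- catalog_units(collection$catalog,
                           if (collection$level == "type") "type"
                           else "component")
    ztab$type <- units$type[match(ztab$component, units$id)]
    ztab$category <- units$category[match(ztab$component, units$id)]
    zsum <- zone_summary(zones, collection$catalog,
                         level = if (collection$level == "type") "type"
                                 else "component")
    emit(zsum$by_type, "zone_summary_by_type.tsv")
  }
  emit(ztab, "zones.tsv")

  pca <- stage("pca", run_pca(metrics))
  emit(data.frame(axis = seq_along(pca$eigenvalues),
                  eigenvalue = pca$eigenvalues,
                  percent_variance = pca$percent_variance,
                  cumulative_percent = pca$cumulative_percent),
       "pca_summary.tsv")
  emit(data.frame(variable = rownames(pca$loadings),
                  as.data.frame(pca$loadings)), "pca_loadings.tsv")
  emit(data.frame(respondent_id = rownames(pca$scores),
                  as.data.frame(pca$scores)), "pca_scores.tsv")

  clusters <- stage("clustering", hcpc(
    pca, retained = config$retain, k = config$k, seed = config$seed))
  emit(data.frame(respondent_id = names(clusters$labels),
                  cluster = unname(clusters$labels)), "clusters.tsv")
  comparison <- NULL
  if (clusters$k == 2L && min(table(clusters$labels)) >= 2L) {
    comparison <- stage("comparison",
                        compare_clusters(metrics, clusters,
                                         test = config$test))
    emit(comparison$metrics, "cluster_comparison.tsv")
    emit(as.data.frame(comparison$composition), "cluster_composition.tsv")
  }

  zone_overlap <- NULL
  if (clusters$k >= 2L) {
    group_zones <- stage("group_zones", {
      lapply(split(names(clusters$labels), clusters$labels), function(ids) {
        sub <- map_collection(unname(collection$maps[ids]),
                              catalog = collection$catalog)
        representation_zones(sub, freq_cut = config$freq_cut,
                             rank_cut = config$rank_cut,
                             rank_mode = config$rank_mode)
      })
    })
    if (length(group_zones) == 2L) {
      zone_overlap <- compare_zone_tables(group_zones[[1]],
                                          group_zones[[2]])
      emit(zone_overlap, "zone_overlap.tsv")
    }
    gmaps <- group_social_maps(collection, clusters$labels)
    for (nm in names(gmaps)) {
      emit(gmaps[[nm]]$edges, paste0("group_", nm, "_edges.tsv"))
    }
  }

  if (!is.null(config$focal) || !is.null(config$focal_types)) {
    focal_map <- stage("focus", focus_subgraph(
      scm, focal = config$focal, focal_types = config$focal_types,
      edge_occ_min = config$focal_edge_occ_min))
    emit(focal_map$nodes, "focal_nodes.tsv")
    emit(focal_map$edges, "focal_edges.tsv")
  }

  report <- list(
    n_respondents = collection$R,
    level = collection$level,
    n_unique_components = nrow(scm$nodes),
    n_link_records = nrow(scm$edges),
    zone_counts = as.list(table(factor(zones$zone, levels = ZONES))),
    retained_axes = clusters$retained_axes,
    k = clusters$k,
    percent_variance_axis1 = pca$percent_variance[1],
    percent_variance_axis2 = pca$percent_variance[2],
    seed = config$seed
  )
  report_path <- file.path(out_dir, "run_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, report_path)

  invisible(list(collection = collection, metrics = metrics,
                 accumulation = curve, scm = scm,
                 scm_filtered = scm_filtered, zones = zones, pca = pca,
                 clusters = clusters, comparison = comparison,
                 zone_overlap = zone_overlap, truth = truth,
                 files = files))
}
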