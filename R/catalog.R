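#' Construct a condensation catalog
#'
#' A condensation catalog maps every verbatim elicited label (`raw_label`) to
#' a canonical `component`, each component to one of a set of `type` groups,
#' and each type to one of the six fixed [CATEGORIES]. It drives the
#' condensation of individual cognitive maps to the component or type level.
#'
#' Invariants enforced: raw labels are unique after [normalize_label()]
#' normalization; `component -> type` and `type -> category` are functions
#' (no component in two types, no type in two categories); every category is
#' drawn from the closed six-element set.
#'
#' @param entries Data frame with columns `raw_label`, `component`, `type`,
#'   `category`.
#' @return An object of class `condensation_catalog`: the entry data frame
#'   with an additional `raw_key` column holding normalized raw labels.
#' @export
condensation_catalog <- function(entries) {
  required <- c("raw_label", "component", "type", "category")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols)) {
    stop_repmap("catalog is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  entries <- as.data.frame(entries)[required]
  for (col in required) entries[[col]] <- as.character(entries[[col]])
  entries$raw_label <- trimws(gsub("\\s+", " ", entries$raw_label))
  entries$raw_key <- normalize_label(entries$raw_label)

  bad_cat <- setdiff(unique(entries$category), CATEGORIES)
  if (length(bad_cat)) {
    stop_repmap("unknown category label(s): ", paste(bad_cat, collapse = ", "))
  }
  dup <- entries$raw_key[duplicated(entries$raw_key)]
  if (length(dup)) {
    stop_repmap("duplicate raw label(s) after normalization: ",
                paste(unique(dup), collapse = ", "))
  }
  comp_types <- unique(entries[c("component", "type")])
  bad <- comp_types$component[duplicated(comp_types$component)]
  if (length(bad)) {
    stop_repmap("component(s) assigned to more than one type: ",
                paste(unique(bad), collapse = ", "))
  }
  type_cats <- unique(entries[c("type", "category")])
  bad <- type_cats$type[duplicated(type_cats$type)]
  if (length(bad)) {
    stop_repmap("type(s) assigned to more than one category: ",
                paste(unique(bad), collapse = ", "))
  }
  structure(entries, class = c("condensation_catalog", "data.frame"))
}

#' Read a condensation catalog from CSV
#'
#' Expects columns `raw_label`, `component`, `type`, `category` (UTF-8,
#' comma-delimited). Labels are normalized for matching; original spellings
#' are kept in `raw_label`.
#'
#' @param path Path to the CSV file.
#' @return A [condensation_catalog()].
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop_repmap("catalog file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  condensation_catalog(df)
}

#' Write a condensation catalog to CSV
#' @param catalog A [condensation_catalog()].
#' @param path Output path.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(
    as.data.frame(catalog)[c("raw_label", "component", "type", "category")],
    path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

# label -> label lookup between condensation levels.
# Returns a named character vector mapping every known source-level label
# (normalized key for raw level, verbatim ids otherwise) to its image.
catalog_mapping <- function(catalog, from, to) {
  from_i <- level_index(from); to_i <- level_index(to)
  if (is.na(from_i) || is.na(to_i)) stop_repmap("unknown condensation level")
  if (from_i > to_i) {
    stop_repmap("cannot map from coarser level '", from,
                "' to finer level '", to, "'")
  }
  src <- switch(from,
    raw = catalog$raw_key, component = catalog$component, type = catalog$type)
  dst <- switch(to,
    raw = catalog$raw_key, component = catalog$component, type = catalog$type)
  keep <- !duplicated(src)
  stats::setNames(dst[keep], src[keep])
}

# resolve map node labels at `level` to their image at `to`; errors listing
# unresolvable labels
resolve_labels <- function(labels, catalog, from, to) {
  mapping <- catalog_mapping(catalog, from, to)
  keys <- if (from == "raw") normalize_label(labels) else labels
  hit <- mapping[keys]
  if (anyNA(hit)) {
    stop_repmap("label(s) not resolvable in catalog at level '", from, "': ",
                paste(unique(labels[is.na(hit)]), collapse = ", "))
  }
  stats::setNames(unname(hit), labels)
}

#' Component metadata from a catalog
#'
#' One row per component (or type) with its type and category, used to look
#' up category proportions and to group zone summaries.
#'
#' @param catalog A [condensation_catalog()].
#' @param level `"component"` or `"type"`.
#' @return Data frame with columns `id`, `type`, `category`.
#' @export
catalog_units <- function(catalog, level = c("component", "type")) {
  level <- match.arg(level)
  if (level == "component") {
    df <- unique(as.data.frame(catalog)[c("component", "type", "category")])
    names(df)[1] <- "id"
  } else {
    df <- unique(as.data.frame(catalog)[c("type", "category")])
    names(df)[1] <- "id"
    df$type <- df$id
    df <- df[c("id", "type", "category")]
  }
  rownames(df) <- NULL
  df
}

#' @export
print.condensation_catalog <- function(x, ...) {
  cat("<condensation_catalog> ", nrow(x), " raw labels -> ",
      length(unique(x$component)), " components -> ",
      length(unique(x$type)), " types -> ",
      length(unique(x$category)), " categories\n", sep = "")
  invisible(x)
}
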