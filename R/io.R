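#' Read a Mental-Modeler-style adjacency matrix
#'
#' Reads one respondent's cognitive map from a square signed adjacency matrix
#' in CSV form: concept labels as first row and first column (same order),
#' cells in \{-1, 0, +1\}, rows acting as cause and columns as effect.
#' Isolated concepts (all-zero row and column) become isolated nodes.
#'
#' @param path CSV file path (UTF-8, comma delimiter).
#' @param respondent_id Respondent identifier.
#' @param respondent_group One of [RESPONDENT_GROUPS].
#' @param drop_self_loops Drop nonzero diagonal cells with a warning instead
#'   of erroring. Default `FALSE`: elicited causal maps have no self-loops,
#'   so a nonzero diagonal signals a dirty export.
#' @param coerce_sign Coerce cells outside \{-1, 0, +1\} with `sign()` and a
#'   warning instead of erroring.
#' @return A [cognitive_map()] at level `"raw"`.
#' @export
read_adjacency_matrix <- function(path, respondent_id,
                                  respondent_group = "other",
                                  drop_self_loops = FALSE,
                                  coerce_sign = FALSE) {
  if (!file.exists(path)) stop_repmap("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        encoding = "UTF-8")
  if (ncol(df) < 2L) stop_repmap("not an adjacency matrix: ", path)
  row_labels <- as.character(df[[1]])
  col_labels <- names(df)[-1]
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(mat) != ncol(mat)) {
    stop_repmap("matrix is not square: ", nrow(mat), " rows x ",
                ncol(mat), " columns")
  }
  if (!identical(row_labels, col_labels)) {
    stop_repmap("row labels do not equal column labels in order")
  }
  if (anyDuplicated(normalize_label(row_labels))) {
    dup <- row_labels[duplicated(normalize_label(row_labels))]
    stop_repmap("duplicate labels after normalization: ",
                paste(unique(dup), collapse = ", "))
  }
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop_repmap("non-numeric or missing cells in matrix")
  if (!all(mat %in% c(-1, 0, 1))) {
    if (coerce_sign) {
      warning("cells outside {-1, 0, +1} coerced with sign()")
      mat <- sign(mat)
    } else {
      stop_repmap("cell value(s) outside {-1, 0, +1}")
    }
  }
  diag_nz <- which(diag(mat) != 0)
  if (length(diag_nz)) {
    if (drop_self_loops) {
      warning("dropped self-loop(s) on: ",
              paste(row_labels[diag_nz], collapse = ", "))
      diag(mat) <- 0
    } else {
      stop_repmap("self-loop(s) on the diagonal: ",
                  paste(row_labels[diag_nz], collapse = ", "))
    }
  }
  nz <- which(mat != 0, arr.ind = TRUE)
  edges <- data.frame(
    source = row_labels[nz[, 1]],
    target = row_labels[nz[, 2]],
    sign = as.integer(mat[nz]),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  cognitive_map(respondent_id, nodes = row_labels, edges = edges,
                respondent_group = respondent_group, level = "raw")
}

#' Write a cognitive map as a square adjacency matrix
#'
#' Round-trips with [read_adjacency_matrix()]: nodes and signed edges are
#' reproduced exactly. Conflict edges (sign 0) cannot be represented in a
#' signed matrix; when present they are omitted from the matrix and emitted
#' to a sidecar TSV report at `<path>.conflicts.tsv`.
#'
#' @param map A [cognitive_map()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_adjacency_matrix <- function(map, path) {
  stopifnot(inherits(map, "cognitive_map"))
  n <- length(map$nodes)
  mat <- matrix(0L, n, n, dimnames = list(map$nodes, map$nodes))
  if (nrow(map$edges)) {
    mat[cbind(match(map$edges$source, map$nodes),
              match(map$edges$target, map$nodes))] <- map$edges$sign
  }
  out <- data.frame(label = map$nodes, mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[1] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  if (nrow(map$conflict_edges)) {
    utils::write.table(map$conflict_edges, paste0(path, ".conflicts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read cognitive maps from an edge-list CSV
#'
#' Expects columns `respondent_id`, `source`, `target`, `sign`; one map is
#' built per respondent. Isolated (cited but unlinked) nodes are supported
#' via rows with an empty `target`. A duplicate ordered pair with conflicting
#' signs within one respondent is an error naming the pair; an exact
#' duplicate row is dropped with a warning.
#'
#' @param path CSV file path.
#' @param metadata Optional data frame with columns `respondent_id`, `group`
#'   assigning stakeholder groups.
#' @param level Condensation level of the labels in the file
#'   (default `"raw"`).
#' @param catalog Optional catalog attached to the returned collection.
#' @return A [map_collection()].
#' @export
read_edge_list <- function(path, metadata = NULL, level = "raw",
                           catalog = NULL) {
  if (!file.exists(path)) stop_repmap("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("respondent_id", "source", "target", "sign")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_repmap("edge list is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  df$respondent_id <- as.character(df$respondent_id)
  df$source <- as.character(df$source)
  df$target <- as.character(df$target)
  groups <- NULL
  if (!is.null(metadata)) {
    groups <- stats::setNames(as.character(metadata$group),
                              as.character(metadata$respondent_id))
  }
  maps <- lapply(split(df, factor(df$respondent_id,
                                  levels = unique(df$respondent_id))),
                 function(d) {
    isolated <- is.na(d$target) | !nzchar(d$target)
    ed <- d[!isolated, , drop = FALSE]
    if (nrow(ed) && !all(ed$sign %in% c(-1, 1))) {
      stop_repmap("sign outside {-1, +1} for respondent ",
                  d$respondent_id[1])
    }
    if (nrow(ed)) {
      key <- paste(ed$source, ed$target, sep = "\r")
      if (anyDuplicated(key)) {
        conflict <- tapply(ed$sign, key, function(s) length(unique(s)) > 1L)
        if (any(conflict)) {
          pairs <- sub("\r", ",", names(conflict)[conflict])
          stop_repmap("conflicting signs for pair(s) (",
                      paste(pairs, collapse = "), ("), ") of respondent ",
                      d$respondent_id[1])
        }
        warning("dropped exact duplicate edge row(s) for respondent ",
                d$respondent_id[1])
        ed <- ed[!duplicated(key), , drop = FALSE]
      }
    }
    nodes <- unique(c(d$source, ed$target))
    grp <- if (!is.null(groups) && d$respondent_id[1] %in% names(groups)) {
      groups[[d$respondent_id[1]]]
    } else "other"
    cognitive_map(d$respondent_id[1], nodes = nodes,
                  edges = ed[c("source", "target", "sign")],
                  respondent_group = grp, level = level)
  })
  map_collection(unname(maps), catalog = catalog)
}

#' Write a map collection as an edge-list CSV
#'
#' Inverse of [read_edge_list()]: signed edges become rows, and isolated
#' nodes become rows with an empty `target` and `sign`.
#'
#' @param collection A [map_collection()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(collection, path) {
  rows <- lapply(collection$maps, function(m) {
    ed <- m$edges
    linked <- unique(c(ed$source, ed$target))
    iso <- setdiff(m$nodes, linked)
    out <- data.frame(
      respondent_id = m$respondent_id,
      source = c(ed$source, iso),
      target = c(ed$target, rep("", length(iso))),
      sign = c(ed$sign, rep(NA_integer_, length(iso))),
      stringsAsFactors = FALSE
    )
    out
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = TRUE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read respondent metadata
#'
#' @param path CSV with columns `respondent_id`, `group`.
#' @return Data frame with those two columns; groups validated against
#'   [RESPONDENT_GROUPS].
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_cols <- setdiff(c("respondent_id", "group"), names(df))
  if (length(missing_cols)) {
    stop_repmap("metadata is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  bad <- setdiff(unique(df$group), RESPONDENT_GROUPS)
  if (length(bad)) {
    stop_repmap("unknown respondent group(s): ", paste(bad, collapse = ", "))
  }
  df[c("respondent_id", "group")]
}
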