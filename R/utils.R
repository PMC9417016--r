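#' Normalize a concept label for catalog matching
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs to a
#' single space, and case-folds. Original spellings are preserved elsewhere
#' (catalog `raw_label`); normalization is used only for matching, because
#' interview transcripts vary typographically.
#'
#' @param x Character vector of labels.
#' @return Character vector of normalized labels.
#' @export
#' @examples
#' normalize_label("  Zebu   Raising ")
normalize_label <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# level comparison: raw < component < type
level_index <- function(level) match(level, MAP_LEVELS)

stop_repmap <- function(..., class = "repmap_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# empty edge data.frame in canonical column order
empty_edges <- function() {
  data.frame(source = character(), target = character(),
             sign = integer(), stringsAsFactors = FALSE)
}

empty_conflicts <- function() {
  data.frame(source = character(), target = character(),
             pos_count = integer(), neg_count = integer(),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
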