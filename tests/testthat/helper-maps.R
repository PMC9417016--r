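# shared builders and independent brute-force oracles
# oracles deliberately use naive loops / explicit matrix arithmetic so they
# share no code path with the implementation they check

make_map <- function(id, nodes, edges = NULL, group = "other",
                     level = "component") {
  cognitive_map(id, nodes = nodes, edges = edges,
                respondent_group = group, level = level)
}

edges_df <- function(...) {
  rows <- list(...)
  data.frame(
    source = vapply(rows, `[[`, character(1), 1),
    target = vapply(rows, `[[`, character(1), 2),
    sign = vapply(rows, function(r) as.integer(r[[3]]), integer(1)),
    stringsAsFactors = FALSE
  )
}

# random valid map over a node pool (caller controls RNG)
random_map <- function(id, pool, p_node = 0.7, p_edge = 0.25,
                       level = "component") {
  nodes <- pool[runif(length(pool)) < p_node]
  if (!length(nodes)) nodes <- sample(pool, 1)
  ed <- NULL
  if (length(nodes) >= 2) {
    pairs <- expand.grid(source = nodes, target = nodes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, ]
    pairs <- pairs[runif(nrow(pairs)) < p_edge, , drop = FALSE]
    if (nrow(pairs)) {
      pairs$sign <- sample(c(-1L, 1L), nrow(pairs), replace = TRUE)
      ed <- pairs
    }
  }
  make_map(id, nodes, ed, level = level)
}

random_collection <- function(n_maps, pool, ...) {
  maps <- lapply(seq_len(n_maps), function(i) {
    random_map(sprintf("r%02d", i), pool, ...)
  })
  map_collection(maps)
}

# --- oracles -------------------------------------------------------------

# frequency by explicit membership count
oracle_frequency <- function(collection) {
  pool <- sort(unique(unlist(lapply(collection$maps, `[[`, "nodes"))))
  out <- numeric(length(pool))
  names(out) <- pool
  for (comp in pool) {
    hits <- 0
    for (m in collection$maps) if (comp %in% m$nodes) hits <- hits + 1
    out[comp] <- hits / collection$R
  }
  out
}

# degree centrality + average ranks by explicit comparison counting
oracle_centrality_ranks <- function(map) {
  score <- numeric(length(map$nodes))
  names(score) <- map$nodes
  for (i in seq_len(nrow(map$edges))) {
    score[map$edges$source[i]] <- score[map$edges$source[i]] + 1
    score[map$edges$target[i]] <- score[map$edges$target[i]] + 1
  }
  rk <- numeric(length(score))
  for (i in seq_along(score)) {
    higher <- sum(score > score[i])
    ties <- sum(score == score[i])
    rk[i] <- higher + (1 + ties) / 2
  }
  names(rk) <- names(score)
  rk
}

# median over citing maps via explicit sort-and-pick
oracle_median_rank <- function(collection) {
  pool <- sort(unique(unlist(lapply(collection$maps, `[[`, "nodes"))))
  per_map <- lapply(collection$maps, oracle_centrality_ranks)
  out <- numeric(length(pool))
  names(out) <- pool
  for (comp in pool) {
    ranks <- c()
    for (rk in per_map) if (comp %in% names(rk)) ranks <- c(ranks, rk[[comp]])
    s <- sort(ranks)
    n <- length(s)
    out[comp] <- if (n %% 2 == 1) s[(n + 1) / 2] else
      (s[n / 2] + s[n / 2 + 1]) / 2
  }
  out
}

# exhaustive quadrant rule
oracle_zones <- function(freq, rank, fc, rc) {
  out <- character(length(freq))
  names(out) <- names(freq)
  for (comp in names(freq)) {
    hf <- freq[[comp]] >= fc
    hc <- rank[[comp]] <= rc
    out[comp] <- if (hf && hc) "core" else if (hf) "first_periphery" else
      if (hc) "contrasting" else "second_periphery"
  }
  out
}

# entrywise sum of signed adjacency matrices padded to the union node set
oracle_weight_matrix <- function(collection) {
  pool <- sort(unique(unlist(lapply(collection$maps, `[[`, "nodes"))))
  total <- matrix(0, length(pool), length(pool),
                  dimnames = list(pool, pool))
  for (m in collection$maps) {
    mat <- matrix(0, length(pool), length(pool),
                  dimnames = list(pool, pool))
    for (i in seq_len(nrow(m$edges))) {
      mat[m$edges$source[i], m$edges$target[i]] <- m$edges$sign[i]
    }
    total <- total + mat
  }
  total
}

# weight matrix of a social_map object, padded to the same universe
scm_weight_matrix <- function(scm) {
  pool <- sort(scm$nodes$node)
  mat <- matrix(0, length(pool), length(pool), dimnames = list(pool, pool))
  if (nrow(scm$edges)) {
    mat[cbind(scm$edges$source, scm$edges$target)] <- scm$edges$weight_sum
  }
  mat
}

# brute-force condensation: group preimages, re-tally with explicit loops
oracle_condense <- function(map, catalog, level) {
  img <- resolve_labels(map$nodes, catalog, map$level, level)
  nodes <- unique(unname(img))
  pos <- neg <- matrix(0L, length(nodes), length(nodes),
                       dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(map$edges))) {
    s <- img[[map$edges$source[i]]]
    t <- img[[map$edges$target[i]]]
    if (s == t) next
    if (map$edges$sign[i] > 0) pos[s, t] <- pos[s, t] + 1L else
      neg[s, t] <- neg[s, t] + 1L
  }
  list(nodes = sort(nodes), pos = pos, neg = neg)
}
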