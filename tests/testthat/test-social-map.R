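test_that("aggregation tallies citations and signed link records", {
  col <- map_collection(list(
    make_map("r1", c("A", "B"), edges_df(list("A", "B", 1))),
    make_map("r2", c("A", "B"), edges_df(list("A", "B", 1)))
  ))
  scm <- build_social_map(col)
  e <- scm$edges
  expect_equal(e$weight_sum, 2L)
  expect_equal(e$occurrence, 2L)
  expect_equal(e$pos_count, 2L)
  expect_equal(e$neg_count, 0L)
  expect_equal(scm$nodes$frequency, c(1, 1))

  # cancellation is retained in the tallies, not collapsed away
  col2 <- map_collection(list(
    make_map("r1", c("A", "B"), edges_df(list("A", "B", 1))),
    make_map("r2", c("A", "B"), edges_df(list("A", "B", -1)))
  ))
  e2 <- build_social_map(col2)$edges
  expect_equal(e2$weight_sum, 0L)
  expect_equal(e2$occurrence, 2L)
  expect_equal(e2$pos_count, 1L)
  expect_equal(e2$neg_count, 1L)
})

test_that("social map equals the entrywise sum of padded matrices", {
  withr::with_seed(21, {
    for (i in 1:60) {
      col <- random_collection(sample(2:6, 1), sprintf("n%02d", 1:10))
      scm <- build_social_map(col)
      expect_equal(scm_weight_matrix(scm), oracle_weight_matrix(col))
      # conservation: links across maps = total pair occurrence
      expect_equal(sum(vapply(col$maps, function(m) nrow(m$edges),
                              numeric(1))),
                   sum(scm$edges$occurrence))
      expect_true(all(abs(scm$edges$weight_sum) <= scm$edges$occurrence))
      expect_true(all(scm$nodes$citation_count >= 1 &
                        scm$nodes$citation_count <= col$R))
    }
  })
})

test_that("aggregation is permutation-invariant", {
  withr::with_seed(5, {
    col <- random_collection(5, sprintf("n%02d", 1:8))
    perm <- map_collection(unname(col$maps)[c(3, 5, 1, 4, 2)])
    expect_equal(build_social_map(col)$edges, build_social_map(perm)$edges)
  })
})

test_that("display filters use strict thresholds", {
  maps <- lapply(1:32, function(i) {
    nodes <- c("common", if (i <= 3) "rare", if (i <= 11) "mid")
    ed <- NULL
    if (i <= 11) ed <- edges_df(list("common", "mid", 1))
    make_map(paste0("r", i), nodes, ed)
  })
  scm <- build_social_map(map_collection(maps))
  # node cited by 3/32 ~ 0.094 is removed at the >10% cut
  f1 <- filter_social_map(scm, node_freq_min = 0.10)
  expect_false("rare" %in% f1$nodes$node)
  expect_true(all(c("common", "mid") %in% f1$nodes$node))
  # edge occurring 11 times survives edge_occ_min = 10, 10 would not
  expect_equal(f1$edges$occurrence, 11L)
  f2 <- filter_social_map(scm, edge_occ_min = 10)
  expect_equal(nrow(f2$edges), 1L)
  f3 <- filter_social_map(scm, edge_occ_min = 11)
  expect_equal(nrow(f3$edges), 0L)
  # thresholds (0,0) are the identity here (no zero-occurrence entries)
  f0 <- filter_social_map(scm, 0, 0)
  expect_equal(f0$nodes, scm$nodes)
  expect_equal(f0$edges, scm$edges)
  # monotone: raising a threshold never adds material
  for (cut in c(0.2, 0.5)) {
    expect_lte(nrow(filter_social_map(scm, cut)$nodes),
               nrow(filter_social_map(scm, cut / 2)$nodes))
  }
})

test_that("group maps partition the aggregate", {
  withr::with_seed(13, {
    col <- random_collection(6, sprintf("n%02d", 1:9))
    labels <- stats::setNames(rep(c("g1", "g2"), each = 3),
                              names(col$maps))
    gm <- group_social_maps(col, labels)
    full <- scm_weight_matrix(build_social_map(col))
    pool <- rownames(full)
    padded <- lapply(gm, function(s) {
      mat <- matrix(0, length(pool), length(pool),
                    dimnames = list(pool, pool))
      if (nrow(s$edges)) {
        mat[cbind(s$edges$source, s$edges$target)] <- s$edges$weight_sum
      }
      mat
    })
    expect_equal(Reduce(`+`, padded), full)
    # all respondents in one group reproduces the full aggregate
    one <- group_social_maps(col, stats::setNames(rep("g", 6),
                                                  names(col$maps)))
    expect_equal(one$g$edges, build_social_map(col)$edges)
    # singleton group: counts are 1 and edges are the respondent's own
    single <- group_social_maps(
      col, stats::setNames(c("a", rep("b", 5)), names(col$maps)))
    expect_true(all(single$a$edges$occurrence == 1))
    expect_equal(nrow(single$a$edges), nrow(col$maps[[1]]$edges))
    expect_error(group_social_maps(col, labels[-1]), "unlabeled")
  })
})

test_that("focal subgraphs keep the 1-hop neighborhood above threshold", {
  col <- map_collection(lapply(1:3, function(i) {
    make_map(paste0("r", i), c("A", "fires", "B", "C"),
             edges_df(list("A", "fires", 1), list("fires", "B", -1)))
  }))
  scm <- build_social_map(col)
  fs <- focus_subgraph(scm, focal = "fires", edge_occ_min = 0)
  expect_setequal(fs$nodes$node, c("A", "fires", "B"))
  # strict threshold: occurrence 3 excluded at edge_occ_min = 3
  fs3 <- focus_subgraph(scm, focal = "fires", edge_occ_min = 3)
  expect_equal(nrow(fs3$edges), 0L)
  expect_equal(fs3$nodes$node, "fires")
  fs2 <- focus_subgraph(scm, focal = "fires", edge_occ_min = 2)
  expect_equal(nrow(fs2$edges), 2L)
  # focal = whole node set at threshold 0 is the identity
  all_fs <- focus_subgraph(scm, focal = scm$nodes$node, edge_occ_min = 0)
  expect_equal(all_fs$nodes, scm$nodes)
  expect_equal(all_fs$edges, scm$edges)
  expect_error(focus_subgraph(scm, focal = "volcano"), "absent")
})

test_that("focal types resolve through the catalog", {
  sim <- generate_collection(generator_config(seed = 8))
  scm <- build_social_map(sim$collection)
  units <- catalog_units(sim$collection$catalog, "component")
  ty <- units$type[1]
  fs <- focus_subgraph(scm, focal_types = ty, edge_occ_min = 2)
  members <- intersect(units$id[units$type == ty], scm$nodes$node)
  expect_true(all(fs$edges$source %in% members |
                    fs$edges$target %in% members))
  expect_true(all(fs$edges$occurrence > 2))
})

test_that("igraph exports carry attributes and styling", {
  sim <- generate_collection(generator_config(seed = 9))
  scm <- filter_social_map(build_social_map(sim$collection),
                           node_freq_min = 0.10, edge_occ_min = 3)
  expect_gt(nrow(scm$edges), 0)
  g <- as_igraph(scm)
  expect_equal(igraph::vcount(g), nrow(scm$nodes))
  expect_equal(igraph::ecount(g), nrow(scm$edges))
  expect_true(all(igraph::E(g)$color %in% c("green", "red", "grey")))
  expect_true(all(igraph::V(g)$category %in% CATEGORIES))
  gml <- withr::local_tempfile(fileext = ".graphml")
  dot <- withr::local_tempfile(fileext = ".dot")
  write_social_map_graphml(scm, gml)
  write_social_map_dot(scm, dot)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), nrow(scm$nodes))
  expect_true(any(grepl("penwidth", readLines(dot))))
})
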