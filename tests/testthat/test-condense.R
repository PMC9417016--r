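demo_catalog <- function() {
  read_catalog(system.file("extdata", "example_catalog.csv",
                           package = "repmap"))
}

test_that("same-sign raw edges merge into one tallied edge", {
  cat1 <- condensation_catalog(data.frame(
    raw_label = c("lemur", "sifaka", "forest"),
    component = c("lemurs", "lemurs", "forest"),
    type = c("species", "species", "habitats"),
    category = "biophysical"
  ))
  m <- make_map("r1", c("lemur", "sifaka", "forest"),
                edges_df(list("lemur", "forest", 1),
                         list("sifaka", "forest", 1)),
                level = "raw")
  out <- condense_map(m, cat1, "component")
  expect_setequal(out$nodes, c("lemurs", "forest"))
  expect_equal(nrow(out$edges), 1L)
  expect_equal(out$edges$sign, 1L)
  expect_equal(nrow(out$conflict_edges), 0L)
})

test_that("exactly cancelling tallies become conflict edges", {
  cat1 <- condensation_catalog(data.frame(
    raw_label = c("fire", "burning", "forest"),
    component = c("fires", "fires", "forest"),
    type = c("threats", "threats", "habitats"),
    category = c("negative_human_action", "negative_human_action",
                 "biophysical")
  ))
  m <- make_map("r1", c("fire", "burning", "forest"),
                edges_df(list("fire", "forest", -1),
                         list("burning", "forest", 1)),
                level = "raw")
  out <- condense_map(m, cat1, "component")
  expect_equal(nrow(out$edges), 0L)
  expect_equal(out$conflict_edges$source, "fires")
  expect_equal(out$conflict_edges$target, "forest")
  expect_equal(out$conflict_edges$pos_count, 1L)
  expect_equal(out$conflict_edges$neg_count, 1L)
})

test_that("majority sign wins and merged self-loops are dropped", {
  cat1 <- condensation_catalog(data.frame(
    raw_label = c("a1", "a2", "a3", "b1"),
    component = c("A", "A", "A", "B"),
    type = c("tA", "tA", "tA", "tB"),
    category = "social"
  ))
  m <- make_map("r1", c("a1", "a2", "a3", "b1"),
                edges_df(list("a1", "b1", 1), list("a2", "b1", 1),
                         list("a3", "b1", -1),  # majority +
                         list("a1", "a2", 1)),  # merges into a self-loop
                level = "raw")
  out <- condense_map(m, cat1, "component")
  expect_equal(out$edges$sign, 1L)
  expect_equal(out$n_dropped_self_loops, 1L)
})

test_that("condensation is idempotent and counts never increase", {
  cat1 <- demo_catalog()
  raws <- cat1$raw_label
  withr::with_seed(7, {
    for (i in 1:20) {
      m <- random_map("r1", raws, p_node = 0.8, p_edge = 0.2, level = "raw")
      once <- condense_map(m, cat1, "component")
      twice <- condense_map(once, cat1, "component")
      expect_identical(once, twice)
      expect_lte(length(once$nodes), length(m$nodes))
      expect_lte(nrow(once$edges) + nrow(once$conflict_edges),
                 nrow(m$edges))
    }
  })
})

test_that("condensation agrees with the brute-force preimage oracle", {
  cat1 <- demo_catalog()
  raws <- cat1$raw_label
  withr::with_seed(11, {
    for (i in 1:500) {
      m <- random_map("r1", sample(raws, 8), p_node = 0.9, p_edge = 0.3,
                      level = "raw")
      for (lvl in c("component", "type")) {
        got <- condense_map(m, cat1, lvl)
        want <- oracle_condense(m, cat1, lvl)
        expect_setequal(got$nodes, want$nodes)
        net <- want$pos - want$neg
        for (j in seq_len(nrow(got$edges))) {
          e <- got$edges[j, ]
          expect_equal(e$sign, sign(net[e$source, e$target]))
        }
        # every nonzero oracle pair is either an edge or a conflict
        nz <- which(want$pos + want$neg > 0, arr.ind = TRUE)
        n_pairs <- nrow(got$edges) + nrow(got$conflict_edges)
        expect_equal(n_pairs, nrow(nz))
        for (j in seq_len(nrow(got$conflict_edges))) {
          ce <- got$conflict_edges[j, ]
          expect_equal(want$pos[ce$source, ce$target],
                       want$neg[ce$source, ce$target])
        }
      }
    }
  })
})

test_that("type-level condensation never increases node counts (32 maps)", {
  sim <- generate_collection(generator_config(seed = 5))
  col <- sim$collection
  typed <- condense_collection(col, "type")
  for (id in names(col$maps)) {
    expect_lte(length(typed$maps[[id]]$nodes),
               length(col$maps[[id]]$nodes))
    want <- oracle_condense(col$maps[[id]], col$catalog, "type")
    expect_setequal(typed$maps[[id]]$nodes, want$nodes)
  }
})

test_that("condensation report audits the merge and is additive", {
  cat1 <- demo_catalog()
  # identity catalog: every raw label its own component
  ident <- condensation_catalog(data.frame(
    raw_label = c("x", "y"), component = c("x", "y"),
    type = c("tx", "ty"), category = "social"
  ))
  before <- map_collection(list(
    make_map("r1", c("x", "y"), edges_df(list("x", "y", 1)), level = "raw")
  ), catalog = ident)
  after <- condense_collection(before, "component")
  rep0 <- condensation_report(before, after)
  expect_equal(rep0$per_respondent$nodes_merged, 0L)
  expect_equal(rep0$per_respondent$edges_merged, 0L)
  expect_equal(rep0$per_respondent$conflicts, 0L)
  expect_equal(rep0$unique_before, rep0$unique_after)

  # full-size universe: 162 components condense to at most 32 types
  sim <- generate_collection(generator_config(seed = 3))
  col <- sim$collection
  typed <- condense_collection(col, "type")
  rep1 <- condensation_report(col, typed)
  expect_equal(rep1$unique_before,
               length(unique(unlist(lapply(col$maps, `[[`, "nodes")))))
  expect_lte(rep1$unique_after, 32L)
  # totals equal the sum of per-respondent entries
  pr <- rep1$per_respondent
  expect_equal(sum(pr$nodes_merged),
               sum(pr$nodes_before) - sum(pr$nodes_after))

  expect_error(condensation_report(before, map_collection(list(
    make_map("r9", "x", level = "component")
  ))), "different respondents")
})

test_that("raw catalog fixture condenses 162 components into 32 types", {
  cat_full <- read_catalog(system.file("extdata", "catalog_synthetic.csv",
                                       package = "repmap"))
  # a raw-level map using typographic variants still resolves
  raws <- cat_full$raw_label[c(1, 200, 40, 2)]
  m <- make_map("r1", raws, edges_df(list(raws[1], raws[3], 1)),
                level = "raw")
  out <- condense_map(m, cat_full, "component")
  expect_true(all(out$nodes %in% cat_full$component))
})
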