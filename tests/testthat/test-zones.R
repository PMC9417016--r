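test_that("component frequency counts citing maps", {
  maps <- lapply(1:32, function(i) {
    make_map(paste0("r", i), c("everywhere", if (i <= 16) "half"))
  })
  freq <- component_frequency(map_collection(maps))
  expect_equal(freq[["half"]], 0.5)
  expect_equal(freq[["everywhere"]], 1.0)
})

test_that("median centrality rank uses only the citing maps", {
  m1 <- make_map("r1", c("X", "a", "b"),
                 edges_df(list("X", "a", 1), list("X", "b", 1),
                          list("a", "b", 1)))           # X rank 1
  m2 <- make_map("r2", c("X", "a", "b"),
                 edges_df(list("a", "b", 1), list("b", "a", 1),
                          list("X", "a", 1)))           # X rank 3
  m3 <- make_map("r3", c("X", "a", "b", "c", "d"),
                 edges_df(list("a", "b", 1), list("b", "c", 1),
                          list("c", "d", 1), list("d", "a", 1),
                          list("a", "c", 1)))           # X rank 5 (isolated)
  col <- map_collection(list(m1, m2, m3))
  med <- median_centrality_rank(col)
  expect_equal(med[["X"]],
               stats::median(c(oracle_centrality_ranks(m1)[["X"]],
                               oracle_centrality_ranks(m2)[["X"]],
                               oracle_centrality_ranks(m3)[["X"]])))
  # single citation: the median is that one rank
  m4 <- make_map("r4", c("Y", "a"), edges_df(list("a", "Y", 1)))
  med4 <- median_centrality_rank(map_collection(list(m4)))
  expect_equal(med4[["Y"]], 1.5)  # tie between Y and a, averaged
  # even number of citing maps: midpoint average
  colXY <- map_collection(list(m1, m2))
  expect_equal(median_centrality_rank(colXY)[["X"]],
               (oracle_centrality_ranks(m1)[["X"]] +
                  oracle_centrality_ranks(m2)[["X"]]) / 2)
})

test_that("quadrant rule places components in the stated zones", {
  freq <- c(widespread_central = 0.9, widespread_shallow = 0.9,
            niche_central = 0.2, niche_shallow = 0.1)
  rank <- c(widespread_central = 2, widespread_shallow = 20,
            niche_central = 3, niche_shallow = 25)
  zt <- classify_zones(freq, rank, freq_cut = 0.5, rank_cut = 10)
  got <- stats::setNames(zt$zone, zt$component)
  expect_equal(got[["widespread_central"]], "core")
  expect_equal(got[["widespread_shallow"]], "first_periphery")
  expect_equal(got[["niche_central"]], "contrasting")
  expect_equal(got[["niche_shallow"]], "second_periphery")
  # ties at the cuts go to the high / central side
  zt2 <- classify_zones(c(x = 0.5), c(x = 10), freq_cut = 0.5,
                        rank_cut = 10)
  expect_equal(zt2$zone, "core")
  expect_error(classify_zones(c(a = 1), c(b = 1)), "different components")
})

test_that("median cuts are resolved, stored, and reproducible", {
  withr::with_seed(31, {
    freq <- stats::setNames(runif(12, 0.05, 1), paste0("c", 1:12))
    rank <- stats::setNames(runif(12, 1, 20), paste0("c", 1:12))
    zt <- classify_zones(freq, rank)
    expect_equal(attr(zt, "freq_cut"), stats::median(freq))
    expect_equal(attr(zt, "rank_cut"), stats::median(rank))
    want <- oracle_zones(freq, rank, stats::median(freq),
                         stats::median(rank))
    expect_equal(stats::setNames(zt$zone, zt$component), want[zt$component])
    # partition + relabeling invariance
    expect_equal(sort(zt$component), sort(names(freq)))
    names2 <- stats::setNames(paste0("z", 12:1), names(freq))
    zt_rel <- classify_zones(stats::setNames(freq, names2[names(freq)]),
                             stats::setNames(rank, names2[names(rank)]))
    expect_equal(stats::setNames(zt_rel$zone, zt_rel$component),
                 stats::setNames(zt$zone, names2[zt$component])[
                   zt_rel$component])
  })
})

test_that("raising a component's frequency never demotes it", {
  withr::with_seed(17, {
    freq <- stats::setNames(runif(10), paste0("c", 1:10))
    rank <- stats::setNames(runif(10, 1, 10), paste0("c", 1:10))
    fc <- 0.5; rc <- 5
    toward_core <- c(second_periphery = 1, contrasting = 2,
                     first_periphery = 2, core = 3)
    for (i in 1:10) {
      z1 <- classify_zones(freq, rank, fc, rc)
      freq2 <- freq
      freq2[i] <- min(1, freq[i] + 0.3)
      z2 <- classify_zones(freq2, rank, fc, rc)
      comp <- names(freq)[i]
      expect_gte(toward_core[[z2$zone[z2$component == comp]]],
                 toward_core[[z1$zone[z1$component == comp]]])
    }
  })
})

test_that("zone summary reproduces planted structure and partitions", {
  # strongly separated planted zones: counts echo the study's 31/20/49
  cfg <- generator_config(
    seed = 77,
    zone_counts = c(core = 31, first_periphery = 24, contrasting = 20,
                    second_periphery = 87),
    zone_prob = list(core = c(0.85, 0.95), first_periphery = c(0.85, 0.95),
                     contrasting = c(0.05, 0.25),
                     second_periphery = c(0.05, 0.25)))
  sim <- generate_collection(cfg)
  zt <- representation_zones(sim$collection)
  zs <- zone_summary(zt, sim$collection$catalog)
  expect_equal(sum(zs$zone_counts), nrow(zt))
  conf <- recovery_report(sim$truth, zone_table = zt)$zone_confusion
  # rows cover the planted zones of every *cited* (hence classified)
  # component
  expect_equal(unname(rowSums(conf)),
               unname(table(factor(sim$truth$zone[zt$component],
                                   levels = ZONES))[ZONES]),
               ignore_attr = TRUE)
  expect_gte(recovery_report(sim$truth, zone_table = zt)$core_accuracy, 0.9)

  # single-component table
  zt1 <- classify_zones(c(forest = 0.8), c(forest = 1), 0.5, 3)
  cat1 <- read_catalog(system.file("extdata", "example_catalog.csv",
                                   package = "repmap"))
  zs1 <- zone_summary(zt1, cat1)
  expect_equal(unname(zs1$zone_counts["core"]), 1L)
  expect_equal(sum(zs1$zone_counts), 1L)
  expect_equal(zs1$by_type$mean_frequency, 0.8)
})

test_that("zone-table comparison reports overlap fractions", {
  za <- classify_zones(c(a = 0.9, b = 0.9, c = 0.1),
                       c(a = 1, b = 2, c = 9), 0.5, 5)
  expect_equal(compare_zone_tables(za, za)$frac_a[1], 1)
  zb <- classify_zones(c(d = 0.9, e = 0.9), c(d = 1, e = 2), 0.5, 5)
  cmp <- compare_zone_tables(za, zb)
  expect_equal(cmp$n_shared[cmp$zone == "core"], 0L)

  # planted two-cluster overlap matches set arithmetic
  sim <- generate_collection(generator_config(seed = 12))
  col <- sim$collection
  labels <- sim$truth$cluster[names(col$maps)]
  subsets <- lapply(split(names(col$maps), labels), function(ids) {
    representation_zones(map_collection(unname(col$maps[ids]),
                                        catalog = col$catalog))
  })
  cmp2 <- compare_zone_tables(subsets[[1]], subsets[[2]])
  core_a <- subsets[[1]]$component[subsets[[1]]$zone == "core"]
  core_b <- subsets[[2]]$component[subsets[[2]]$zone == "core"]
  expect_equal(cmp2$n_shared[cmp2$zone == "core"],
               length(intersect(core_a, core_b)))
  expect_equal(cmp2$frac_a[cmp2$zone == "core"],
               length(intersect(core_a, core_b)) / length(core_a))
})

test_that("full zoning chain matches the brute-force oracle", {
  withr::with_seed(41, {
    for (i in 1:200) {
      col <- random_collection(sample(2:8, 1), sprintf("n%02d", 1:12))
      freq <- component_frequency(col)
      rank <- median_centrality_rank(col)
      expect_equal(freq, oracle_frequency(col))
      expect_equal(rank[names(freq)], oracle_median_rank(col)[names(freq)])
      zt <- representation_zones(col)
      want <- oracle_zones(freq, rank[names(freq)],
                           stats::median(freq),
                           stats::median(rank[names(freq)]))
      expect_equal(stats::setNames(zt$zone, zt$component),
                   want[zt$component])
    }
  })
})
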