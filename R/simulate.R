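#' Configuration for the synthetic map generator
#'
#' Builds the parameter set for [generate_universe()] and
#' [generate_collection()]. Defaults emulate the study conditions of the
#' motivating survey: 32 respondents, a universe of 162 components grouped
#' into 32 types and six categories, per-map sizes truncated to \[20, 97\],
#' and two equally-mixed respondent clusters contrasting in map size, link
#' load, category mix and negative-human-action share (an "ecocentric" and a
#' "social-ecological" profile). Zone structure is planted by drawing each
#' component's citation probability from its zone's interval, and core /
#' contrasting components receive a centrality boost when edges are drawn.
#' Edge signs come from a fixed per-ordered-pair ground truth flipped with a
#' small probability, which reproduces ambivalent links (the same pair
#' judged positive by some respondents and negative by others).
#'
#' @param seed Integer seed; every downstream draw derives from it.
#' @param R Number of respondents.
#' @param n_components,n_types Universe size (components, types).
#' @param zone_counts Named integer vector over [ZONES]; must sum to
#'   `n_components`.
#' @param zone_prob Named list over [ZONES] of `c(lo, hi)` citation
#'   probability intervals.
#' @param category_counts Named integer vector over [CATEGORIES]; must sum
#'   to `n_components`.
#' @param cluster_specs List of per-cluster lists with fields `name`, `mix`
#'   (mixing proportions summing to 1), `size_mean`, `size_sd` (truncated
#'   normal target map size), `link_rate` (expected links per node),
#'   `link_cv` (lognormal spread of the link count), `category_mix` (six
#'   weights summing to 1), `group_mix` (five weights over
#'   [RESPONDENT_GROUPS]).
#' @param size_bounds `c(min, max)` map size bounds (clipped).
#' @param centrality_boost Degree multiplier for planted core and
#'   contrasting components (>= 1).
#' @param pair_salience_sd Log-scale SD of the shared per-pair salience
#'   weights. Link choice within a map is weighted by a lognormal salience
#'   drawn once per ordered pair at the universe level, so respondents
#'   concentrate on the same salient links (as interviewees citing the same
#'   well-known causal relations do); 0 makes pair choice uniform.
#' @param sign_pos_prob Probability that a pair's ground-truth sign is +1.
#' @param sign_flip_prob Probability that an emitted edge's sign is flipped
#'   relative to the ground truth.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(
    seed = 1,
    R = 32,
    n_components = 162,
    n_types = 32,
    zone_counts = c(core = 31, first_periphery = 24, contrasting = 20,
                    second_periphery = 87),
    zone_prob = list(core = c(0.65, 0.90),
                     first_periphery = c(0.55, 0.85),
                     contrasting = c(0.10, 0.30),
                     second_periphery = c(0.04, 0.22)),
    category_counts = c(biophysical = 48, social = 63,
                        ecosystem_service = 33, ecosystem_disservice = 3,
                        positive_human_action = 6,
                        negative_human_action = 9),
    cluster_specs = list(
      list(name = "ecocentric", mix = 0.5,
           size_mean = 29.1, size_sd = 7.6,
           link_rate = 41.8 / 29.1, link_cv = 0.20,
           category_mix = c(biophysical = 0.33, social = 0.36,
                            ecosystem_service = 0.21,
                            ecosystem_disservice = 0.00,
                            positive_human_action = 0.03,
                            negative_human_action = 0.08),
           group_mix = c(researcher = 9, ngo_member = 2, project_member = 1,
                         tour_operator = 4, other = 0) / 16),
      list(name = "social_ecological", mix = 0.5,
           size_mean = 45.8, size_sd = 10.1,
           link_rate = 81.2 / 45.8, link_cv = 0.39,
           category_mix = c(biophysical = 0.26, social = 0.43,
                            ecosystem_service = 0.20,
                            ecosystem_disservice = 0.01,
                            positive_human_action = 0.04,
                            negative_human_action = 0.05),
           group_mix = c(researcher = 3, ngo_member = 7, project_member = 5,
                         tour_operator = 1, other = 0) / 16)
    ),
    size_bounds = c(20, 97),
    centrality_boost = 3,
    pair_salience_sd = 2,
    sign_pos_prob = 0.7,
    sign_flip_prob = 0.1) {
  zone_counts <- zone_counts[ZONES]
  if (anyNA(zone_counts) || sum(zone_counts) != n_components) {
    stop_repmap("zone_counts must cover the four zones and sum to ",
                n_components)
  }
  category_counts <- category_counts[CATEGORIES]
  if (anyNA(category_counts) || sum(category_counts) != n_components) {
    stop_repmap("category_counts must cover the six categories and sum to ",
                n_components)
  }
  mixes <- vapply(cluster_specs, `[[`, numeric(1), "mix")
  if (abs(sum(mixes) - 1) > 1e-9) {
    stop_repmap("cluster mixing proportions must sum to 1")
  }
  cluster_specs <- lapply(cluster_specs, function(cs) {
    if (abs(sum(cs$category_mix) - 1) > 0.05) {
      stop_repmap("category_mix of cluster '", cs$name,
                  "' must sum to 1")
    }
    # printed category shares may carry rounding error; renormalize
    cs$category_mix <- .mix_vector(cs$category_mix)
    cs
  })
  probs <- unlist(zone_prob)
  if (any(probs < 0 | probs > 1)) {
    stop_repmap("citation probabilities must lie in [0, 1]")
  }
  if (size_bounds[1] < 2 || size_bounds[2] < size_bounds[1]) {
    stop_repmap("infeasible size bounds")
  }
  structure(
    list(seed = as.integer(seed), R = as.integer(R),
         n_components = as.integer(n_components),
         n_types = as.integer(n_types),
         zone_counts = zone_counts, zone_prob = zone_prob,
         category_counts = category_counts,
         cluster_specs = cluster_specs, size_bounds = size_bounds,
         centrality_boost = centrality_boost,
         pair_salience_sd = pair_salience_sd,
         sign_pos_prob = sign_pos_prob, sign_flip_prob = sign_flip_prob),
    class = "generator_config"
  )
}

# normalize cluster category_mix against CATEGORIES order
.mix_vector <- function(mix) {
  v <- mix[CATEGORIES]
  v[is.na(v)] <- 0
  v / sum(v)
}

# truncated normal via rejection (bounds are part of the size model)
rtruncnorm1 <- function(mean, sd, lo, hi) {
  for (i in 1:10000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

# moments of N(mu, sigma) truncated to [lo, hi]
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# underlying normal parameters whose truncation to [lo, hi] realizes the
# requested mean and sd (so configured map-size statistics are the realized
# ones, not pre-truncation ones)
match_truncnorm <- function(mean, sd, lo, hi) {
  obj <- function(par) {
    mm <- truncnorm_moments(par[1], exp(par[2]), lo, hi)
    (mm[["mean"]] - mean)^2 + (mm[["sd"]] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Generate the component universe
#'
#' Deterministically (given the seed) builds a condensation catalog of
#' `n_components` components in `n_types` types and the six categories,
#' together with the planted ground truth: each component's representation
#' zone and citation probability (drawn uniformly from its zone's interval)
#' and each ordered pair's ground-truth sign. Types are allocated to
#' categories proportionally to category sizes; about a third of the
#' components receive a second, typographically-varied raw label so that
#' label normalization and condensation are exercised.
#'
#' @param config A [generator_config()].
#' @return List with `catalog` (a [condensation_catalog()]) and `truth`
#'   (list: `zone`, `citation_prob`, `category` — named by component —
#'   and `sign` — a signed matrix over components).
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed, {
    nc <- config$n_components
    comp_ids <- sprintf("cmp%03d", seq_len(nc))
    category <- rep(CATEGORIES, times = config$category_counts)

    # allocate types to categories proportionally (each category >= 1 type)
    raw_alloc <- config$n_types * config$category_counts / nc
    n_ty <- pmax(1L, round(raw_alloc))
    while (sum(n_ty) > config$n_types) {
      i <- which.max(n_ty - raw_alloc); n_ty[i] <- n_ty[i] - 1L
    }
    while (sum(n_ty) < config$n_types) {
      i <- which.min(n_ty - raw_alloc); n_ty[i] <- n_ty[i] + 1L
    }
    abbrev <- c(biophysical = "bio", social = "soc",
                ecosystem_service = "esv", ecosystem_disservice = "eds",
                positive_human_action = "pha",
                negative_human_action = "nha")
    type_labels <- unlist(lapply(seq_along(CATEGORIES), function(i) {
      sprintf("type_%s_%02d", abbrev[[CATEGORIES[i]]], seq_len(n_ty[i]))
    }))
    type_cat <- rep(CATEGORIES, times = n_ty)
    # round-robin components onto their category's types
    type_of <- character(nc)
    for (g in CATEGORIES) {
      idx <- which(category == g)
      tys <- type_labels[type_cat == g]
      type_of[idx] <- tys[((seq_along(idx) - 1L) %% length(tys)) + 1L]
    }

    zone <- sample(rep(ZONES, times = config$zone_counts))
    citation_prob <- vapply(zone, function(z) {
      iv <- config$zone_prob[[z]]
      stats::runif(1, iv[1], iv[2])
    }, numeric(1))
    names(zone) <- names(citation_prob) <- comp_ids

    sign_mat <- matrix(
      ifelse(stats::runif(nc * nc) < config$sign_pos_prob, 1L, -1L),
      nc, nc, dimnames = list(comp_ids, comp_ids))
    salience <- matrix(
      stats::rlnorm(nc * nc, 0, config$pair_salience_sd),
      nc, nc, dimnames = list(comp_ids, comp_ids))

    # raw labels: every component one canonical label; some get a
    # typographic variant to exercise normalization and condensation
    entries <- data.frame(raw_label = comp_ids, component = comp_ids,
                          type = type_of, category = category,
                          stringsAsFactors = FALSE)
    variant <- stats::runif(nc) < 1 / 3
    if (any(variant)) {
      extra <- entries[variant, , drop = FALSE]
      extra$raw_label <- toupper(sub("cmp", "Cmp ", extra$raw_label))
      entries <- rbind(entries, extra)
    }
    list(
      catalog = condensation_catalog(entries),
      truth = list(zone = zone, citation_prob = citation_prob,
                   category = stats::setNames(category, comp_ids),
                   sign = sign_mat, salience = salience)
    )
  })
}

#' Generate a synthetic collection of cognitive maps
#'
#' Draws `R` respondent maps at the component level. Respondents are
#' allocated to clusters in the configured proportions (rounded, shuffled);
#' each respondent draws their map size from their cluster's truncated
#' normal (so realized size statistics follow the configured mean/SD/range
#' directly), splits it across categories by the cluster's category mix
#' (largest remainder, capped at category availability), and samples that
#' many components per category weighted by planted citation probability.
#' Links are then sampled among the included nodes with weights boosting
#' planted core and contrasting components, at the cluster's links-per-node
#' rate with lognormal spread; each link's sign is the pair's ground-truth
#' sign, flipped with the configured probability.
#'
#' @param config A [generator_config()].
#' @param universe Optional result of [generate_universe()] (regenerated
#'   from the config when omitted).
#' @return List with `collection` (a [map_collection()] at component
#'   level, catalog attached) and `truth` (the universe ground truth plus
#'   `cluster` and `group`, named by respondent).
#' @export
generate_collection <- function(config, universe = NULL) {
  stopifnot(inherits(config, "generator_config"))
  universe <- universe %||% generate_universe(config)
  catalog <- universe$catalog
  truth <- universe$truth
  comp_ids <- names(truth$zone)
  p <- truth$citation_prob
  category <- truth$category
  boost <- ifelse(truth$zone %in% c("core", "contrasting"),
                  config$centrality_boost, 1)
  ids_by_cat <- split(comp_ids, factor(category, levels = CATEGORIES))
  avail <- lengths(ids_by_cat)
  # size_mean/size_sd are realized (post-truncation) statistics; recover
  # the underlying normal parameters once per cluster
  size_pars <- lapply(config$cluster_specs, function(cs) {
    match_truncnorm(cs$size_mean, cs$size_sd,
                    config$size_bounds[1], config$size_bounds[2])
  })

  with_local_seed(config$seed + 1L, {
    R <- config$R
    # deterministic cluster sizes (largest remainder), shuffled order
    mixes <- vapply(config$cluster_specs, `[[`, numeric(1), "mix")
    sizes <- floor(R * mixes)
    rem <- order(R * mixes - sizes, decreasing = TRUE)
    i <- 1L
    while (sum(sizes) < R) {
      sizes[rem[i]] <- sizes[rem[i]] + 1L
      i <- i %% length(sizes) + 1L
    }
    cluster_idx <- sample(rep(seq_along(sizes), times = sizes))
    resp_ids <- sprintf("r%02d", seq_len(R))

    # stakeholder groups: per-cluster counts, largest remainder, shuffled
    group_of <- character(R)
    for (ci in seq_along(config$cluster_specs)) {
      members <- which(cluster_idx == ci)
      gm <- config$cluster_specs[[ci]]$group_mix[RESPONDENT_GROUPS]
      gm[is.na(gm)] <- 0
      gn <- floor(length(members) * gm)
      remg <- order(length(members) * gm - gn, decreasing = TRUE)
      j <- 1L
      while (sum(gn) < length(members)) {
        gn[remg[j]] <- gn[remg[j]] + 1L
        j <- j %% length(gn) + 1L
      }
      group_of[members] <- sample(rep(RESPONDENT_GROUPS, times = gn))
    }

    maps <- vector("list", R)
    for (r in seq_len(R)) {
      cs <- config$cluster_specs[[cluster_idx[r]]]
      sz <- size_pars[[cluster_idx[r]]]
      n_target <- round(rtruncnorm1(sz[["mu"]], sz[["sigma"]],
                                    config$size_bounds[1],
                                    config$size_bounds[2]))
      n_target <- min(n_target, sum(avail))
      mix <- .mix_vector(cs$category_mix)
      # per-category counts: largest remainder, capped at availability,
      # overflow redistributed to categories with remaining capacity
      exact <- n_target * mix
      n_by_cat <- pmin(floor(exact), avail)
      frac <- exact - floor(exact)
      while (sum(n_by_cat) < n_target) {
        room <- which(n_by_cat < avail)
        i <- room[which.max(frac[room])]
        n_by_cat[i] <- n_by_cat[i] + 1L
        frac[i] <- frac[i] - 1
      }
      # weighted sampling by planted citation probability within category
      nodes <- unlist(lapply(CATEGORIES, function(g) {
        ng <- n_by_cat[[g]]
        if (ng == 0L) return(character(0))
        ids <- ids_by_cat[[g]]
        if (ng >= length(ids)) return(ids)
        sample(ids, ng, prob = p[ids])
      }), use.names = FALSE)
      inc <- comp_ids %in% nodes
      nodes <- comp_ids[inc]
      n <- length(nodes)

      l_target <- round(cs$link_rate * n *
                          exp(stats::rnorm(1, 0, cs$link_cv)))
      l_target <- max(1L, min(as.integer(l_target), n * (n - 1L)))
      src <- rep(seq_len(n), each = n)
      tgt <- rep(seq_len(n), times = n)
      ok <- src != tgt
      src <- src[ok]; tgt <- tgt[ok]
      w <- boost[inc][src] * boost[inc][tgt] *
        truth$salience[cbind(nodes[src], nodes[tgt])]
      pick <- sample.int(length(src), l_target, prob = w)
      e_src <- nodes[src[pick]]
      e_tgt <- nodes[tgt[pick]]
      sg <- truth$sign[cbind(e_src, e_tgt)]
      flip <- stats::runif(l_target) < config$sign_flip_prob
      sg[flip] <- -sg[flip]
      edges <- data.frame(source = e_src, target = e_tgt,
                          sign = as.integer(sg), stringsAsFactors = FALSE)
      edges <- edges[order(edges$source, edges$target), , drop = FALSE]
      maps[[r]] <- cognitive_map(resp_ids[r], nodes = nodes, edges = edges,
                                 respondent_group = group_of[r],
                                 level = "component")
    }
    cluster_names <- vapply(config$cluster_specs, `[[`, character(1),
                            "name")
    truth$cluster <- stats::setNames(cluster_names[cluster_idx], resp_ids)
    truth$group <- stats::setNames(group_of, resp_ids)
    list(collection = map_collection(maps, catalog = catalog),
         truth = truth)
  })
}

#' Recovery metrics against planted ground truth
#'
#' Test-harness summary of how well the analysis recovered the generator's
#' planted structure: zone confusion matrix and core-zone accuracy, cluster
#' adjusted Rand index, and mean absolute error between observed citation
#' frequencies and planted citation probabilities.
#'
#' @param truth Ground truth from [generate_collection()].
#' @param zone_table Optional `zone_table` from [representation_zones()].
#' @param cluster_labels Optional named labels (or `cluster_result`).
#' @param frequencies Optional named frequencies from
#'   [component_frequency()].
#' @return List with any of `zone_confusion` (planted x assigned),
#'   `core_accuracy`, `cluster_ari`, `frequency_mae`.
#' @export
recovery_report <- function(truth, zone_table = NULL, cluster_labels = NULL,
                            frequencies = NULL) {
  out <- list()
  if (!is.null(zone_table)) {
    planted <- truth$zone[zone_table$component]
    out$zone_confusion <- table(
      planted = factor(planted, levels = ZONES),
      assigned = factor(zone_table$zone, levels = ZONES))
    core <- names(truth$zone)[truth$zone == "core"]
    seen_core <- intersect(core, zone_table$component)
    out$core_accuracy <- if (length(seen_core)) {
      mean(zone_table$zone[match(seen_core, zone_table$component)] == "core")
    } else NA_real_
  }
  if (!is.null(cluster_labels)) {
    labels <- if (inherits(cluster_labels, "cluster_result")) {
      cluster_labels$labels
    } else cluster_labels
    ids <- intersect(names(labels), names(truth$cluster))
    out$cluster_ari <- adjusted_rand_index(truth$cluster[ids], labels[ids])
  }
  if (!is.null(frequencies)) {
    ids <- intersect(names(frequencies), names(truth$citation_prob))
    out$frequency_mae <-
      mean(abs(frequencies[ids] - truth$citation_prob[ids]))
  }
  out
}
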