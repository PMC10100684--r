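spec_neutral <- function(seed = 1, m = 0.2, n_taxa = 100, n_samples = 10,
                         reads = 2000) {
  community_sim_spec(n_taxa, n_samples, reads, "neutral", m = m, seed = seed)
}

test_that("simulation specs are validated", {
  expect_error(community_sim_spec(100, 10, 1000, "neutral"), "requires")
  expect_error(community_sim_spec(100, 10, 1000, "neutral", m = 1.2), "m")
  expect_error(community_sim_spec(100, 10, 1000, "neutral", m = 0), "m")
  expect_error(community_sim_spec(100, 10, 1000, "block_network",
                                  n_modules = 200), "n_modules")
  expect_error(community_sim_spec(100, 10, 1000, "niche",
                                  gradient_groups = NULL), "gradient_groups")
  expect_error(community_sim_spec(1, 10, 1000, "neutral", m = 0.5))
})

test_that("identical spec and seed give bit-identical output in every regime", {
  for (sim_fn in list(
    function(s) simulate_neutral(spec_neutral(seed = s)),
    function(s) simulate_niche_gradient(
      community_sim_spec(50, 9, 1000, "niche", seed = s)),
    function(s) simulate_dispersal_structured(
      community_sim_spec(50, 9, 1000, "dispersal", seed = s)),
    function(s) simulate_block_network(
      community_sim_spec(20, 12, 2000, "block_network", n_modules = 4,
                         seed = s)))) {
    a <- sim_fn(7)
    b <- sim_fn(7)
    c <- sim_fn(8)
    expect_identical(a$table$counts, b$table$counts)
    expect_false(identical(a$table$counts, c$table$counts))
  }
})

test_that("ground truth satisfies its invariants", {
  sim <- simulate_neutral(spec_neutral())
  expect_equal(sum(sim$ground_truth$metacommunity_abundances), 1,
               tolerance = 1e-9)
  expect_true(all(sim$ground_truth$metacommunity_abundances >= 0))

  blk <- simulate_block_network(
    community_sim_spec(20, 12, 2000, "block_network", n_modules = 4,
                       seed = 2))
  expect_true(all(blk$ground_truth$true_edges %in% blk$table$taxon_ids))
  expect_equal(nrow(blk$ground_truth$true_edges), 4 * choose(5, 2))
})

test_that("multinomial niche regime has exact library sizes", {
  sim <- simulate_niche_gradient(community_sim_spec(50, 9, 1234, "niche",
                                                    seed = 3))
  expect_true(all(colSums(sim$table$counts) == 1234))
  expect_identical(sim$metadata$region,
                   rep(c("estuary", "nearshore", "offshore"), each = 3))
})

test_that("migration rate controls the occupancy-abundance transition", {
  # model property: the occupancy curve's transition zone (freq between
  # 0.05 and 0.95) spans a wider abundance range at low N*m — dispersal
  # limitation blurs the detection threshold
  width <- function(m, N = 2000) {
    g <- 10^seq(-6, -0.3, length.out = 2000)
    fr <- ncm_predict(g, N, m, 1 / N)
    diff(range(g[fr > 0.05 & fr < 0.95]))
  }
  expect_gt(width(0.05), 2 * width(0.8))
  # and simulated tables sort by fitted m accordingly
  f_lo <- suppressWarnings(ncm_fit(simulate_neutral(
    spec_neutral(seed = 3, m = 0.05, n_taxa = 300, n_samples = 20))$table))
  f_hi <- suppressWarnings(ncm_fit(simulate_neutral(
    spec_neutral(seed = 3, m = 0.8, n_taxa = 300, n_samples = 20))$table))
  expect_lt(f_lo$m, f_hi$m)
})

test_that("near-full migration concentrates local abundance at p", {
  # Beta(Nmp, Nm(1-p)) has mean p and tiny variance when N m is large
  sim <- simulate_neutral(community_sim_spec(10, 20, 50000, "neutral",
                                             m = 1, seed = 5))
  rel <- relative_abundance(sim$table)
  p <- sim$ground_truth$metacommunity_abundances
  expect_true(all(abs(rowMeans(rel) - p) < 0.02))
  expect_lt(max(apply(rel, 1, stats::sd)), 0.02)
})

test_that("salinity-matched taxa are enriched in their group", {
  hits <- 0
  for (s in 1:20) {
    sim <- simulate_niche_gradient(community_sim_spec(80, 12, 2000, "niche",
                                                      seed = s))
    gt <- sim$ground_truth
    marine <- which(abs(gt$niche_optima - 30) < 2)
    if (!length(marine)) next
    rel <- relative_abundance(sim$table)
    offshore <- sim$metadata$region == "offshore"
    estuary <- sim$metadata$region == "estuary"
    if (mean(rel[marine, offshore]) > mean(rel[marine, estuary])) {
      hits <- hits + 1
    }
  }
  expect_gt(hits, 15)
})

test_that("flat niche response removes the group signal", {
  sim <- simulate_niche_gradient(community_sim_spec(50, 12, 2000, "niche",
                                                    niche_width = Inf,
                                                    seed = 4))
  # all taxa share one multinomial probability vector; occupancy cannot
  # depend on region, so PERMANOVA should not find structure
  p <- permanova(bray_curtis(sim$table, "none"), sim$metadata$region,
                 n_permutations = 199, seed = 1)$p_value
  expect_gt(p, 0.05)
})

test_that("dispersal occupancy matches the assigned probabilities", {
  sim <- simulate_dispersal_structured(
    community_sim_spec(120, 24, 2000, "dispersal", seed = 6))
  occ_obs <- rowSums(sim$table$counts > 0)
  pr <- sim$ground_truth$occupancy_probabilities
  # exact binomial 99.5% central bounds, per taxon
  lo <- qbinom(0.0025, 24, pr)
  hi <- qbinom(0.9975, 24, pr)
  expect_gt(mean(occ_obs >= lo & occ_obs <= hi), 0.95)
})

test_that("block modules are correlated within and not between", {
  sim <- simulate_block_network(
    community_sim_spec(20, 30, 10000, "block_network", n_modules = 4,
                       seed = 9))
  r <- suppressWarnings(stats::cor(t(sim$table$counts),
                                   method = "spearman"))
  mod <- sim$ground_truth$module_assignment
  same <- outer(mod, mod, "==") & upper.tri(r)
  diff <- !outer(mod, mod, "==") & upper.tri(r)
  expect_gt(min(r[same]), 0.8)
  expect_lt(max(abs(r[diff])), 0.8)
})

test_that("zero module loading yields no block correlation", {
  sim <- simulate_block_network(
    community_sim_spec(20, 30, 10000, "block_network", n_modules = 4,
                       module_loading = 0, seed = 10))
  net <- try(suppressWarnings(infer_network(sim$table)), silent = TRUE)
  n_edges <- if (inherits(net, "try-error")) 0L else igraph::ecount(net)
  expect_lte(n_edges, 1L)
})

test_that("neutral occupancy tracks the model band of its own parameters", {
  # abundance-decile mean occupancy against the 95% Wilson band at the
  # generating parameters; the curve's detection limit is an approximation
  # (a taxon exactly at d is detected with probability 1 - 1/e, not 1), so
  # the transition-zone decile can sit at the band edge — require 8/10
  # deciles inside in at least 90% of replicates
  ok <- vapply(1:10, function(s) {
    sim <- simulate_neutral(spec_neutral(seed = s, n_taxa = 200,
                                         n_samples = 30, reads = 5000))
    oa <- occupancy_abundance(sim$table)
    oa <- oa[oa$p > 0 & oa$p < 1, ]
    pred <- ncm_predict(oa$p, 5000, 0.2, 1 / 5000)
    band <- planknet:::wilson_interval(pred, 30, 0.95)
    dec <- cut(rank(oa$p, ties.method = "first"), 10, labels = FALSE)
    inside <- vapply(split(seq_len(nrow(oa)), dec), function(ix) {
      m <- mean(oa$freq[ix])
      m >= mean(band$lower[ix]) && m <= mean(band$upper[ix])
    }, logical(1))
    mean(inside)
  }, numeric(1))
  expect_gte(mean(ok >= 0.8), 0.9)
})
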