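test_that("the abundance filter keeps exactly the taxa above threshold", {
  # mean relative abundances straddling 0.01%
  m <- cnt_matrix(rbind(c(5000L, 5000L),
                        c(4989L, 4991L),
                        c(5L, 5L),        # 0.05% -> kept
                        c(1L, 0L),        # 0.005% -> dropped
                        c(5L, 4L)))       # 0.045% -> kept
  tab <- otu_table(m)
  expect_message(out <- filter_low_abundance(tab, 1e-4), "kept 4")
  expect_identical(out$taxon_ids, c("t01", "t02", "t03", "t05"))
  expect_error(suppressMessages(filter_low_abundance(tab, 0.9)), "every")
})

test_that("co-monotone taxa get an edge with r = 1; constant taxa get none", {
  set.seed(3)
  base <- sort(rpois(20, 40))
  m <- cnt_matrix(rbind(base, base * 2L, rep(7L, 20),
                        sample(base)), samples = sprintf("S%02d", 1:20))
  net <- infer_network(otu_table(m))
  expect_true(igraph::are_adjacent(net, "t01", "t02"))
  e <- igraph::E(net)[igraph::V(net)["t01"] %--% igraph::V(net)["t02"]]
  expect_equal(e$r, 1)
  expect_false("t03" %in% igraph::V(net)$name)  # constant: no edges
})

test_that("the edge set equals a brute-force cor.test oracle", {
  for (s in 1:4) {
    set.seed(s)
    lam <- exp(rnorm(8, 3, 1))
    m <- cnt_matrix(matrix(rpois(8 * 15, lam), 8, 15))
    m[, colSums(m) == 0] <- 1L
    tab <- otu_table(m)
    net <- suppressWarnings(infer_network(tab, r_min = 0.5, p_max = 0.05))
    oracle <- character(0)
    for (i in 1:7) for (j in (i + 1):8) {
      if (sd(m[i, ]) == 0 || sd(m[j, ]) == 0) next
      ct <- suppressWarnings(cor.test(m[i, ], m[j, ], method = "spearman",
                                      exact = FALSE))
      if (abs(ct$estimate) >= 0.5 && ct$p.value < 0.05) {
        oracle <- c(oracle, paste(rownames(m)[i], rownames(m)[j], sep = "|"))
      }
    }
    got <- apply(igraph::as_edgelist(net), 1, function(e)
      paste(sort(e), collapse = "|"))
    expect_setequal(got, oracle)
  }
})

test_that("every stored edge satisfies the stored thresholds", {
  sim <- simulate_block_network(
    community_sim_spec(30, 20, 5000, "block_network", n_modules = 3,
                       seed = 2))
  net <- infer_network(sim$table)
  expect_true(all(abs(igraph::E(net)$r) >= 0.8))
  expect_true(all(igraph::E(net)$p < 0.01))
  expect_false(any(igraph::which_loop(net)))
  expect_false(any(igraph::which_multiple(net)))
  deg <- igraph::degree(net)
  expect_true(all(deg >= 1))  # isolated nodes excluded
})

test_that("edges are invariant to monotone transforms and sample order", {
  sim <- simulate_block_network(
    community_sim_spec(20, 15, 3000, "block_network", n_modules = 2,
                       seed = 5))
  cnt <- sim$table$counts
  key <- function(net) sort(apply(igraph::as_edgelist(net), 1, function(e)
    paste(sort(e), collapse = "|")))
  n0 <- suppressWarnings(infer_network(otu_table(cnt)))
  n1 <- suppressWarnings(infer_network(otu_table(cnt[, sample(ncol(cnt))])))
  sq <- cnt; storage.mode(sq) <- "double"; sq <- sq^2
  storage.mode(sq) <- "integer"
  n2 <- suppressWarnings(infer_network(otu_table(sq)))
  expect_identical(key(n0), key(n1))
  expect_identical(key(n0), key(n2))
})

test_that("topology metrics match closed forms on canonical graphs", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- paste0("n", 1:4)
  top <- topology(k4, seed = 1)
  expect_equal(top$graph_density, 1)
  expect_equal(top$average_clustering_coefficient, 1)
  expect_equal(top$average_path_length, 1)
  expect_equal(top$diameter, 1)
  expect_equal(top$n_components, 1)
  expect_equal(top$average_degree, 2 * 6 / 4)

  p4 <- igraph::make_graph(~ a - b, b - c, c - d)
  tp <- topology(p4, seed = 1)
  expect_equal(tp$diameter, 3)
  expect_equal(tp$average_clustering_coefficient, 0)

  two_k5 <- igraph::disjoint_union(igraph::make_full_graph(5),
                                   igraph::make_full_graph(5))
  igraph::V(two_k5)$name <- paste0("n", 1:10)
  tk <- topology(two_k5, seed = 1)
  expect_equal(tk$n_components, 2)
  # two equal blocks with no between edges: Q = 0.5
  expect_gte(tk$modularity, 0.4)
  expect_equal(tk$modularity, 0.5, tolerance = 1e-9)
})

test_that("fragmentation follows log(CL)/log(N)", {
  con <- igraph::make_ring(6)
  igraph::V(con)$name <- paste0("n", 1:6)
  expect_equal(fragmentation(con), 0)

  iso <- igraph::make_empty_graph(7, directed = FALSE)
  igraph::V(iso)$name <- paste0("n", 1:7)
  expect_equal(fragmentation(iso), 1)

  two <- igraph::disjoint_union(igraph::make_full_graph(6),
                                igraph::make_full_graph(4))
  igraph::V(two)$name <- paste0("n", 1:10)
  expect_equal(fragmentation(two), log(2) / log(10))
  expect_equal(fragmentation(two), log2(2) / log2(10), tolerance = 1e-12)

  single <- igraph::make_empty_graph(1, directed = FALSE)
  expect_error(fragmentation(single), "undefined")
})

test_that("attack trajectories behave on hand-built graphs", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:5))
  tr <- attack(star, "betweenness", k = 1, seed = 1)
  expect_equal(tr$removed_node[2], "hub")
  expect_equal(tr$f[2], 1)           # 5 isolated leaves: log5/log5
  expect_equal(tr$f[1], 0)

  tr0 <- attack(star, "degree", k = 0, seed = 1)
  expect_equal(nrow(tr0), 1)
  expect_equal(tr0$f, 0)

  # barbell: two K5s joined through one bridge node
  g <- igraph::disjoint_union(igraph::make_full_graph(4),
                              igraph::make_full_graph(4))
  g <- igraph::add_vertices(g, 1)
  igraph::V(g)$name <- c(paste0("a", 1:4), paste0("b", 1:4), "bridge")
  g <- igraph::add_edges(g, c("bridge", "a1", "bridge", "b1"))
  tb <- attack(g, "betweenness", k = 1, seed = 1)
  expect_equal(tb$removed_node[2], "bridge")
  expect_equal(tb$f[2], log(2) / log(8))
  expect_error(attack(star, "degree", k = 6, seed = 1), "k")
})

test_that("betweenness agrees with an O(n^3) path-counting oracle", {
  p5 <- igraph::make_graph(~ v1 - v2, v2 - v3, v3 - v4, v4 - v5)
  expect_equal(unname(betweenness_oracle(p5)),
               unname(igraph::betweenness(p5)))
  set.seed(9)
  g <- igraph::sample_gnp(20, 0.2)
  igraph::V(g)$name <- sprintf("n%02d", 1:20)
  expect_equal(betweenness_oracle(g), igraph::betweenness(g),
               tolerance = 1e-9)
})

test_that("gatekeeper rankings surface hubs and bridges", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:5))
  igraph::V(star)$abundance <- c(0.01, 0.4, 0.2, 0.2, 0.1, 0.09)
  gk <- gatekeeper_table(star, top_k = 3)
  expect_equal(gk$rankings$by_betweenness[1], "hub")
  expect_equal(gk$rankings$by_degree[1], "hub")
  expect_equal(gk$rankings$by_abundance[1], "leaf1")

  p5 <- igraph::make_graph(~ m1 - m2, m2 - m3, m3 - m4, m4 - m5)
  igraph::V(p5)$abundance <- rep(0.2, 5)
  gk5 <- gatekeeper_table(p5, top_k = 1)
  expect_equal(gk5$rankings$by_betweenness[1], "m3")
})

test_that("domain subnetworks equal recomputation on the restricted table", {
  sim <- simulate_block_network(
    community_sim_spec(30, 25, 8000, "block_network", n_modules = 3,
                       seed = 7))
  tab <- sim$table
  dom <- rep(c("prokaryote", "microeukaryote"), length.out = 30)
  tab <- otu_table(tab$counts, domain = dom)
  meta <- suppressWarnings(infer_network(tab))
  sub <- domain_subnetwork(meta, "prokaryote")
  # same pipeline on the prokaryote-only table: identical edges, since
  # Spearman correlations of a pair do not depend on the other taxa
  prok <- subset_otu_table(tab, taxa = which(dom == "prokaryote"))
  ref <- suppressWarnings(infer_network(prok))
  key <- function(g) sort(apply(igraph::as_edgelist(g), 1, function(e)
    paste(sort(e), collapse = "|")))
  expect_identical(key(sub), key(ref))
})

test_that("network artifacts are written and loadable", {
  sim <- simulate_block_network(
    community_sim_spec(20, 20, 4000, "block_network", n_modules = 2,
                       seed = 8))
  net <- infer_network(sim$table)
  et <- withr::local_tempfile(fileext = ".tsv")
  gm <- withr::local_tempfile(fileext = ".graphml")
  tj <- withr::local_tempfile(fileext = ".json")
  top <- write_network(net, edge_tsv = et, graphml = gm, topology_json = tj,
                       seed = 1)
  el <- read.delim(et)
  expect_equal(nrow(el), igraph::ecount(net))
  expect_true(all(c("source", "target", "r", "p", "sign") %in% names(el)))
  back <- igraph::read_graph(gm, format = "graphml")
  expect_equal(igraph::ecount(back), igraph::ecount(net))
  js <- jsonlite::read_json(tj)
  expect_equal(js$n_edges, top$n_edges)
})
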