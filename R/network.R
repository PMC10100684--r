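#' Drop low-abundance taxa before network inference
#'
#' Removes OTUs whose mean relative abundance across the samples entering the
#' network falls below the threshold (default 0.01% = 1e-4), the usual guard
#' against spurious correlations among rare taxa.
#'
#' @param table an [otu_table].
#' @param min_mean_rel_abundance threshold on mean relative abundance.
#' @return The filtered [otu_table]; the numbers kept/dropped are reported
#'   via a message.
#' @export
filter_low_abundance <- function(table, min_mean_rel_abundance = 1e-4) {
  stopifnot(inherits(table, "otu_table"))
  keep <- rowMeans(relative_abundance(table)) >= min_mean_rel_abundance
  if (!any(keep)) stop("abundance filter removed every taxon")
  message(sprintf("abundance filter: kept %d, dropped %d taxa",
                  sum(keep), sum(!keep)))
  subset_otu_table(table, taxa = which(keep))
}

#' Infer a Spearman co-occurrence network
#'
#' Scores every taxon pair by Spearman's rank correlation across samples
#' (average ranks for ties) with a two-sided p-value from the t
#' approximation, and keeps an edge when `|r| >= r_min` and `p < p_max`
#' (after optional Benjamini-Hochberg correction). Taxa with constant
#' abundance have undefined correlations and get no edges; isolated taxa are
#' excluded from the graph. Node attributes carry mean relative abundance
#' and, when available, the domain flag.
#'
#' @param table an [otu_table] with >= 5 samples (a warning is issued below
#'   10, where Spearman p-values are unreliable).
#' @param r_min minimum absolute correlation (default 0.8).
#' @param p_max maximum p-value (default 0.01).
#' @param correction `"none"` (default; raw p-values) or `"BH"`.
#' @return An [igraph::igraph] undirected graph with edge attributes `r`,
#'   `p`, `sign` and node attributes `name`, `abundance`, `domain` (if
#'   present); graph attributes record the thresholds.
#' @export
infer_network <- function(table, r_min = 0.8, p_max = 0.01,
                          correction = c("none", "BH")) {
  stopifnot(inherits(table, "otu_table"))
  correction <- match.arg(correction)
  assert_scalar_in(r_min, "r_min", 0, 1, open_lo = TRUE)
  assert_scalar_in(p_max, "p_max", 0, 1, open_lo = TRUE, open_hi = TRUE)
  n <- ncol(table$counts)
  if (n < 5) stop("need at least 5 samples")
  if (n < 10) warning("fewer than 10 samples: Spearman p-values are unreliable")
  variable <- apply(table$counts, 1, function(x) length(unique(x)) > 1)
  if (sum(variable) < 2) stop("fewer than 2 taxa with variable abundance")
  cnt <- table$counts[variable, , drop = FALSE]
  r <- stats::cor(t(cnt), method = "spearman")
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1 - 1e-12] <- 0  # perfectly monotone pairs
  ut <- upper.tri(r)
  if (correction == "BH") p[ut] <- stats::p.adjust(p[ut], method = "BH")
  keep <- ut & abs(r) >= r_min & p < p_max
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(from = rownames(cnt)[idx[, 1]],
                      to = rownames(cnt)[idx[, 2]],
                      r = r[keep], p = p[keep],
                      sign = ifelse(r[keep] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  ab <- rowMeans(relative_abundance(table))
  igraph::V(g)$abundance <- as.numeric(ab[igraph::V(g)$name])
  if (!is.null(table$domain)) {
    igraph::V(g)$domain <-
      table$domain[match(igraph::V(g)$name, table$taxon_ids)]
  }
  g <- igraph::set_graph_attr(g, "r_min", r_min)
  g <- igraph::set_graph_attr(g, "p_max", p_max)
  g <- igraph::set_graph_attr(g, "correction", correction)
  g
}

#' Network topology report
#'
#' The standard descriptive metrics for microbial co-occurrence graphs:
#' node/edge counts, average degree (2E/N), graph density, number of
#' connected components, diameter of the largest component, average shortest
#' path length over connected node pairs, mean local clustering coefficient,
#' and modularity of a seeded multi-level (Louvain) community partition of
#' the unsigned graph.
#'
#' @param net an igraph graph (e.g. from [infer_network()]).
#' @param seed integer seed for the community detection.
#' @return A list of class `topology_report`.
#' @export
topology <- function(net, seed = 1L) {
  if (igraph::vcount(net) == 0) stop("empty graph")
  n <- igraph::vcount(net)
  e <- igraph::ecount(net)
  comp <- igraph::components(net)
  big <- igraph::induced_subgraph(
    net, which(comp$membership == which.max(comp$csize)))
  mod <- with_seed(derive_seed(seed, "topology_louvain"), function() {
    cl <- igraph::cluster_louvain(igraph::as_undirected(net))
    igraph::modularity(cl)
  })
  structure(list(
    n_nodes = n,
    n_edges = e,
    average_degree = 2 * e / n,
    graph_density = igraph::edge_density(net),
    n_components = comp$no,
    diameter = igraph::diameter(big, weights = NA),
    average_path_length = igraph::mean_distance(net, weights = NA,
                                                unconnected = TRUE),
    average_clustering_coefficient =
      igraph::transitivity(net, type = "localaverage", isolates = "zero"),
    modularity = mod,
    conventions = paste("diameter: largest component;",
                        "path length: connected pairs only")),
    class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("Network: %d nodes, %d edges (average degree %.3f)\n",
              x$n_nodes, x$n_edges, x$average_degree))
  cat(sprintf("  density %.4f | components %d | diameter %d | avg path %.3f\n",
              x$graph_density, x$n_components, x$diameter,
              x$average_path_length))
  cat(sprintf("  avg clustering %.3f | modularity %.3f\n",
              x$average_clustering_coefficient, x$modularity))
  invisible(x)
}

#' Network fragmentation
#'
#' f = log(CL) / log(N) with CL the number of connected components and N the
#' number of nodes; 0 for a connected graph, 1 when fully atomised, and
#' invariant to the logarithm base.
#'
#' @param net an igraph graph with >= 2 nodes.
#' @return Fragmentation in `[0, 1]`.
#' @export
fragmentation <- function(net) {
  n <- igraph::vcount(net)
  if (n <= 1) stop("fragmentation undefined for fewer than 2 nodes")
  log(igraph::components(net)$no) / log(n)
}

# rank node names under a removal strategy; ties broken lexicographically
rank_nodes <- function(net, strategy) {
  score <- switch(strategy,
    betweenness = igraph::betweenness(net, weights = NA),
    degree = igraph::degree(net),
    abundance = {
      ab <- igraph::V(net)$abundance
      if (is.null(ab)) stop("graph has no 'abundance' node attribute")
      stats::setNames(ab, igraph::V(net)$name)
    },
    stop("unknown strategy: ", strategy))
  nm <- igraph::V(net)$name
  nm[order(-score, nm)]
}

#' Targeted or random node-removal attack
#'
#' Removes `k` nodes consecutively under a strategy (highest betweenness
#' centrality, highest degree, most relative abundance, or random) and
#' records the fragmentation of the remaining induced subgraph after every
#' removal, with N in the fragmentation formula equal to the remaining node
#' count. By default nodes are ranked once on the intact network; with
#' `adaptive = TRUE` the ranking is recomputed after each removal. Ties are
#' broken by taxon id lexicographic order.
#'
#' @param net an igraph graph.
#' @param strategy `"betweenness"`, `"degree"`, `"abundance"` or `"random"`.
#' @param k number of removals, `0 <= k < n_nodes`.
#' @param adaptive re-rank after each removal (default `FALSE`).
#' @param seed integer seed (used by the random strategy).
#' @return A data.frame of class `attack_trajectory` with columns `step`
#'   (0..k; step 0 is the intact network), `removed_node` (`NA` at step 0),
#'   `n_remaining`, `components`, `f`.
#' @export
attack <- function(net, strategy = c("betweenness", "degree", "abundance",
                                     "random"),
                   k, adaptive = FALSE, seed = 1L) {
  strategy <- match.arg(strategy)
  n0 <- igraph::vcount(net)
  if (k >= n0) stop("'k' must be smaller than the number of nodes")
  order_full <- with_seed(derive_seed(seed, "attack"), function() {
    if (strategy == "random") sample(igraph::V(net)$name) else
      if (!adaptive) rank_nodes(net, strategy) else NULL
  })
  g <- net
  out <- data.frame(step = 0L, removed_node = NA_character_,
                    n_remaining = n0,
                    components = igraph::components(net)$no,
                    f = fragmentation(net), stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    victim <- if (!is.null(order_full)) order_full[i] else
      rank_nodes(g, strategy)[1]
    g <- igraph::delete_vertices(g, victim)
    nv <- igraph::vcount(g)
    out <- rbind(out, data.frame(
      step = i, removed_node = victim, n_remaining = nv,
      components = if (nv > 0) igraph::components(g)$no else 0L,
      f = if (nv > 1) fragmentation(g) else NA_real_,
      stringsAsFactors = FALSE))
  }
  attr(out, "strategy") <- strategy
  attr(out, "adaptive") <- adaptive
  class(out) <- c("attack_trajectory", "data.frame")
  out
}

#' Gatekeeper rankings
#'
#' Ranks nodes by betweenness centrality, degree and relative abundance
#' (top `top_k` each) and reports the overlap between the rankings — the
#' device used to show that high-betweenness "gatekeepers" also tend to have
#' high degree while rarely being the most abundant taxa.
#'
#' @param net an igraph graph with an `abundance` node attribute.
#' @param top_k ranking depth (default 20, capped at the node count).
#' @return A list with `rankings` (data.frame: `rank`, `by_betweenness`,
#'   `by_degree`, `by_abundance`), `node_attributes` (per-node table), and
#'   `overlap` (pairwise intersection sizes of the three top-k sets plus the
#'   Spearman correlation of betweenness with degree over all nodes).
#' @export
gatekeeper_table <- function(net, top_k = 20) {
  if (igraph::vcount(net) == 0) stop("empty graph")
  top_k <- min(top_k, igraph::vcount(net))
  bt <- rank_nodes(net, "betweenness")[seq_len(top_k)]
  dg <- rank_nodes(net, "degree")[seq_len(top_k)]
  ab <- rank_nodes(net, "abundance")[seq_len(top_k)]
  btw <- igraph::betweenness(net, weights = NA)
  deg <- igraph::degree(net)
  nodes <- data.frame(taxon_id = igraph::V(net)$name,
                      degree = as.numeric(deg),
                      betweenness = as.numeric(btw),
                      abundance = igraph::V(net)$abundance,
                      stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(igraph::V(net)$domain)) nodes$domain <- igraph::V(net)$domain
  list(rankings = data.frame(rank = seq_len(top_k), by_betweenness = bt,
                             by_degree = dg, by_abundance = ab,
                             stringsAsFactors = FALSE),
       node_attributes = nodes,
       overlap = list(
         betweenness_degree = length(intersect(bt, dg)),
         betweenness_abundance = length(intersect(bt, ab)),
         degree_abundance = length(intersect(dg, ab)),
         betweenness_degree_spearman =
           unname(stats::cor(btw, deg, method = "spearman"))))
}

#' Induced single-domain subnetwork
#'
#' Restricts a co-occurrence graph to nodes of one domain (prokaryote-only or
#' microeukaryote-only networks are induced subgraphs of the meta-network).
#'
#' @param net an igraph graph with a `domain` node attribute.
#' @param domain `"prokaryote"` or `"microeukaryote"`.
#' @return The induced igraph subgraph, with isolated nodes removed.
#' @export
domain_subnetwork <- function(net, domain) {
  dv <- igraph::V(net)$domain
  if (is.null(dv)) stop("graph has no 'domain' node attribute")
  g <- igraph::induced_subgraph(net, which(dv == domain))
  igraph::delete_vertices(g, which(igraph::degree(g) == 0))
}

#' Write network artifacts
#'
#' Edge list TSV (`source`, `target`, `r`, `p`, `sign`), GraphML with node
#' attributes, and a topology JSON.
#'
#' @param net an igraph graph from [infer_network()].
#' @param edge_tsv,graphml,topology_json output paths (`NULL` skips one).
#' @param seed seed passed to [topology()].
#' @return Invisibly, the [topology()] report.
#' @export
write_network <- function(net, edge_tsv = NULL, graphml = NULL,
                          topology_json = NULL, seed = 1L) {
  if (!is.null(edge_tsv)) {
    el <- igraph::as_data_frame(net, what = "edges")
    names(el)[1:2] <- c("source", "target")
    utils::write.table(el, edge_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(graphml)) {
    igraph::write_graph(net, graphml, format = "graphml")
  }
  top <- topology(net, seed = seed)
  if (!is.null(topology_json)) {
    jsonlite::write_json(unclass(top), topology_json, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(top)
}
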