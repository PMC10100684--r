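# Small fixtures built in code, shared across test files.

# counts matrix with named dims
cnt_matrix <- function(x, taxa = NULL, samples = NULL) {
  m <- as.matrix(x)
  storage.mode(m) <- "integer"
  rownames(m) <- taxa %||% sprintf("t%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("S%02d", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

toy_table <- function() {
  otu_table(cnt_matrix(rbind(c(5L, 3L, 0L),
                             c(3L, 3L, 2L),
                             c(1L, 0L, 4L),
                             c(1L, 2L, 1L))))
}

# igraph helpers
graph_from_pairs <- function(pairs, isolated = character(0)) {
  g <- igraph::graph_from_edgelist(as.matrix(pairs), directed = FALSE)
  if (length(isolated)) g <- igraph::add_vertices(g, length(isolated),
                                                  name = isolated)
  g
}

# all n! permutations of 1:n as rows (n small)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# O(n^3) betweenness oracle: BFS shortest-path counting (Brandes-free,
# unweighted, undirected), returns the same unnormalised convention as
# igraph::betweenness
betweenness_oracle <- function(g) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g)
  bc <- stats::setNames(numeric(n), igraph::V(g)$name)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t) next
    # BFS from s recording distances and path counts
    dist <- rep(Inf, n); cnt <- rep(0, n)
    dist[s] <- 0; cnt[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in as.integer(adj[[v]])) {
        if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
        if (dist[w] == dist[v] + 1) cnt[w] <- cnt[w] + cnt[v]
      }
      frontier <- unique(nxt)
    }
    if (is.infinite(dist[t]) || cnt[t] == 0) next
    # count s-t shortest paths through each interior vertex v:
    # paths via v = cnt_s(v) * cnt_v(t) when dist_s(v) + dist_v(t) = dist_s(t)
    distt <- rep(Inf, n); cntt <- rep(0, n)
    distt[t] <- 0; cntt[t] <- 1
    frontier <- t
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in as.integer(adj[[v]])) {
        if (is.infinite(distt[w])) { distt[w] <- distt[v] + 1; nxt <- c(nxt, w) }
        if (distt[w] == distt[v] + 1) cntt[w] <- cntt[w] + cntt[v]
      }
      frontier <- unique(nxt)
    }
    interior <- setdiff(which(dist + distt == dist[t]), c(s, t))
    for (v in interior) bc[v] <- bc[v] + cnt[v] * cntt[v] / cnt[t]
  }
  bc
}
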