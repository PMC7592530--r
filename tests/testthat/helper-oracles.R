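# Independent oracles and random-input generators shared across tests.
# These deliberately avoid the package's internal code paths: weights come
# from igraph shortest-path reachability (not the package's boolean matrix
# closure) and influence sums are evaluated directly on the unsplit induced
# subgraph, treating shared genes as members of both sides.

oracle_side_weights <- function(net, members) {
  verts <- intersect(members, igraph::V(net)$name)
  n <- length(verts)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  if (n == 1L) return(stats::setNames(0, verts))
  sub <- igraph::induced_subgraph(net, verts)
  d <- igraph::distances(sub, mode = "out")
  reach <- is.finite(d) & d > 0
  w <- rowSums(reach) / (n - 1)
  w[verts]
}

# Naive non-split evaluation of both directional influence scores.
oracle_influence <- function(net, a_members, b_members) {
  verts <- igraph::V(net)$name
  pa <- intersect(a_members, verts)
  pb <- intersect(b_members, verts)
  wa <- oracle_side_weights(net, pa)
  wb <- oracle_side_weights(net, pb)
  sub <- igraph::induced_subgraph(net, union(pa, pb))
  ed <- igraph::as_data_frame(sub, what = "edges")
  ab <- ed$from %in% pa & ed$to %in% pb
  ba <- ed$from %in% pb & ed$to %in% pa
  c(a_on_b = sum((1 - wa[ed$from[ab]]) * wb[ed$to[ab]]),
    b_on_a = sum((1 - wb[ed$from[ba]]) * wa[ed$to[ba]]))
}

# Random network plus a pair of (optionally overlapping) vertex subsets.
random_pair_case <- function(seed, n_vertices = 14, edge_prob = 0.25,
                             size_a = 6, size_b = 6, n_shared = 0) {
  net <- random_background(n_vertices, edge_prob, seed = seed)
  v <- igraph::V(net)$name
  set.seed(seed * 7 + 3)
  shared <- if (n_shared > 0) sample(v, min(n_shared, length(v))) else character()
  a <- union(shared, sample(v, min(size_a, length(v))))
  b <- union(shared, sample(v, min(size_b, length(v))))
  list(net = net, a = a, b = b)
}

# The canonical worked example: two 3-gene chains joined by one
# tail-to-head cross edge.
chain_fixture <- function() make_fixture("chain", sizes = c(3, 3))

chain_pair <- function() {
  fx <- chain_fixture()
  pair_graph(fx$network, fx$sets[[1]], fx$sets[[2]], min_present = 3)
}
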