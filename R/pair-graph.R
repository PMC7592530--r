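#' Extract the two-pathway subgraph for a pair of gene sets
#'
#' Induces the subgraph of the global network on the union of the two gene
#' sets and splits genes shared by both sets into side-specific
#' *pseudo-vertices* (one copy on side A, one on side B). Every original
#' edge expands to all side-consistent copies, each classified as
#' `intra_A`, `intra_B`, `cross_AB` (tail on side A, head on side B) or
#' `cross_BA`. The split leaves each side's internal topology identical to
#' the induced subgraph on that set alone, which is what makes cross-edge
#' permutation well defined for overlapping pathways.
#'
#' Genes in a set but absent from the network carry no topological position
#' and are dropped (with a message reporting how many).
#'
#' @param net an [interaction_network()].
#' @param a,b the two gene sets ([gene_set()] objects or character vectors
#'   of symbols).
#' @param min_present minimum number of each set's members that must be
#'   present in the network (default 6, i.e. "more than 5 genes").
#' @param permissive if `TRUE`, an undersized side is a warning rather than
#'   an error.
#' @return an object of class `pair_graph`: list with `set_a`/`set_b`
#'   (names), `a_genes`/`b_genes` (symbols present, in set order), `shared`
#'   (symbols in both), and `edges` (data.frame `from`, `to`, `from_side`,
#'   `to_side`, `type`).
#' @export
pair_graph <- function(net, a, b, min_present = 6L, permissive = FALSE) {
  a <- as_gene_set(a, "A"); b <- as_gene_set(b, "B")
  verts <- net_vertices(net)
  pa <- intersect(a$members, verts)
  pb <- intersect(b$members, verts)
  n_absent <- (length(a$members) - length(pa)) + (length(b$members) - length(pb))
  if (n_absent > 0L)
    message(sprintf("%d gene(s) of '%s'/'%s' absent from the network were dropped",
                    n_absent, a$name, b$name))
  if (length(pa) == 0L && length(pb) == 0L)
    stop_data("neither '%s' nor '%s' has members in the network", a$name, b$name)
  for (side in list(list(a$name, pa), list(b$name, pb))) {
    if (length(side[[2]]) < min_present) {
      msg <- sprintf("gene set '%s' has %d member(s) in the network (minimum %d)",
                     side[[1]], length(side[[2]]), min_present)
      if (permissive) warning(msg, call. = FALSE) else stop_data("%s", msg)
    }
  }

  # side-consistent expansion of each original induced edge: every copy of
  # the edge that is well defined on the split vertex set is kept, so an
  # edge between two shared genes yields all four copies (both intra and
  # both cross directions)
  ed <- net_edges(net)
  fa <- ed$from %in% pa; fb <- ed$from %in% pb
  ta <- ed$to %in% pa;   tb <- ed$to %in% pb
  sel <- list(intra_A = fa & ta, intra_B = fb & tb,
              cross_AB = fa & tb, cross_BA = fb & ta)
  counts <- vapply(sel, sum, integer(1))
  efrom <- c(ed$from[sel$intra_A], ed$from[sel$intra_B],
             ed$from[sel$cross_AB], ed$from[sel$cross_BA])
  eto <- c(ed$to[sel$intra_A], ed$to[sel$intra_B],
           ed$to[sel$cross_AB], ed$to[sel$cross_BA])
  # bare-bones data.frame construction: this runs once per scored pair
  ex <- structure(
    list(from = efrom, to = eto,
         from_side = rep(c("A", "B", "A", "B"), counts),
         to_side = rep(c("A", "B", "B", "A"), counts),
         type = rep(names(sel), counts)),
    class = "data.frame", row.names = .set_row_names(length(efrom)))
  # rows are grouped by type in the order of `sel`; keep the ranges so the
  # scoring hot path can slice plain vectors instead of the data.frame
  ends <- cumsum(counts)
  ranges <- lapply(seq_along(counts), function(i)
    if (counts[i] == 0L) integer() else seq(ends[i] - counts[i] + 1L, ends[i]))
  names(ranges) <- names(sel)

  structure(list(set_a = a$name, set_b = b$name,
                 a_genes = pa, b_genes = pb,
                 shared = intersect(pa, pb),
                 edges = ex,
                 edge_from = efrom, edge_to = eto, type_rows = ranges),
            class = "pair_graph")
}

#' @export
print.pair_graph <- function(x, ...) {
  tab <- table(factor(x$edges$type,
                      levels = c("intra_A", "intra_B", "cross_AB", "cross_BA")))
  cat(sprintf("<pair_graph> %s (%d genes) vs %s (%d genes), %d shared\n",
              x$set_a, length(x$a_genes), x$set_b, length(x$b_genes),
              length(x$shared)))
  cat(sprintf("  edges: %s\n",
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

side_genes <- function(pair, side) {
  if (side == "A") pair$a_genes else pair$b_genes
}

#' Convert a pair graph to an igraph
#'
#' Pseudo-vertices are rendered as side-qualified vertex names (`A|sym`,
#' `B|sym`) with vertex attributes `gene` and `side` and an edge attribute
#' `type`. Mainly for inspection and export.
#'
#' @param pair a [pair_graph()].
#' @return a directed igraph.
#' @export
pair_graph_igraph <- function(pair) {
  vn <- c(paste0("A|", pair$a_genes), paste0("B|", pair$b_genes))
  vt <- data.frame(name = vn,
                   gene = c(pair$a_genes, pair$b_genes),
                   side = rep(c("A", "B"),
                              c(length(pair$a_genes), length(pair$b_genes))),
                   stringsAsFactors = FALSE)
  ed <- pair$edges
  igraph::graph_from_data_frame(
    data.frame(from = paste0(ed$from_side, "|", ed$from),
               to = paste0(ed$to_side, "|", ed$to),
               type = ed$type, stringsAsFactors = FALSE),
    directed = TRUE, vertices = vt)
}

# Transitive closure by boolean matrix doubling; rows/cols named by gene.
# Self-reachability (cycles through oneself) is excluded by construction of
# the weights, not here.
reach_matrix <- function(genes, from, to) {
  n <- length(genes)
  adj <- matrix(FALSE, n, n, dimnames = list(genes, genes))
  if (length(from)) adj[cbind(from, to)] <- TRUE
  reach <- adj
  repeat {
    nxt <- reach | ((reach %*% reach) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

#' Within-pathway downstream-position weights
#'
#' The weight of a gene is the proportion of the *other* genes of its own
#' pathway that lie downstream of it: `w_i = n_d / (n - 1)`, where `n_d`
#' counts the distinct other genes reachable from gene i by directed paths
#' that stay inside the side's intra edges, and `n` is the number of the
#' side's genes present in the network. Heads of a pathway get weights near
#' 1, tails get 0; a gene is never counted as downstream of itself, even on
#' a cycle through it. A singleton side has weight 0 by convention.
#'
#' @param pair a [pair_graph()].
#' @param side `"A"` or `"B"`.
#' @return named numeric vector of weights in `[0, 1]`, one per side gene.
#' @export
downstream_weights <- function(pair, side = c("A", "B")) {
  side <- side[1]
  if (!side %in% c("A", "B")) stop_data("side must be 'A' or 'B'")
  genes <- side_genes(pair, side)
  n <- length(genes)
  if (n <= 1L) return(stats::setNames(rep(0, n), genes))
  rows <- pair$type_rows[[paste0("intra_", side)]]
  reach <- reach_matrix(genes, pair$edge_from[rows], pair$edge_to[rows])
  diag(reach) <- FALSE
  rowSums(reach) / (n - 1)
}

#' Direct-downstream indicator of one gene over the opposite pathway
#'
#' Returns the 0/1 vector, indexed by the opposite side's genes, marking
#' which of them the given gene points to via a cross edge. Only these
#' direct targets enter the influence score; indirect downstream genes are
#' accounted for through the position weights.
#'
#' @param pair a [pair_graph()].
#' @param gene gene symbol on `side`.
#' @param side the side (`"A"` or `"B"`) whose copy of `gene` is queried.
#' @return named integer vector of 0/1 over the opposite side's genes.
#' @export
direct_downstream <- function(pair, gene, side = c("A", "B")) {
  side <- match.arg(side)
  if (!gene %in% side_genes(pair, side))
    stop_data("gene '%s' is not a side-%s vertex of this pair graph", gene, side)
  other <- if (side == "A") "B" else "A"
  targets <- side_genes(pair, other)
  cross <- pair$edges[pair$edges$type == paste0("cross_", side, other) &
                        pair$edges$from == gene, , drop = FALSE]
  stats::setNames(as.integer(targets %in% cross$to), targets)
}

#' Directional influence scores of a gene-set pair
#'
#' The influence of pathway A on pathway B sums, over A's genes, the term
#' `(1 - w_i) * sum of w_v over B-genes v directly hit by gene i`, where the
#' `w` are the [downstream_weights()] of the respective sides. Tail genes of
#' A (small `w_i`) hitting head genes of B (large `w_v`) contribute most,
#' encoding the "tail acts on head" signature of a genuine upstream
#' relationship. Equivalently it is the sum of `(1 - w_tail) * w_head` over
#' the distinct `cross_AB` edges.
#'
#' @param pair a [pair_graph()].
#' @return named numeric vector `c(a_on_b = , b_on_a = )`, both `>= 0`.
#' @export
influence_scores <- function(pair) {
  wa <- downstream_weights(pair, "A")
  wb <- downstream_weights(pair, "B")
  score_dir <- function(w_tail, w_head, type) {
    rows <- pair$type_rows[[type]]
    if (length(rows) == 0L) return(0)
    sum((1 - w_tail[pair$edge_from[rows]]) * w_head[pair$edge_to[rows]])
  }
  c(a_on_b = score_dir(wa, wb, "cross_AB"),
    b_on_a = score_dir(wb, wa, "cross_BA"))
}

#' Raw topological impact score
#'
#' `raw = influence(A on B) - influence(B on A)`: positive when A is
#' upstream of B, negative for the reverse, 0 for pairs with no cross
#' edges. Exactly antisymmetric under swapping the two sets.
#'
#' @param pair a [pair_graph()].
#' @return a single real number.
#' @export
raw_topo_score <- function(pair) {
  s <- influence_scores(pair)
  unname(s["a_on_b"] - s["b_on_a"])
}
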