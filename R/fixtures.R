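#' Generate a synthetic two-pathway (or cascade) fixture
#'
#' Builds a small directed network containing pathways with known internal
#' topology and planted cross-pathway structure, so that scoring behaviour
#' can be checked against analytically known ground truth. Gene symbols are
#' namespaced per pathway (`P1.g01`, ...), so overlap between sets only
#' ever arises by explicit construction.
#'
#' Topologies:
#' \describe{
#'   \item{`chain`}{two linear pathways; `n_cross` edges run from the tail
#'     end of P1 to the head end of P2 (tail-to-head: the planted "P1
#'     upstream" signature). Ground-truth raw score is computed in closed
#'     form from the chain weights.}
#'   \item{`fan_out` / `fan_in`}{P1 is a hub-to-leaves (or leaves-to-hub)
#'     star, P2 a chain; cross edges from P1's zero-weight genes to P2's
#'     head.}
#'   \item{`cycle`}{both pathways are directed cycles; every gene has
#'     weight 1, so any cross edge contributes 0 and the raw score is
#'     exactly 0.}
#'   \item{`parallel_mirror`}{two equal chains with mirrored cross edges
#'     (P1 tail to P2 head and P2 tail to P1 head), cancelling exactly:
#'     planted direction "none", raw score 0.}
#'   \item{`planted_cascade`}{three chains wired P1 -> P2 -> P3 with
#'     `n_cross` tail-to-head edges per consecutive pair; ground truth is
#'     the two directed super-module edges.}
#' }
#'
#' @param topology one of `"chain"`, `"fan_out"`, `"fan_in"`, `"cycle"`,
#'   `"parallel_mirror"`, `"planted_cascade"`.
#' @param sizes vertex count per pathway (length 2, or 3 for the cascade).
#' @param n_cross number of planted cross edges (per consecutive pair for
#'   the cascade); must not exceed what the topology can host distinctly.
#' @param overlap number of genes shared between the two pathways
#'   (chain/cycle only): the last `overlap` genes of P1 also open P2.
#' @param background optional list `list(n_vertices =, edge_prob =)` adding
#'   a random background network ([random_background()]) on separate
#'   namespaced genes.
#' @param seed integer seed controlling the background (the planted part is
#'   fully deterministic).
#' @return list with `network` ([interaction_network()]), `sets`
#'   (`gene_set_list`), and `truth`: list with `direction` (`"P1"`,
#'   `"none"`, or `"cascade"`), `raw_score` (exact, or `NA` when overlap
#'   makes the closed form inapplicable), and for cascades
#'   `super_module_edges` (2-column matrix of planted directed edges).
#' @export
make_fixture <- function(topology = c("chain", "fan_out", "fan_in", "cycle",
                                      "parallel_mirror", "planted_cascade"),
                         sizes = c(6, 6), n_cross = 1L, overlap = 0L,
                         background = NULL, seed = 1L) {
  topology <- match.arg(topology)
  n_path <- if (topology == "planted_cascade") 3L else 2L
  if (length(sizes) == 1L) sizes <- rep(sizes, n_path)
  if (length(sizes) != n_path)
    stop_data("topology '%s' needs %d pathway sizes, got %d",
              topology, n_path, length(sizes))
  if (any(sizes < 1L)) stop_data("pathway sizes must be >= 1")
  if (n_cross < 0L) stop_data("n_cross must be >= 0")
  if (overlap > 0L && !topology %in% c("chain", "cycle"))
    stop_data("overlap is only supported for chain and cycle topologies")
  if (overlap > min(sizes))
    stop_data("overlap (%d) exceeds the smallest pathway (%d)",
              overlap, min(sizes))

  genes <- lapply(seq_len(n_path), function(p)
    sprintf("P%d.g%02d", p, seq_len(sizes[p])))

  # overlap: P2's first `overlap` genes are P1's last `overlap` genes
  if (overlap > 0L) {
    shared <- utils::tail(genes[[1]], overlap)
    genes[[2]][seq_len(overlap)] <- shared
  }

  chain_edges <- function(g) {
    if (length(g) < 2L) return(NULL)
    data.frame(from = g[-length(g)], to = g[-1], stringsAsFactors = FALSE)
  }
  cycle_edges <- function(g) {
    if (length(g) < 2L) return(NULL)
    data.frame(from = g, to = c(g[-1], g[1]), stringsAsFactors = FALSE)
  }
  star_out <- function(g) data.frame(from = g[1], to = g[-1],
                                     stringsAsFactors = FALSE)
  star_in <- function(g) data.frame(from = g[-1], to = g[1],
                                    stringsAsFactors = FALSE)

  # chain weights: w(g_i) = (n - i) / (n - 1)
  chain_w <- function(n) if (n == 1L) 0 else (n - seq_len(n)) / (n - 1)

  # tail-to-head cross edges from pathway src to pathway dst:
  # edge k runs src[last - (k-1)] -> dst[k]; distinct pairs by construction
  plant_cross <- function(src, dst, k) {
    if (k == 0L) return(NULL)
    if (k > min(length(src), length(dst)))
      stop_data("n_cross = %d exceeds what pathways of sizes %d/%d can host",
                k, length(src), length(dst))
    data.frame(from = src[length(src) - seq_len(k) + 1L],
               to = dst[seq_len(k)], stringsAsFactors = FALSE)
  }
  # closed-form raw score of plant_cross on two chains
  cross_truth <- function(n1, n2, k) {
    w1 <- chain_w(n1); w2 <- chain_w(n2)
    sum((1 - w1[n1 - seq_len(k) + 1L]) * w2[seq_len(k)])
  }

  edges <- list(); truth <- list(direction = "P1", raw_score = NA_real_)
  if (topology %in% c("chain", "cycle")) {
    intra_fun <- if (topology == "chain") chain_edges else cycle_edges
    edges <- list(intra_fun(genes[[1]]), intra_fun(genes[[2]]),
                  plant_cross(genes[[1]], genes[[2]], n_cross))
    truth$raw_score <- if (overlap > 0L) NA_real_
      else if (topology == "cycle") 0
      else cross_truth(sizes[1], sizes[2], n_cross)
    if (topology == "cycle") truth$direction <- "none"
  } else if (topology %in% c("fan_out", "fan_in")) {
    star_fun <- if (topology == "fan_out") star_out else star_in
    # cross from P1 genes with weight 0 (leaves of fan_out, the hub of
    # fan_in) to the head of P2
    src <- if (topology == "fan_out") genes[[1]][-1] else genes[[1]][1]
    if (n_cross > min(length(src), sizes[2]))
      stop_data("n_cross too large for this fan fixture")
    fan_cross <- if (n_cross == 0L) NULL else
      data.frame(from = src[seq_len(n_cross)],
                 to = genes[[2]][seq_len(n_cross)],
                 stringsAsFactors = FALSE)
    edges <- list(star_fun(genes[[1]]), chain_edges(genes[[2]]), fan_cross)
    w2 <- chain_w(sizes[2])
    truth$raw_score <- if (n_cross == 0L) 0 else sum(w2[seq_len(n_cross)])
  } else if (topology == "parallel_mirror") {
    if (sizes[1] != sizes[2])
      stop_data("parallel_mirror needs equal pathway sizes")
    edges <- list(chain_edges(genes[[1]]), chain_edges(genes[[2]]),
                  plant_cross(genes[[1]], genes[[2]], n_cross),
                  plant_cross(genes[[2]], genes[[1]], n_cross))
    truth <- list(direction = "none", raw_score = 0)
  } else { # planted_cascade
    edges <- list(chain_edges(genes[[1]]), chain_edges(genes[[2]]),
                  chain_edges(genes[[3]]),
                  plant_cross(genes[[1]], genes[[2]], n_cross),
                  plant_cross(genes[[2]], genes[[3]], n_cross))
    truth <- list(direction = "cascade", raw_score = NA_real_,
                  super_module_edges = cbind(from = c("P1", "P2"),
                                             to = c("P2", "P3")))
  }

  edge_df <- do.call(rbind, Filter(Negate(is.null), edges))
  if (is.null(edge_df) || nrow(edge_df) == 0L)
    stop_data("fixture spec produced no edges")
  prov <- sprintf("fixture: %s sizes=%s n_cross=%d overlap=%d seed=%d",
                  topology, paste(sizes, collapse = ","), n_cross, overlap, seed)
  if (!is.null(background)) {
    bg <- random_background(background$n_vertices, background$edge_prob,
                            seed = seed)
    edge_df <- rbind(edge_df, igraph::as_data_frame(bg, what = "edges")[, 1:2])
  }
  net <- interaction_network(edge_df, provenance = prov)

  sets <- as_gene_sets(lapply(seq_len(n_path), function(p)
    gene_set(sprintf("P%d", p), genes[[p]], source = topology)))
  list(network = net, sets = sets, truth = truth)
}

#' Random directed background network
#'
#' Directed Erdos-Renyi graph on namespaced background genes (`BG.g01`,
#' ...), with self-loops excluded and isolated vertices removed;
#' deterministic for a given seed. Used to embed planted fixtures in a
#' larger network and to check that scores depend only on the induced
#' pair subgraph.
#'
#' @param n_vertices number of background genes.
#' @param edge_prob edge probability in `(0, 1]`; 0 would leave every
#'   vertex isolated and is rejected.
#' @param seed integer seed.
#' @return an `interaction_network`.
#' @export
random_background <- function(n_vertices, edge_prob, seed = 1L) {
  if (edge_prob <= 0 || edge_prob > 1)
    stop_data("edge_prob must be in (0, 1]: 0 leaves all vertices isolated")
  if (n_vertices < 2L) stop_data("need at least 2 background vertices")
  set.seed(seed)
  g <- igraph::sample_gnp(n_vertices, edge_prob, directed = TRUE,
                          loops = FALSE)
  igraph::V(g)$name <- sprintf("BG.g%02d", seq_len(n_vertices))
  interaction_network(igraph::as_data_frame(g, what = "edges")[, 1:2],
                      provenance = sprintf("random background: n=%d p=%g seed=%d",
                                           n_vertices, edge_prob, seed))
}
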