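#' Build a global gene-interaction network from an edge table
#'
#' The interaction network is the universe in which all pairwise scores are
#' computed: a directed [igraph][igraph::igraph-package] graph whose vertices
#' are gene symbols and whose edge `u -> v` means "u acts directly on v".
#' Construction enforces the container invariants: self-loops are removed,
#' duplicate edges are collapsed, and isolated vertices (which can only arise
#' from an explicit vertex list) are dropped. Counts of everything removed
#' are appended to the `provenance` graph attribute.
#'
#' @param edges data.frame whose first two columns are source and target
#'   gene symbols. Extra columns are ignored.
#' @param vertices optional character vector of additional vertex symbols
#'   (vertices without any surviving edge are removed again).
#' @param provenance character vector describing where the edges came from.
#' @param normalize_case if `TRUE`, symbols are uppercased before merging.
#'   Off by default: symbol comparison is case-sensitive exact match, since
#'   e.g. mouse symbols are conventionally mixed-case.
#' @return a directed `igraph` object, additionally classed
#'   `interaction_network`, with a `provenance` graph attribute.
#' @seealso [read_edge_list()], [read_kgml()], [merge_networks()]
#' @export
interaction_network <- function(edges, vertices = NULL,
                                provenance = character(),
                                normalize_case = FALSE) {
  if (!is.data.frame(edges) || ncol(edges) < 2L)
    stop_data("edge input must be a data.frame with at least 2 columns")
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  vertices <- as.character(vertices %||% character())
  if (normalize_case) {
    from <- toupper(from); to <- toupper(to); vertices <- toupper(vertices)
  }
  if (any(!nzchar(from)) || any(!nzchar(to)))
    stop_data("edge table contains empty gene symbols")

  keep <- from != to
  n_loops <- sum(!keep)
  ed <- unique(data.frame(from = from[keep], to = to[keep],
                          stringsAsFactors = FALSE))
  n_dup <- sum(keep) - nrow(ed)
  verts <- union(unique(c(ed$from, ed$to)), unique(vertices))
  if (length(verts) == 0L)
    stop_data("network is empty after removing self-loops")
  g <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                     vertices = data.frame(name = verts))
  iso <- which(igraph::degree(g, mode = "all") == 0)
  n_iso <- length(iso)
  if (n_iso > 0L) g <- igraph::delete_vertices(g, iso)
  if (igraph::vcount(g) == 0L)
    stop_data("network is empty after removing isolated vertices")

  prov <- c(provenance,
            sprintf("cleanup: removed %d self-loop(s), %d duplicate edge(s), %d isolated vertex(es)",
                    n_loops, n_dup, n_iso))
  g <- igraph::set_graph_attr(g, "provenance", prov)
  # cache the edge table and vertex names: pair extraction is called once
  # per gene-set pair and re-deriving these from the igraph dominates the
  # cost of all-pairs scans
  g <- igraph::set_graph_attr(g, "edge_cache",
                              igraph::as_data_frame(g, what = "edges")[, 1:2])
  g <- igraph::set_graph_attr(g, "vertex_cache", igraph::V(g)$name)
  class(g) <- unique(c("interaction_network", class(g)))
  g
}

# Cached accessors; fall back to igraph when the graph was modified after
# construction (cache sizes no longer match) or never carried a cache.
net_edges <- function(net) {
  ca <- igraph::graph_attr(net, "edge_cache")
  if (!is.null(ca) && nrow(ca) == igraph::ecount(net)) return(ca)
  igraph::as_data_frame(net, what = "edges")[, 1:2]
}

net_vertices <- function(net) {
  ca <- igraph::graph_attr(net, "vertex_cache")
  if (!is.null(ca) && length(ca) == igraph::vcount(net)) return(ca)
  igraph::V(net)$name
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d genes, %d directed interactions\n",
              igraph::vcount(x), igraph::ecount(x)))
  prov <- igraph::graph_attr(x, "provenance")
  if (length(prov)) cat(paste0("  ", prov, collapse = "\n"), "\n")
  invisible(x)
}

#' Network provenance record
#'
#' @param net an `interaction_network`.
#' @return character vector of source files and cleanup steps applied.
#' @export
network_provenance <- function(net) {
  igraph::graph_attr(net, "provenance") %||% character()
}

#' Read a directed edge list into an interaction network
#'
#' Reads a TSV/CSV file whose first column is the source gene symbol and
#' second column the target. A line with a single field declares a bare
#' vertex (which, having no edges, is subsequently removed as isolated).
#' The usual cleanup ([interaction_network()]) is applied.
#'
#' @param path path to the edge-list file.
#' @param header `"auto"` (default) sniffs a header row by looking for
#'   common column names (from/to/source/target/...), `"yes"`/`"no"` force.
#' @param sep field separator; `NULL` (default) sniffs tab vs comma from the
#'   first line.
#' @param normalize_case see [interaction_network()].
#' @return an `interaction_network`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB", "B\tC", "C\tC"), f)
#' net <- read_edge_list(f)   # the self-loop C->C is dropped
#' @export
read_edge_list <- function(path, header = c("auto", "yes", "no"), sep = NULL,
                           normalize_case = FALSE) {
  header <- match.arg(header)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !any(nzchar(trimws(lines))))
    stop_data("edge list '%s' is empty", path)
  if (is.null(sep)) {
    first <- lines[nzchar(trimws(lines))][1]
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  fields <- lapply(fields, function(f) trimws(f))
  # strsplit drops trailing empty fields; count separators on the raw line
  # so "A<TAB>" is flagged as an edge row with a missing target
  n_raw <- (nchar(lines) - nchar(gsub(sep, "", lines, fixed = TRUE))) /
    nchar(sep) + 1L

  start <- 1L
  if (header == "yes") {
    start <- 2L
  } else if (header == "auto" && length(fields[[1]]) >= 2L) {
    hdr_names <- c("from", "to", "source", "target", "src", "dst",
                   "gene1", "gene2", "regulator", "regulated")
    if (any(tolower(fields[[1]][1:2]) %in% hdr_names)) start <- 2L
  }
  if (start > length(fields)) stop_data("edge list '%s' has a header but no data rows", path)

  edges_from <- character(); edges_to <- character(); verts <- character()
  for (i in seq(start, length(fields))) {
    f <- fields[[i]]
    f <- f[nzchar(f)]
    if (length(fields[[i]]) == 0L || all(!nzchar(fields[[i]])))
      next  # blank line
    if (n_raw[i] >= 2L && length(f) < 2L)
      stop_data("edge list '%s', line %d: empty gene symbol", path, i)
    if (length(f) == 1L) {
      verts <- c(verts, f)
    } else {
      edges_from <- c(edges_from, f[1])
      edges_to <- c(edges_to, f[2])
    }
  }
  if (length(edges_from) == 0L && length(verts) == 0L)
    stop_data("edge list '%s' contains no usable rows", path)
  if (length(edges_from) == 0L)
    stop_data("edge list '%s' contains no edges (vertex-only rows)", path)
  interaction_network(data.frame(from = edges_from, to = edges_to,
                                 stringsAsFactors = FALSE),
                      vertices = verts,
                      provenance = sprintf("edge list: %s (%d data row(s))",
                                           path, length(edges_from) + length(verts)),
                      normalize_case = normalize_case)
}

#' Merge several interaction networks
#'
#' Union of vertex and edge sets, followed by the standard cleanup. Merging
#' is order-independent: permuting the inputs yields identical vertex and
#' edge sets.
#'
#' @param ... `interaction_network` objects (or a single list of them).
#' @return an `interaction_network`.
#' @export
merge_networks <- function(...) {
  nets <- list(...)
  if (length(nets) == 1L && is.list(nets[[1]]) && !igraph::is_igraph(nets[[1]]))
    nets <- nets[[1]]
  if (length(nets) == 0L) stop_data("no networks to merge")
  eds <- lapply(nets, function(n) igraph::as_data_frame(n, what = "edges")[, 1:2])
  prov <- unlist(lapply(nets, network_provenance))
  interaction_network(do.call(rbind, eds),
                      provenance = c(prov, sprintf("merged %d network(s)", length(nets))))
}
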