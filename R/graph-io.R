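#' Write a graph to TSV, GraphML or DOT
#'
#' Serializes an [interaction_network()], a [super_module()] graph, or any
#' directed igraph. TSV output is a tab-separated edge table
#' (`from`, `to`, `weight`, plus `p_value` when present); GraphML and DOT are
#' produced by igraph and retain vertex and edge attributes. TSV and GraphML
#' can be read back with [read_graph_file()]; DOT is write-only (intended
#' for Graphviz rendering).
#'
#' @param graph an igraph, `interaction_network`, or `super_module`.
#' @param path output file path.
#' @param format one of `"tsv"`, `"graphml"`, `"dot"`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(graph, path, format = c("tsv", "graphml", "dot")) {
  format <- match.arg(format)
  if (inherits(graph, "super_module")) graph <- graph$graph
  if (!igraph::is_igraph(graph)) stop_data("not a graph object")
  if (igraph::vcount(graph) == 0L) stop_data("refusing to write an empty graph")
  if (format == "tsv") {
    ed <- igraph::as_data_frame(graph, what = "edges")
    if (is.null(ed$weight)) ed$weight <- rep(1, nrow(ed))
    cols <- c("from", "to", "weight", intersect("p_value", names(ed)))
    utils::write.table(ed[, cols, drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    # strip the S3 veneer: igraph's C writers want a plain igraph
    class(graph) <- "igraph"
    igraph::write_graph(graph, path, format = format)
  }
  invisible(path)
}

#' Read a graph written by [write_graph_file()]
#'
#' @param path input file path.
#' @param format `"tsv"` or `"graphml"` (DOT is not readable).
#' @return a directed igraph with whatever attributes the file carries; no
#'   cleanup is applied, so round-tripping reproduces the graph exactly.
#' @export
read_graph_file <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml")
    return(igraph::read_graph(path, format = "graphml"))
  ed <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(ed) < 2L) stop_data("graph TSV '%s' needs at least 2 columns", path)
  igraph::graph_from_data_frame(ed, directed = TRUE)
}
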