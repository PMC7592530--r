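#' All-pairs score matrix over a collection of gene sets
#'
#' Scores every unordered pair of gene sets once ([topo_score()]) and
#' arranges the results row-over-column: entry `[i, j]` is the score of set
#' i over set j, so a positive entry means the row set is upstream of the
#' column set. The mirror entry is filled by antisymmetry and the p-value
#' matrix is symmetric. Per-pair permutation seeds are derived from the
#' master seed and the sorted pair of set names ([derive_seed()]), making
#' the matrix independent of input order and trivially parallelizable.
#'
#' @param net an [interaction_network()].
#' @param sets a `gene_set_list` (e.g. from [read_gmt()]) or named list of
#'   symbol vectors; at least 2 usable sets.
#' @param n_perm permutations per pair.
#' @param seed master seed.
#' @param min_present minimum members present per set (see [pair_graph()]).
#' @param on_undersized `"error"` (default) or `"drop"` undersized sets
#'   with a warning.
#' @param exhaustive_if_small see [null_distribution()].
#' @return an object of class `topo_matrix`: list with `set_names`,
#'   `scores` (normalized, antisymmetric), `raw_scores`, `pvalues`
#'   (symmetric, diagonal 1), `n_perm`, `seed`, `dropped`, `provenance`.
#' @export
topo_matrix <- function(net, sets, n_perm = 1000L, seed = 1L,
                        min_present = 6L,
                        on_undersized = c("error", "drop"),
                        exhaustive_if_small = TRUE) {
  on_undersized <- match.arg(on_undersized)
  sets <- as_gene_sets(sets)
  verts <- igraph::V(net)$name
  n_present <- vapply(sets, function(s) length(intersect(s$members, verts)),
                      integer(1))
  bad <- names(sets)[n_present < min_present]
  if (length(bad) > 0L) {
    if (on_undersized == "error")
      stop_data("gene set(s) below the size threshold in the network: %s",
                paste(bad, collapse = ", "))
    warning(sprintf("dropping undersized gene set(s): %s",
                    paste(bad, collapse = ", ")), call. = FALSE)
    sets <- sets[setdiff(names(sets), bad)]
  }
  if (length(sets) < 2L) stop_data("need at least 2 usable gene sets")

  nm <- names(sets)
  n <- length(nm)
  scores <- matrix(0, n, n, dimnames = list(nm, nm))
  raw <- matrix(0, n, n, dimnames = list(nm, nm))
  pvals <- matrix(1, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      lohi <- order(c(nm[i], nm[j]))          # canonical orientation
      ii <- c(i, j)[lohi[1]]; jj <- c(i, j)[lohi[2]]
      ps <- derive_seed(seed, nm[ii], nm[jj])
      res <- topo_score(net, sets[[ii]], sets[[jj]], n_perm = n_perm,
                        seed = ps, min_present = min_present,
                        exhaustive_if_small = exhaustive_if_small)
      scores[ii, jj] <- res$norm_score; scores[jj, ii] <- -res$norm_score
      raw[ii, jj] <- res$raw_score;     raw[jj, ii] <- -res$raw_score
      pvals[ii, jj] <- pvals[jj, ii] <- res$p_value
    }
  }
  structure(list(set_names = nm, scores = scores, raw_scores = raw,
                 pvalues = pvals, n_perm = as.integer(n_perm),
                 seed = seed, dropped = bad,
                 provenance = network_provenance(net)),
            class = "topo_matrix")
}

#' @export
print.topo_matrix <- function(x, ...) {
  cat(sprintf("<topo_matrix> %d gene sets, n_perm = %d, seed = %s\n",
              length(x$set_names), x$n_perm, format(x$seed)))
  cat("normalized scores (row over column):\n")
  print(round(x$scores, 4))
  invisible(x)
}

#' Write a score matrix to TSV files
#'
#' @param x a [topo_matrix()].
#' @param scores_path,pvalues_path output paths for the score and p-value
#'   matrices (TSV with set names as row/column headers).
#' @param which `"normalized"` (default) or `"raw"` scores.
#' @return invisibly, the two paths.
#' @export
write_topo_matrix <- function(x, scores_path, pvalues_path,
                              which = c("normalized", "raw")) {
  which <- match.arg(which)
  m <- if (which == "normalized") x$scores else x$raw_scores
  utils::write.table(m, scores_path, sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(x$pvalues, pvalues_path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(c(scores_path, pvalues_path))
}

#' Read a score matrix back from TSV files
#'
#' @param scores_path,pvalues_path files written by [write_topo_matrix()].
#' @return a `topo_matrix` (raw scores unavailable, `n_perm`/`seed` NA).
#' @export
read_topo_matrix <- function(scores_path, pvalues_path) {
  m <- as.matrix(utils::read.delim(scores_path, row.names = 1,
                                   check.names = FALSE))
  p <- as.matrix(utils::read.delim(pvalues_path, row.names = 1,
                                   check.names = FALSE))
  if (!identical(dimnames(m), dimnames(p)))
    stop_data("score and p-value matrices have different set names")
  structure(list(set_names = rownames(m), scores = m, raw_scores = NULL,
                 pvalues = p, n_perm = NA_integer_, seed = NA,
                 dropped = character(), provenance = character()),
            class = "topo_matrix")
}

#' Jaccard similarity matrix of gene sets
#'
#' Intersection-over-union of the member sets; the classical similarity
#' contrast to topological scoring (shared genes vs directed influence).
#'
#' @param sets a `gene_set_list` or named list of symbol vectors (>= 2).
#' @return symmetric numeric matrix with unit diagonal.
#' @export
jaccard_matrix <- function(sets) {
  sets <- as_gene_sets(sets)
  if (length(sets) < 2L) stop_data("need at least 2 gene sets")
  nm <- names(sets)
  n <- length(nm)
  m <- matrix(1, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      a <- sets[[i]]$members; b <- sets[[j]]$members
      m[i, j] <- m[j, i] <-
        length(intersect(a, b)) / length(union(a, b))
    }
  }
  m
}

#' Assemble significant positive scores into a super-module graph
#'
#' Keeps every directed edge `i -> j` whose score meets the threshold
#' (`score >= score_min`) at significance (`p <= p_max`); negative and
#' sub-threshold scores are excluded. The surviving edges form a directed
#' weighted graph whose vertices are gene-set names; sets with no
#' surviving edge are dropped from the graph and listed in the `left_out`
#' report (no significant upstream/downstream relationship). Weakly
#' connected components are reported as separate super-modules.
#'
#' @param x a [topo_matrix()].
#' @param score_min minimum score for an edge (default 1).
#' @param p_max maximum p-value (default 0.05).
#' @param annotations optional named vector of vertex labels (e.g.
#'   up/down-regulation calls from an upstream differential analysis);
#'   pass-through metadata, never computed here.
#' @return an object of class `super_module`: list with `graph` (igraph
#'   with `weight` and `p_value` edge attributes), `components` (list of
#'   name vectors), `left_out`, `score_min`, `p_max`.
#' @export
assemble_super_module <- function(x, score_min = 1, p_max = 0.05,
                                  annotations = NULL) {
  if (!inherits(x, "topo_matrix")) stop_data("x must be a topo_matrix")
  m <- x$scores; p <- x$pvalues
  keep <- which(m >= score_min & p <= p_max &
                  row(m) != col(m), arr.ind = TRUE)
  nm <- x$set_names
  ed <- data.frame(from = nm[keep[, 1]], to = nm[keep[, 2]],
                   weight = m[keep], p_value = p[keep],
                   stringsAsFactors = FALSE)
  ed <- ed[order(ed$from, ed$to), , drop = FALSE]
  used <- union(ed$from, ed$to)
  g <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                     vertices = data.frame(name = used))
  if (!is.null(annotations) && length(used) > 0L) {
    lab <- unname(annotations[used])
    g <- igraph::set_vertex_attr(g, "annotation",
                                 value = ifelse(is.na(lab), "", lab))
  }
  comps <- if (length(used) > 0L) {
    membership <- igraph::components(g, mode = "weak")$membership
    unname(split(names(membership), membership))
  } else list()
  structure(list(graph = g, components = comps,
                 left_out = setdiff(nm, used),
                 score_min = score_min, p_max = p_max),
            class = "super_module")
}

#' @export
print.super_module <- function(x, ...) {
  cat(sprintf("<super_module> %d pathway(s), %d directed edge(s), %d component(s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              length(x$components)))
  cat(sprintf("  filters: score >= %g, p <= %g\n", x$score_min, x$p_max))
  if (length(x$left_out))
    cat(sprintf("  left out: %s\n", paste(x$left_out, collapse = ", ")))
  invisible(x)
}

#' Annotated gene-level interaction subgraph of a pathway pair
#'
#' The induced (unsplit) subgraph on the union of two gene sets, with each
#' vertex labeled `A-only`, `B-only` or `shared` for visualization. With
#' `interacting_only = TRUE` the graph is restricted to genes on at least
#' one cross-pathway edge plus their within-pathway neighbors, mirroring
#' how published pair figures show only the interacting region.
#'
#' @inheritParams pair_graph
#' @param interacting_only restrict to the interacting region.
#' @return a directed igraph with a `role` vertex attribute; export with
#'   [write_graph_file()].
#' @export
pair_interaction_subgraph <- function(net, a, b, interacting_only = TRUE,
                                      min_present = 6L, permissive = TRUE) {
  pair <- pair_graph(net, a, b, min_present = min_present,
                     permissive = permissive)
  genes <- union(pair$a_genes, pair$b_genes)
  role <- ifelse(genes %in% pair$shared, "shared",
                 ifelse(genes %in% pair$a_genes, "A-only", "B-only"))
  names(role) <- genes
  sub <- igraph::induced_subgraph(net, genes)
  sub <- igraph::set_vertex_attr(sub, "role",
                                 value = unname(role[igraph::V(sub)$name]))
  if (interacting_only) {
    cross <- pair$edges[startsWith(pair$edges$type, "cross"), , drop = FALSE]
    seeds <- union(cross$from, cross$to)
    intra <- pair$edges[startsWith(pair$edges$type, "intra"), , drop = FALSE]
    nb <- union(intra$to[intra$from %in% seeds],
                intra$from[intra$to %in% seeds])
    keep <- intersect(union(seeds, nb), igraph::V(sub)$name)
    sub <- igraph::induced_subgraph(sub, keep)
  }
  sub
}
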