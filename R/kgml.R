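#' Read KEGG KGML pathway files into a merged interaction network
#'
#' Parses KGML (KEGG pathway XML), extracts gene-gene relations, and merges
#' them into one global directed network. Only `entry` elements of type
#' `"gene"` contribute vertices; `group` entries are expanded to their
#' constituent gene components; relations touching compound/map entries are
#' dropped. A relation `entry1 -> entry2` becomes directed edges from every
#' gene token of entry1 to every gene token of entry2, all with weight 1
#' (relation subtypes are ignored). Files describing metabolic maps
#' (detected by the presence of `<reaction>` elements) are skipped unless
#' `include_metabolic = TRUE`, mirroring the practice of building the global
#' network from signalling pathways only.
#'
#' @param paths character vector of KGML file paths.
#' @param include_metabolic include files that contain `<reaction>` elements.
#' @param id_map optional gene-ID-to-symbol mapping: a two-column data.frame
#'   (id, symbol) or a named character vector. Unmapped IDs keep their
#'   original token and a warning reports how many.
#' @param normalize_case see [interaction_network()].
#' @return an `interaction_network` merging all usable relations.
#' @export
read_kgml <- function(paths, include_metabolic = FALSE, id_map = NULL,
                      normalize_case = FALSE) {
  if (length(paths) == 0L) stop_data("no KGML files given")
  all_edges <- list()
  used <- character()
  for (path in paths) {
    doc <- tryCatch(xml2::read_xml(path), error = function(e)
      stop_data("cannot parse KGML file '%s': %s", path, conditionMessage(e)))
    if (!include_metabolic &&
        length(xml2::xml_find_all(doc, ".//reaction")) > 0L) {
      message(sprintf("skipping metabolic pathway file '%s'", path))
      next
    }
    ed <- kgml_gene_edges(doc)
    if (nrow(ed) > 0L) {
      all_edges[[length(all_edges) + 1L]] <- ed
      used <- c(used, path)
    }
  }
  if (length(all_edges) == 0L)
    stop_data("no usable gene-gene relations found in %d KGML file(s)",
              length(paths))
  edges <- unique(do.call(rbind, all_edges))
  if (!is.null(id_map)) {
    map <- as_id_map(id_map)
    edges$from <- map_symbols(edges$from, map)
    edges$to <- map_symbols(edges$to, map)
  }
  interaction_network(edges,
                      provenance = sprintf("KGML: %s", used),
                      normalize_case = normalize_case)
}

# Extract gene->gene edges from one parsed KGML document.
kgml_gene_edges <- function(doc) {
  entries <- xml2::xml_find_all(doc, ".//entry")
  ids <- xml2::xml_attr(entries, "id")
  types <- xml2::xml_attr(entries, "type")
  names_attr <- xml2::xml_attr(entries, "name")

  tokens <- vector("list", length(entries))
  names(tokens) <- ids
  for (i in seq_along(entries)) {
    tokens[[i]] <- if (identical(types[i], "gene"))
      strsplit(trimws(names_attr[i]), "\\s+")[[1]] else character()
  }
  # groups expand to their member genes (one level is all KGML uses)
  for (i in which(types == "group")) {
    comp <- xml2::xml_attr(xml2::xml_find_all(entries[[i]], "./component"), "id")
    tokens[[i]] <- unique(unlist(tokens[comp], use.names = FALSE))
  }

  rels <- xml2::xml_find_all(doc, ".//relation")
  out_from <- character(); out_to <- character()
  for (r in rels) {
    t1 <- tokens[[xml2::xml_attr(r, "entry1")]]
    t2 <- tokens[[xml2::xml_attr(r, "entry2")]]
    if (length(t1) == 0L || length(t2) == 0L) next  # non-gene endpoint
    grid <- expand.grid(from = t1, to = t2, stringsAsFactors = FALSE)
    out_from <- c(out_from, grid$from)
    out_to <- c(out_to, grid$to)
  }
  unique(data.frame(from = out_from, to = out_to, stringsAsFactors = FALSE))
}

as_id_map <- function(id_map) {
  if (is.data.frame(id_map)) {
    if (ncol(id_map) < 2L) stop_data("id_map data.frame needs 2 columns (id, symbol)")
    stats::setNames(as.character(id_map[[2]]), as.character(id_map[[1]]))
  } else if (is.character(id_map) && !is.null(names(id_map))) {
    id_map
  } else {
    stop_data("id_map must be a 2-column data.frame or a named character vector")
  }
}

map_symbols <- function(x, map) {
  hit <- x %in% names(map)
  if (any(!hit)) {
    warning(sprintf("%d gene ID(s) not in mapping table kept as-is (e.g. %s)",
                    sum(!hit), utils::head(unique(x[!hit]), 1)), call. = FALSE)
  }
  x[hit] <- unname(map[x[hit]])
  x
}
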