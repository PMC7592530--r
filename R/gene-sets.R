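#' Create a gene set
#'
#' A gene set is a named collection of gene symbols: a pathway from a curated
#' database, or a user-defined functional module (e.g. from co-expression or
#' crosstalk analysis). Symbols are stored with set semantics (duplicates
#' collapsed, case preserved).
#'
#' @param name non-empty character scalar identifying the set.
#' @param members character vector of gene symbols; must be non-empty.
#' @param source optional free-text provenance (e.g. the GMT description
#'   field).
#' @return an object of class `gene_set` with elements `name`, `members`,
#'   `source`.
#' @examples
#' gene_set("S1", c("TP53", "MDM2", "CDKN1A"))
#' @export
gene_set <- function(name, members, source = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_data("gene set name must be a non-empty string")
  members <- unique(as.character(members))
  members <- members[nzchar(members)]
  if (length(members) == 0L)
    stop_data("gene set '%s' has no members", name)
  structure(list(name = name, members = members, source = source),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$members)))
  utils::str(x$members, give.head = FALSE)
  invisible(x)
}

# Coerce user input (gene_set, character vector, or 1-element named list)
# into a gene_set, inventing a name from the argument if needed.
as_gene_set <- function(x, default_name = "set") {
  if (inherits(x, "gene_set")) return(x)
  if (is.character(x)) return(gene_set(default_name, x))
  if (is.list(x) && !is.null(x$name) && !is.null(x$members))
    return(gene_set(x$name, x$members, x$source))
  stop_data("cannot interpret object of class '%s' as a gene set",
            paste(class(x), collapse = "/"))
}

# Coerce a collection (gene_set_list, list of gene_set, or named list of
# character vectors) into a named list of gene_set objects.
as_gene_sets <- function(x) {
  if (inherits(x, "gene_set")) x <- list(x)
  if (!is.list(x)) stop_data("expected a list of gene sets")
  nm <- names(x)
  out <- lapply(seq_along(x), function(i) {
    default <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else sprintf("set%d", i)
    as_gene_set(x[[i]], default_name = default)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  if (anyDuplicated(names(out)))
    stop_data("duplicate gene set names: %s",
              paste(unique(names(out)[duplicated(names(out))]), collapse = ", "))
  structure(out, class = "gene_set_list")
}

#' @export
print.gene_set_list <- function(x, ...) {
  cat(sprintf("<gene_set_list> %d sets\n", length(x)))
  for (s in x) cat(sprintf("  %s (%d genes)\n", s$name, length(s$members)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' GMT is the tab-separated gene-set format popularized by MSigDB: one set
#' per line, `name TAB description TAB symbol TAB symbol ...`. Duplicate
#' symbols within a line are collapsed.
#'
#' @param path path to a GMT file.
#' @return a `gene_set_list` (named list of [gene_set()] objects); each set's
#'   `source` holds the GMT description field.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_data("GMT file '%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop_data("GMT file '%s', line %d: expected at least 3 tab-separated fields, got %d",
                path, i, length(f))
    gene_set(f[1], f[-(1:2)], source = f[2])
  })
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop_data("GMT file '%s' contains duplicate set names: %s", path,
              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(sets) <- nm
  structure(sets, class = "gene_set_list")
}

#' Write gene sets to a GMT file
#'
#' Inverse of [read_gmt()]; used to make simulated fixtures self-hosting
#' (generated sets can be re-read by the same readers the real workflow
#' uses).
#'
#' @param sets a `gene_set_list` or named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  sets <- as_gene_sets(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$source %||% "na", s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
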