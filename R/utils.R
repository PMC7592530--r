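`%||%` <- function(a, b) if (is.null(a)) b else a

# Error subclasses so the CLI can map failures onto exit codes
# (2 = usage, 3 = data) without string matching.
stop_data <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("pathtopo_data_error", "pathtopo_error", "error")))
}

stop_usage <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("pathtopo_usage_error", "pathtopo_error", "error")))
}

#' Derive a deterministic 31-bit seed from a master seed and labels
#'
#' Per-pair permutation seeds in [topo_matrix()] are derived from the master
#' seed and the *sorted* pair of gene-set names with a Horner string hash, so
#' the matrix is independent of the order in which gene sets are supplied and
#' pairs can be scored in parallel without a shared RNG stream.
#'
#' @param master_seed integer master seed.
#' @param ... character labels mixed into the hash (e.g. the two set names).
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(master_seed, ...) {
  key <- paste(c(format(master_seed), ...), collapse = "\x1f")
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}
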