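# Internal: per-direction contribution lookup tables.
# cross_AB entry [tail, head] = (1 - wA[tail]) * wB[head]; likewise BA.
pair_contributions <- function(pair) {
  wa <- downstream_weights(pair, "A")
  wb <- downstream_weights(pair, "B")
  list(wa = wa, wb = wb,
       c_ab = outer(1 - wa, wb),
       c_ba = outer(1 - wb, wa))
}

cross_counts <- function(pair) {
  c(ab = sum(pair$edges$type == "cross_AB"),
    ba = sum(pair$edges$type == "cross_BA"))
}

# Draw one random endpoint assignment for all cross edges. Tails and heads
# are sampled uniformly and independently per edge; the RNG consumption
# order here is the contract shared by permute_cross_edges() and
# null_distribution(), so the two are interchangeable under one seed.
draw_assignment <- function(n_a, n_b, k_ab, k_ba) {
  list(ab_tail = if (k_ab) sample.int(n_a, k_ab, replace = TRUE) else integer(),
       ab_head = if (k_ab) sample.int(n_b, k_ab, replace = TRUE) else integer(),
       ba_tail = if (k_ba) sample.int(n_b, k_ba, replace = TRUE) else integer(),
       ba_head = if (k_ba) sample.int(n_a, k_ba, replace = TRUE) else integer())
}

# Influence scores of a permuted pair, computed from an endpoint
# assignment. Coinciding permuted edges collapse (the direct-downstream
# operator is an indicator, so a target gene counts once per source gene).
assignment_scores <- function(asg, contrib) {
  score <- function(tails, heads, cm) {
    if (length(tails) == 0L) return(0)
    pr <- unique(cbind(tails, heads))
    sum(cm[pr])
  }
  c(a_on_b = score(asg$ab_tail, asg$ab_head, contrib$c_ab),
    b_on_a = score(asg$ba_tail, asg$ba_head, contrib$c_ba))
}

#' Randomly permute the cross edges of a pair graph
#'
#' Draws, for every cross edge, a new tail uniformly from the tail-side
#' vertices and a new head uniformly from the head-side vertices, keeping
#' the edge's direction (A-to-B edges stay A-to-B). Intra-pathway edges are
#' untouched, so each pathway's internal topology is exactly preserved, and
#' the number of cross edges per direction is conserved. Pseudo-vertices
#' participate like any other vertex, and permuted edges may coincide with
#' existing ones.
#'
#' Uses R's RNG; call [set.seed()] (or let the higher-level drivers do it)
#' for reproducibility.
#'
#' @param pair a [pair_graph()].
#' @return a new `pair_graph` with resampled cross-edge endpoints.
#' @export
permute_cross_edges <- function(pair) {
  k <- cross_counts(pair)
  if (sum(k) == 0L) return(pair)
  asg <- draw_assignment(length(pair$a_genes), length(pair$b_genes),
                         k[["ab"]], k[["ba"]])
  ab <- pair$type_rows$cross_AB
  ba <- pair$type_rows$cross_BA
  pair$edge_from[ab] <- pair$a_genes[asg$ab_tail]
  pair$edge_to[ab] <- pair$b_genes[asg$ab_head]
  pair$edge_from[ba] <- pair$b_genes[asg$ba_tail]
  pair$edge_to[ba] <- pair$a_genes[asg$ba_head]
  pair$edges$from <- pair$edge_from
  pair$edges$to <- pair$edge_to
  pair
}

#' Empirical null distribution of the directional influence scores
#'
#' Repeatedly permutes the cross-edge endpoints ([permute_cross_edges()])
#' and records both directional influence scores per draw. When the full
#' outcome space (the product over cross edges of tail x head choices) is
#' no larger than `n_perm` and `exhaustive_if_small` is set, the space is
#' enumerated exactly instead of sampled, and p-values downstream use exact
#' fractions.
#'
#' @param pair a [pair_graph()].
#' @param n_perm number of Monte-Carlo permutations (default 1000).
#' @param seed optional integer seed for the Monte-Carlo draws.
#' @param exhaustive_if_small enumerate the outcome space when feasible.
#' @return an object of class `null_distribution`: list with
#'   `samples_a_on_b`, `samples_b_on_a`, `n_perm`, `seed`, `exhaustive`,
#'   plus the pair fingerprint used for consistency checks.
#' @export
null_distribution <- function(pair, n_perm = 1000L, seed = NULL,
                              exhaustive_if_small = TRUE) {
  if (n_perm < 1L) stop_data("n_perm must be >= 1")
  n_a <- length(pair$a_genes); n_b <- length(pair$b_genes)
  k <- cross_counts(pair)
  k_tot <- sum(k)
  contrib <- pair_contributions(pair)

  space <- if (k_tot == 0L) 1 else (as.double(n_a) * n_b)^k_tot
  exhaustive <- exhaustive_if_small && space <= n_perm

  if (exhaustive) {
    combos <- exhaustive_scores(contrib, n_a, n_b, k[["ab"]], k[["ba"]])
    s_ab <- combos$a_on_b
    s_ba <- combos$b_on_a
  } else {
    if (!is.null(seed)) set.seed(seed)
    s_ab <- numeric(n_perm); s_ba <- numeric(n_perm)
    for (i in seq_len(n_perm)) {
      asg <- draw_assignment(n_a, n_b, k[["ab"]], k[["ba"]])
      sc <- assignment_scores(asg, contrib)
      s_ab[i] <- sc[["a_on_b"]]; s_ba[i] <- sc[["b_on_a"]]
    }
  }
  structure(list(samples_a_on_b = s_ab, samples_b_on_a = s_ba,
                 n_perm = as.integer(n_perm), seed = seed,
                 exhaustive = exhaustive,
                 pair_id = list(set_a = pair$set_a, set_b = pair$set_b,
                                n_a = n_a, n_b = n_b,
                                k_ab = k[["ab"]], k_ba = k[["ba"]])),
            class = "null_distribution")
}

# Enumerate the full outcome space: each cross edge independently takes one
# of the n_tail * n_head endpoint assignments.
exhaustive_scores <- function(contrib, n_a, n_b, k_ab, k_ba) {
  per_edge <- c(rep(n_a * n_b, k_ab), rep(n_b * n_a, k_ba))
  if (length(per_edge) == 0L) return(list(a_on_b = 0, b_on_a = 0))
  grid <- do.call(expand.grid, lapply(per_edge, seq_len))
  decode <- function(idx, n_tail) cbind(((idx - 1L) %% n_tail) + 1L,
                                        ((idx - 1L) %/% n_tail) + 1L)
  a_on_b <- numeric(nrow(grid)); b_on_a <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    row <- as.integer(grid[r, ])
    if (k_ab > 0L) {
      pr <- unique(decode(row[seq_len(k_ab)], n_a))
      a_on_b[r] <- sum(contrib$c_ab[pr])
    }
    if (k_ba > 0L) {
      pr <- unique(decode(row[k_ab + seq_len(k_ba)], n_b))
      b_on_a[r] <- sum(contrib$c_ba[pr])
    }
  }
  list(a_on_b = a_on_b, b_on_a = b_on_a)
}

#' Normalize a raw score against its null and compute the p-value
#'
#' Each directional influence score is normalized by subtracting the mean
#' of its permuted counterpart; the normalized score is the difference of
#' the two normalized influences (equivalently, the raw score minus the
#' null mean of the permuted score difference). The p-value is the chance
#' that a permuted score difference is at least as extreme as the observed
#' raw score, one-sided in the direction of the observed sign (ties count
#' as extreme); a Phipson-Smyth add-one keeps Monte-Carlo p-values off 0,
#' while exhaustive nulls use the exact fraction. A raw score of 0 (in
#' particular, a pair with no cross edges) yields p = 1.
#'
#' @param pair the [pair_graph()] the null was computed on.
#' @param null a [null_distribution()] for the same pair.
#' @param alternative `"directional"` (default, one-sided toward the
#'   observed sign, which preserves p(A,B) = p(B,A)) or `"two.sided"`.
#' @return a `topo_result` object; see [topo_score()] for the fields.
#' @export
normalize_and_test <- function(pair, null,
                               alternative = c("directional", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!inherits(null, "null_distribution"))
    stop_data("null must be a null_distribution")
  k <- cross_counts(pair)
  pid <- null$pair_id
  if (!identical(pid$n_a, length(pair$a_genes)) ||
      !identical(pid$n_b, length(pair$b_genes)) ||
      !identical(pid$k_ab, k[["ab"]]) || !identical(pid$k_ba, k[["ba"]]))
    stop_data("null distribution does not match this pair graph")

  infl <- influence_scores(pair)
  raw_a <- infl[["a_on_b"]]; raw_b <- infl[["b_on_a"]]
  raw <- raw_a - raw_b
  norm_a <- raw_a - mean(null$samples_a_on_b)
  norm_b <- raw_b - mean(null$samples_b_on_a)
  norm <- norm_a - norm_b

  diffs <- null$samples_a_on_b - null$samples_b_on_a
  if (raw == 0) {
    p <- 1
  } else {
    extreme <- switch(alternative,
                      directional = if (raw > 0) diffs >= raw else diffs <= raw,
                      two.sided = abs(diffs) >= abs(raw))
    p <- if (null$exhaustive) {
      sum(extreme) / length(diffs)
    } else {
      (1 + sum(extreme)) / (null$n_perm + 1)
    }
  }
  p <- min(1, p)

  structure(list(set_a = pair$set_a, set_b = pair$set_b,
                 raw_influence_a = raw_a, raw_influence_b = raw_b,
                 raw_score = raw,
                 norm_influence_a = norm_a, norm_influence_b = norm_b,
                 norm_score = norm,
                 p_value = p,
                 null = null,
                 n_present_a = length(pair$a_genes),
                 n_present_b = length(pair$b_genes),
                 n_shared = length(pair$shared),
                 n_cross_ab = k[["ab"]], n_cross_ba = k[["ba"]],
                 alternative = alternative),
            class = "topo_result")
}

#' Score the upstream/downstream relationship of two gene sets
#'
#' End-to-end driver: extracts the pair graph, computes the raw directional
#' influence scores, builds the empirical null by cross-edge permutation,
#' and returns the normalized score with its permutation p-value. A
#' positive normalized score indicates the first set acts upstream of the
#' second. Comparing a set against itself (identical member sets) is
#' reported as score 0 with p = 1 without computation, as forced by
#' antisymmetry.
#'
#' @inheritParams pair_graph
#' @inheritParams null_distribution
#' @inheritParams normalize_and_test
#' @return a `topo_result`: raw and normalized influence scores and score
#'   difference, permutation p-value, the null distribution, and pair
#'   metadata (genes present per side, shared genes, cross-edge counts).
#' @examples
#' fx <- make_fixture("chain", sizes = c(3, 3))
#' res <- topo_score(fx$network, fx$sets[[1]], fx$sets[[2]],
#'                   n_perm = 100, seed = 1, min_present = 3)
#' res$norm_score   # 0.75: the chain fixture's exhaustive-null value
#' @export
topo_score <- function(net, a, b, n_perm = 1000L, seed = NULL,
                       min_present = 6L, permissive = FALSE,
                       exhaustive_if_small = TRUE,
                       alternative = c("directional", "two.sided")) {
  alternative <- match.arg(alternative)
  a <- as_gene_set(a, "A"); b <- as_gene_set(b, "B")
  if (setequal(a$members, b$members)) {
    null <- structure(list(samples_a_on_b = numeric(), samples_b_on_a = numeric(),
                           n_perm = 0L, seed = seed, exhaustive = TRUE,
                           pair_id = list(set_a = a$name, set_b = b$name,
                                          n_a = NA_integer_, n_b = NA_integer_,
                                          k_ab = 0L, k_ba = 0L)),
                      class = "null_distribution")
    return(structure(list(set_a = a$name, set_b = b$name,
                          raw_influence_a = 0, raw_influence_b = 0,
                          raw_score = 0,
                          norm_influence_a = 0, norm_influence_b = 0,
                          norm_score = 0, p_value = 1,
                          null = null,
                          n_present_a = NA_integer_, n_present_b = NA_integer_,
                          n_shared = length(a$members),
                          n_cross_ab = 0L, n_cross_ba = 0L,
                          alternative = alternative,
                          self_comparison = TRUE),
                     class = "topo_result"))
  }
  pair <- pair_graph(net, a, b, min_present = min_present,
                     permissive = permissive)
  null <- null_distribution(pair, n_perm = n_perm, seed = seed,
                            exhaustive_if_small = exhaustive_if_small)
  normalize_and_test(pair, null, alternative = alternative)
}

#' @export
print.topo_result <- function(x, ...) {
  cat(sprintf("<topo_result> %s vs %s\n", x$set_a, x$set_b))
  cat(sprintf("  normalized score: %.4g   (raw %.4g)   p = %.4g%s\n",
              x$norm_score, x$raw_score, x$p_value,
              if (isTRUE(x$null$exhaustive)) " [exhaustive null]" else ""))
  cat(sprintf("  influence A->B: raw %.4g / norm %.4g; B->A: raw %.4g / norm %.4g\n",
              x$raw_influence_a, x$norm_influence_a,
              x$raw_influence_b, x$norm_influence_b))
  cat(sprintf("  genes present: %s / %s; shared %d; cross edges A->B %d, B->A %d\n",
              format(x$n_present_a), format(x$n_present_b), x$n_shared,
              x$n_cross_ab, x$n_cross_ba))
  invisible(x)
}

#' Flatten a scoring result to a one-row data frame
#'
#' @param x a `topo_result`.
#' @param ... unused.
#' @return one-row data.frame with all scalar fields (null samples are not
#'   included; see [write_result()] to dump them to a sidecar file).
#' @export
as.data.frame.topo_result <- function(x, ...) {
  data.frame(set_a = x$set_a, set_b = x$set_b,
             raw_influence_a = x$raw_influence_a,
             raw_influence_b = x$raw_influence_b,
             raw_score = x$raw_score,
             norm_influence_a = x$norm_influence_a,
             norm_influence_b = x$norm_influence_b,
             norm_score = x$norm_score,
             p_value = x$p_value,
             n_perm = x$null$n_perm,
             exhaustive = x$null$exhaustive,
             n_present_a = x$n_present_a, n_present_b = x$n_present_b,
             n_shared = x$n_shared,
             n_cross_ab = x$n_cross_ab, n_cross_ba = x$n_cross_ba,
             stringsAsFactors = FALSE)
}

#' Write a scoring result to TSV or JSON
#'
#' @param x a `topo_result`.
#' @param path output path.
#' @param format `"tsv"` (one row, all scalar fields) or `"json"`.
#' @param null_samples optional path for a sidecar TSV of the permutation
#'   samples (two columns, one row per permutation).
#' @return `path`, invisibly.
#' @export
write_result <- function(x, path, format = c("tsv", "json"),
                         null_samples = NULL) {
  format <- match.arg(format)
  df <- as.data.frame(x)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(as.list(df), path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(null_samples)) {
    utils::write.table(
      data.frame(a_on_b = x$null$samples_a_on_b,
                 b_on_a = x$null$samples_b_on_a),
      null_samples, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
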