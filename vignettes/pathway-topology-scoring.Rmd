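---
title: "Scoring upstream/downstream relationships between gene sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring upstream/downstream relationships between gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathtopo)
```

## The problem and the model

Pathway analysis of a transcriptome experiment typically ends with a list of
enriched gene sets. Those sets are not independent actors: signalling flows
*between* them, and knowing that module X sits upstream of module Y is often
the mechanistic insight the enrichment list itself cannot provide. This
package scores that relationship for any pair of gene sets with more than a
handful of members, using only a global directed gene-interaction network —
no expression values enter the score.

The model rests on three ideas.

**A gene's position inside its own pathway is informative.** Within the
subnetwork induced by a gene set, we weight each gene by the fraction of its
fellow members lying downstream of it: $w_i = n_d/(n-1)$, where $n_d$ is the
number of *other* members reachable from gene $i$ by directed paths that
stay inside the set, and $n$ is the number of members present in the
network. On a linear chain the weights grade smoothly from 1 at the head to
0 at the tail; on a directed cycle every gene has weight 1 (a gene is never
counted as downstream of itself).

**Upstream relationships look like "tail acts on head".** The influence of
set $A$ on set $B$ sums, over the direct cross edges from $A$-genes to
$B$-genes, the product $(1-w_{\text{tail}})\,w_{\text{head}}$. A tail gene
of $A$ (low $w$) feeding a head gene of $B$ (high $w$) is the canonical
upstream signature and contributes close to 1; a head-to-tail edge
contributes nearly 0. Only *direct* cross edges are counted: the influence
of an upstream $A$-gene is already accounted for through the weight of the
downstream $A$-genes that carry it forward, and counting indirect targets
in $B$ would re-use positional information and bias the sum. All edges
carry weight 1 — current interaction databases give no comparable
quantitative strength, and signs (activation vs inhibition) are likewise
out of scope. The raw score is the difference
$\text{Influence}_{A\to B}-\text{Influence}_{B\to A}$, which makes it
exactly antisymmetric.

**Significance must be calibrated per pair.** Pathway topologies vary so
much that no universal null exists; a fan-in meeting a fan-out can produce a
large raw score by shape alone. The null is therefore empirical: cross-edge
endpoints are re-drawn uniformly (tails from the source side, heads from the
target side, directions fixed), leaving each side's internal topology
untouched. The permutation means of the two directional influences are
subtracted from the observed ones (giving the *normalized* score), and the
p-value is the chance of a permuted score difference at least as extreme as
the observed raw score.

## Pseudo-vertices for overlapping sets

When the two sets share genes, an edge at a shared gene is simultaneously
intra- and inter-pathway, and naive permutation would corrupt the internal
topology. Shared genes are therefore duplicated into two side-specific
pseudo-vertices before anything is scored. Every original edge expands to
all side-consistent copies: an edge between two shared genes yields both
intra copies and both cross copies; an edge from a shared gene to an
$A$-only gene yields an intra-$A$ copy and a cross $B{\to}A$ copy, and so
on. This expansion rule is chosen precisely so that the raw influence
scores computed on the split graph equal a direct evaluation on the unsplit
graph in which shared genes are treated as members of both sides — the test
suite enforces that equality against an independently coded oracle on random
overlapping pairs. Pseudo-vertices are full citizens of the permutation
space: a permuted edge may land on the two copies of the same gene, or
coincide with an existing edge (forbidding such collisions would break
uniformity for dense cross-edge sets; coinciding copies collapse through
the indicator in the influence sum).

## Parameters

* `min_present = 6`: each set needs more than 5 members present in the
  network; below that, position weights carry almost no information. With
  fewer members the pair is rejected (or warned about in permissive mode).
  Members absent from the network are dropped and do not enter $n$ — a gene
  the network knows nothing about has no topological position.
* `n_perm = 1000` permutations per pair. This puts the Monte-Carlo p-value
  floor at $1/1001$, fine enough for the conventional 0.05 threshold even
  after screening tens of pairs; raise it if you need sharper tail
  estimates. When the full outcome space of endpoint assignments is no
  larger than `n_perm`, it is enumerated exactly instead (`exhaustive`),
  and p-values become exact fractions.
* `seed`: all randomness flows from one integer. `topo_matrix()` derives a
  per-pair seed from the master seed and the *sorted* pair of set names, so
  results are independent of input order and pairs can be scored in any
  order or in parallel.
* Assembly thresholds `score_min = 1`, `p_max = 0.05`: an edge enters the
  super-module only when the row set is significantly and substantially
  upstream. A normalized score of 1 corresponds to one clean tail-to-head
  interaction beyond the permutation expectation; both knobs are explicit
  arguments (and CLI flags) rather than claims of a universally right
  value.
* `alternative = "directional"`: the p-value is one-sided toward the sign
  of the observed raw score, which preserves $p(A,B)=p(B,A)$ under
  antisymmetry. Ties (permuted value equal to the observed) count as
  extreme — the conservative choice. A two-sided variant is available.

## Numerical and degenerate-input choices

Reachability for the weights is computed by boolean matrix closure over the
side's intra edges; sides of size 1 take weight 0 by convention (the lone
gene is simultaneously head and tail). Comparing a set with itself is
reported as score 0 with p = 1 without computation, forced by antisymmetry.
Pairs with no cross edges have raw and normalized scores exactly 0 and
p-value exactly 1 — this is the degenerate contract the acceptance script
recomputes. Monte-Carlo p-values use the add-one correction
$(1+\#\text{extreme})/(n_{\text{perm}}+1)$ so they are never 0; exhaustive
p-values are exact and never smaller than one over the space size, since
the observed assignment itself belongs to the space. Symbol matching is
case-sensitive exact string comparison (mouse symbols are mixed-case); an
opt-in uppercasing hook exists for sloppy inputs. Gene-ID conversion for
KGML networks is delegated to a user-supplied two-column table — no
annotation service is contacted, and unmapped IDs keep their token with a
warning.

## What the fixture generator emulates — and what it does not

`make_fixture()` builds the structures the scoring logic must get right:
linear chains (graded weights), fans (degenerate weight distributions),
cycles (all weights 1, so any cross edge contributes 0), mirrored parallel
pathways (exact cancellation, the "no direction" control), explicit overlap
(pseudo-vertex splitting), and a three-pathway planted cascade embedded in
an Erdős–Rényi background (super-module recovery). For analytically
solvable topologies the generator records the exact raw score in closed
form, computed independently of the scoring code, and the tests require
exact agreement.

Real pathway collections differ from these fixtures in ways the tests
deliberately do not claim to cover: scale-free degree structure, hub genes
shared by dozens of pathways, curation noise and missing interactions, and
database-specific definitions of "the same" pathway. Passing tests
demonstrate the algorithm's internal correctness and calibration, not that
any particular KEGG/MSigDB release yields biologically correct orderings —
the quality of the global network bounds the quality of every score.

## Problem sizes used by the checks

The test suite runs at desk scale: worked examples on 3+3- and 6+6-gene
chains (exhaustive nulls of 9 and 36 outcomes), 100–200 random fixtures for
the antisymmetry and split-invariance properties, a 10-vertex random
digraph for the exhaustive subset-pair comparison against a from-scratch
oracle (all ~200,000 unordered pairs of subsets up to size 5), Monte-Carlo
nulls of 10,000 draws against exhaustive enumeration, and 20 seeds of an
8+8+8 planted cascade with 30 background genes for end-to-end recovery.

## Known limitations

Only upstream/downstream structure is assessed — cooperative or mutually
regulating pathway pairs score near 0 by design and must be studied with
other tools. Set memberships are taken as given: the method neither refines
gene sets nor constructs modules de novo, so redundant or noisy input sets
propagate into the super-module. Edge signs and strengths are ignored. The
score is only as good as the global network; for organisms with sparse
interaction curation the results should be treated with caution.
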