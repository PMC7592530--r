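# pathtopo

Pathway enrichment tells you *which* gene sets changed; it does not tell you
how those gene sets relate to one another. `pathtopo` quantifies the
**upstream/downstream relationship between two gene sets** (curated pathways
or user-defined functional modules) on a global directed gene-interaction
network, and assembles many such relationships into directed "super-module"
graphs. It is aimed at transcriptome analysts who already have a list of
enriched pathways or modules and want the signal-flow structure among them.

## The score

All computation happens on a global directed network whose vertices are gene
symbols and whose edge *u → v* means "u acts directly on v" (typically merged
from curated signalling pathways). For a pair of gene sets *A* and *B*:

1. **Position weights.** Each gene *i* of a set gets a weight equal to the
   fraction of its fellow set members reachable downstream of it inside the
   set's own induced subnetwork:

   *w*<sub>i</sub> = *n*<sub>d</sub> / (*n* − 1),

   where *n*<sub>d</sub> counts the other set members reachable from *i* by
   directed paths within the set and *n* is the number of set members present
   in the network. Heads of a pathway score near 1, tails score 0.

2. **Directional influence.** The influence of *A* on *B* sums, over the
   cross edges that run from *A*-genes to *B*-genes,

   InfluenceScore<sub>A</sub> = Σ<sub>i∈A</sub> (1 − *w*<sub>Ai</sub>) ·
   **DDs**(*i*) · **w**<sub>B</sub><sup>T</sup>,

   where **DDs**(*i*) is the 0/1 indicator of the *B*-genes directly
   downstream of *i*. Tail-of-*A* genes hitting head-of-*B* genes contribute
   most — the signature of a genuine upstream relationship. Only direct cross
   edges count; indirect effects are carried by the weights.

3. **Raw score.** raw = InfluenceScore<sub>A</sub> − InfluenceScore<sub>B</sub>;
   positive means *A* is upstream of *B*, and the score is exactly
   antisymmetric in the two sets.

4. **Permutation calibration.** Cross-edge endpoints are repeatedly
   re-drawn uniformly (directions fixed, each set's internal topology
   untouched); genes shared by both sets are first split into side-specific
   *pseudo-vertices* so that permutation is well defined for overlapping
   sets without disturbing either set's internal structure. Each directional
   influence is normalized by subtracting its permutation mean, and the
   p-value is the chance that a permuted score difference is at least as
   extreme as the observed raw score. Small outcome spaces are enumerated
   exhaustively; pairs with no cross edges score 0 with p = 1.

A matrix of normalized scores over many gene sets, thresholded on score and
p-value, becomes a directed weighted graph whose vertices are pathways — the
super-module.

## Worked example

Two 6-gene linear pathways joined by a single cross edge from the tail of P1
to the head of P2 — the cleanest possible "P1 upstream" signal:

```r
library(pathtopo)
fx  <- make_fixture("chain", sizes = c(6, 6))
res <- topo_score(fx$network, fx$sets[["P1"]], fx$sets[["P2"]],
                  n_perm = 1000, seed = 1)
res
#> <topo_result> P1 vs P2
#>   normalized score: 0.75   (raw 1)   p = 0.02778 [exhaustive null]
#>   influence A->B: raw 1 / norm 0.75; B->A: raw 0 / norm 0
#>   genes present: 6 / 6; shared 0; cross edges A->B 1, B->A 0
```

The tail→head edge contributes (1 − 0) × 1 = 1 to P1's influence on P2 and
nothing in reverse, so the raw score is 1. The 36 possible endpoint
assignments of the single cross edge average an influence of 0.25, giving a
normalized score of 0.75; exactly one assignment reaches the observed score,
so p = 1/36 ≈ 0.028. All-pairs scoring arranges such results
row-over-column (positive ⇒ row upstream of column):

```r
topo_matrix(fx$network, fx$sets, n_perm = 1000, seed = 1)
#> <topo_matrix> 2 gene sets, n_perm = 1000, seed = 1
#> normalized scores (row over column):
#>       P1   P2
#> P1  0.00 0.75
#> P2 -0.75 0.00
```

while `jaccard_matrix(fx$sets)` shows the two sets share no genes — directed
influence and set similarity are different axes. `assemble_super_module()`
filters a matrix (defaults: score ≥ 1, p ≤ 0.05) into the super-module
graph, with sets lacking any significant relationship reported as left out.

A command-line interface (`inst/cli/pathtopo`) exposes the same workflow as
`build-net`, `score`, `matrix`, `assemble` and `simulate` subcommands; real
networks can be built from TSV edge lists or KEGG KGML files
(`read_edge_list()`, `read_kgml()`), and gene sets from GMT files
(`read_gmt()`).

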