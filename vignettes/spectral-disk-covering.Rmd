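---
title: "Spectral disk-covering phylogeny reconstruction from gene orders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral disk-covering phylogeny reconstruction from gene orders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectree)
```

## The problem

Gene-order data describe a genome as a signed permutation of a shared
gene set $1..g$: the order of the genes along one linear chromosome,
with the sign encoding the strand. Inversions (reversals) flip a
contiguous block and its signs; for many organellar genomes and several
eukaryotic lineages they dominate structural evolution. The inversion
distance between two such genomes — the minimum number of inversions
transforming one into the other — is computable in polynomial time from
the breakpoint graph by the Hannenhalli–Pevzner formula

$$d = (g + 1) - c + h + f,$$

where $c$ counts the alternating cycles of the breakpoint graph over the
$2g+2$ unsigned gene extremities, $h$ the hurdles (unoriented components
protected in the nesting order), and $f$ the fortress correction.

Maximum parsimony (MP) over gene orders seeks the unrooted tree, with a
genome assigned to every internal vertex, minimizing the sum of
inversion distances along edges. Even scoring one fixed topology is
NP-hard (it embeds the inversion *median* problem — find a genome
minimizing the summed distance to three given genomes), and the number
of unrooted binary topologies grows as $(2n-5)!!$: 15 at $n=5$,
2,027,025 at $n=10$. `spectree` attacks this with a divide-and-conquer
("disk-covering") strategy: decompose the genomes into two possibly
overlapping subsets (*disks*) using spectral graph bipartitioning,
recurse until disks hold at most three genomes, solve those directly
with inversion medians, and merge the sub-topologies back up, using the
MP criterion at every merge to select among a small set of candidates.

## The spectral decomposition

For a disk of $n$ genomes with pairwise inversion distances $d_{ij}$,
a similarity graph is built with the Gaussian kernel

$$w_{ij} = \exp\!\left(-\frac{d_{ij}^2}{2\sigma^2}\right),
  \qquad \sigma = \alpha\, d_{\max},$$

where $d_{\max}$ is the largest pairwise distance in the disk and
$\alpha = 0.125$ by default. The decomposition uses the Fiedler vector
(the eigenvector for the second-smallest eigenvalue) of the
*random-walk* Laplacian $L_{rw} = D^{-1}(D - W)$. The unnormalized
Laplacian is rejected because, via the relation between $D^{-1/2}$-scaled
eigensystems, it inflates the magnitude of entries for genomes with many
close neighbours — magnitudes are exactly what the method uses to judge
boundary proximity. Numerically we solve the symmetric form
$L_{sym} = D^{-1/2}(D-W)D^{-1/2}$ with R's deterministic dense symmetric
eigensolver and map the eigenvector back by $D^{-1/2}$; the two share
eigenvalues, and the symmetric solve is the stable route. The vector is
normalized to unit length with the largest-magnitude entry positive
(ties broken by the lowest index), which fixes every downstream decision
deterministically.

Signs give the initial bipartition; magnitudes give confidence. With the
sorted entries $v_{(1)} \le \dots \le v_{(n)}$, the gap between the
smallest positive and largest negative entry is compared against
$\theta_1/\sqrt{n}$ (the $1/\sqrt{n}$ scaling compensates for the unit
normalization of the eigenvector). A wide gap signals a long
uninterrupted edge in the underlying history, and the split is taken as
is. A narrow gap triggers an overlap: walking outward from the boundary
on each side, genomes move into the overlapping region until the gap
between consecutive sorted entries exceeds $\theta_2/\sqrt{n}$, so that
a block of near-boundary genomes is never cut through the middle.
Entries exactly zero always join the overlap. Defaults are
$\theta_1 = 0.5$ and $\theta_2 = 0.25$: these are calibrated values —
chosen once so that, across all four simulation regimes, the recursive
decomposition never produced a decomposition incompatible with the
generating tree (the property the compatibility test suite enforces) —
not transcriptions of reference values.

Two guards keep decompositions usable. First, the exclusive region of
each disk must stay non-empty (outermost overlap members are released if
a side is consumed), and the overlap is capped at
`max_overlap_fraction` (default 0.5) of the disk. Second, the
*big-overlap avoidance* rewrite: when two long edges isolate two small
groups, every central genome has a near-zero entry and the walk would
drown the disk in overlap. Each child disk is therefore decomposed once
more; if a child splits cleanly into two non-overlapping parts with one
part holding the entire overlap, the other part becomes one side of a
rewritten, non-overlapping decomposition. Decomposing a disk where all
genomes are identical is degenerate; the pipeline deduplicates identical
genomes up front and re-attaches them as zero-length cherries at the
end.

## Medians and topology scoring

The inversion median solver first *condenses* the three genomes:
adjacencies present in all three (in the signed sense) are collapsed
into blocks, the standard reduction that preserves distances and shrinks
the instance to the disagreement structure. On the condensed instance an
exact breadth-first branch-and-bound runs from the input genome with the
smallest distance sum $U$: any genome $m$ satisfies
$f(m) \ge d(s,m) + d(b,c)$, so levels beyond $U - d(b,c)$ cannot
improve, and the half-perimeter bound
$\lceil (d_{ab}+d_{ac}+d_{bc})/2 \rceil$ certifies optimality when
reached. A node budget (default 20,000) keeps the search bounded; when
it is exceeded the solver falls back to a greedy descent over candidate
reversals read off the oriented gray edges of the breakpoint graph
against each target, with limited sideways (equal-score) moves, run from
multiple deterministic starts: the best state so far, each input genome,
and the midpoints of greedy pairwise sorting paths. Results from the
fallback are flagged `heuristic`. In the simulation regimes used here,
over 99% of pipeline medians terminate with the optimality certificate.

A fixed topology is scored GRAPPA-style: every internal vertex is
revisited in a fixed breadth-first order and relabeled with the median
of its three neighbours whenever that strictly lowers the score, until a
full pass changes nothing (`max_passes` = 50 guards cycling, which we
have not observed). Two refinements reduce the local-optimum noise of
this iteration. First, the refinement is run from two initializations —
the labels inherited from the merge, and a nearest-leaf initialization
in which every internal vertex starts at the median of its three closest
leaves — keeping the better result. Second, a zero-collapse sweep:
score-neutral label adoptions between adjacent internal vertices, and
score-neutral joint relabelings of short-edge endpoints onto common
Steiner candidates, are applied so that an internal edge whose split has
no real support ends with identical endpoint labels (length zero)
instead of asserting a phantom split. This matters because accuracy is
assessed on bipartitions after contracting zero-length edges.

## Merging

*Non-overlapping disks.* All genomes of one tree — internal
reconstructions included — are compared against all genomes of the
other; for the closest cross pair $(u, v)$, each of the up-to-3 edges
incident to $u$ is bridged to each of the up-to-3 edges incident to $v$
by subdividing both and joining the new vertices, giving at most nine
candidates (ties in the minimum distance extend the enumeration to all
tied pairs). The new vertices are initialized by medians of their
already-labeled neighbourhoods — the merge order guarantees two
assigned neighbours, which is the mechanism that makes initial labels
accurate — and every candidate is rescored in full. The lowest score
wins; among equal scores we prefer the candidate asserting the fewest
positive-length internal edges (the least-resolved equally parsimonious
tree), then enumeration order. This tie-break is a deliberate design
choice: at signal-free regions equally parsimonious candidates differ
only in phantom resolutions, and the least-assertive one is the
defensible report.

*Overlapping disks.* The two trees are restricted to the overlap; an
internal edge of one restriction conflicts when its bipartition of the
overlap is incompatible with some bipartition of the other. Conflicting
edges are contracted in the original trees. A backbone tree over the
overlap is then built from the union of the remaining (now mutually
compatible) overlap splits, and the exclusive subtrees of both inputs
are grafted onto it: a piece hanging off a retained branch vertex
attaches at the matching backbone vertex (matched through partition
signatures after contracting backbone edges the restriction does not
resolve); pieces hanging along a suppressed path attach on the backbone
edge carrying that path's split. Pieces from a single tree keep their
path order as a chain — that order is part of the sub-topology being
preserved — while pieces from *both* trees on the same path gather at
one multifurcating vertex, because neither sub-topology constrains
their relative order. Every multifurcation (from contraction, stacking,
or an unresolved backbone) is then expanded into all
$(2k-5)!!$ binary resolutions, combined multiplicatively and capped at
`max_candidates` (default 10,000, with a loud warning; the
$\theta$-parameters are the intended overlap-size control, the cap is a
safety net); all candidates are labeled, rescored and ranked as above.

*Tie propagation.* A disk often admits several equally parsimonious
sub-topologies — most visibly in regions the generating process left
unresolved — and which one a local merge reports is arbitrary. Instead
of committing, every node of the recursion carries forward the full set
of equal-score sub-trees (deduplicated by topology, ordered by least
asserted resolution, capped at `max_ties`, default 4), and the parent
merge evaluates every combination. A tie that is genuinely arbitrary at
the disk level is thereby settled where more genomes weigh in; on small
instances this is what makes the pipeline reach the exhaustive-search
minimum whenever the decomposition is compatible. The reported tree is
the first of the top-level tied set.

After the final merge the tree is rescored from scratch; the reported
parsimony score is always recomputable from the returned labeling.

## Simulators

The experiment driver reproduces four regimes at desk scale:
uniform-random topologies (sequential leaf addition, uniform over the
$(2n-5)!!$ topologies) with integer edge lengths uniform on $0..16$;
pure-birth (Yule) topologies (birth rate 0.001, death 0) with the same
length regime; and pure-birth topologies with skewed lengths — each
provisional duration multiplied by $2^s$, $s \sim U(-2,2)$, then all
lengths scaled by one constant so the leaf-to-leaf diameter equals $1g$
or $2g$ and rounded to integers. The $2^s$ form is a deliberate
interpretation: a multiplier drawn uniformly from $(-2, 2)$ would be
negative half the time, which is not meaningful for lengths, while the
exponentiated form is the standard skew device and yields the
right-skewed distribution (few long, many short edges) the regime is
meant to produce.

Evolution applies exactly `edge length` inversions per edge from an
identity ancestor of $g = 100$ genes, drawing the inversion *length*
uniformly on $1..g$ first and then the start position uniformly among
the feasible windows, which makes the length distribution exactly
uniform (drawing windows uniformly would make it triangular). An
optional gamma length distribution (rounded, clamped to $[1, g]$) is
provided for experiments on length-biased regimes; its parameters carry
no reference defaults. Every simulated vertex genome is retained, so
tests can compare against the true ancestral labeling, and each
replicate consumes a single seeded RNG stream (topology, lengths,
inversions), making runs byte-reproducible.

Edge length 0 is allowed — the model tree then contains an edge no
method can recover — and accuracy comparisons contract model edges
shorter than 0.5 beforehand, the same threshold applied to
fractional-length reconstructions. Compatibility of decompositions,
by contrast, is judged against the model tree as simulated (all edges),
the literal reading of an "edge in the model tree".

What the generators do *not* emulate: unequal gene content (no
insertions, deletions, duplications), transpositions or translocations,
multiple chromosomes, rate variation across lineages beyond the length
regimes, and any sequence-level signal. Passing tests therefore speak to
the rearrangement-only, equal-content regime; real organellar data add
violations of all of these assumptions.

## Accuracy accounting

`fp_fn()` counts, over internal edges only, bipartitions asserted by the
reconstruction but absent from the model (FP) and model bipartitions the
reconstruction misses (FN), both after the 0.5-length contraction;
$(FP+FN)/2$ is half the Robinson–Foulds distance for binary pairs. A
decomposition is *compatible* when some model-tree edge separates the
two exclusive regions (overlap genomes are ignored); an incompatible one
is *recoverable* when replaying the merge on the ground-truth
sub-topologies still returns the model topology.

At the study scale used throughout ($n = 20$, $g = 100$, 10 replicates
per regime; property suites at $n \in \{10, 20, 40\}$ and exhaustive
checks at $n \le 7$ with smaller $g$), reconstruction errors are rare
and concentrated where the model tree itself is weak: regions bounded by
zero- or unit-length edges, where an alternative resolution is genuinely
one step more parsimonious than the generating topology. We verified on
probe cases — with an independent Sankoff-style dynamic program over a
candidate-label pool — that these preferences are properties of the
parsimony criterion on the data, not search failures; no labeling of the
generating topology beats the alternative. They are the gene-order
analogue of the classical observation that the most parsimonious tree
is not always the true tree.

## Numerical and degenerate-input choices

* Distances, medians and scores are integers throughout; no floating
  tolerance enters the combinatorial core. The only floating point is in
  the eigensolve, where determinism comes from LAPACK's deterministic
  dense symmetric solver plus the fixed sign convention.
* Stable sorts and fixed visit orders (sorted adjacency lists,
  lowest-leaf BFS) make every pipeline stage reproducible; ties in
  eigenvector entries keep input order.
* A disk whose genomes are all identical cannot be decomposed spectrally
  and is split arbitrarily after deduplication upstream makes this
  unreachable in practice.
* One sign class empty in the Fiedler vector (all entries one-signed
  after the zero rule): the genome with the extreme entry is split off
  alone, preserving the strict-shrink guarantee that terminates the
  recursion.
* The hurdle/fortress analysis runs only when an unoriented nontrivial
  cycle exists; the fortress branch follows the protected-hurdle
  definition literally. Fortresses cannot occur at the sizes our
  exhaustive oracle covers ($g \le 6$, where the distance is verified
  against breadth-first search over the full move graph), so that branch
  rests on the formula rather than an oracle — a known residual risk of
  every HP implementation tested at small scale.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
mt <- uniform_random_tree(10, 0, 16)      # model topology + lengths
mt <- evolve_genomes(mt, g = 100)         # 100-gene genomes at the leaves
st <- reconstruct(mt$genomes)             # full pipeline
st$score                                  # parsimony score of the result
fp_fn(st$tree, mt$tree)                   # FP/FN against the model
```

## Limitations

Inversion-only, equal-content, linear unichromosomal genomes; breakpoint
distance is available as an alternative metric for matrices but the
median machinery is inversion-specific. The median fallback is heuristic
for distant triples (flagged on every result). The overlap merge fixes
attachment ambiguities that neither sub-topology constrains via
enumeration, but attachment-position ambiguity *within* a region one
tree leaves unresolved is settled deterministically rather than
enumerated, a scope choice that keeps the candidate set small. Runtime
is dominated by median calls; beyond a few hundred genomes the
distance-matrix and merge costs grow quickly and the implementation is
not tuned for that scale.
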