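---
title: "Probe-set classification of microbial proteomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe-set classification of microbial proteomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoprobe)
```

## The method

Microbial genomes differ enormously in gene content, and whole-proteome
sequence comparison is dominated by the non-conserved majority of each
proteome. The probe-set method takes the opposite route: it looks only at
short, highly conserved amino-acid sequence patterns — PROSITE-style
descriptors of functional sites (active sites, binding sites, signatures of
transporters and receptors), typically 10–20 residues long. Each descriptor
is a "probe"; a collection of them (on the order of a thousand in full-scale
use) is a probe set. An organism is then represented not by its sequences but
by how often each probe occurs in its proteome, so the representation
emphasizes functional capacity and disregards the noisy bulk of the
proteome.

The pipeline has four stages, one module each:

1. **Probes** (`parse_pattern`, `count_occurrences`, `read_probe_file`):
   parse descriptors and count matches in protein sequences.
2. **Profiles** (`frequency_pattern`, `build_matrix`, `pattern_cc`,
   `standardize_matrix`): turn occurrence counts into normalized frequency
   patterns and compare them.
3. **Clustering** (`spearman_distance`, `build_tree`): build the
   classification tree by average-linkage clustering under Spearman-rank
   distance.
4. **Tree comparison** (`travel_distance_matrix`, `tree_cc`,
   `same_topology`): quantify how similar two classification trees are.

A synthetic-data module (`random_probes`, `synthetic_proteome`,
`truncate_proteome`, `truncation_experiment`) generates seeded test inputs
and runs the robustness experiments, so everything above can be exercised
without downloading genome databases.

## Probe matching

A descriptor such as `Q-[LIV]-H-H-[SA]-x(2)-D-G-[FY]-H` is a dash-separated
list of position elements: exact residues, `[..]` ambiguity sets, `{..}`
exclusion sets, and the `x` wildcard, each with an optional `(n)` or `(n,m)`
repeat. A leading `<` anchors the match to the sequence start, a trailing
`>` to the end.

The **occurrence** of a probe in a sequence is defined here as the number of
distinct start positions at which the pattern matches. Overlapping matches
all count; a variable-repeat pattern that can match one start position in
several ways counts that position once. This convention is deterministic and
independent of greedy-versus-lazy repeat semantics (any one way to match a
start suffices), which is why it was chosen over counting match *extents*.
Matching is implemented with a zero-width lookahead regular expression so
every start position is examined; the test suite checks it against a
brute-force enumerator over all start positions and repeat-length
combinations.

Non-standard sequence letters (B, J, O, U, X, Z, `*`) never satisfy an exact
residue, an ambiguity set, or an exclusion set — an exclusion set `{P}` is
compiled as the *positive* class of the 19 standard letters other than P. By
default the `x` wildcard does accept non-standard letters (an unknown residue
is still a residue); `wildcard_nonstandard = FALSE` restricts `x` to the 20
standard letters. Sequences are uppercased on ingest.

Probe files can be PROSITE flat files (`ID`/`AC`/`PA`/`CC` lines, `PA`
continued across lines, records closed by `//`) or plain two-column TSV.
Patterns annotated as highly frequent (the `/SKIP-FLAG=TRUE` comment) carry a
`skip_flagged` marker and can be dropped at load time with
`drop_frequent = TRUE`; such patterns occur so widely that they carry little
classification signal.

## Frequency patterns

For probe $i$ and organism $A$, the frequency is

$$ f_i^A = \frac{\text{total occurrences of probe } i
   \text{ across all proteins of } A}{\text{number of protein-coding genes of } A}, $$

so proteome size cancels out. Occurrences are totalled across proteins
rather than recorded as per-protein presence/absence: a paralog family with
many copies of a functional site is genuinely more committed to that
function, and the total keeps that signal. The gene count defaults to the
number of FASTA records when no annotation is supplied.

The probe-set frequency pattern of an organism is the vector
$(f_1, \dots, f_n)$ over the whole probe set, zero frequencies retained so
all patterns stay aligned. Similarity between two patterns is their Pearson
product-moment correlation coefficient (`pattern_cc`).

For side-by-side visual comparison, `standardize_matrix` replaces every
column of a frequency matrix by its z-scores,
$f_i' = (f_i - \mu) / \sigma$, where $\mu$ and $\sigma$ are the column mean
and standard deviation across organisms. Two choices are fixed here so
output is reproducible bit-for-bit: $\sigma$ is the population
(divide-by-$N$) standard deviation, and a constant column (where the z-score
is undefined) maps to all zeros — the neutral "no signal" value.

## Classification trees

Organisms are clustered agglomeratively. The distance between two frequency
patterns is $1 - \rho$, where $\rho$ is the Spearman rank correlation
(average ranks on ties); rank correlation is used instead of Pearson because
a handful of very frequent probes would otherwise dominate, and $1 - \rho$
is the similarity-to-distance transform conventional in expression-style
clustering tools. Clusters are merged by **average linkage**: the distance
between two clusters is the mean of all between-cluster pairwise distances,
and the closest pair is merged until one cluster remains. The merge height
of each internal node is that mean distance; a child edge's branch length is
its parent's height minus its own, so the tree is ultrametric.

When two cluster pairs are tied at the minimal distance, the pair whose
smallest original-row indices are lexicographically least is merged first.
Ties are genuinely possible with rank-based distances on small probe sets,
and this rule makes the tree a deterministic function of the input matrix.
The implementation is checked against `stats::hclust(method = "average")` on
random (tie-free) matrices: identical merge heights to $10^{-9}$ and
identical topologies.

Trees are rooted (`phylo` objects from the **ape** package), written and
read as Newick; multifurcating input trees are accepted.

## Comparing trees: the traveling distance

Two classification trees over the same organisms are compared through their
**leaf-to-leaf traveling-distance matrices**. For leaves $X$ and $Y$ with
lowest common ancestor (LCA) $Z$: if $X$'s path toward $Z$ passes through
$m$ ancestor nodes before reaching $Z$, and $Y$'s passes through $n$, the
traveling distance is $m + n$. The LCA itself is not counted, so sibling
leaves are at distance 0 and every entry is a small non-negative integer
reflecting pure topology (branch lengths are ignored). Counting the LCA on
both sides instead (`include_lca = TRUE`) adds exactly 2 to every
off-diagonal entry and therefore changes nothing downstream; the option
exists to make that explicit.

The **tree CC** (`tree_cc`) is the Pearson correlation between the two
matrices' upper triangles, with entries paired by leaf label (never by
positional order). Only the upper triangle enters: the diagonal is
identically zero and the lower triangle duplicates the upper, and including
either would distort the correlation. Identical topologies give exactly 1 —
`tree_cc` returns exactly `1` when the aligned triangles are identical, so
the self-comparison is not subject to floating-point rounding — and
independently generated random trees give values centered on 0 (the test
suite checks the mean over 500 seeded pairs of 20-leaf trees against 0 at
three standard errors).

`same_topology` is the exact counterpart: two rooted trees are identical iff
their canonical forms match, where the canonical form sorts every node's
children by their smallest descendant leaf label and ignores branch lengths.

Random binary trees for the null distribution (`random_tree`) are built by
uniform sequential pair-joining of the leaf set under a seed: repeatedly two
subtrees are chosen uniformly at random and joined. This is the natural
seeded generator for an exchangeable null; it is not the uniform
distribution over labeled topologies, which the null claim does not require.

## Synthetic data: what it emulates and what it does not

`synthetic_proteome` emulates the one feature of real proteomes the
classifier consumes: group-structured probe frequencies. A `group_profile`
fixes, for each probe $i$, an expected number $\lambda_i$ of occurrences per
protein-coding gene. Each organism gets `genes_per_organism` background
proteins of uniform random standard residues (configurable to empirical
residue frequencies), and for each probe a Poisson($\lambda_i \times$ genes)
number of concrete match instances — strings sampled uniformly from the
pattern's repeat and residue choices — is planted at random non-overlapping
positions. If the requested rates cannot be placed without overlap the
generator stops and says so rather than silently under-planting.

What this does *not* emulate: real domain architecture (motifs co-occurring
in the same protein in fixed orders), compositional bias of real proteomes,
correlated probe families, or homology between organisms beyond the shared
rate profile. Passing tests therefore demonstrate that the pipeline recovers
planted frequency structure and tolerates random proteome loss — not that
any particular real taxonomy would be recovered.

Default study conditions used by the tests: the two-group recovery check
uses 2 groups of 5 organisms, 40 genes per organism, 8 probes of which each
group "owns" 4 at rate 0.5 occurrences/gene against a 0.02 background rate —
a separation comparable to distinguishing host-associated from free-living
metabolic repertoires. The truncation fixture uses 12 organisms in 4 groups
of 3 (the full-scale experiment used 87 real organisms, 3 per taxonomic
class; 4 × 3 keeps the same 3-per-class design at a size where the whole
grid runs in seconds), 60 genes per organism, and 16 probes.

## Truncation experiments

`truncation_experiment` reproduces the incomplete-genome robustness design.
`truncate_proteome` keeps a uniform random sample of
$\lceil r \times n \rceil$ proteins (retain fraction $r$), without
replacement, and scales the gene count by the same fraction (rounded up) so
frequencies stay calibrated — otherwise truncation would shrink every
frequency by $r$ and the *rank*-based distance would see a spurious global
shift. Removal is at the protein level, since proteins are what the
classifier consumes.

Against the reference tree built from the full proteomes, each replicate
runs two designs:

* **(a) one-at-a-time:** each organism in turn is truncated, the tree is
  rebuilt, and a *precise classification* is scored when the rebuilt
  topology is exactly the reference topology (`same_topology`); accuracy is
  precise classifications over organisms — so per replicate it is always a
  multiple of $1/N$.
* **(b) all-at-once:** every organism is truncated simultaneously and the
  rebuilt tree's `tree_cc` against the reference is recorded.

Means and standard deviations are taken over the replicates (default 10, the
protocol that attaches an error bar to each truncation rate). At $r = 1$
both designs reproduce the reference tree exactly — accuracy 1, CC 1,
standard deviations 0 — and the test suite checks that both measures are
non-increasing across $r \in \{1.0, 0.7, 0.4, 0.1\}$ on the 12-organism
fixture, allowing one standard deviation of sampling noise per step.
Internally the per-protein occurrence counts of each proteome are computed
once and truncations subsample rows of that count table, which is what makes
the full grid cheap; the sampling distribution is identical to truncating
the proteome itself.

## Numerical and design notes

* **Pattern correlation.** `pattern_cc` is the standard Pearson coefficient;
  a zero-variance pattern raises an error rather than returning `NA`.
* **Population vs sample sd in standardization.** Population; fixed for
  bit-reproducibility of standardized matrices.
* **Tie-breaks in clustering.** Lexicographically least pair of smallest
  original-row indices, as above.
* **Degenerate inputs.** Empty sequences match nothing; an all-tied
  frequency pattern has no rank correlation and errors with the offending
  organism pair named; a star tree has a constant (all-zero) traveling
  distance matrix, and `tree_cc` reports the undefined correlation instead
  of guessing.
* **Seeds.** Every generator takes an explicit seed and restores the
  caller's RNG state; derived sub-seeds are drawn below $2^{31}$.
* **Centered correlation.** Some clustering tools optionally use an
  *uncentered* correlation; only the centered (ordinary) Spearman/Pearson
  forms are implemented here.

## Limitations

* Generalized PROSITE matrix profiles (scored profiles) are out of scope;
  profile-only records in a flat file are skipped with a warning.
* `tree_cc` requires both trees to carry exactly the same leaf set — a
  limitation inherited from correlating paired matrix entries.
* The synthetic generator's independence assumptions (see above) make it a
  correctness harness, not a realism benchmark.
* Circular frequency-pattern graphics are not rendered; `standardize_matrix`
  plus any heatmap tool covers that need externally.

## A small worked example

```{r example}
probes <- random_probes(8, seed = 3)
profiles <- list(
  group_profile("host", c(rep(0.5, 4), rep(0.02, 4)), 3, 40),
  group_profile("free", c(rep(0.02, 4), rep(0.5, 4)), 3, 40))
proteomes <- make_group_proteomes(profiles, probes, seed = 4)
m <- build_matrix(probes, proteomes)
round(m[, 1:4], 3)

tree <- build_tree(m)
write_newick(tree)

res <- truncation_experiment(proteomes, probes, retain_fraction = 0.5,
                             replicates = 10, seed = 5)
res
```

The planted two-group structure appears as the root bipartition of the tree,
and at 50% truncation the reclassification accuracy and tree CC quantify how
much of the classification survives incomplete proteomes.
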