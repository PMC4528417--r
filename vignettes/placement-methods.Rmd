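---
title: "Phylogenetic placement of V(D)J rearrangements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic placement of V(D)J rearrangements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An immunoglobulin heavy-chain read is a mosaic: a V gene segment, a short
and heavily edited D remnant, and a J segment, joined with non-templated
(N) nucleotides and exonucleolytic deletions, then diversified further by
somatic hypermutation. Assigning such a read back to its germline V and J
alleles is the first step of repertoire analysis. Pure similarity search
treats every reference allele as an island; `vdjplace` instead exploits
the fact that germline alleles are *related* — they sit on a phylogeny —
and frames assignment as placement of the query on two fixed reference
trees with an unknown switch point between them.

## The model

A candidate explanation of a read is an **attachment model**
$m = (b_V, b_J, x)$: a branch of the V reference tree, a branch of the J
reference tree, and a breakpoint $x$ splitting the read into a V-scored
prefix and a J-scored suffix. Under a time-reversible substitution model,
the likelihood of the full reference tree with the query attached
mid-branch depends on the rest of the tree only through the conditional
likelihood vectors at the two ends of the attachment branch. Scoring a
model therefore reduces to a three-taxon star per segment — the query,
the branch's parent-side "outside" partial and its child-side "inside"
partial — with three free branch lengths $(t_p, t_c, t_q)$ optimised by
maximum likelihood. This equivalence is exact and is enforced by a test
that grafts the query onto the full tree and compares log-likelihoods to
within $10^{-6}$.

Sites that the breakpoint assigns to one segment but that map to the
other region's reference columns are scored as the stationary probability
of the query base *plus* the reference-tree likelihood of their column,
so that every model of a given read is scored on the same data. Omitting
the reference-column term would reward models for pushing sites out of
the scored segment — an instability we observed and removed early on.

Models are compared by the small-sample Akaike information criterion,

$$\mathrm{AICc} = -2\ln L + 2k + \frac{2k(k+1)}{n-k-1},$$

with $k = 7$ (two three-taxon stars' branch lengths plus the breakpoint;
the GTR parameters are fitted once per reference and shared by all
models, so they cancel from comparisons) and $n$ the number of scored
columns, constant across a read's models by the convention above. Every
distinct model evaluated during the search receives an Akaike weight
$\propto \exp(-\tfrac12\,\Delta\mathrm{AICc})$, normalised to sum to one.
Weights are summed by (V label, J label) pair: the top pair is the
reported rearrangement and all pairs with weight $\ge 0.01$ form the
credible set. Branch labels follow two rules: a node with a zero-length
child branch inherits that child's label (a zero branch means an
identical sequence, so the internal node *is* that allele), otherwise a
node carries the most resolved level of the allele>gene>family hierarchy
shared by all its descendant tips. Branch-length optimisers floor edges
near $10^{-8}$; we snap anything below $10^{-7}$ to exact zero so the
first rule fires where it should.

## The search

The model space (branches × branches × breakpoints) is searched with a
CHC-style genetic algorithm: population 32, elitist best-of-union
survival, free (uniform) recombination, incest prevention by a minimum
genome distance whose threshold decays on stagnation, and cataclysmic
restarts that refill the population with mutated copies of the elite
(per-locus resampling probability 0.35). The search stops after three
consecutive restarts without AICc improvement. Two refinements proved
necessary at small population sizes and are part of the package's design:
the initial population is *stratified* across the branch lists (cycling
shuffled branch indices) so that tree coverage does not depend on luck,
and after termination the elite is polished by deterministic coordinate
sweeps — all breakpoints at 1-nt resolution for the elite branch pair,
then every V branch and every J branch at the elite breakpoint — with all
swept models entering the weighted model set. With these, the GA attains
the exhaustive-search optimum on at least 95% of fixture queries (a
tested property), while evaluating a few hundred models instead of
thousands.

The breakpoint window runs from 30 nt upstream of the FW3 3' cysteine
codon to the first query position mapped to a J column: the junction is
where V/J identity actually switches, and the window keeps exhaustive
enumeration (the test oracle) tractable.

## Mapping, junction, D

Before placement, each read is aligned (affine-gap local alignment, both
strands; match 5, mismatch −4, gap open 10, extend 1) against the
MRCA(V)+MRCA(J) concatenation and every \*01 V × \*01 J concatenation;
the best-scoring template fixes orientation, reading frame (inherited
from the codon-aligned reference columns, not estimated from the query)
and the query↔column correspondence used for region segmentation. We use
nucleotide rather than translated scoring for this step: the frame comes
from the template either way, a single alignment engine then serves both
mapping and D assignment, and for substitution-dominated divergence the
rankings agree; the frame-aware part of "codon-aware" is retained where
it matters, in boundary and junction bookkeeping. Reads scoring below a
dinucleotide-shuffle null (mean + 3 SD of 100 shuffles, computed once per
run) can be declared unmappable.

The junction runs from the FW3 3' cysteine codon to the start of the J
region, located by the first `[FW]G.G` amino-acid motif in the J region
or, failing that, the query position of the conserved tryptophan column.
A rearrangement is productive when an in-frame junction exists and the
mapped translation has no stop codon. CDR3 is reported both as the full
junction and as its interior (Cys excluded). D alleles are assigned by
affine-gap Smith–Waterman of the junction against the forward and
reverse-complement D dictionary (match 5, mismatch −4, open 10, extend 1,
minimum score 15 ≈ three matched codons); all alleles tied at the maximum
are reported as equally likely. D assignment by short local alignment is
*expected* to be the weakest link — D remnants are short and eroded from
both ends — and the evaluation suite asserts that degradation rather than
hiding it.

## The simulator

The synthetic-data generator defines the conditions under which the
package's claims are tested.

* **Reference**: 3 V families × 3 genes × 2 alleles (96 codons, the
  usual FR1–CDR1–FR2–CDR2–FR3 layout, FW3 ending in the conserved Cys),
  2 J genes × 2 alleles (15-nt head, then `WGQG…TVSS`), 6 D genes × 2
  alleles of 11–17 nt. Sequences are evolved along the known
  family>gene>allele hierarchy (≈40/14/2–3 substitutions per level), so
  the true tree, the labels and the naming hierarchy agree by
  construction. Every allele carries private substitutions: most tips are
  distinct from reconstructed ancestors, as in a deduplicated real
  reference, while occasional near-zero branches still exercise the
  label-inheritance rule.
* **Rearrangements**: alleles are sampled with inverse-alleles-per-gene
  weights (genes equiprobable); deletion and N lengths are drawn from
  truncated geometric distributions whose means follow published
  junction statistics (≈2 nt off the V 3' end, ≈4 nt off each D end and
  the J 5' end, ≈7 N nucleotides per joint); reads are retained only if
  stop-free, CDR3-recognisable (`C[A-Z]{2,32}W` by default) and in-frame
  with the `[FW]G.G` and `TVSS` motifs present. Empirically inferred
  tables can be substituted via a documented TSV schema
  (`read_length_table()`).
* **Hypermutation**: a 5-mer context model — positions drawn by
  mutability weight (ends clamped to zero, weights recomputed after each
  hit, mutated sites not revisited so the Hamming distance equals the
  requested count), replacement bases drawn from the 5-mer's substitution
  row. The shipped default is uniform (a clearly labelled stand-in);
  real 5-mer tables load from TSV.

What the generator does **not** emulate: sequencing error and indel
hypermutation (substitution-only), P-nucleotides, biased N composition,
unequal gene usage, and the scale and shape of a 282-allele human
reference. Passing tests therefore demonstrate the machinery's
correctness and its qualitative behaviour (V robust under mutation, D
fragile, credible sets growing with divergence), not the exact headline
percentages achievable on the full human reference, which requires
externally downloaded IMGT data.

## Numerical choices

* GTR fitted per region on the fixed topology (ML branch lengths,
  empirical base frequencies) via `phangorn::optim.pml`; the placement
  kernel consumes the eigendecomposition of the normalised rate matrix.
* Per-branch Brent optimisation cycled until the segment log-likelihood
  improves by less than $10^{-6}$ (max 50 cycles), lengths clamped to
  $[0, 10]$, with an explicit zero-length candidate per branch because
  boundary optima (identical sequences) are common and meaningful.
* Joint-ML ancestral reconstruction breaks ties in the fixed order
  A<C<G<T; all-gap columns stay gaps; ambiguity codes are missing data
  throughout (likelihood sums over compatible states).
* Reference columns with identical conditional vectors are collapsed to
  pattern classes per branch; per-node scaling guards against underflow
  on large references.
* Coordinates are 0-based half-open internally, 1-based inclusive in
  TSV output. Equal summed weights tie-break lexicographically.
* Rooting: supplied trees are used as-is; built trees (BioNJ on pairwise
  ML distances) are rooted to maximise the number of monophyletic
  families, ties broken by the longest root branch, midpoint as
  fallback.

## Evaluation conventions

Per region the benchmark table reports: correct-top (truth, up to
synonyms of identical sequence, holds the highest model-averaged
support; for D, membership in the top-score tie set), correct-in-credible,
wrong (with wrong-gene as a subset), and no-assignment. Best assignments
that are internal gene/family-level labels ancestral to the truth are
tallied in their own `ancestral_top` column — the convention for them is
genuinely ambiguous, and folding them silently into either correct or
wrong would hide exactly the phylogenetic behaviour that distinguishes
the method. Clone-level support is aggregated as the unweighted mean of
per-read credible weights (a `sum` option exists). Clonal clustering
connects reads whose credible sets share a (V, J) pair and takes
connected components of the resulting undirected graph (the sharing
relation is symmetric, so "strongly connected" adds nothing).

## Problem sizes

The test suite and `scripts/acceptance.R` run everything against the
synthetic reference: all 54 simple concatenations, 50–60 reads per
deletion/mutation condition, 100 queries for the GA-versus-exhaustive
comparison, and 8–10 clones of 10–12 reads for clustering — sizes chosen
so the whole battery completes on a single CPU while keeping binomial
noise within the tolerances the checks state.

## Known limitations

* Per-query GTR parameters are not re-estimated (bundle-wide fit); a
  codon-model scoring path is out of scope.
* One V/J breakpoint per read: multiple rearrangements or chimeras are
  not modelled; D is handled by alignment only.
* Akaike weights are conditional on the reference: absent alleles can
  attract confident wrong assignments at the allele level.
* J allele (as opposed to gene) resolution on the synthetic reference is
  intrinsically limited: alleles differ by one or two substitutions, and
  J 5' deletions can remove the distinguishing sites entirely.
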