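# vdjplace

Phylogenetic placement of immunoglobulin heavy-chain reads onto germline
V and J reference trees.

## What it does, and for whom

Adaptive-immunity sequencing produces reads that are somatic mosaics of
three germline segments — V, D and J — joined with non-templated
nucleotides, trimmed by exonucleases, and further diversified by somatic
hypermutation. Repertoire analyses (germline gene usage, CDR3 spectra,
clonotype structure) all start by assigning each read back to its
germline V and J alleles. Similarity search handles unmutated reads
well, but germline alleles are phylogenetically related, and at 10–20%
divergence from germline the best-hit allele is often not the right one.

`vdjplace` treats assignment as statistical phylogenetics. A candidate
explanation of a read is an *attachment model* `(b_V, b_J, x)`: a branch
of the V reference tree, a branch of the J reference tree, and a
breakpoint `x` splitting the read into V-scored and J-scored segments.
By time reversibility of the GTR substitution model, the likelihood of
the full reference tree with the query attached mid-branch reduces
exactly to two three-taxon computations with free branch lengths
`(t_p, t_c, t_q)` per segment — so scoring is independent of reference
size. Models are ranked by the small-sample Akaike information
criterion,

    AICc = -2 ln L + 2k + 2k(k+1)/(n-k-1),   k = 7,

searched with a CHC-style genetic algorithm (elitist selection, free
recombination, incest prevention, cataclysmic restarts), and summarised
by Akaike weights: the (V, J) label pair with the highest summed weight
is the call, and all pairs with weight ≥ 0.01 form the credible set —
an uncertainty statement a single best hit cannot give. D alleles are
assigned by affine-gap Smith–Waterman of the junction against forward
and inverted germline D sequences; reads whose credible sets share a
rearrangement are clustered into putative clones.

The package also ships the evaluation machinery: a synthetic germline
generator with a known tree, a V(D)J rearrangement simulator (deletion
and N-length distributions, retention filters, 5-mer context-dependent
hypermutation), and benchmark tabulation against simulated truth.

## Worked example

```r
library(vdjplace)

bundle <- synthetic_bundle(seed = 42)      # reference with a known tree
bundle
#> V(D)J classifier bundle
#>   V: 18 alleles (0 synonyms), tree with 14 internal nodes
#>   J: 4 alleles (0 synonyms)
#>   D: 12 entries (forward + inverted)
#>   provenance: synthetic_germline(seed=42)

sim   <- simulate_repertoire(bundle, n = 5, n_mut = 40, seed = 7)
calls <- classify_reads(sim$reads, bundle, seed = 1)
call  <- calls[["sim00001"]]
```

The first read carries 40 substitutions (about 10% divergence). Its call:

```
best rearrangement: IGHV1-2*01 / IGHJ2*01 (support 0.786)
credible set:
           v        j weight
1 IGHV1-2*01 IGHJ2*01 0.7860
2 IGHV1-2*01 IGHJ2*02 0.0833
3 IGHV1-2*01    IGHJ2 0.0718
4 IGHV1-2*02 IGHJ2*01 0.0252
5    IGHV1-2 IGHJ2*01 0.0245
D call: IGHD2-2*02   CDR3: DDSACCP (7 aa)   productive: TRUE
truth: IGHV1-2*01 / IGHD3-3*02 / IGHJ2*01
```

The true V and J alleles win with 79% of the model-averaged weight; the
alternatives are the sibling allele, the sibling J, and the gene-level
internal branches — exactly the neighbourhood phylogenetic uncertainty
should cover. The D call is wrong: after end-trimming and 40 mutations
the D remnant is a few bases long, and short-alignment D assignment is
expected to fail first (the benchmark table below shows the same).

```r
evaluate_assignments(calls, sim$truth,
                     synonyms = list(v = bundle$v$synonyms,
                                     j = bundle$j$synonyms))
#>   region correct_top correct_in_credible ancestral_top wrong wrong_gene no_assignment n
#> 1      V         100                   0             0     0          0             0 5
#> 2      D          20                   0             0    80         40             0 5
#> 3      J          60                  40             0     0          0             0 5
```

V is recovered on top for all five reads; J is always in the credible
set (allele-level J resolution is intrinsically limited at this
divergence); D degrades sharply — the documented failure mode.

A command-line interface wraps the same functions
(`exec/vdjplace build-ref | classify | simulate | evaluate | cluster |
summarize`); classification emits a per-read TSV and a JSON report with
full credible sets and per-branch supports.

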