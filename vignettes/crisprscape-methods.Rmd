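---
title: "Methods: comparative CRISPR-Cas characterization with crisprscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative CRISPR-Cas characterization with crisprscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprscape)
```

# Scope

`crisprscape` characterizes CRISPR-Cas systems across a set of bacterial
genome assemblies and places them in a comparative-genomics context. It was
developed around the freshwater bloom-forming cyanobacterium *Microcystis
aeruginosa*, a species in which every sequenced strain carries at least one
CRISPR locus, seven direct-repeat (DR) families circulate, and four cas-operon
subtypes (I-A, I-D, III-A, III-B) occur. The pipeline covers:

1. de novo CRISPR array detection (`detect_arrays`),
2. direct-repeat family typing with strand canonicalization
   (`cluster_repeats`) and stem-loop verification (`fold_repeat`),
3. cas-operon subtype assignment from annotated gene neighborhoods
   (`call_subtype`, `type_cas_loci`),
4. spacer dereplication, proto-spacer search, source classification and PAM
   inference (`search_protospacers`, `classify_sources`,
   `build_pam_profile`),
5. a pan-genome layer: 50/50 reciprocal-best-hit orthology, Markov
   clustering, core/pan rarefaction and shared-family matrices,
6. whole-genome relatedness: fragment-based ANI and tetranucleotide z-score
   correlation (TETRA),
7. a synthetic-data generator with ground-truth manifests, so that every
   stage has planted-truth tests.

A reference fixture ships with the package: `reference_loci()` encodes the
per-locus summary of the species' 71 published CRISPR loci (strain, repeat
string, family, unit count, cas gene complement, subtype) and
`reference_repeats()` the 16 distinct repeat strings it contains.

# Array detection

Detection is a deterministic k-mer-seeded repeat chainer. All exact k-mer
pairs (`seed_k = 8`) whose separation lies in
[`min_repeat_len + min_spacer_len`, `max_repeat_len + max_spacer_len`] =
[50, 120] nt seed candidates; k-mers with fewer than three distinct bases are
discarded (homopolymers and microsatellites are the classic false-positive
mode of repeat finders). Every occurrence of a seeding k-mer is chained into
a ladder whose successive gaps fit one repeat plus one spacer, and the common
repeat extent is then fixed by column voting across all units: a column joins
the repeat while at most `tol` units deviate from the column majority
(`tol = 1` with five or more units, else 0) and no unit accumulates more than
`max_repeat_mismatches = 2` off-consensus columns. The defaults
(repeats 24-48 nt, spacers 26-72 nt, at least 3 units) are the canonical
ranges for CRISPR elements; three units is the acceptance rule for a positive
locus.

Remaining choices are deterministic by construction: the consensus is the
per-column majority with lexicographic tie-break; terminal units beyond the
mismatch tolerance are trimmed; chains are split wherever an inter-repeat gap
leaves the spacer bounds (this is what separates two same-repeat arrays 100 nt
apart); and overlapping candidates resolve by most units, then longest, then
leftmost. Orientation is assigned from the conserved repeat 3' terminus:
the repeat families of this species end in GAAAC, except the DR7-like family
which ends in TACAC; if only the reverse complement ends in a known motif the
array is reported on the minus strand with the flipped consensus, and with
neither motif the orientation is `unknown`.

Nearby same-repeat loci are *not* merged in the primary output — draft
assemblies interrupt arrays, and published locus tables count the fragments
separately — but `merge_adjacent_report()` reports which detected loci would
merge within a configurable distance, so both readings are available.

# Repeat families

Repeats are canonicalized across strands (GAAAC terminus preferred, then
TACAC, then the lexicographically smaller orientation) and clustered by
single linkage under at most 2 substitutions after end-gap-free alignment
with at most 2 nt of terminal truncation. Single linkage is deliberate:
single-SNP variants of one repeat must merge transitively into one family,
which is how near-identical variants (e.g. the A/T-to-G/C substitution at
base 24 of the most common family) are treated as a single repeat type.
Family labels DR1-DR7 are anchored on the known canonical strings whenever
they occur in the input, so that cross-referencing against the fixture is
stable; other families are labelled in descending member count.

Secondary structure is checked by base-pair maximization (Nussinov dynamic
programming, minimum hairpin loop 3 nt, Watson-Crick plus GU pairs on the
transcribed sequence) rather than thermodynamic minimum-free-energy folding:
the package asserts only stem-loop *existence*, and an energy model would add
a dependency without changing that qualitative statement. The
maximum-cardinality structure is not unique, so `fold_repeat` runs two
deterministic co-optimal tracebacks (pair-latest and stack-preferring) and
reports the one with the longer contiguous stem. All seven canonical repeat
families fold with a stem of at least 3 bp, consistent with the partially
palindromic repeats expected to form the hairpin recognized by Cas proteins.

# Cas subtype assignment

Typing is annotation-label-driven: genes within `window_bp = 20000` of an
array (a window that covers the longest known operon of this species with
margin) are collected in genomic order, labels are lower-cased, a
"predicted" qualifier is stripped, and double-named markers are normalized
(cas10d to csc3, cmr2 to cas10). The four operon templates ship as editable
JSON (`cas_subtype_templates()`):

* I-A: cas6, cas3, cas8a, cas7, cas5 (+ cas1, cas2)
* I-D: cas3, csc3, csc2, csc1, cas6, cas4 (+ cas1, cas2)
* III-A: cas10, csm3, csm4, csm5, csm6, cas6
* III-B: cas10, cmr3, cmr4, cmr6 (+ cas1, cas2)

The adaptation module (cas1 + cas2) is optional everywhere: its absence never
demotes a call — two strains of the species run complete interference
operons without it — it only clears `adaptation_module_present`.

A locus is called when the best template reaches
`min_core_fraction = 0.75` of its core genes in locally colinear order
(intervening unannotated genes ignored; 0.75 tolerates the draft-assembly
truncation seen when operons split across contig ends while rejecting
single-gene matches). Equal recall resolves to the template with more matched
genes, and a still-tied neighborhood is reported `Incomplete`. Below the
recall threshold one further rule applies: if the neighborhood contains
signature genes that belong to exactly one template (cmr genes for III-B, csm
for III-A, csc for I-D, cas8a/cas7/cas5 for I-A), the locus is called as that
subtype. This rule is forced by the reference data themselves: the published
locus table types one 2-gene neighborhood as III-B while calling other 1-2
gene neighborhoods (bare cas1/cas2) Incomplete, and no flat gene-count rule
reproduces both. With it, re-derived calls match the published subtype column
for all 71 fixture loci.

`dr_subtype_association()` tabulates family-by-subtype counts with an
exclusivity flag per family. On the fixture it reproduces the published
pattern: DR2/DR3/DR4 loci type exclusively as III-B, DR1 as I-D, and DR5
loci carry no typed cas system. Note the published prose swaps DR6 and DR7
relative to the locus table (I-A versus III-A); the package follows the
locus-level data, which is the view the fixture encodes.

# Spacers, proto-spacers and PAM

Spacers are compared on the oriented strand and deduplicated exactly;
`dereplicate_spacers` keeps the full occurrence mapping, so within-genome and
across-genome unique counts are both available.

The proto-spacer search is an ungapped seed-and-extend scan of both target
strands with 11-mer exact seeds, scored +1 per match and -2 per mismatch. The
acceptance thresholds are a raw score of at least 20 *and* at least 25
aligned bp. The +1/-2 scheme is chosen so that "score 20" means exactly "a
20-bp perfect match", which is how the original filter was calibrated; true
BLASTN bit scores of a 20-bp perfect match are not 20 under any standard
Karlin-Altschul parameterization, so the raw-score reading is adopted and
documented here. On each diagonal the maximal segment is exact (maximum
score; ties resolve to the longest, then leftmost segment), which makes the
search agree with a brute-force all-offsets oracle on small inputs. Hits
inside the query genomes' own arrays are removed before any downstream use.

Source classification gives each unique spacer the category of its
best-scoring surviving hit, with score ties resolved phage > plasmid >
bacterial chromosome > environmental, and `none` for spacers without hits;
fractions are reported over all unique spacers and sum to 1. PAM profiles are
position count matrices over the 10-nt flank on the chosen side *on the
proto-spacer strand* (position -1 abuts the proto-spacer 5' end), with
per-position information content IC = 2 - H bits and a consensus letter
where IC >= 0.5. Flanks truncated at contig edges are N-padded and excluded
column-wise.

# Pan-genome layer

Orthology follows the 50/50 rule: an undirected edge joins two proteins iff
they are reciprocal best hits (by local BLOSUM62 alignment score, gap open
11 / extend 1) with at least 50% identity over at least 50% of the length of
*both* proteins. Candidate pairs are prescreened by shared amino-acid 5-mers
— the same word-seeding idea BLASTP uses — so only plausibly homologous
pairs are aligned; best-hit ties break by identity, then protein id. The
published protocol additionally screened by E-value (printed as "E >= 1e-5",
almost certainly a typo for <=); at package scale the explicit
identity/coverage thresholds subsume that screen, so no E-value computation
is made.

Gene families come from a from-scratch Markov clustering (MCL) of the
weighted ortholog graph: self-loops with weight equal to the maximum incident
edge weight (standard regularization that stabilizes convergence on small
graphs), column normalization, then alternating expansion (matrix squaring)
and inflation (elementwise power 2.0 by default, renormalized) until the
matrix moves less than `tol = 1e-6`, with clusters read off as connected
components of the converged non-zero structure. Inflation 2.0 is the
conventional default granularity; pushing inflation toward 1 approaches
connected components and large inflation fragments clusters, and both
directions are covered by tests.

Rarefaction draws `n_perm` random genome orderings under a fixed seed and
reports mean and standard deviation of core (families in all k genomes) and
pan (families in at least one) sizes per prefix length k; monotonicity holds
for every single ordering by construction, and the tests assert it
per-ordering. The shared-family matrix reports
100 x |families in both| / |families in either| per genome pair (the matrix
convention of the reference analysis), *and* the per-genome variant
normalized by each genome's own family count, because the published text
mixes the two; they are labelled distinctly. Strain-specific counts are
reported both as families and as member genes, since "core genome = 2192"
style statements are ambiguous between the two readings.

# ANI and TETRA

ANI is fragment-based: the query is cut into 1020-nt fragments (a trailing
fragment shorter than half length is dropped), each fragment is placed in the
reference by shared 16-mer diagonal voting and locally aligned (+1/-2,
affine gaps 5/2) at its best location on either strand, fragments are
retained iff identity >= 30% over >= 70% of their length, and ANI is the mean
identity of retained fragments. MUMmer-based ANIm implementations leave
their alignment settings implicit; the fragment-based (ANIb-style)
definition is fully specifiable without an external aligner, which is why it
is implemented here — agreement with ANIm values on real genome pairs is
therefore approximate by construction, and the retention parameters are
exposed as arguments.
`species_boundary_report()` applies both published species thresholds (94 and
95%).

TETRA counts all overlapping tetranucleotides on each genome plus its
reverse complement (making the statistic strand-symmetric by construction),
takes expected counts from the maximal-order Markov model
E(n1n2n3n4) = N(n1n2n3) N(n2n3n4) / N(n2n3), forms z = (obs - exp)/sqrt(exp)
— a Poisson variance approximation, simpler than the exact variance and
monotone-equivalent for correlation purposes — and reports the Pearson
correlation of the two 256-long z vectors. Genomes under 50 kb trigger a
stability warning; zero trinucleotide counts set the affected z to 0 with a
warning.

One generator subtlety matters for interpreting the tests: an i.i.d. random
genome has *no* tetranucleotide signature once the Markov expectation is
removed, so z vectors from two halves of such a genome are uncorrelated
noise. The compositional self-similarity that TETRA exploits in real genomes
is therefore emulated by `make_biased_genome()`, an order-3 Markov chain with
seeded, randomly biased transition probabilities: halves of one biased genome
correlate at r > 0.99 while independently seeded biased genomes do not.
I.i.d. genomes anchor the near-zero-correlation expectations instead.

# The synthetic-data generator

`make_genome()` draws i.i.d. bases at 42% GC — the composition shared by all
strains of the modelled species — and `simulate_study()` assembles the full
bundle: one background genome with seven planted arrays (one per repeat
family, alternating strands, unit counts configurable; the defaults exercise
3 through 50 units against the published range of 3-187, and the
13.6-kb 187-unit case is covered by a dedicated test), mobile-element targets
carrying planted proto-spacers with an upstream GTT PAM (the motif reported
for the type I systems of this species), proteomes with planted
core/accessory/unique family structure at 85% within-family identity, and a
JSON-round-trippable manifest of every planted truth.

Planted spacers are rejection-sampled to keep planted-truth tests
single-valued: a spacer shares no 15-mer with the repeat, the background or
other spacers (no accidental proto-spacers or seeds), and the characters
flanking the repeat/spacer boundaries are constrained away from
near-unanimity so that the detector's boundary voting cannot extend a repeat
into the spacers by chance — without this, exact boundary recovery from a
3-unit array would be information-theoretically ambiguous whenever all
spacer-start characters coincide, an ambiguity every repeat detector shares.
`plant_array` overwrites background in place (contig length unchanged), so
manifest coordinates stay valid regardless of planting order.

What the generator does *not* emulate: insertion-sequence landscapes and
repeat-rich real backgrounds, phage genome architecture, within-array repeat
degeneration gradients, assembly gaps inside arrays, and real proteome
length/composition distributions. Passing planted-truth tests therefore
demonstrates correctness of the algorithms under the stated statistical
conditions, not field performance on arbitrary draft assemblies.

# Problem sizes and runtime choices

The shipped tests run detection on 30-150 kb genomes with up to 187 planted
units, false-positive screening on a 1-Mb random genome, oracle comparisons
on 100 spacer/target pairs (spacers 29-50 nt, targets 200 nt), PAM recovery
over 200 planted proto-spacers, the pan-genome recovery at 6 genomes x 250
proteins (1500 proteins, 500 planted families), and ANI/TETRA on 40-60 kb
genomes with a 300-400 kb biased genome for the signature test. These sizes
were chosen to exercise every code path at full statistical fidelity while
keeping the whole suite in the minutes range on a single core.

# Known limitations

* Detection assumes assemblies, not reads, and treats N as matching nothing;
  arrays interrupted by gaps surface as separate loci (see
  `merge_adjacent_report`).
* Cas typing trusts annotation labels; it performs no profile-HMM search, so
  unannotated or creatively labelled cas genes are invisible to it.
* The proto-spacer search is ungapped; an indel inside a proto-spacer splits
  the hit into diagonals that must pass the thresholds separately.
* ANI here is ANIb-style, not ANIm; absolute values on real genome pairs can
  differ from MUMmer-based tools by a few tenths of a percent.
* MCL uses dense matrices, which is the right trade-off at the package's
  design scale (thousands of proteins) but not for millions.
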