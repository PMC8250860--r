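---
title: "Methods: trait-association pan-genome screening with stalkscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-association pan-genome screening with stalkscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Some marine iron-oxidizing bacteria (Zetaproteobacteria such as
*Mariprofundus*) excrete twisted stalks — ribbon-shaped organo-mineral
fibers — while close relatives instead produce "dreads" or amorphous iron
oxides. When a morphological trait like this segregates cleanly across a
collection of sequenced isolates, the genes behind it can be hunted with a
pan-genome screen: cluster all proteins of all genomes into ortholog
families, then extract the families present in **every** trait-positive
genome and absent from **every** trait-negative genome. stalkscan implements
that screen end to end, together with the supporting analyses such a study
needs (AAI relatedness, pan-genome openness, synteny of candidate cassettes,
short-motif conservation, COG enrichment), and a synthetic-community
generator that provides planted ground truth for all of it.

## The model and its stages

### Alignment kernel

Every similarity decision rests on one kernel: optimal global alignment with
affine gap penalties (Gotoh algorithm) and **free terminal gaps**, under
BLOSUM62 with gap open 11 and gap extension 1 — blastp's defaults. Free end
gaps make the kernel behave like blastp on near-full-length homologs while
remaining a deterministic, exactly testable dynamic program.

Conventions the literature leaves open are pinned here:

* **percent identity** = identical residues / aligned columns of the core
  region (terminal gap columns excluded; internal gap columns count as
  mismatch columns);
* **coverage** = percentage of a sequence's residues inside the core aligned
  region, reported for query and subject separately;
* **tie-breaking** in the traceback: diagonal > up > left, gap closure
  preferred over extension; at the boundary, the corner cell is preferred,
  then the last row right-to-left, then the last column bottom-up. Ties can
  produce co-optimal alignments with different identities, which is why the
  brute-force oracle in the test suite checks the score exactly and the
  identity against the set of co-optimal values.

Non-standard residue letters (B, Z, J, U, O) are mapped to `X`, scored by the
matrix's `X` column, and never counted as identities.

### Pre-clustering and the similarity graph

Following the CD-HIT-then-MCL architecture of pan-genome pipelines, a greedy
longest-first pass first absorbs near-identical redundancy (identity >= 95%,
mutual coverage >= 90%); representatives then enter an all-vs-all similarity
graph with an edge wherever identity >= the threshold under study.

Two numerical choices matter here:

* **k-mer prescreen.** All-vs-all alignment is gated by shared 4-mers. Two
  unrelated proteins of lengths La and Lb share about La·Lb/20^4 distinct
  4-mers by chance, so a candidate pair must exceed that background by four
  standard deviations (plus a margin of two). This sets the prescreen's
  detection limit near 40–45% identity for typical 300-residue proteins: a
  pair at p identity shares about L·p^4 true 4-mers, so pairs at >= 50%
  essentially never miss, while homologs below ~40% are deliberately left to
  the dedicated distant-homolog search, which aligns without any prescreen —
  the same two-stage treatment the screen applies biologically (sub-threshold
  homologs are "absent" for the presence/absence rule and recovered
  afterwards).
* **graph-stage coverage floor (40%).** With free terminal gaps, two
  unrelated proteins can align a short segment above 30% identity; requiring
  both coverages >= 40% removes those spurious edges. The floor is kept
  deliberately below the 70% audit threshold so that split-gene fragments
  (an assembly artifact where one gene is divided across two contigs, with
  ~45–55% coverage against full-length homologs) still cluster with their
  family. Coverage is then *audited*, not filtered, downstream: families
  failing 70% mutual coverage are flagged and retained, because a split gene
  is evidence of an artifact, not of absence.

### Markov clustering

Families are read off the similarity graph with MCL at inflation 1.5. Only
the inflation value is canonical; the remaining numerics are pinned for
reproducibility: self-loop weight equal to the node's maximum incident edge
weight, expansion by matrix squaring, entries below 1e-5 pruned after
inflation, convergence when the maximum elementwise change drops below 1e-6
(at most 100 iterations, with a warning and the current interpretation on
non-convergence). Clusters are read from attractor rows; attractors with
mutual positive flow merge, and every other node follows its largest flow,
ties resolved toward the lexicographically smallest node id. Because MCL flow
can never cross connected components, components are clustered independently;
the test suite checks the implementation against a literal whole-matrix
reference iteration on graphs up to 12 nodes.

### The trait screen

At each identity threshold in the sweep (default 30–90% in steps of 10), the
screen returns families with members in all trait-positive genomes and none
in any trait-negative genome. "Absent" means zero members *at that clustering
threshold* — no secondary sensitive re-search — and the union report over the
30–80% range (the 90% tier excluded, where families fragment below the
all-positives requirement) is the headline candidate list. Both gene and
family counts are reported per threshold and for the union, since a "gene
count" is ambiguous when paralogs and split genes exist.

Two follow-ups complete the screen: the coverage audit described above, and a
distant-homolog search that reports, per candidate family and outgroup
genome, the best hit with identity in [floor, ceiling) (defaults 20–40%) and
coverage >= 50% — the tool for asking whether trait-negative relatives carry
diverged copies of the candidate cluster.

### Synteny

Candidate genes are grouped into cassettes: maximal runs along a contig with
at most `max_gap` (default 1) intervening non-member genes, using the
locus-rank order that the loader assigns from coordinates. Order conservation
across genomes compares family-order signatures up to full reversal (clusters
are drawn strand-normalized; individual strands are reported but not part of
the signature). A genome whose members sit on two cassettes — the split-gene
case — is flagged "fragmented" and judged by its largest fragment rather than
failing the synteny call.

### AAI and genome relatedness

Average amino-acid identity between two genomes is the mean identity of
reciprocal best-hit protein pairs passing 30% identity and 70% coverage,
where coverage is measured on the shorter sequence of the pair (the
CompareM-style convention; the tool's own definition is undocumented, so this
is pinned and configurable). Best hits rank by identity, then score, then
lexicographic gene id. Genome clustering applies Bray-Curtis dissimilarity to
AAI profile rows — each genome's vector of AAI values to all *other* genomes,
excluding the self and mutual entries of the pair — followed by average
linkage (UPGMA), ties broken toward the lexicographically smallest label
pair. Whether the original analysis used Bray-Curtis of profiles or
`1 - AAI/100` directly is not recoverable from its description; both are
implemented (`method = "braycurtis"` default, `"identity"` alternative).
Species-rank groups are connected components at AAI strictly above 95%.

### Pan-genome openness

Accumulation curves record pan and core sizes over random genome orderings
(default 100 permutations, one master seed). Heaps' law is fit by ordinary
least squares of log(median pan size) on log(N); the pan-genome is called
open when the exponent gamma exceeds 0.01 — the qualitative open/closed
statement needs a numeric rule, and 0.01 separates fitting noise from real
growth at desk scale.

### Motifs and conservation

Candidate proteins are scanned for the literal short motifs associated with
c-di-GMP binding (RxxD, RxxxR) and glycosyltransferase activity (QxxRW, DxD,
TED). Letters are standard one-letter amino-acid codes — where the source
literature's parenthetical glosses conflict with the codes (e.g. "RxxD
(glutamine-…)"), the one-letter code wins: R is arginine. `x` matches any of
the 20 standard residues, never a gap; all occurrences including overlapping
ones are reported (TED and DxD overlap by construction); positions are
1-based on the ungapped sequence, with a helper to map them into MSA column
space. Conservation counting uses a center-star multiple alignment (center =
sequence with the best summed pairwise score; "once a gap, always a gap"
merging) and reports columns where all rows agree on one residue with no gap.

### COG enrichment

COG categories are consumed as a gene-to-letters table (assignment itself
needs the CDD database and is out of scope). Enrichment of a category in a
pan-genome subdivision is a two-sided Fisher exact test on the 2x2 table of
assigned genes, Benjamini-Hochberg corrected across all tests of one call;
genes with several categories count toward each. Degenerate margins return
p = 1 with a flag instead of failing.

## The synthetic community

The generator emits what the screen assumes the world looks like, at the
study's design point: 11 trait-positive and 5 trait-negative genomes (2
"dread" + 3 "amorphous"), ~200 genes each at test scale (150 core families,
60 phylogenetically patterned accessory families — contiguous blocks over a
fixed genome ordering — and 10 strain-specific genes per genome), protein
lengths lognormal with median 300 aa, and on top of that:

* a **planted six-gene cluster**, contiguous and order-conserved in every
  positive genome, member identities drawn from 55–75% — mid-range
  conservation, matching a candidate cluster detectable at a 50% threshold
  but fragmenting by 80%;
* a **five-gene neighbor cassette** directly adjacent to the cluster, present
  in all positives, four of the five families also in the dread genomes and
  the fifth in one amorphous genome — conserved context that must *never*
  enter the trait-unique set;
* **decoy families** present in all positives plus exactly one negative, the
  near-miss controls for the screen's negation rule;
* **distant homologs** of every cluster family in the dread genomes at
  25–38% identity — below the screen's world but inside the
  distant-homolog-search window;
* a **split-gene artifact**: in one positive genome, one cluster gene is
  divided into an N-terminal (~55%) and C-terminal (~45%) fragment on two
  different contigs, the C-terminal part keeping the cassette position.

Divergence is substitution-only over a *family-wide set of variable
positions*: every member re-randomizes the same positions, so pairwise member
identity tracks the family target (rather than its square, as independent
mutation would give) and coverage stays at 100% — the split gene is the only
coverage perturbation by design, which isolates what each filter is being
tested on. Distant homologs mutate a superset of the family's variable
positions, so homolog-member identity tracks the homolog target. Realized
identities are recorded in a truth ledger sufficient to score sensitivity and
specificity of every stage without re-alignment.

What the generator does **not** emulate: tree-structured gene gain/loss,
indels and length variation within families, composition bias, paralog
families, mobile elements, or annotation errors beyond the single split gene.
A green test therefore establishes that the pipeline's logic is correct on
data satisfying its assumptions — not that the screen is robust to messy real
annotations.

## Numerical and design choices in brief

* Partial-sequence filter: proteins < 40 aa or with internal stops are
  removed before clustering (the upstream convention is "removed partial
  sequences" without a number; 40 aa is configurable).
* Pre-cluster thresholds 95%/90% — tight enough that only near-identical
  redundancy merges, leaving threshold-sensitive divergence to MCL.
* AAI exactness holds in the >= 70% identity regime, where the optimal
  affine-gap alignment of a substitution-only mutant stays gap-free; below
  ~65% occasional compensating gaps shift aligned identity from the Hamming
  identity by a fraction of a point.
* All randomness (generator, permutations) flows through one integer seed;
  two runs with the same configuration are byte-identical.
* Newick export writes ultrametric branch lengths (merge height h = depth
  h/2) and quotes labels containing reserved characters.

## Known limitations

* The similarity graph's prescreen misses genuine homology below ~40%
  identity by design; analyses that need those edges (e.g. a 30% threshold
  tier on fast-evolving families) inherit the limitation, and the
  distant-homolog search is the supported route to such pairs.
* Paralogs are kept in one family (no synteny-based paralog splitting), and
  the screen counts a genome "present" from one member regardless of copy
  number.
* Center-star MSA is a 2-approximation, adequate for counting conserved
  columns in small, highly similar candidate families, not a general MSA
  replacement.
* The pipeline is protein-level throughout; nucleotide-level analyses
  (core-genome alignment, dN/dS) are out of scope.
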