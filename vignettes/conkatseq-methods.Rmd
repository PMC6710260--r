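---
title: "Inferring clustered biosynthetic domains from amplicon co-occurrence in partitioned clone libraries"
author: "conkatseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring clustered biosynthetic domains from amplicon co-occurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Soil metagenomes encode enormous numbers of biosynthetic gene clusters
(BGCs) — notably nonribosomal peptide synthetase (NRPS) and polyketide
synthase (PKS) systems — most of which belong to genomes too rare to
assemble from shotgun reads. Cosmid libraries capture this DNA as ~38 kb
inserts that preserve local gene order, and are arrayed as hundreds to
thousands of subpools of thousands of clones each. `conkatseq` exploits a
simple consequence of that design: two loci that sit close together on a
chromosome are frequently *co-captured* on the same insert, so their PCR
amplicons co-occur across library subpools far more often than chance.
The package turns degenerate-primer amplicon surveys of conserved domains
(adenylation, ketosynthase, and similar targets) into networks of domain
variants predicted to be physically clustered, and hence into recoverable,
potentially novel BGCs.

## The statistical model

For every pair of domain variants the package forms the 2x2 table of
subpools containing both, one, or neither variant. Under the null of
independent dispersal across the $N$ subpools, the number of co-occupied
subpools $n_{11}$ is hypergeometric given the margins, and the evidence
for physical linkage is the right tail

$$p = \Pr(X \ge n_{11}), \qquad
X \sim \mathrm{Hypergeom}(N,\; n_{11}+n_{10},\; n_{11}+n_{01}),$$

computed by direct summation of log-space binomial coefficients
(log-gamma), accurate for libraries of thousands of subpools. Only the
enrichment direction indicates linkage, hence the one-sided test. Pairs
sharing fewer than 3 subpools are not tested — they cannot reach
significance and dominate the pair count — and the multiple-testing family
is the set of pairs actually tested. P-values are adjusted with the
two-stage Benjamini–Krieger–Yekutieli step-up (stage 1: Benjamini–Hochberg
at $q' = q/(1+q)$; its rejection count estimates the true nulls; stage 2:
BH at $q'\,m/(m-r_1)$). The adjusted value reported per pair is the
smallest level $q$ at which the two-stage procedure rejects it, so the
single decision rule "adjusted $p < 10^{-6}$" is well defined; the
inversion is computed exactly (see the numerical notes below).
Significant pairs become edges;
connected components of three or more variants are reported as domain
networks.

## From reads to the occurrence matrix

Paired-end reads carry a column barcode (forward) and a row barcode
(reverse) addressing the 24 x 16 = 384 wells of a PCR plate. Assignment
requires a unique best barcode match on both axes within a configurable
Hamming budget (default 0 — for 8–12 nt barcodes exact matching is the
conservative choice); reads with `N` in the barcode window are left
unassigned, and unassigned reads are reported by category, not dropped
silently. Only the forward read is carried into analysis: after the
barcode is stripped it is truncated to a fixed `total_len` and the first
`primer_len` bases (spacer + degenerate primer) are removed, so every
retained read is an equal-length, primer-free domain sequence; shorter
reads are discarded. Coordinates are 0-based half-open internally.

Reads are dereplicated per subpool and clustered greedily at 95% global
identity: distinct sequences are processed in decreasing total-abundance
order (ties broken lexicographically) and each joins the first centroid it
matches, otherwise founding a new cluster. Centroids are static — no
re-centroiding — which makes the procedure deterministic and idempotent on
its own centroids. Identity is identical aligned columns over all
alignment columns (gaps included, end-to-end alignment at match +1,
mismatch −1, gap −2 per position). For equal-length sequences the
clusterer screens candidates by exact Hamming identity and runs the full
dynamic program only for centroids within 0.05 identity below the
threshold; sequences further below cannot plausibly clear it with gaps.
This mirrors the prescreen heuristics of the standard centroid-clustering
tools while keeping every reported identity an alignment identity.

Three filters then remove noise: (i) member sequences with fewer than
`min_reads` total reads (default 2 — the per-domain cut-offs used on real
data are experiment-specific, so this is a required configuration value
with a documented default); (ii) member sequences with fewer than 5% of
the centroid sequence's reads, the classic signature of PCR/sequencing
error shadows (the centroid itself is exempt); (iii) clusters spanning
fewer than 3 distinct wells, which cannot support co-occurrence
inference. The result is the variant x subpool occurrence matrix; tables
from different primer systems over the same library are merged row-wise
for joint analysis.

## Network post-processing and similarity scoring

Sequencing error and microheterogeneity can split one locus into several
near-identical nodes of a network. `merge_similar_nodes` merges same-type
nodes above 90% identity by single linkage within each network, keeping
the highest-read centroid, unioning subpool sets and collapsing parallel
edges to their smallest adjusted p-value. The ≥3-node size filter is
applied after merging: merging is an anti-redundancy step, and a
"network" that collapses to two distinct domains no longer meets the
reporting unit. Merging never crosses domain types, since cross-type
amplicons are non-homologous.

Networks are compared to reference BGC protein sets by translating each
centroid (auto-frame: fewest internal stops, ties to the lowest frame) and
aligning locally under BLOSUM62 (gap open 11, extend 1), keeping hits
covering at least 80% of the query. Instead of the E-value gate a
database-calibrated aligner would apply, classification rests entirely on
the coverage and identity thresholds; this avoids pretending to a
database-size calibration that has no bearing on threshold-based
decisions. "Independent positions" is operationalised as: two nodes may
not claim intervals with more than 25% reciprocal overlap on the same
protein. The best combination of matches maximises total identity under
that constraint, solved exactly by branch-and-bound (exhaustively verified
on small instances in the tests). If at least half the network's domains
are assigned, the similarity score is the median percent identity over
*all* domains with unmatched domains entering as zeros — the reading under
which "taking non-matching domains into account" does something — and a
switch (`count_unmatched`) exposes the alternative. Networks score as
"known" at ≥75% median identity to any reference; two networks from
different samples are "closely related" when at least 50% of one's domains
match the other's at ≥90% identity (evaluated from one side — the relation
is intentionally asymmetric for unequal network sizes). Validation against
assembled contigs maps each centroid to both strands at the nucleotide
level and counts nodes at ≥93% identity (≥80% query coverage) as validated
clustering predictions; validated + false always equals the node count.

## The simulator

The simulator is the package's source of ground truth. It generates a
community of genomes with log-normal abundances (the field's usual
stand-in for skewed species-abundance distributions; the shape is
configurable), places one or more BGCs per genome as runs of domains
spaced 2–8 kb apart, and materialises sequence only for the domain
amplicons (independent random DNA, mutually far below every clustering
threshold). Clones draw a genome proportional to abundance, a uniform
insert start, and a truncated-normal insert length (mean 38 kb, clamped to
20–45 kb), and are dealt round-robin over a random permutation into
fixed-size subpools — exact dealing, matching physical arraying; a Poisson
alternative would only blur subpool sizes. Detection applies i.i.d.
per-(domain, subpool) dropout, a deliberate simplification of
amplification bias that errs toward false negatives, which is the failure
mode the statistical design tolerates. Read mode expands every detection
into barcoded read pairs with per-base substitution errors on the domain
sequence (no indels, so fixed-length trimming semantics hold; barcodes are
emitted error-free — barcode errors only shrink assignment counts and are
accounted by the demultiplexing report). Both emission modes draw the
detection table identically for a given seed, which is what makes the
read-level pipeline exactly comparable to the direct matrix.

Default study conditions follow the two library structures the method was
designed around — 2304 subpools of ~5000 cosmids (`preset = "arizona"`)
and a desk-scale benchmark of 384 subpools of 1000 clones with 20
single-BGC genomes (`preset = "small"`). One generator value is not
dictated by those structures: the simulated genome size. It is set to
5 Mb, a mid-range soil bacterial genome, so that the scaled-down benchmark
(≈14.6 Gb of cloned DNA) reproduces the detectability regime of the
full-scale libraries (hundreds of Gb): rare community members sit near,
but mostly above, the ≥3-subpool evidence threshold. The closed-form
companion of the design is the co-capture probability
$\max(0, (L-d)/L)$ for loci $d$ apart and inserts of length $L$, which
the simulated libraries reproduce empirically.

Recovery is scored by mapping retained variants back to true domains
(exact sequence match, falling back to ≥95% identity): precision over all
predicted pairs against co-resident truth, recall against the
*detectable* truth — pairs co-captured in at least `min_shared` subpools —
because pairs the library never exhibits are not failures of the
statistics. Pairs whose variants map to the same domain (split variants)
are excluded as non-claims; an empty prediction reports precision 1 with
an explicit zero-support flag.

What the simulator does not model: chimeras, quality-score structure,
vector/host contamination, indel sequencing errors, cross-contamination
between subpools and index switching. Passing the simulated benchmarks
therefore demonstrates the correctness of the statistical machinery and
the read-processing plumbing under the stated noise model, not robustness
to every artifact of real libraries — the latter is exactly why the
validation-against-contigs path exists.

## Numerical and design choices

* Fisher tails are summed in log space; all tables with $N \le 30$ are
  checked against independent tail enumeration to $10^{-12}$ relative
  error in the test suite.
* The two-stage FDR adjustment is inverted in closed form: with
  $b_i$ the ordinary BH q-values and $t_r = b_r/(1-b_r)$ the level at
  which stage 1 first rejects $r$ hypotheses, rank $i$'s adjusted value
  is $\min_r \max(t_r, g_i(r))$ where $g_i(r)$ solves the stage-2
  condition with equality; the two branches cross monotonically, so all
  thresholds are located in one vectorised pass. Adjusted values are
  capped at 1 when no level up to 1 rejects; the tests verify the
  inversion against a brute-force run of the procedure at perturbed
  levels.
* Greedy clustering tie-breaks: equal-abundance sequences are processed
  in lexicographic order, making cluster identities reproducible.
* Degenerate inputs: empty read sets, empty candidate-pair sets and empty
  networks flow through as empty results, never errors; unknown variants
  and malformed schemes fail loudly.
* Deterministic outputs: network ids are the lexicographically smallest
  member variant; exports are byte-stable for identical inputs.
* The test-suite problem sizes (384-subpool libraries of 76k–384k clones,
  read sets of ~60k pairs, 100-fold null calibrations at 500x384) were
  chosen as the smallest instances that still exercise every code path at
  realistic occupancy levels.

## Known limitations

* The default `min_reads = 2` filter is a placeholder for
  experiment-specific read-count cut-offs; real surveys should set it
  from their sequencing depth.
* The mismatch tolerance of barcode demultiplexing on real data is
  unspecified upstream; the exact-match default is conservative and
  configurable.
* Whether published network counts precede or follow node merging is
  ambiguous; this package applies the size filter after merging and
  documents both orders as computable.
* Read-mode simulation addresses a single 384-well plate; multi-plate
  experiments are assumed demultiplexed by sample index upstream.
* The similarity scorer's assignment is exact only within practical
  network sizes (tens of nodes with few candidate hits each); degenerate
  adversarial instances would fall back to long branch-and-bound runs.
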