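---
title: "Methods: detecting IAA signaling genes and their co-occurrence structure"
author: "phycosignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting IAA signaling genes and their co-occurrence structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Indole-3-acetic acid (IAA) is an auxin that bacteria and eukaryotic
phytoplankton exchange as an interkingdom signal: bacteria synthesise
IAA through three routes whose last-step enzymes are indoleacetamide
hydrolase (IAM pathway), indoleacetaldehyde dehydrogenase (IPA
pathway) and indoleacetonitrile nitrilase (IAOx/IAN pathway), and the
algal cell cycle responds through an IAA-regulated cyclin. In an
algal–bacterial bioreactor metagenome, reads carrying these genes mark
the *signaled* fraction of the community, and the question of interest
is whether signaled bacteria dominate the positive co-occurrence
structure between bacteria and phytoplankton.

`phycosignal` implements the complete inference chain as testable R
code: reference-database construction, translated homology screening,
RPKM quantification, genus-level LCA taxonomy, and thresholded Spearman
co-occurrence networks ending in the signaled positive-edge fraction.

# Reference database construction

Curated protein FASTA files — one per gene subtype — are parsed with
`read_protein_fasta()` and made non-redundant per subtype with
`dedupe()`, a greedy incremental clustering in the cd-hit style:
records are sorted by length (descending, ties broken by id for
determinism) and each record joins the first cluster whose
representative it matches at identity ≥ 0.97, otherwise it founds a
new cluster. Identity here is the *clustering* convention: identical
positions on the optimal global-overlap alignment divided by the
length of the shorter sequence. Clustering never crosses subtype
boundaries, because the subtype is the unit of downstream
quantification. The default threshold of 0.97 is exposed as a
parameter; representative sets shrink monotonically as the threshold
drops, and clustering is idempotent — both properties are enforced by
tests.

The alignment behind this identity uses a match/mismatch scoring
(match 1, mismatch 0, free gaps) rather than an affine-gap model:
at curation scale the heuristics that make cd-hit fast do not change
the answer, and the simple model makes the denominator convention
explicit.

# Translated homology screening

Each read is translated in all six frames (`six_frame_translate()`),
frames are split at stop codons, and fragments shorter than 8 aa are
discarded; codons containing `N` translate to `X`. Every fragment is
aligned against every reference with Smith–Waterman local alignment
under BLOSUM62 with affine gaps (open 11, extend 1) — an exact search
rather than a seeded heuristic, which is feasible at the read counts
this package targets and removes any dependence on an external
aligner. Alignment is delegated to `Biostrings::pairwiseAlignment()`
and is cross-checked in the test suite against an independent
textbook dynamic-programming implementation.

Raw scores are converted to E-values with the Karlin–Altschul formula
`E = K·m·n·exp(−λS)` using the standard gapped BLOSUM62/11/1
parameters λ = 0.267 and K = 0.041, with `m` the fragment length and
`n` the total residue count of the reference database. No effective
search-space correction is applied, so E-values differ slightly from
BLASTX output; the annotation rule is insensitive to this at the
E ≤ 1e-5 cutoff because true hits score orders of magnitude below it.

A read is annotated with the subtype of its best hit (highest bit
score; ties broken by lower E-value, then reference id) only when that
hit has identity **strictly** above 50% and alignment length
**strictly** above 25 aa; the E-value filter is inclusive (≤ 1e-5).
Identity at this stage is the *reporting* convention — identical
positions over all alignment columns, gaps included — which differs
deliberately from the clustering identity above. A read carries at
most one subtype. Up to ten passing hits per read are retained for
taxonomic binning.

# RPKM quantification

Subtype abundance per sample is the sum over references of
`count × 10⁹ / (3·L_aa × total_reads)`: protein lengths are converted
to coding-nucleotide lengths (×3) so that magnitudes are comparable to
nucleotide-gene RPKM. The per-million denominator is the sample's
**total clean reads**, not the annotated reads: the screened gene set
is tiny, and normalising by annotated reads alone would make the unit
degenerate. This choice is configurable through the `totals` argument
of `subtype_abundance()`.

# Genus-level LCA taxonomy

Each annotated read's top hits pass through three MEGAN-style filters:
hits below bit score 50 are dropped; only hits within 10% of the best
retained score survive the top-percent filter; and surviving hits are
mapped to the genus of their reference (references without a genus
tag are dropped). The read is placed on the lowest common ancestor of
the surviving genera. Min-support is interpreted as a **fraction** of
the sample's placed reads (an absolute count of 0.01 would be
meaningless): nodes whose support is strictly below 0.01 have their
reads promoted, in a single leaf-to-root pass, to the nearest ancestor
meeting the threshold. Reads resting above genus rank are reported
UNCLASSIFIED, mirroring the genus-only reporting of the study design.
Promotion order under min-support is not uniquely defined in the
MEGAN literature; the single-pass rule used here is deterministic and
monotone (raising min-support never increases genus-level
assignments, a tested property).

References are mapped to taxa via their `genus=` header tag rather
than a protein-accession-to-taxid service, keeping the pipeline
self-contained; the taxonomy itself is a user-supplied TSV in
NCBI nodes/names form.

# Co-occurrence networks

Genus abundance series across samples feed pairwise Spearman
correlations, restricted to bacterium–phytoplankton pairs (the
networks of interest are bipartite; intra-kingdom correlations are
never computed). An edge requires `|ρ| > 0.6` **and** `p < 0.01`,
both strict; negative correlations are kept with their sign. The
magnitude reading of the threshold is forced by the presence of
negative edges in the downstream partition.

Spearman's ρ is the Pearson correlation of ranks (tie-corrected). The
two-sided p-value uses the **exact permutation distribution** when
n ≤ 9 — all n! permutations are enumerated — and the t approximation
with n − 2 degrees of freedom otherwise. The exact route matters
because the reactor designs this method targets have as few as six
samples, where the t approximation is anti-conservative. A
consequence worth knowing: at n = 4 the smallest achievable two-sided
exact p is 2/24 ≈ 0.083, so no edge can pass p < 0.01; the method
needs n ≥ 5 (ideally more) to produce edges at the default
thresholds, and `build_network()` refuses n < 4 outright.

Network metrics follow the NetworkAnalyzer definitions: density
`2E/(N(N−1))`; heterogeneity, the coefficient of variation of degree
(population variance); centralization `(N/(N−2))(d_max/(N−1) − density)`;
closeness per node as reachable-count over summed shortest-path
lengths within components; and Stephenson–Zelen information
centrality from `C = (D − A + J)⁻¹` per component,
`I_i = 1/(C_ii + (tr C − 2 rowsum_i C)/N)`. Isolated nodes take
closeness and information centrality 0. The node set of a constructed
network is the edge-incident genera (as in an imported edge list);
`network_metrics()` accepts any `signaling_network`, including ones
with isolated nodes added explicitly. All five metrics are verified
against a brute-force oracle (exhaustive BFS, direct matrix
inversion) on random graphs in the test suite.

The headline statistic, `signaled_positive_fraction()`, partitions
positive edges by the signaled status of their **bacterial** endpoint
and reports `100 × n_signaled / (n_signaled + n_non-signaled)` to two
decimals. Phytoplankton flags do not affect the partition. With the
published counts of 26 signaled and 11 non-signaled positive pairs
this evaluates to 70.27%.

No multiple-testing correction is applied to the edge tests by
default, matching the practice this pipeline reproduces; users who
want control of the network-wide error rate can filter the returned
edge table by `p.adjust(edges$p, "BH")` themselves.

# The synthetic community generator

`simulate_fixture()` produces fully self-contained fixtures: a toy
rank-complete taxonomy; reference proteins per subtype with
genus-tagged variants; per-sample reads; and genus abundance series
with planted correlation structure. Defaults describe a small
bioreactor-style community: 12 samples, 150 nt reads, 200 reads per
sample, five signaled bacterial genera (Pseudomonas carrying the IPA
dehydrogenase, Hydrogenophaga, Zoogloea and Serratia the IAM
hydrolase, Variovorax the nitrilase), seven non-signaled bacteria,
and three phytoplankton with Chlorella as the signaled alga. Gene
variants diverge from genus-specific parent proteins at 2% amino-acid
mutation rate; reads carry 0.5% sequencing error. Gene-bearing read
counts scale with the genus's abundance series around a mean of 25
per genus per sample.

Two generator choices deserve explanation. First, genus variants are
derived from *private* parent proteins that are not emitted into the
reference set: emitting a 98%-identical parent/variant pair would
collapse under 0.97 clustering and strip the genus tag that taxonomy
depends on. Non-redundancy clustering is instead exercised by an
explicitly planted ~99%-identity untagged duplicate per subtype.
Second, abundance series use a log-normal latent-factor model — every
phytoplankton genus carries a per-sample factor `F ~ N(0,1)`, coupled
bacteria load on it with ±1 and log-noise sd 0.3 — so that Spearman
detection of a planted pair is a genuine statistical event that
exercises the p-value path, rather than a rank construction that
would pass trivially.

What the generator does **not** emulate: real genome structure, GC
content and coverage biases; homology between background reads and
real protein families (background is uniform-random nucleotide, which
makes screening precision testable but optimistic); shared evolution
among references of one subtype (parents are independent random
proteins, so cross-genus hits are rarer than in real data, making the
LCA's top-percent filter less stressed than it would be on real
reads); and reactor chemistry. Passing tests therefore demonstrate
correctness of the inference chain under controlled truth, not field
performance on environmental metagenomes.

Problem sizes in the tests were chosen to exercise every code path at
desk scale: the shared unit fixture uses 6 samples × 60 reads; the
end-to-end recovery checks use the full default community
(12 × 200 reads); fraction recovery uses 24 samples × 50 replicates
per planted fraction. The planted-truth recovery criteria — genus
recall ≥ 0.95, precision ≥ 0.99, planted fraction recovered within
±0.1 — hold with wide margins (observed ≈ 0.998, 1.0, ±0.002).

# Degenerate inputs and numerical notes

* Constant abundance series are an error for `spearman()` and are
  silently skipped as candidate edges by `build_network()` (no rank
  correlation is defined for them).
* `signaled_positive_fraction()` errors on a network without positive
  edges rather than returning 0/0.
* Centralization is undefined below 3 nodes and errors.
* The exact-permutation comparison uses a 1e-12 slack on |ρ| so that
  floating-point noise cannot drop permutations tied with the
  observed statistic.
* All generators are pure functions of `(config, seed)`; identical
  seeds give byte-identical output files.

# Pipeline orchestration

`pipeline_config()` validates every threshold against its documented
range, and `run_stage()`/`run_pipeline()` enforce stage order
(refdb → screen → abundance/taxonomy → network), erroring with the
name of the missing upstream stage. Every output file carries a
`# config_hash=` header naming the md5 of the configuration that
produced it, and reruns with the same configuration are
byte-identical. The R functions are the interface; no shell wrapper
is provided because the package is meant to be driven from R scripts
and analyses.

# Known limitations

* The exact Smith–Waterman search is quadratic in read × reference
  volume; the design target is planted-truth validation and
  moderate-size screens, not tens of millions of reads.
* E-values lack BLAST's effective-length corrections (documented
  above); absolute E-values should not be compared against BLASTX
  output to the decimal.
* The LCA stage resolves only to genus, by design.
* Network inference assumes exchangeable samples; autocorrelated
  time-series designs will overstate significance.
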