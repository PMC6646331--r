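---
title: "phytonet: methods, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phytonet: methods, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Traditional herbal medicine supplies long lists of phytochemicals with
anecdotal efficacy against complex diseases such as epilepsy, but no
systematic account of *which* constituent acts on *which* human protein.
Network pharmacology attacks this by combining chemical similarity,
drug-likeness filters, multi-source target prediction and graph analysis of
the resulting compound–protein–drug networks. phytonet implements that
cascade as a reusable pipeline: each stage is an exported, unit-tested
function; a seeded generator produces synthetic versions of all eight input
tables with planted ground truth, so every stage is verifiable without
access to curated proprietary databases.

## Chemical similarity

### SMILES handling

A native parser covers the organic subset, aromatic lowercase atoms,
bracket atoms with explicit hydrogens and charges, branches and ring
closures. Canonicalization uses Morgan-style iterative neighborhood
refinement with full individualization branching on residual ties, taking
the lexicographically smallest emitted string. This guarantees that
chemically identical inputs (same molecular graph) map to one canonical
form and that the map is idempotent — both are tested properties.

**Deliberate limitation:** no aromaticity perception or kekulization is
performed. Aromatic flags are taken as written, so `c1ccccc1` and
`C1=CC=CC=C1` are distinct records. Identity checks throughout the package
compare canonical forms, never raw strings, but only at the level of the
SMILES graph as written. Real-world libraries mixing kekulized and aromatic
writings of the same molecule would need upstream normalization; the
synthetic generator emits internally consistent forms, so planted truth is
unaffected.

### Path fingerprints

Fingerprints follow the FP2 contract: all linear paths of 1–7 heavy atoms
are enumerated; each fragment encodes elements, aromatic flags, charges and
bond orders, reading direction canonicalized; single-atom fragments that
are plain C, N or O are excluded; each distinct fragment is hashed to one
bit of an `n_bits = 1024` set. The hash is a plain polynomial rolling hash,
chosen for cross-platform, cross-session stability (tested). Bit-exact
agreement with any particular OpenBabel build is *not* promised — the
original tool's hashing is unpublished — which is why similarity
thresholds, not exact TC values, drive all downstream screens. Both
`n_bits` and the fragment length cap are exposed.

Correctness is established against an independent exhaustive
path-enumeration oracle (a deliberately naive list-growing enumerator in
the test helpers) on molecules of up to 12 heavy atoms.

### Tanimoto and degenerate inputs

`TC = |A∩B| / (|A|+|B|−|A∩B|)`. When both fingerprints are empty the
printed formula is 0/0; phytonet defines the value as **0 with a warning**.
Rationale: a fragment-free species (e.g. elemental phosphorus) should not
appear maximally similar to another fragment-free species. `TC = 1` holds
iff the bit sets are equal and non-empty (tested identity).

### Clustering

Compound trees use agglomerative clustering on distance 1 − TC. The
linkage is configurable (`single` default, `complete`, `average`); the
field tool chain this emulates does not document its linkage, so phytonet
picks the simplest and exposes the choice. Ties on merge distance are
broken by the lexicographically smallest member id — `stats::hclust` is
deliberately not used because its tie handling depends on input order.
Trees are ultrametric: a node merging at distance *d* sits at elevation
*d*/2, and branch lengths are elevation differences, so two leaves merging
at *d* each get a branch of *d*/2.

## Drug-likeness screen

All inequalities are strict, exactly as the protocol words them: MW < 500
Da, HBD < 5, HBA < 10, logP < 5, Caco-2 score > 0.9, intestinal absorption
> 30 %, hepatotoxicity and Ames both negative. The common "one Lipinski
violation allowed" relaxation is **not** applied, because the protocol
phrases all four rules as requirements; thresholds are configurable if a
user wants the relaxed variant. ADMET values are consumed as annotations
(the predictive models that produce them are out of scope). Records with
missing descriptors are marked unevaluable (`passed = NA`) and reported,
never silently dropped. The screen is a pure function of the record;
monotonicity (worsening any property never flips fail→pass) is a tested
property.

## Target consensus

Per-source thresholds: BindingDB-style interaction score ≥ 0.85 and
STITCH-style confidence ≥ 0.4 (both inclusive, per the printed wording),
SwissTarget-style "top-15" implemented as a rank cutoff `rank ≤ 15` — a
probability column, if present, is carried through untouched. Protein
identity is normalized to upper-case accessions with isoform suffixes
stripped; gene symbols are converted through an explicit mapping table, and
no network lookups ever happen. Votes are the number of distinct sources
asserting a pair; raising any threshold can only lower votes (tested
monotone property), and no pair is lost or duplicated in the merge (tested
conservation property).

## Networks

`layered_network` wraps igraph with typed layers; intra-layer edges are
rejected except where explicitly allowed (PPI). Choices worth recording:

- **STRING score scales.** Exports occur both as 0–1 probabilities and
  0–1000 milli-scores; any score > 1 in the input switches the whole
  column to the milli-score reading (divide by 1000) before thresholding.
- **Provenance.** The pool → mapped → interacting → giant-component
  bookkeeping is emitted as a structured report at each stage rather than
  log prose.
- **Giant component ties** are broken by edge count, then smallest node
  id; the operation is idempotent (tested).
- **GraphML round trips** are exact: attribute types (integer/logical NAs
  included) are recorded in a graph attribute and restored on read,
  because GraphML itself has no NA.

## Network statistics

- **Betweenness** is exact, with fractional credit among tied shortest
  paths, normalized by 2/((n−1)(n−2)). On disconnected graphs it is
  computed per component but normalized globally, and the report is
  flagged. Graphs with fewer than 3 nodes get 0 with a warning. Equality
  with a brute-force shortest-path enumerator is tested on random graphs
  of ≤ 12 nodes.
- **Power-law fits** use OLS on (log₁₀ k, log₁₀ n_k) over raw degree
  counts — not cumulative, not log-binned — matching the convention of
  log-log degree-distribution plots. Maximum-likelihood estimators are a
  deliberate non-goal. A noiseless planted histogram must be recovered to
  1e−9; a multinomially resampled one to 0.1 (both tested).
- **MCODE** is implemented natively in its three published stages: vertex
  weighting (highest k-core of the closed neighborhood × that core's
  density), seeded growth admitting neighbors with weight ≥
  (1 − node_score_cutoff) × seed weight, and post-processing (k-core
  check, iterated haircut, optional fluff). Parameters default to the
  canonical plugin values (degree cutoff 2, node score cutoff 0.2, k-core
  2, max depth 100, haircut on, fluff off) and are fully exposed, since
  module counts are parameter-sensitive. Each node joins at most one
  module; seeds and orderings are tie-broken by node id, so output is
  deterministic (tested). Planted cliques over a sparse background must be
  recovered exactly (tested).

## Selection cascades

NM-proteins are the DPC targets lying in the configured nervous-system
pathways *and* in the approved drug-target list; the pre-intersection set
is also reported. The D/D1/D2 datasets follow directly. The
drug-similarity screen applies the dual criterion — TC > 0.85 and TC ≠ 1
with non-identical canonical SMILES. The protocol's wording admits two
readings; phytonet defaults to the **per-pair** reading (both conditions
must hold for the same compound–drug pair), which is the stricter one, and
exposes `criteria = "per_dpc"` for the alternative (a compound with any
identical drug twin is then excluded outright). Hit sets shrink
monotonically in the TC threshold (tested).

The AED overlap uses votes ≥ 2 on both sides by default, mirroring the
high-confidence convention of the consensus networks, and flags compounds
that cover an AED's complete filtered target set. Module back-mapping
attaches every compound–protein edge incident to a module's members,
retaining vote attributes, and flags compounds targeting ≥ 2 members.

## The synthetic world

The generator's defaults mirror the emulated study's stated scale: 63
herbs, 1,993 raw phytochemicals deduplicating to 867 unique structures,
2,337 drugs of which 40 are AEDs, a 1,179-protein disease gene pool (half
supplied as symbols through the mapping table), 10 nervous-system
pathways, and three prediction sources with rows deliberately straddling
every threshold. Molecules are random hetero-atom chains of 16–28 heavy
atoms with occasional branches and double bonds: chemically meaningless,
but valid, canonicalizable, and similarity-controllable — a single
terminal-atom substitution on such a chain lands TC in (0.85, 1), which the
generator verifies post hoc and records. Planted near-duplicates are wired
end-to-end (ADMET pass forced, an above-threshold prediction to an
NM-protein, the base drug targeting the same protein), so the
drug-similarity cascade must recover exactly them; the PPI contains
planted cliques over an Erdős–Rényi background (p = 0.004, clique edges
scored ≥ 0.9).

What a green test therefore establishes: the pipeline's *mechanics* —
deduplication, threshold logic, vote merging, graph construction, module
detection, cascade set algebra — are correct against planted truth. What
it does not establish: that real phytochemical libraries behave like
random chains (they do not: real molecules have rings, stereochemistry,
tautomers, and similarity distributions with heavy tails), nor that the
emulated study's headline counts are reproduced (those depend on its
curated supplementary tables, which are not redistributable; the spec's
quantitative target list is accordingly empty).

One top-level seed fans out to per-table sub-seeds through an affine map
kept below 2³¹, so regenerating one table does not perturb the others, and
generation is byte-deterministic under a fixed seed (tested).

## Known limitations

- No kekulization/aromaticity perception (see above); no stereochemistry
  (stereo markers parsed and ignored); disconnected SMILES (`.`) rejected.
- Hash folding to 1024 bits can collide fragments; TC values are therefore
  approximations of fragment-set Tanimoto, as in every folded fingerprint.
- The canonicalizer's individualization branching is exponential on
  pathologically symmetric graphs (irrelevant for drug-like molecules).
- ADMET predictors, docking, structure modelling, GO enrichment and
  pathway-map rendering are out of scope by design; their outputs are
  consumed as annotations where relevant.
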