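---
title: "XLinkMS methods: distance validation of cross-links and the companion quantifications"
author: "XLinkMS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{XLinkMS methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(XLinkMS)
```

## Scope and model

XLinkMS operates downstream of spectrum-level cross-link identification.
Its unit of data is the *unique lysine–lysine connection*: an unordered
pair of (accession, residue) endpoints, supported by one or more
cross-link spectrum matches (CSMs), optionally carrying a search score
and an FDR estimate. Identification itself — spectral search, decoy
handling, FDR estimation — is out of scope; tables are consumed as
produced by the search engine.

The structural model is deliberately minimal: a structure is a set of
chains, each an ordered list of residues with author numbering and a
single Cα coordinate (the highest-occupancy conformer when alternates
exist, ties broken by altloc identifier). A cross-link is validated by
the Cα–Cα Euclidean distance between its endpoints against a maximum
distance restraint; 35 Å is the default, the accepted bound for the
DSBSO cross-linker (spacer arm plus two lysine side chains). Solvent-
accessible surface distances and NZ–NZ variants are intentionally not
implemented: Cα–Cα against a generous bound is the field's standard
first-pass validation and needs no side-chain modeling.

## Endpoint canonicalization and deduplication

Cross-links are undirected, so every record is stored with its endpoints
in lexicographic order by (accession, residue). All downstream counting
is defined on this canonical form, which makes deduplication a plain
group-by and guarantees orientation invariance (asserted
property-style in the tests). When duplicate rows collapse, CSM counts
are summed; for the scalar evidence fields the best value is kept
(maximum score, minimum FDR) — a deterministic choice where upstream
semantics are unspecified. FDR filtering is inclusive
(`fdr <= threshold`): "reported at 2% FDR" conventionally includes the
boundary. Percent-dialect FDR columns (maxima above 1) are rescaled to
fractions when auto-detection is enabled, because supplementary-table
dialects vary.

Multi-accession endpoint fields (shared peptides) take the first
accession and flag the row; protein-group-aware inference is out of
scope and would change the unit of counting.

## Chain assignment and homo-oligomer ambiguity

Protein sequences rarely match coordinate files exactly — tags,
truncations, renumbered chains. Each chain's residue sequence (from the
3-letter codes) is globally aligned (Needleman–Wunsch, BLOSUM62, gap
open 10, extend 0.5) against every candidate protein; the chain is
assigned to the best protein whose identity — exact matches over the
protein length — reaches `minIdentity`. The default 0.9 tolerates
engineered tags and point mutants while rejecting paralogs, which in
vacuolar complexes (e.g. V-ATPase proteolipids) can exceed 50% identity
but must not cross-assign. The per-copy residue map follows the aligned
columns (gaps excluded), so author renumbering and internal deletions
are reconciled without any external numbering service.

A protein may own several chains — homo-oligomer copies. A cross-link
endpoint then maps ambiguously, and the package resolves the ambiguity
by the **minimum distance over all admissible copy pairings**, including
cross-copy pairings of intra-protein links (a residue is never paired
with itself). Minimum-distance resolution is the field-standard,
most-permissive reading: a link is counted violated only if *no*
placement explains it. The per-link enumeration is exposed in the tests,
which assert the chosen distance never exceeds any enumerated pair.

Links that cannot be placed are never silently dropped: the mapping
status distinguishes `protein_absent` (no chain assigned to the
accession) from `endpoint_missing` (no copy has the residue with a Cα).
Agreement is `nSatisfied / nMapped` — unmappable links are excluded
from the denominator, since an agreement statistic describes links the
structure can actually test. With nothing mapped the agreement is
reported as absent (`NA`), never 0. The satisfaction boundary is
inclusive (`distance <= 35` counts), the deterministic choice where the
behaviour exactly at the bound is not otherwise specified.

Distance histograms use left-closed right-open bins starting at 0, with
a default width of 5 Å (configurable; fine enough to show the
restraint shoulder, coarse enough not to be noise at typical link
counts).

## Docking restraints and model ranking

For integrative docking a restraint must be unambiguous, so each link is
pinned to one (chain, residue) pair per endpoint — the first copy in
canonical chain order that covers the residue. The exported line dialect
is

```
assign (segid A and resid 12 and name CA) (segid B and resid 80 and name CA) 35.0 35.0 0.0
```

target 35 Å, lower margin 35 (effective lower bound 0), upper margin 0:
"anything up to 35 Å satisfies". The numbers are configurable since
docking-server defaults differ; the dialect is round-trip parseable and
byte-stable, which the tests exercise.

Candidate models are scored by mapping every link (`nEvaluated` is the
number that mapped) and ranked by satisfied count descending, total
violation `sum(max(0, d - 35))` ascending, then model id — a total
order, so any permutation of the input ranks identically and a fully
satisfied model always ranks first.

## Interaction network

Only inter-protein links create edges; a self-pair is evidence about a
protein's fold, not an interaction. Edge weight is the number of unique
residue pairs, with CSM totals carried as an attribute rather than the
weight — two distinct cross-linked residue pairs are stronger evidence
for an interface than one pair seen twice. Nodes are restricted to
proteins with surviving edges (a drawable interactome);
`keepIsolated = TRUE` reverses this. `minLinks` filters weakly supported
edges and is monotone by construction.

## SILAC enrichment statistics

A replicate's heavy/light ratio is computable only when both channel
intensities are positive; there are no pseudocounts, matching upstream
quantification with re-quantification disabled. Log2 ratios are
median-centred per replicate by default — the standard assumption that
most proteins are unchanged — and the planted-shift test asserts the
centring removes an injected offset exactly.

The per-protein test is an equal-variance two-tailed Student's *t*. Two
groupings are provided because "heavy vs light" can mean either: the
default `two_group` mode compares log2 heavy intensities against log2
light intensities across replicates; `one_sample` tests the replicate
log2 ratios against 0. Both require 2 usable replicates per group;
proteins below that are flagged, not dropped silently. Degenerate inputs
are handled by contract rather than NaN: zero pooled variance with zero
difference gives p = 1, with nonzero difference the numerical floor.
Significance tiers follow the volcano-plot convention — red p < 1e−14,
orange p < 1e−4, blue p < 0.05, strict boundaries, raw p-values. A
Benjamini–Hochberg column is emitted for reference but never gates the
tiers, which mirror how such volcano plots are annotated. Label-swap
concordance negates the reverse orientation's ratios and reports the
Pearson correlation and sign-agreement fraction over shared proteins
(at least 3 required).

## Image quantification

Background subtraction is the flat-kernel realisation of rolling-ball:
grayscale morphological opening with a disc of the given radius
(default 50 px, configurable — large enough that puncta and membrane
rings are never eaten). The morphology is computed on the image rescaled
to [0, 1] and mapped back, so absolute intensity scales are preserved.
ImageJ's paraboloid variant differs in detail; the contracts that matter
(flat fields map to 0, features narrower than the ball survive, local
contrast over a smooth gradient increases) are asserted in tests.

The Otsu threshold maximizes between-class variance over a 256-bin
histogram scaled to the image min–max; the mask is *strictly above* the
threshold; ties resolve to the lowest threshold; 3-D stacks are
thresholded per volume. An exhaustive 256-level search oracle verifies
the threshold on every tested image. Manders coefficients default to the
thresholded (JaCoP-style) definition,
`M1 = sum(A[maskA & maskB]) / sum(A[maskA])`, bounded in [0, 1] and
invariant under positive channel scaling; the plain variant
(denominator over all of A) is selectable. Line profiles sample by
bilinear interpolation at uniform arc length and are min–max normalized
per channel within the profile (a constant trace degenerates to zeros
by contract). The membrane/cytosol ratio divides the mean along a
membrane polyline by the average of three circular cytosolic region
means — exactly three, as the quantification is defined. Marker-defined
regions are connected components of the marker's Otsu mask
(8-connectivity in 2-D, 26 in 3-D) of at least 5 pixels, a floor that
suppresses shot-noise specks.

## The synthetic-data generators

Every generator is a pure function of its parameters and a master seed;
substreams are derived per generator name so stages can be re-seeded
independently. The generators emulate the *structure* of each input
class, not its full realism:

* **Complexes** are 3.8 Å fixed-step random walks (the Cα virtual bond
  length) with ~8% lysines, the typical yeast frequency. Chains may
  self-intersect — only pairwise distances matter downstream. Copies are
  exact rigid transforms, so copy superposition RMSD is 0 by
  construction. Proteins are offset 40 Å apart so that lysine pairs
  populate both sides of the 35 Å restraint.
* **Cross-link tables** plant satisfying links at mapped distance
  ≤ 33 Å and violating links at > 37 Å (a 2 Å guard band so remeasurement
  is unambiguous), plus decoys referencing absent proteins. The planted
  satisfied fraction is therefore exact, and the tests assert exact
  recovery.
* **SILAC tables** are log-normal intensities with a per-protein base
  abundance and N(0, 0.25²) replicate channel noise on the log2 scale;
  enriched proteins carry a log2 effect of 2 on the heavy channel,
  sign-flipped in the reverse orientation. Effect 2 / SD 0.25 / 3
  replicates corresponds to a noncentral-*t* power near 1 at α = 0.05,
  which the tests verify against the closed-form oracle.
* **Images** are Gaussian puncta (σ 1.5 px, peak 1) with additive
  Gaussian noise (default SD 0.01, i.e. SNR 100) and a planted overlap
  fraction, or an annular ring at a planted multiple of a uniform
  background with polyline/disk ROIs in the sidecar.

What passing these tests does *not* show: robustness to real detector
noise models, chromatic shift, uneven illumination, realistic missed
cleavages or protein-inference ambiguity, or conformational ensembles —
all explicitly outside the generators' scope.

## Problem sizes and runtime choices

The test suite and the acceptance script run at desk scale by design:
complexes of 2 proteins × 200 residues (≈ 30 lysines), 50-link planted
tables, 1000-protein SILAC tables with 3 replicates, 128-px images, 20
seeds for the Manders recovery loop. These sizes put every planted
quantity well inside its sampling tolerance while keeping the whole
suite under a minute on one CPU.

## Known limitations

* Distances are Cα–Cα only; no SASD or side-chain-aware variants.
* One accession per endpoint; protein groups are truncated to their
  first member.
* Conformational ensembles are not handled — a single coordinate set is
  a single hypothesis, and mapping against a structure captured in one
  state can legitimately violate links formed in another.
* The restraint exporter pins ambiguous endpoints to the first copy in
  chain order; when copies are not equivalent this choice is logged but
  may not be the energetically relevant one.
* The 95%-scale agreement numbers reported for real interactome
  datasets require those datasets and their reference structures;
  within this package such values are exercised on synthetic complexes
  with planted truth.
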