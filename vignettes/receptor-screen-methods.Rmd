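---
title: "Methods: the mast-cell immunoreceptor candidate screen"
author: "ReceptorScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the mast-cell immunoreceptor candidate screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ReceptorScreen)
```

## The screening problem

Mast cells respond to their environment through surface immunoreceptors,
and new regulators of mast-cell activation are most likely to be found
among genes that (i) are expressed in mast cells, (ii) encode single-pass
membrane proteins with the extracellular domain families typical of
immunoreceptors — the immunoglobulin-like (Ig-like) superfamily and the
C-type lectin-like (CLECT) family — (iii) carry intracellular signaling
capability, and (iv) are preferentially expressed in mast cells relative
to other leukocytes, in more than one species. ReceptorScreen implements
this discovery funnel as a reusable, fully tested pipeline. The canonical
positive control is the angiopoietin receptor Tie2 (gene *Tek*): an
Ig-like ectodomain, a single transmembrane helix and a cytoplasmic
protein-tyrosine-kinase domain, enriched in mast cells of both human and
mouse.

The funnel evaluates four per-gene predicates in order:

1. **Expressed in human mast cells.** The gene's aggregated human
   mast-cell (MC) expression must strictly exceed a threshold (default 0
   on the supplied normalized values — the weakest defensible reading of
   "expressed"; the cutoff is a config knob because the appropriate value
   depends on the upstream quantification).
2. **Receptor family.** A CDD-style domain hit whose label belongs to the
   Ig-like or CLECT label set must lie (mostly) in the extracellular
   region.
3. **Signaling capability.** The cytoplasmic region must carry an ITAM,
   ITIM, ITIM-like or PI3K-binding motif, or a catalytic PTKc/PTPc
   domain.
4. **Mouse abundance.** The mouse ortholog's MC expression — the maximum
   over the MC microarray samples — must be strictly greater than 100
   normalized units.

Survivors are ranked by cross-cell-type specificity in both species.

## Expression aggregation and the specificity score

A cell type's expression is defined as the **maximum** over that cell
type's samples (the aggregation used for the mouse microarray compendium;
mean and median are available but non-default). For a gene $g$ with
aggregated values $E_{MC}$ and $E_c$ for comparison cell types
$c \in C$, the specificity score is the average fold change

$$ S(g) \;=\; \frac{1}{|C|} \sum_{c \in C}
   \frac{E_{MC} + \varepsilon}{E_{c} + \varepsilon}. $$

The comparison panels default to T cells, B cells and monocytes for human
and to T, B, monocytes, NK cells, dendritic cells and macrophages for
mouse — the non-MC panels of the cross-cell-type comparison. The
pseudocount $\varepsilon$ (default 1, in the same normalized units as the
matrix) keeps the ratio defined when a comparison cell type reads zero;
at $\varepsilon = 0$ the score is exactly scale-invariant, and the
$\varepsilon \to 0$ limit recovers the plain fold-change average whenever
all denominators are positive (both properties are enforced by tests).
The score is reported on the linear scale exactly as defined; a log2
companion column is available and clearly labelled as a convenience.

Human and mouse scores are combined by **geometric mean** (default).
This choice was open: nothing in the funnel's definition fixes how the
two species are merged into one ranking. The geometric mean is symmetric
in the species and penalizes genes whose specificity is carried by one
species only; `combine = "min"` offers the conservative alternative.
Ties in the ranking break lexicographically by gene id so that reruns are
reproducible.

## Membrane topology

Motif scanning and family assignment need to know which residues are
extracellular and which cytoplasmic. An explicit topology table always
takes precedence; it is validated to tile each protein exactly. When no
table covers a protein, a deliberately simple fallback predictor is used:
Kyte–Doolittle hydropathy averaged over a sliding window of 19 residues;
maximal runs of window centers with mean above 1.6 (merged across gaps of
up to 3 centers) become transmembrane candidates; candidates are trimmed
symmetrically into the 15–30-residue band plausible for a membrane helix,
or discarded if shorter than 15; the strongest surviving candidate (by
peak window mean) is kept, assuming single-pass type-I architecture —
N-terminal flank extracellular, C-terminal flank cytoplasmic. Multi-pass
proteins are out of the predictor's scope: they are handled only through
explicit topology tables, because the screen targets single-pass
immunoreceptors. A 19/1.6 window/threshold pair is the classical setting
for membrane-helix detection; both are exposed in the configuration.

A geometric consequence worth knowing: with a 19-residue window, a
hydrophobic stretch must be at least about 21 residues long (with
ordinarily hydrophilic flanks) before a full ≥15-center run of
above-threshold windows can form. The synthetic generator therefore
plants 21-residue helices.

## The motif grammar and scanner

Signaling motifs are expressed in a small pattern language: `Y` a single
residue, `[LI]` a residue class, `x` the wildcard, `x(6,12)` a bounded
spacer. The built-in set is

| motif | pattern | class |
|---|---|---|
| ITAM | `Yxx[LI]x(6,12)Yxx[LI]` | activating |
| ITIM | `[ILSV]xYxx[LV]` | inhibitory |
| ITIM-like | `[ILSTV]xYxx[ILV]` | inhibitory |
| PI3K-binding | `YxxM` | activating |

These are the standard consensus definitions; all four can be overridden
from a YAML motif config, including adding an ITSM (`TxYxx[VI]`) if a
broader inhibitory definition is wanted. The scanner reports **every**
distinct (motif, start, end) span, instantiating each spacer at every
feasible length rather than collapsing to the shortest match — downstream
logic only needs existence, and the exhaustive convention makes the
scanner a pure function that an independent brute-force matcher can check
exactly. Matches are confined to cytoplasmic segments, and the unknown
residue `X` matches only the wildcard, so unreadable sequence never
creates signaling evidence. Kinase/phosphatase capability is taken from
the domain-hit table (PTKc/PTPc labels, majority-cytoplasmic by the same
overlap rule), not re-derived from sequence.

## Domain-family assignment

A hit supports a family when its label is in the family's label set and
at least `minOverlap` (default 0.5) of its span lies within extracellular
segments. The 50% default is symmetric and testable; the label sets
(`IG`, `IGc1/2`, `IGv`, `V-set`, `C1/C2-set`, `I-set` for Ig-like;
`CLECT`, `C-type lectin-like` for CLECT) are conventions over CDD-style
labels and fully configurable, since family nomenclature varies between
annotation snapshots. When one protein carries support for both families,
both support sets are recorded and the reported class follows the hit
with the smallest e-value, ties resolving to Ig-like; this tie-break is
documented rather than meaningful, and affects reporting only — the
family predicate passes either way.

The funnel operates on genes, using one representative protein per gene
(the longest isoform, ties broken by protein id). Isoform-level screening
would need per-isoform expression, which neither input provides.

## What the synthetic generator emulates

`generateFixture()` builds a complete, self-consistent study: proteins
with planted ectodomain/TM/tail architectures, domain hits, a topology
table, paired human and mouse expression matrices with sample maps, an
ortholog map and a ground-truth manifest. Its defaults are the package's
fixed study conditions:

* 100 genes; 5 true receptors; 5 designated failures for each of the four
  stages; the remainder background.
* Human: MC/T/B/Mos with 3 samples each (RNA-seq-like); mouse: the
  seven-cell-type panel with 2 samples each (microarray-like duplicates).
* Per-sample noise: cell-type mean × lognormal(0, σ), σ = 0.25 — positive
  and right-skewed, which is all the threshold/ratio-based rules are
  sensitive to.
* True-receptor MC enrichment follows geometric tiers 4 × 1.8^(i−1)
  (≈ 4, 7.2, 13, 23, 42). The tiers are spaced so that the intended
  specificity ordering remains identifiable under the sampling noise; the
  strongest tier also receives the receptor-kinase (Ig-like + cytoplasmic
  PTKc, Tie2-like) architecture.
* Mouse baselines for genes that must clear the abundance stage are drawn
  from 60–120 so that MC means land well above the 100-unit boundary;
  designated mouse-stage failures get an MC mean of 30. Because the
  designated verdict is a construction guarantee rather than a noise
  outcome, MC samples that drift across the boundary are rescaled back
  (to ≤95 or ≥105 respectively).
* Background and flanking sequence is drawn with a hydrophilic bias but
  every residue has positive probability, so spurious motif hits occur at
  a known, nonzero rate — tests must exercise the compartment rule, not
  rely on motifs being absent by construction. Designated signaling
  failures are the one exception: their tails are tyrosine-free, which
  makes "fails exactly the signaling stage" deterministic since every
  built-in motif and both catalytic classes require evidence the
  generator controls.

Everything is a deterministic function of the spec and seed, to the byte.
`perturbFixture()` applies single, recorded modifications (lower the
mouse abundance, drop an ortholog, move a motif into the ectodomain,
flatten MC enrichment to an exact target fold change) for
cause-and-effect tests.

What the generator does **not** emulate: read-level RNA-seq or
probe-level microarray structure, normalization artifacts, correlated
noise between cell types, realistic CDD e-value distributions, paralogy
(the ortholog map is one-to-one by construction). Passing tests on these
fixtures therefore demonstrate the correctness of the screen's logic —
filters, aggregation, scoring, ranking — on inputs with known truth, not
the biological recall of the screen on real compendia.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere.
* Thresholds are strict (`>`): a mouse MC maximum of exactly 100 fails.
* A protein with no cytoplasmic segment yields an empty motif-hit table,
  not an error; zero funnel survivors yield an empty ranked table plus a
  warning, not an error.
* Division by zero in the specificity score is refused with an
  instruction to set a positive pseudocount, rather than silently
  returning `Inf`.
* Sequences shorter than the hydropathy window cannot be segmented by the
  fallback and are rejected with an instruction to supply a topology
  table.
* Genes without an ortholog, or absent from the mouse matrix, fail the
  mouse stage and are reported in the run log; nothing is imputed.

## Problem sizes used in the checks

The package's property checks run the scanner against an exhaustive
independent matcher on 10,000 random 50-residue tails and 200 random
grammars, verify the specificity closed form on 1,000 random profiles to
1e-12, and run the full screen on twenty 100-gene fixtures for funnel
monotonicity and byte-level determinism plus one fixture with 5 planted
receptors and 20 designated failures for exact recovery. These sizes give
each property thousands of independent trials while keeping a complete
run of the suite comfortably on a laptop.

## Known limitations

* Absolute survivor counts on a real transcriptome are not reproducible
  from this package alone: they depend on the raw sequencing data and
  its quantification, the domain-database snapshot that produced the
  hits, and the exact motif table in force. The package reproduces the
  *procedure*, with every such constant exposed in the configuration and
  covered by tests.
* The fallback topology predictor is intentionally minimal; for real
  proteomes a dedicated TM predictor's output should be supplied as the
  topology table.
* Motif consensus definitions differ between sources; the defaults are
  standard but the config file is the authoritative place to encode a
  particular study's definitions.
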