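---
title: "Methods: reference-anchored motif evolution analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-anchored motif evolution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifshift)
```

# The analytical problem

Given a set of orthologous proteins — say IRF5 sequences from sharks to
songbirds — and a handful of functionally characterized regions annotated
on one well-studied reference (a nuclear export signal, a serine-rich
phosphorylation region, a three-residue DNA-binding-domain signature),
the questions are positional: is the *homologous* window in each ortholog
still there, does it still satisfy the functional sequence pattern, how
conserved is each column, and on which branches of the species tree did a
signature motif change state?

`motifshift` answers these with five cooperating components: pairwise
alignment + coordinate lifting, consensus scanning, conservation
profiling, parsimony on a taxonomy, and structure-level checks. A seeded
simulator generates families with known ground truth so that every claim
the pipeline makes can be verified mechanically.

# Region lifting through pairwise alignment

Every ortholog is aligned to its subfamily reference with an optimal
global alignment (Needleman–Wunsch with affine gaps), and annotated
windows are mapped through the alignment's column correspondence.

Design choices, and why:

* **Pairwise-to-reference rather than one multiple alignment.** Lifting a
  reference interval only requires reference–query homology, and a
  pairwise optimum is verifiable against an independent
  dynamic-programming oracle, which an MSA heuristic is not. An external
  MSA can still be consumed: anything that provides the same per-column
  (reference position, query position) map can feed `lift_region()`.
* **Scoring.** BLOSUM62, gap open 10, gap extend 1 (a gap of length *k*
  costs 10 + *k*), terminal gaps penalized. These are the standard
  protein defaults; nothing downstream is sensitive to small changes as
  long as the conserved windows align, which is the regime the method is
  intended for (recognizable orthologs, not twilight-zone homology).
* **The unknown residue `X` scores 0 against everything** and never
  satisfies a residue comparison. This keeps a sequencing ambiguity from
  either attracting or repelling the traceback, and makes conservation
  checks conservative: an `X` at an interface position counts as *not
  conserved*.
* **Window edges aligned to gaps.** When a window-edge reference position
  aligns to a query gap, the lifted boundary snaps inward to the first
  aligned residue and the lift is flagged `partial` rather than silently
  trimmed; a window whose every position aligns to gaps is `missing`.
  Downstream consumers can then decide what partial evidence is worth.
* **Coordinates are 1-based inclusive everywhere**, matching how protein
  positions are quoted in the literature.

Tie-breaking among co-optimal tracebacks follows the alignment engine's
deterministic rule; scores are invariant to it, and the property tests
compare scores, not paths, against the oracle.

# NES consensus scanning

The scanner enumerates **all** matches of

Φ₁ – X₂,₃ – Φ₂ – X₂,₃ – Φ₃ – X – Φ₄,  Φ ∈ {L, I, V, F, M}

including overlapping matches and alternative spacer decompositions of
the same span. Reporting losslessly (rather than collapsing to unique
spans) is what makes the scanner testable by exact list equality against
a brute-force enumeration; consumers deduplicate if they wish. Match
length is forced to 9–11 by the pattern. The annotated reference NES
window spans 12 residues — wider than the longest possible match — so
window validation asks for *containment* of at least one match, not span
equality; matches merely overlapping a window edge are reported
separately. Experimentally established critical positions inside a
window are supplied as window-relative offsets by the user
(`critical_residues()`), not hard-coded, because they are data about a
particular protein, not part of the pattern.

# Conservation profiles

Per-column relative frequencies are computed over non-gap characters;
the gap fraction is reported separately rather than folded into the
frequencies (occupancy-scaled stack heights are a rendering choice, not a
data property). Information content is

IC = log₂(20) − H,  H = −Σ p log₂ p,

in bits, with no background-composition adjustment and no small-sample
correction — the plain logo convention. All-gap columns have undefined
IC and are flagged. `X` is tallied as an observed character; in
X-heavy data this can push a column's entropy above log₂20 and IC
slightly negative, which is reported as computed rather than clamped.

# Parsimony on the taxonomy

Signature motifs are extracted at the lifted position (a Neoaves FDG is
found because it sits where the reference YDG sits, not because anything
searched for "FDG") and classified into a configurable set
(default YDG/FDG/LDG/VDG, else `other`). Minimal substitution histories
are computed by unweighted Sankoff dynamic programming, which on
multifurcating trees is exactly the Fitch/Hartigan generalization. The
implementation also runs a root-to-leaf pass, yielding:

* the exact minimum number of changes;
* per-node candidate sets — states realized by at least one globally
  optimal labeling (from the combined up + down costs);
* the exact number of optimal labelings (a product-sum count alongside
  the cost recursion), hence `is_unique`;
* one deterministic optimal labeling: the root takes the alphabetically
  first optimal state, and each child keeps its parent's state whenever
  that is optimal, so unavoidable changes are reported on the earliest
  branch consistent with optimality; remaining ties break
  alphabetically.

A caution that the simulator makes concrete: a chain of transitions
(Y→F→L→V) planted along a ladder where each derived state is witnessed
by a *single* child clade is not uniquely recoverable — an equally
parsimonious history postpones each change into the subtending clades.
The default taxonomies are therefore built so that every branch carrying
a planted transition has the derived state witnessed by at least two
child lineages (Neoaves and Passeriformes are multifurcations), making
the planted history the strict optimum. On real data the `is_unique`
flag and candidate sets carry exactly this information, and should be
read before narrating "the" history.

# Structure checks

Predicted models store per-residue confidence (pLDDT, 0–100) in the PDB
B-factor column; residues below 50 are removed before any comparison,
and a model losing every residue is flagged rather than silently
compared. Superposition is the Kabsch algorithm over CA atoms paired by
the sequence alignment of the two (filtered) chains, with the SVD
determinant sign corrected so only proper rotations are returned;
structural similarity is called at RMSD < 1 Å. Both thresholds are
arguments. CA-only superposition is a deliberate choice: the pairing
comes from sequence homology, which speaks for residues, not atoms.

Degenerate inputs: fewer than three pairs is an error by default, since
a real superposition that small is meaningless; `allow_degenerate = TRUE`
exists because the one- and two-point systems have closed-form optima
(0 and |d₁ − d₂|/2) that anchor the test suite.

Interface conservation lifts each reference interface position (default:
the STAT2 F174 / IRF9 L274-A276-F283-Q285 contact set) onto the query as
a width-1 window. A position lost to a deletion is reported not-liftable
and, by default, counts against conservation rather than shrinking the
denominator. A repair utility (`sanitize_x()`) can replace an ambiguous
`X` by the majority residue of companion orthologs at the homologous
position; it is off by default and logs every replacement.

Because curated database records cannot be redistributed here, the
package ships a *constructed* stand-in set
(`synthetic_interface_pairs()`): a reference pair carrying the documented
interface residues and query pairs at 2% and 25% background divergence
(one with an ambiguous `X` and a short insertion) that keep the
interface intact. They exercise the full lifting machinery — including
coordinate shifts across an insertion — but they are synthetic, and say
nothing about any real species until real sequences are supplied.

# The simulator: what it emulates, and what it does not

`simulate_family()` evolves a root sequence along a taxonomy with branch
lengths in expected substitutions per site. Per branch, each site draws
a Poisson(rate × length) number of events; an event resamples the
residue uniformly within the site's allowed set (excluding the current
residue). Site categories: free background (rate multiplier 1.0),
slowed window positions (0.2), hydrophobic anchors resampling within
{L,I,V,F,M} (0.25), and fixed positions (0). Indels (rate 0.004 per
free site per unit branch length, length 1–4) are placed only outside
windows — deletions truncate at window boundaries — so true window
coordinates remain well-defined per leaf and are recorded as ground
truth. Planted transitions overwrite a window's content
deterministically on the branch into a named node and are inherited
below. All randomness comes from one seeded stream; the same seed gives
byte-identical output.

The default fixture mirrors the shape of a jawed-vertebrate ortholog
survey: 30 species in five labeled groups (cartilaginous fishes,
mammals, palaeognaths, galloanserans, neoavians), an IRF5-like family of
500 residues carrying signature (60–62), NES (150–161, hydrophobic
anchors at window offsets 2/5/8/10) and SRR (447–468) windows, and an
IRF6-like family whose signature never changes. The companion
`bird_motif_fixture()` holds 58 bird species — the scale of an avian
signature survey — across the same clade structure. The serine-rich
region is modeled as invariant across the whole family: real data show
within-mammal identity with some between-group variation, and the
invariant limit keeps the within-group identity property deterministic
at every seed, at the cost of not emulating between-group SRR drift.

What the simulator deliberately does **not** emulate: empirical
substitution matrices (WAG/LG), rate heterogeneity beyond the four
categories, indels inside conserved windows, convergent (homoplastic)
motif changes, alignment-hostile low-complexity regions, and isoform or
annotation noise. Passing the planted-truth tests therefore shows the
pipeline is correct under its stated assumptions — conserved anchored
windows, indels outside them, tree-consistent motif history — not that
real families satisfy those assumptions.

# Problem sizes and numerical tolerances

The verification suite runs at sizes chosen to finish in minutes on one
core while leaving no behavior untested: 10,000 random length-60
sequences for scanner/oracle equality; 200 random pairs of length ≤ 8
for alignment-score/oracle equality (the Gotoh oracle itself is checked
against exhaustive alignment enumeration on tiny pairs); 50 random
6-leaf trees against exhaustive internal-labeling enumeration plus 100
seeded simulator replicates for transition recovery; closed-form IC
checks at 10⁻⁹; superposition exactness at 10⁻⁸–10⁻⁹ and the
reflection case against a Nelder–Mead rotation-search oracle at 10⁻⁶;
and two full pipeline runs compared byte for byte. PDB coordinates
carry three decimals, so superpositions read back from PDB text are
exact only to ~10⁻³ Å and are tested at that precision.

# Known limitations

* Pairwise lifting inherits pairwise-alignment error in regions of very
  low similarity; for twilight-zone orthologs a curated MSA fed through
  the same column-map contract is the better source of homology.
* Parsimony reports minimal histories; it cannot see multiple hits on a
  branch and does not estimate rates — for those, likelihood ancestral
  reconstruction is the right tool.
* The interface check tests residue identity at lifted positions, a
  necessary but not sufficient condition for a preserved binding mode.
* PDB is the only structure format consumed (pLDDT from B-factors, the
  predictor convention); mmCIF is out of scope.
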