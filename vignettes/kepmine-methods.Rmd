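---
title: "Mining KEX2-processed repeat proteins: model, parameters and design choices"
author: "kepmine authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining KEX2-processed repeat proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kepmine)
```

## The biological model

KEX2-processed repeat proteins (KEPs) are secreted precursors with a
recognizable architecture: an N-terminal signal peptide, then several
tandem copies of a short core peptide, each copy ending in a dibasic
motif — two consecutive basic residues among KR, RR, KK and RK. The
Golgi endoproteinase KEX2 cleaves the peptide bond on the C-terminal
side of the dibasic motif, so each released fragment carries the motif
at its C-terminus. Downstream exopeptidases complete maturation: the
carboxypeptidase KEX1 removes the C-terminal basic residues one at a
time, and the dipeptidyl aminopeptidase STE13 removes N-terminal
dipeptides whose second residue is proline or alanine (the X-P / X-A
recognition motif familiar from ascomycete alpha-pheromone precursors;
X is typically D or E). Peptides whose mature N-terminus is glutamine
can cyclize to pyroglutamate, losing NH~3~ (−17.026549 Da); this changes
the mass but not the letter sequence. Under heterologous expression,
additional nonspecific C-terminal trimming of secreted peptides is
observed, and occasional cleavage after isolated (monobasic) K/R
residues occurs in vivo.

`kepmine` implements this model in three layers: a proteome **screen**
that calls KEPs, a **maturation** enumerator that predicts the peptide
forms a KEP can yield, and a **matcher** that connects predicted
monoisotopic masses to observed peptidomics masses.

## The screen and its parameters

Every precursor is cleaved in silico after each dibasic motif
occurrence; overlapping motifs (as in `KRR`) each produce a cut, which
can yield single-residue fragments — accepted as a literal reading of
cleavage *at* the dibasic residues. The signal-peptide region is *not*
excised before mining; the signal call is used only as a filter, and
the first fragment therefore contains the signal region.

Fragments are compared all-against-all within one protein. Percent
identity is computed from the optimal Smith–Waterman local alignment
under BLOSUM62 with affine gap penalties 11 (open) / 1 (extend) — the
long-standing defaults of protein database search — as 100 × identical
columns / alignment length including gap columns; when no
positive-scoring local alignment exists the identity is 0. Two tiers
define similarity:

* **tier 1**: length difference fewer than 30 residues (exclusive) and
  identity at least 70 % (inclusive);
* **tier 2**, for short fragments: both fragments shorter than 20
  residues, length difference fewer than 8, identity at least 40 %.

The tier-2 "<20 residues" condition is required of *both* fragments —
the symmetric, stricter reading. A protein passes the screen when it
has a signal-peptide call, at least 2 distinct cut positions, length at
most 800 residues, and some fragment similar to at least 2 *other*
fragment instances (identical repeat copies count as distinct partners;
this is what lets a precursor with three identical repeats pass).

### The minimum-coverage gate

A bare local alignment is a poor similarity criterion for very short
sequences: any two fragments sharing a single residue have a
positive-scoring one-column alignment of 100 % identity, which would
make the 40 % tier vacuous. Database-search tools do not report such
matches because their word seeding and significance model discard them.
As a deterministic, self-contained stand-in, `kepmine` treats an
alignment that spans less than a configurable fraction
(`minAlignmentCoverage`, default 0.5) of the *shorter* fragment as no
match. The value 0.5 is the conventional half-coverage cutoff used in
homology screening; it leaves every full-length repeat match untouched
(identical repeats align end-to-end) while discarding one- and
two-residue coincidences. The exported `percentIdentity()` defaults to
no coverage gate, i.e. the pure definition above; the gate is a
property of the mining configuration.

### Determinism and symmetry

Co-optimal Smith–Waterman alignments can differ in identity even though
they tie in score, and which one an aligner returns may depend on which
sequence is the pattern. `kepmine` therefore orients every pair
canonically (lexicographically smaller sequence as pattern) before
aligning, making `percentIdentity(a, b) == percentIdentity(b, a)` hold
by construction rather than by luck.

### Other mining knobs

* `stripBasicForMining` (default off) removes trailing K/R before
  similarity scoring; whether the original screen compared fragments
  with or without the motif is not determinable, and the default keeps
  the motif (it is part of the cleavage product).
* `minFragmentLength` (default 1) can exclude very short fragments from
  scoring; by default nothing is excluded.
* An alternative "global, end-gap-free" alignment mode
  (`alignType = "overlap"`) is available for short fragments that lack
  a positive-scoring local alignment under stringent matrices.
* Monobasic cleavage is *off* during mining — the screen is defined on
  the four dibasic motifs — and available in maturation.
* Fragments containing non-standard letters (X and other ambiguity
  codes, which the readers retain) are excluded from similarity scoring
  and from maturation; the thresholds are defined on standard residues
  and exclusion is conservative.

## The maturation model

For each precursor the signal region is excised when the annotation
provides a cleavage position (the mature N-terminus is then the
signal-peptidase cut). The remainder is cleaved at KEX2 sites and each
fragment is expanded through an ordered cascade:

1. **KEX1**: 0 to `maxKex1Trim` (default 2, one dibasic motif) trailing
   K/R removed one at a time, stopping at the first non-basic residue;
   the fully trimmed form is the canonical product.
2. **STE13**: iterative removal of N-terminal dipeptides whose second
   residue is in `ste13SecondResidues` (default A, P). Applied only to
   fragments whose N-terminus is a KEX2 cut or the signal-peptidase cut
   — the biological order of events — and not after C-terminal
   truncation. Intermediates are emitted by default
   (`ste13EmitIntermediates`), since whether trimming is processive to
   completion in basidiomycetes is unknown; detected peptides so far
   are fully trimmed forms.
3. **C-terminal truncation**: 0 to `maxCTruncation` single-residue
   removals (default 0). Off by default because such trimming is
   attributed to nonspecific degradation during heterologous
   expression; values up to 5 reproduce the truncated series observed
   there.
4. **Pyroglutamate**: when the intermediate starts with Q, both the
   unmodified and the pyro-Q form (mass −17.026549 Da) are emitted.
   N-terminal glutamate cyclization is not modelled — only Q-derived
   pyro forms have been observed in this system.

Peptides outside the `minPeptideLength`–`maxPeptideLength` window
(defaults 2 and 60) are dropped. With `monobasic = TRUE`, cleavage
after isolated K/R is modelled as *partial*: the fragments of both the
dibasic-only and the full cleavage pattern are enumerated, so enabling
the option only adds peptides. (Modelling it as complete cleavage would
remove every peptide spanning an isolated basic residue, contradicting
the observation that products with and without single-arginine cleavage
coexist.)

Each peptide records 1-based inclusive precursor coordinates, the
ordered provenance of steps applied (`kex2_cut`, `kex1_trim`,
`ste13_trim`, `c_trunc`, `pyroglu`), and its monoisotopic mass.
`replayProvenance()` re-applies a recorded step list to the parent
fragment; the test suite uses it to verify that provenance reproduces
every emitted peptide exactly. Two deduplication stages apply: exact
duplicates on (start, end, modifications) arising from alternative step
paths keep the shortest provenance; identical (sequence, modification)
entries from different repeat copies collapse into one row whose
`multiplicity` counts the distinct loci and whose coordinates are those
of the first locus.

## Masses and matching

Monoisotopic residue masses are computed from elemental monoisotopic
masses (H 1.00782503207, C 12, N 14.0030740048, O 15.9949146196,
S 31.97207100); a peptide mass is the residue sum plus one water
(18.010565 Da) plus modification deltas. The matcher reports every
(observed, predicted) pair whose signed error
ppm = 10^6^ (obs − theo)/theo is within the tolerance (default 10 ppm),
computed against the theoretical mass and inclusive at the boundary; a
10^−9^ ppm fuzz keeps the inclusive boundary inclusive in floating
point. Observed masses are *neutral* monoisotopic masses —
charge-state deconvolution belongs upstream. The four common
search-engine variable modifications (amidation, oxidation,
hydroxylation, methylation) are available to the matcher as optional
per-peptide deltas but are never enumerated by the maturation model,
which reflects that none has been confirmed on final peptides in this
system.

## The synthetic-proteome generator

`simulateProteome()` builds fixtures that emulate the precursor
architecture: Met + hydrophobic-biased signal region (16–24 residues) +
optional short leader (0–4 residues) + *k* identical copies of
(optional X-P/X-A prefix + core + dibasic motif), *k* in 3–7, cores
6–15 residues, + optional tail. Cores, leaders and tails are drawn from
the 18-letter non-basic alphabet so the cleavage-site layout is exactly
as designed, and the leader is kept shorter than the signal region so
that the first repeat's fragment (which carries signal + leader) stays
within the tier-1 length window of the repeat fragments — real KEP
pro-regions are similarly short. The ground-truth table records repeat
coordinates and the canonical core peptide each KEP should yield after
KEX1 + STE13.

Five decoy classes each violate one acceptance criterion: `no_signal`
(annotation is authoritative and says no), `one_site` (a single cut),
`too_long` (padded past 800 residues), `shuffled_repeats` and
`random_protein` (no repeat similarity). The shuffled class applies a
per-fragment residue shuffle *including* the dibasic motif residues,
then the decoy is re-cleaved from scratch. This choice matters: if the
motif were kept intact at each repeat junction, shuffled copies would
share their terminal motif and their full residue composition, and a
substantial fraction of such short pairs clears the 40 % tier under any
local-alignment engine — the class would not behave as a negative
control. Shuffling the motif residues scatters the basic residues,
destroying both the repeat similarity and, usually, part of the
cleavage-site layout, which is exactly what "no longer a KEP" means.

What the generator does *not* emulate: realistic amino-acid background
frequencies (sampling is uniform within each alphabet), homologous but
diverged repeat copies (implanted copies are identical), signal-peptide
sequence realism (the annotation table, not the sequence, drives the
pipeline), and mass-spectral noise (observed-mass fixtures are derived
from predictions with controlled ppm offsets). Passing the fixture
tests therefore demonstrates the screen's logic and determinism, not
its behaviour on diverged natural repeats, where the similarity
thresholds — not the machinery — decide the outcome.

## Numerical and interface conventions

* All file coordinates are 1-based inclusive; tables are TSV with
  header rows; FASTA identifiers are the first whitespace-delimited
  header token.
* Sequences are canonicalized on input: upper-cased, one terminal `*`
  stripped (an internal `*` is an error), ambiguity codes retained but
  excluded from scoring/maturation as above. How the source gene
  catalogue handled ambiguity codes is unspecified, so exclusion is
  this package's choice.
* Length-difference bounds are exclusive ("fewer than"), identity and
  ppm bounds inclusive ("at least" / "within").
* The cleavage-site count filter counts distinct cut positions after
  overlap handling.
* Peptide masses are written with 6 decimal places; mass arithmetic is
  reproducible to well below 10^−4^ Da.
* `simulateProteome()` restores the caller's RNG state; identical seeds
  give byte-identical fixtures.

## Problem sizes used by the tests and acceptance script

The oracle-equivalence checks run 1000 random sequences of up to 200
residues against a brute-force dipeptide-window scan. The recovery
statistics run 200 seeded replicates of the default fixture (10
implanted KEPs + 40 decoys each): implanted-KEP sensitivity is required
to be 1.0 and shuffled-decoy rejection at least 95 %. Canonical-peptide
recovery by the maturation model is checked over 20 fixtures. These
sizes give stable statistics (16 000 decoy decisions for the rejection
rate) at a few minutes of runtime.

## Known limitations

* The similarity engine is a self-contained Smith–Waterman definition,
  not the heuristic database-search tool behind the original screen;
  at-scale KEP counts on a real proteome can differ by a few calls
  around the thresholds. The tier thresholds themselves are taken as
  given.
* Signal-peptide calls are consumed, never computed; the quality of a
  real-proteome screen is bounded by the external predictor's calls.
* The screen is sequence-architecture only: a protein with repetitive
  dibasic-flanked fragments that is not secreted through the
  conventional pathway will still be called if its annotation says
  "signal present".
* MS/MS fragment-ion scoring, search-engine FDR modelling and
  quantification are out of scope; the matcher operates on neutral
  peptide masses only.
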