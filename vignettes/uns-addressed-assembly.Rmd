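---
title: "UNS-addressed modular assembly of multi-TU DNA circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{UNS-addressed modular assembly of multi-TU DNA circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unskit)
```

## The problem and the model

Large mammalian gene circuits carry many transcription units (TUs) —
promoter/gene/polyA blocks — on a single vector. Building such vectors is
hard: mammalian parts are long, often repetitive (the same promoter or
reporter reused several times), and riddled with common restriction sites,
which defeats both Type IIs cloning and PCR-based stitching at this scale.

`unskit` implements a *nucleotide addressing system* for one-pot isothermal
(Gibson) assembly. Each TU lives on a circular **position vector** whose
insert is flanked by two designed 40-bp **unique nucleotide sequences**
(UNSs) and two I-SceI sites. The UNS pair encodes the TU's circuit
position: position *i* is flanked by `UNS_i`/`UNS_{i+1}`. An **adaptor
vector** bridges the last TU to the linking address `UNSX` and contributes
a selection marker (Kan or Tet); a **carrier vector** supplies the
propagation backbone between `UNSX` and `UNS1`. I-SceI digestion releases
every insert, the pooled fragments share 40-bp terminal homology only at
intended junctions, and a single circular product is the only way to
satisfy every overlap — the addresses, not the cargo, dictate the outcome.
That is why repeated internal parts are harmless: in the model, annealing
is restricted to terminal windows, so only fragment *ends* can pair.

The assembled circuit (`pCircuit`) is itself reusable: a *hierarchical*
carrier embeds relay addresses — the next round's `UNS1` and `UNS2` — plus
intact I-SceI sites around its backbone. Flap trimming at every Gibson
junction removes half of each 18-bp I-SceI site, so no internal site
survives assembly; re-digestion therefore excises the entire circuit as a
clean position 1–2 part for the next round. Kan and Tet adaptors alternate
between rounds so parental vectors can be selected against.

## Address design

`design_uns_set()` draws uniform random 40-mers and keeps those passing,
in order: GC fraction within `[gc_min, gc_max]`, homopolymer runs of at
most `homopolymer_max`, no forbidden motif on either strand (the I-SceI,
XbaI, XhoI, FseI and PacI sites by default — an address carrying an
excision site would be cut apart), hairpin stems of at most
`threshold_hairpin`, self-dimers of at most `threshold_cross`, and a
nearest-neighbor duplex Tm within `[tm_min, tm_max]`. An orthogonal set is
then selected greedily: seed with the lowest-self-dimer candidate, then
repeatedly add the candidate minimizing the worst cross-annealing score
against all chosen members and their reverse complements, rejecting
anything above `threshold_cross`. Ties go to the lexicographically
smallest sequence, so the whole procedure is deterministic given the seed.

Scores are *exact-complementarity lengths*, not free energies:
`cross_anneal_score(a, b)` is the longest common substring between `a` and
the reverse complement of `b`, `hairpin_stem()` the longest contiguous
intramolecular stem with a loop of at least 3 nt. Contiguous perfect
duplex length is the standard fast proxy for annealing propensity in
overlap design, it is deterministic, and it is checkable against
brute-force oracles; a thermodynamic scorer could be slotted in behind the
same interface. Melting temperatures use the unified nearest-neighbor
parameter set (SantaLucia 1998) with duplex initiation, terminal A:T
penalties, and the entropic salt correction, at 0.25 µM total strand and
50 mM Na⁺ — documented constants, exposed as arguments.

Defaults (all in `design_config()`): GC 0.40–0.60, Tm 62–72 °C, hairpin
≤ 5 nt, cross-annealing ≤ 12 nt, homopolymers ≤ 4 nt, pool size 5000.
These reflect common overlap-design practice: a 12-nt shared duplex is far
below the 40-nt intended overlap yet long enough that random 40-mers
rarely violate it, so feasible sets of a dozen addresses are found in
small candidate pools. With every constraint active, roughly a quarter of
uniform random 40-mers are accepted; infeasible configurations fail with
the acceptance rate and the tightest filter named.

## Assembly planning and simulation

`plan_assembly()` turns an ordered circuit design into an executable plan:
I-SceI digestion for every position vector, XbaI+XhoI for the adaptor,
FseI or PacI for the carrier; the fragment roster with expected UNS
flanks; the marker-alternated adaptor (first round defaults to Kan, a
choice the protocol leaves open); and bench quantities — 70 fmol per
position vector, 280 fmol adaptor and 140 fmol carrier into the digests,
7 fmol of each digested part into the one-pot reaction, with masses from
the 650 g/mol/bp rule. Address collisions (two entries with one UNS pair)
are hard errors, because a duplicated address makes the junction graph
ambiguous. `predict_final_sequence()` concatenates the UNS-trimmed insert
bodies around the circle, counting each shared address once.

`simulate_one_pot()` models the reaction mechanistically but
deterministically: 5'→3' exonuclease chew-back exposes terminal single
strands, so homology search runs only over the terminal `chew_window`
(default 80 nt) of each fragment end, in both orientations; a junction
needs an exact match of at least `min_overlap` (default 20 nt, half the
address length) with unmatched terminal flaps of at most `flap_tolerance`
(default 15 nt — comfortably above the 9-nt I-SceI remnants left outside
the UNSs, which polymerase/exonuclease flap removal trims). The simulator
enumerates every simple cycle in the oriented junction graph; a run is
`unique_circular` only when exactly one product exists, it uses every
fragment, and no fragment end has two possible partners. Mismatches and
gaps are not modeled (addresses are designed for exact complementarity),
and no kinetics or yields are predicted — this is design verification, not
chemistry.

Because a one-pot reaction has no input order, products are reported in a
canonical circular form: the lexicographically least rotation over both
strands (Booth's algorithm). The planner canonicalizes its prediction the
same way, which makes "planner equals simulator, byte for byte" a
meaningful cross-check of two independent code paths — address arithmetic
on one side, homology-graph traversal on the other.

## What the synthetic fixtures emulate — and what they do not

`make_fixture_library()` builds complete synthetic campaigns: promoters of
0.2–1.5 kb, genes of 0.7–3 kb, a 250-bp insulator stand-in placed in
tandem, a 220-bp polyA, 0.9–1.2-kb markers, 2–3-kb backbones; one position
vector per TU, a carrier, and Kan/Tet adaptors at every closing address.
Part sequences are uniform random DNA scrubbed of the five framework
enzymes' sites, mirroring a sequence-verified parts library. A
`repeat_fraction` rebuilds later TUs from TU1's promoter and gene to
emulate repetitive circuits. Everything is deterministic in one seed.

Random DNA lacks the compositional biases of real mammalian sequence
(CpG islands, repeats, homopolymer stretches), real insulator/polyA
identities, and any notion of expression. Passing tests on these fixtures
therefore demonstrates the *addressing logic* — digestion, junction
formation, uniqueness, hierarchy — not wet-lab success rates; colony
correctness percentages are empirical quantities this package only reasons
about through `screening_stats()`. Gateway recombination is likewise
modeled as deterministic cassette substitution with short att-scar
spacers, since position vectors, not recombination chemistry, are the
point.

Test and acceptance runs use circuits of 1–12 TUs (up to ~36 parts and
~54 kb of predicted sequence), one 7-TU + 5-TU hierarchical campaign, and
oracle batteries of 40–1000 random cases per operation — sizes chosen so
the whole suite exercises the target regime in about a minute.

## Diagnostics

`restriction_map()` digests a construct with an enzyme panel and annotates
each predicted band under a deliberately simple gel model: bands are
visible within 250–20 000 bp and separable when they differ by at least 8%
(`gel_model()`), a pure size-ratio rule with no migration physics.
`select_diagnostic_panel()` searches panels of up to three enzymes
exhaustively (larger searches are refused rather than approximated) for
the panel that best distinguishes the correct circuit from failure-mode
constructs — the re-circularized carrier and single-TU dropout hypotheses
from `misassembly_alternatives()`. Colony screening follows the closed
form: the chance that all *k* picked colonies are wrong is `(1-p)^k`, so
two colonies suffice for <10% risk whenever the per-colony success rate
exceeds `1 - sqrt(0.1) ≈ 0.68`, and `colonies_for_risk()` inverts the
formula.

## Numerical and design choices

* Coordinates are 0-based, half-open, top strand, throughout; circular
  searches scan the doubled sequence and keep hits starting before the
  origin repeat.
* Fragments are delimited by top-strand cut coordinates, so digest
  fragment lengths always sum to the parent length; overhang content is
  recorded on end descriptors. Exact I-SceI cut offsets (9/5, 4-nt 3'
  overhang) follow REBASE; they never reach a Gibson junction because
  chew-back erases overhangs.
* IUPAC degeneracy is honored in enzyme sites only; part sequences must be
  concrete A/C/G/T.
* The hierarchical module always re-enters at position 1–2, as the
  protocol demonstrates; re-addressing a module elsewhere is deliberately
  unsupported. Module-internal addresses are scanned (exact match, both
  strands) against every address of the new round, and collisions are
  errors, not warnings — the fixtures avoid them by giving each round an
  independently designed set.
* The simulator reports all products when several exist; nothing is
  sampled, so identical inputs always give identical output.

## Limitations

Partial digestion, methylation sensitivity, star activity, annealing
mismatches, reaction kinetics and transformation efficiency are all out of
scope. The gel model knows nothing about band intensity or smearing. The
address designer optimizes a greedy max-min criterion, which is
reproducible but not guaranteed optimal; for the set sizes this framework
needs (a dozen addresses), random 40-mer pools are far from the
feasibility boundary and greedy selection is ample.
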