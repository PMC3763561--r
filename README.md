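# unskit — UNS-addressed modular DNA circuit assembly

`unskit` is an R toolkit for designing and verifying, entirely in silico,
the hierarchical construction of large multi-transcription-unit (TU) DNA
circuits by one-pot isothermal (Gibson) assembly with a *nucleotide
addressing system*. It is aimed at synthetic biologists planning
mammalian-scale circuit builds (tens of kilobases, dozens of parts,
repetitive cargo) who want the addressing, digestion, assembly and
diagnostic steps checked before touching a pipette.

## The core idea

Each TU sits on a circular **position vector** whose insert is flanked by
two orthogonal 40-bp **unique nucleotide sequences** (UNSs) and two
18-bp I-SceI sites. The UNS pair is the TU's address: position *i* carries
`UNS_i`/`UNS_(i+1)`. An **adaptor vector** bridges the last TU to the
linking address `UNS X` and supplies a Kan or Tet marker (alternated
between rounds); a **carrier vector** contributes the backbone between
`UNS X` and `UNS 1`. After I-SceI excision, the pooled fragments share
40-bp terminal homology only at intended junctions, so the Gibson
reaction's chew-back/anneal/ligate cycle has exactly one way to close a
circle:

```
UNS1 —TU1— UNS2 —TU2— … —UNSn+1 —marker— UNSX —backbone— UNS1
```

Because annealing only happens at fragment ends, repeated *internal*
parts cannot divert junctions. Assembled circuits re-enter the pipeline:
a hierarchical carrier embeds the next round's `UNS1`/`UNS2` plus intact
I-SceI sites around its backbone, so re-digestion releases the whole
circuit as a position 1–2 part.

The package provides: a UNS designer (rejection sampling + greedy max-min
orthogonal selection, with nearest-neighbor melting temperatures, hairpin
and cross-annealing scores); restriction-site finding and digestion
simulation on linear/circular DNA; sequence-level models of position,
carrier and adaptor vectors plus a deterministic fixture generator; an
assembly planner (addresses, digestion roster, marker alternation, fmol
pooling, predicted product); a one-pot Gibson simulator with ambiguity
detection; and diagnostics (restriction maps under a gel model, panel
selection, colony-screening statistics).

## Worked example

Design six numbered addresses plus `UNSX`, build a synthetic 5-TU
campaign, plan it, and simulate the pot:

```r
library(unskit)

cfg  <- design_config(rng_seed = 11, n_candidates = 60)
set  <- design_uns_set(6, cfg)
set
#> <uns_set> 7 members (UNS1, UNS2, UNS3, UNS4, UNS5, UNS6, UNSX), 40 bp each

fx   <- make_fixture_library(11, 5, uns_set = set)
plan <- plan_assembly(fx$design, fx$uns_set, fx$registry)
plan
#> <assembly_plan> 7 inputs (5 entries + adaptor[Kan] + carrier), predicted 24917 bp circular

plan$roster[, c("input", "enzymes", "uns_left", "uns_right", "fmol_digest")]
#>                 input   enzymes uns_left uns_right fmol_digest
#> 1     pPos1_TU1_P1_G1    I-SceI     UNS1      UNS2          70
#> 2     pPos2_TU2_P2_G2    I-SceI     UNS2      UNS3          70
#> 3     pPos3_TU3_P3_G3    I-SceI     UNS3      UNS4          70
#> 4     pPos4_TU4_P4_G4    I-SceI     UNS4      UNS5          70
#> 5     pPos5_TU5_P5_G5    I-SceI     UNS5      UNS6          70
#> 6 pAdaptor_UNS6_X_Kan XbaI+XhoI     UNS6      UNSX         280
#> 7            pCarrier      FseI     UNSX      UNS1         140

res <- simulate_one_pot(plan_fragments(plan))
res
#> <one_pot_result> status unique_circular, 1 product(s)
#>   - 24917 bp circular from 7 fragment(s)

identical(canonical_circular(plan$predicted_sequence),
          res$products[[1]]$sequence$residues)
#> [1] TRUE

verify_junctions(res$products[[1]], set)$pass
#> [1] TRUE

screening_stats(0.7, 2)   # risk that two picked colonies are both wrong
#> [1] 0.09
```

The roster reads directly as a bench protocol: digest 70 fmol of each
position vector with I-SceI, 280 fmol of the adaptor with XbaI+XhoI,
140 fmol of the carrier with FseI, then pool 7 fmol of each digested part
(`protocol_sheet(plan)` converts to ng and µl). The simulator's single
`unique_circular` product matching the planner's byte-for-byte prediction
is the design's green light; an `ambiguous` status pinpoints address
collisions before they cost a cloning round.

A command-line wrapper is installed as `exec/unskit` in the package tree
(subcommands `design-uns`, `fixtures`, `plan`, `simulate`, `map`,
`screen`), e.g.
`Rscript <pkg>/exec/unskit design-uns --n 11 --seed 7 --out uns.fasta`.

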