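---
title: "Model and methods: in-silico enzymatic sequencing of heparin oligosaccharides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: in-silico enzymatic sequencing of heparin oligosaccharides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GAGdigest)
```

# Scope

GAGdigest models the structure elucidation of heparin and
low-molecular-weight heparin (LMWH) oligosaccharides by combined enzymatic
digestion — heparin lyases (heparinases I/II/III) and heparanase — read out
by negative-mode ion-pair electrospray mass spectrometry. This vignette
documents the underlying model: the sequence grammar and its assumptions,
the mass arithmetic, the enzyme rule tables, the fragment-ion model and its
two isomer-discrimination rules, the inference procedure, the synthetic
chain generator and its default parameters, and the known limitations.

# Sequence model

A sequence is an ordered run of residues, written nonreducing end (NRE) to
reducing end (RE), alternating between uronic-type and amine-type classes:

* `ΔU` — 4,5-unsaturated uronic acid (lyase elimination product); NRE only;
  optional 2-O-sulfate.
* `I` / `G` / `U` — saturated uronic acid as iduronic, glucuronic, or
  epimer-unknown; optional 2-O-sulfate.
* `A` — glucosamine with an N-substituent (`NS`, `NAc`, or free `NH2`) and
  optional 3-O- and 6-O-sulfates.
* `aM.ol` — 2,5-anhydromannitol, the reduced RE residue formed by
  nitrous-acid depolymerisation; RE only; optional 6-O-sulfate.
* `Rc` — a ring-contracted deamination side product; modelled as an
  amine-type residue with no substituent positions.

Assumptions built into the validity rules: strict uronic/amine alternation;
`ΔU` only at position 1; `aM.ol` only at the last position; uronic residues
carry at most a 2-O-sulfate; `aM.ol` carries at most a 6-O-sulfate (its C3
hydroxyl is treated as never sulfated, so deaminative cleavage at
3-O-sulfated glucosamines is not modelled); `Rc` carries nothing. A
composition code `ΔU/U/A n,s,a[,Rc][–aM.ol]` (NRE class, residue count,
total sulfates, N-acetyls, end-group flags) determines the residue-class
layout — and therefore the neutral mass — completely.

# Mass engine

Neutral monoisotopic mass is the sum of free-residue masses minus one water
per glycosidic bond, plus 79.95682 Da per sulfate and 42.01057 Da per
N-acetyl group. Residue masses (Da): ΔU 176.03209 (C6H8O6), U 194.04265
(C6H10O7), A 179.07937 (C6H13NO5), aM.ol and Rc 164.06847 (C6H12O5). The
`Rc` mass assignment is the one numerical choice here that is not a textbook
value: the residue's chemical identity is uncertain, but C6H12O5 is the
composition consistent with the observed ring-contracted species' m/z, so
the mass is fixed while the structure stays open. The test suite
cross-checks the whole table against an independent elemental-formula
oracle.

Ions are `[M − hH + kDBA]h−`: remove `h` protons (the charge), attach `k`
neutral dibutylamine molecules (129.15175 Da), giving
`m/z = (M − h·1.007276 + k·129.15175)/h`. `m/z` is strictly increasing in
`k` with spacing exactly `129.15175/h`. Intact-species values are reported
to 3 decimals and fragment-scale values to 2, matching the precision at
which such data are printed; matching tolerance defaults to 0.01 m/z.

# Enzyme rule tables

Both enzyme models are *plain data frames* evaluated by a generic engine,
so specificities can be edited or replaced without touching code.

## Heparin lyases (eliminative)

`lyaseRules()` holds one row per donor/acceptor pattern for the bond
glucosamine→uronic: heparinase I cleaves N-sulfated glucosamine onto
2-O-sulfated iduronic acid; heparinase III cleaves N-acetylated glucosamine
onto unsulfated iduronic and N-sulfated glucosamine onto unsulfated
glucuronic acid; heparinase II is modelled maximally broad (any glucosamine
onto any uronic). Two blocking rules apply after pattern matching: a bond
onto glucuronic acid is protected when the residue two positions downstream
is a 3-O-sulfated glucosamine (the antithrombin-binding-region linkage no
lyase cleaves), and any bond is protected when that residue is the
anhydromannitol RE. Cleavage is eliminative: the acceptor uronic residue
becomes `ΔU` (epimer information erased, 2-O-sulfation kept), and the sum
of product masses equals the parent mass exactly. The fixed point is
independent of cleavage order; `order = "random"` exists to exercise that
confluence property in tests.

## Heparanase (hydrolytic)

Candidate sites are bonds from an *unsulfated glucuronic* acid onto the
following amine-type residue. `heparanaseRules()` is an *ordered* verdict
table evaluated top-to-bottom; the first matching row decides:

| rule | condition | verdict |
|------|-----------|---------|
| R0a | downstream residue is `aM.ol` or `Rc` | resist |
| R0b | downstream glucosamine is N-acetylated | resist |
| R1  | downstream glucosamine lacks 6-O-sulfate | resist |
| R2  | glucosamine upstream of the G lacks 6-O-sulfate | resist |
| R3  | uronic residue two positions upstream is 2-O-sulfated | partial |
| R4  | otherwise | cleave |

R0b is a conservative default (no N-acetylated acceptor substrate is
covered by the evidence the rules were built from). Hydrolysis adds one
water per cut. A substrate whose only applicable sites are "partial"
contributes both its cleavage products and itself (kept among the *partial
survivors*); fates are classified as `resistant` (no cleavable or partial
site), `disappears` (≥ 1 fully susceptible site), or `partial`.

# Fragment-ion model

CID fragments follow Domon–Costello nomenclature: glycosidic B/C
(NRE-retaining) and Y/Z (RE-retaining) ions at every bond, with exact
complementarity `B_i + Y_(n−i) = M`, `C = B + H2O`, `Z = Y − H2O`; 0,2
cross-ring cleavage of glucosamine rings into a C1–C2 unit (C2H5NO,
59.03711 Da, carries the N-substituent) and a C3–C6 unit (C4H8O4,
120.04226 Da, carries O3 and O6), the two summing exactly to the free
residue mass; and internal ions from one glycosidic plus one cross-ring
cut. Sulfate retention is combinatorial from 0 up to the number of sulfates
the covered atoms actually carry (CID readily strips SO3), with at most one
CO2 loss (only for fragments covering a uronic carboxyl) and at most one
extra H2O loss; charge runs from 1 to `min(maxCharge, retained + 1)`.

Two deliberate rules make the model discriminative rather than maximally
permissive, and they are the numerical choices that let MS/MS split the
trisulfated disaccharide isomers `G–ANS3S6S` and `I2S–ANS6S` (identical
mass, identical plain glycosidic fragments):

1. **Free-hydroxyl gate for water loss.** The extra H2O loss is only
   enumerated for fragments retaining at least one never-sulfated ring
   hydroxyl (O3/O6). A glucosamine sulfated at both O3 and O6 offers none,
   so the Z1 − H2O ion at m/z 222.01 is available to `I2S–ANS6S` but not to
   `G–ANS3S6S`.
2. **Sulfation gate for the bare C3–C6 internal ion.** The internal
   C3–C6 fragment (a `0,2A`-type bare unit) is only enumerated when that
   unit carries both a 3-O- and a 6-O-sulfate, reflecting the propensity of
   0,2 cross-ring cleavage for highly sulfated glucosamine rings. This
   makes the ion at m/z 198.99 specific to the 3-O-sulfated isomer.

Without these two gates, combinatorial retention would let both isomers
match every diagnostic ion and the annotation would carry no structural
information. Annotation (`annotateMSMS()`) assigns each peak the candidate
with the smallest |error| within tolerance; `compareIsomers()` tabulates
per-isomer matches and flags diagnostic peaks.

# Structure inference

`enumerateSequences()` generates every sequence with a given composition by
a depth-first search with sulfate/acetyl budget pruning, under editable
constraints (`gagConstraints()`) encoding biosynthetic regularities:
2-O-sulfated uronic residues are enumerated as iduronic only; unsulfated
uronic residues may be either epimer; 3-O-sulfation is restricted to
N-sulfated glucosamine that opens the chain or follows an unsulfated
glucuronic acid (the antithrombin-binding-region context); free-amine
glucosamine is off by default. The enumeration cap is 10 residues — at the
octasaccharide scale the constrained space is a few thousand candidates and
inference completes in well under a second per species.

`inferStructures()` keeps the candidates whose *simulated* behaviour
reproduces every evidence record: predicted fate equals observed fate, and
the simulated fixed-point products contain every non-trace companion
composition. Companions are checked against full digestion products only
(not partial survivors). Trace companions are soft evidence validated at
the level of the returned set: they must be producible by at least one
member, including by single-hydrolysis "leakage" at nominally resistant
sites — this accommodates the trace monosaccharides seen for resistant
species without letting them veto candidates. Infeasible evidence yields an
empty set, not an error.

# Synthetic chain generator

`chainModel()` describes a heparin-like population; `generatePool()` draws
oligosaccharide fragments from freshly built parent polymers
(`parentLength = 40` residues) by mimicking nitrous-acid depolymerisation:
cut points are N-sulfated, non-3-O-sulfated glucosamines, and for the
`"amol"` RE style the cut residue becomes anhydromannitol (N-sulfate lost,
6-O-sulfate kept). Defaults and their rationale:

| parameter | default | rationale |
|-----------|---------|-----------|
| `lengthRange` | 4–8 | the tetra- to octasaccharide window where enzymatic sequencing is informative |
| `p2S` | 0.8 | heparin iduronic residues are predominantly 2-O-sulfated |
| `pG` | 0.15 | glucuronic acid is the minor epimer in heparin |
| `p6S` | 0.85 | 6-O-sulfation is the prevalent glucosamine O-sulfation |
| `pNAc` | 0.12 | N-acetylation is a minor fraction in heparin-derived material |
| `atbrRate` | 0.05 | sparse insertion of the antithrombin-binding pentasaccharide `ANX6S–G–ANS3S6S–I2S–ANS6S` |
| `atbrNSfrac` | 1 | the N-sulfated motif variant; its flanking cut point is what produces `G–ANS3S6S`-initiated fragments |
| `pRc` | 0.02 | ring-contracted residues are a rare side product |

These defaults are fixed study conditions describing heparin-like material,
not tuning knobs. `noiseModel()` adds m/z jitter, peak dropout, decoy peaks
and a detection fraction for partial-cleavage products;
`simulateExperiment()` converts digestion products to peaks under a
mass-banded ion-form policy (singly charged below 700 Da through triply
charged, 3–4 adducts above 1600 Da) with exact ground truth.
`recoveryExperiment()` closes the loop: simulate a noiseless heparanase
digest of each generated chain, transcribe fate and product compositions
into evidence, infer, and check the planted sequence is in the consistent
set — the completeness property of the inference engine.

# Limitations

* Epimer assignments (I vs G) come only from enzyme behaviour; NMR-scale
  information is out of scope, and unsulfated uronic residues in lyase
  products retain an unknown epimer unless evidence constrains it.
* The heparanase rule table is a discrete abstraction of a
  context-dependent enzyme; rule R0b (N-acetylated acceptors resist) is an
  unvalidated conservative default, and kinetics ("partial") is reduced to
  a three-valued verdict.
* Heparinase II is modelled maximally broad; genuine hepII sequence
  preferences are not represented.
* Fragment intensities are not modelled — only candidate existence within
  tolerance — and sulfate migration during CID is ignored.
* Deaminative chemistry at 3-O-sulfated glucosamines (which would yield a
  3-O-sulfated anhydromannitol) is not modelled, consistent with the
  residue grammar.
* The generator produces linear chains only; linkage-region species are
  supported in the mass table (`Gal`, `Xyl`, `Ser`) but not in the grammar.

# Session info

```{r}
sessionInfo()
```
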