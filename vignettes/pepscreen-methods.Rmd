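---
title: "Methods: in silico GI digestion and drug-likeness screening of food-protein peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico GI digestion and drug-likeness screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscreen)
```

## The problem

Dietary proteins release short peptides during gastrointestinal (GI)
digestion, and some of those peptides inhibit angiotensin-converting enzyme
(ACE, a blood-pressure target) or dipeptidyl peptidase IV (DPP-IV, a type-2
diabetes target).  Invertebrate paramyosins — glutamate-rich muscle proteins
abundant in octopus, squid, scallop, mussel, oyster, abalone, shrimp and sea
cucumber — are a promising but under-explored source.  `pepscreen`
implements the complete discovery pipeline as reusable, tested code:

1. **digest** proteins in silico with gastric/pancreatic proteases,
2. **match** released fragments against a catalog of experimentally
   validated anti-ACE/anti-DPP-IV peptides,
3. **build** each candidate peptide's molecular graph and compute its
   physicochemical descriptors,
4. **screen** candidates for GI absorption, safety and drug-likeness.

## Digestion model

A protease is a cleavage specificity: a set of P1 residues after which it
cuts and a set of P1′ residues that suppress the cut when they follow the
bond.  The default rule set is pepsin at pH 1.3 (cuts after F or L, no
blocking), trypsin (after K or R, not before P) and chymotrypsin A (after
W, Y or F, not before P).  The three enzymes act *concurrently* and
digestion is *complete*: a peptide bond is cut iff at least one enzyme can
cut it, and no missed cleavages are modelled.  This single-pass model — no
sequential gastric-then-intestinal phases, no kinetics — is the standard
"enzyme action" idealisation for bioactive-peptide mining, and it makes the
digest a deterministic function of the sequence.  Blocking is per-enzyme:
a bond blocked for chymotrypsin by a following proline can still be cut by
pepsin.

Fragments are the maximal runs between cuts; their in-order concatenation
reconstructs the parent (a tested invariant), free amino acids are retained
as class-1 fragments, and fragment counts are reported in the length
classes 1, 2, 3, 4 and >4 residues.  The rules live in a TSV file
(`enzyme_rules.tsv`), so alternative specificities are a data edit, not a
code change.  Because published servers do not print their exact rule
tables, whole-proteome fragment counts are sensitive to this choice; the
bundled set reflects the standard published specificities, consistent with
the C-termini (F/L/Y/K) of every catalogued dipeptide.

```{r digest}
frags <- digest(protein_record("demo", "VYAKLE"), default_enzyme_rules())
frags$sequence
```

## Bioactivity catalog

Matching uses exact full-sequence equality against a catalog of known
bioactive peptides — the semantics of searching released fragments against
a curated database, not substring or similarity search.  The bundled
catalog records the eight validated anti-ACE dipeptides (AY, CF, EF, GM,
IL, TF, VF, VY), the eight validated anti-DPP-IV peptides (AY, IL, SL, TF,
TY, VF, VL, VY), three known anti-ACE peptides with poor absorption (ASL,
ITF, IVR) and four reverse-screen predictions (anti-ACE: GIL, DL, AK;
anti-DPP-IV: IAL) stored as annotations with their prediction
probabilities.  Occurrence counts (every repeat) and unique-sequence sets
are both first-class outputs; the bifunctional set is the intersection of
the two activities' unique sets.

## Peptide chemistry

Each canonical residue has a bundled heavy-atom template (neutral free
amino acid).  A peptide graph condenses templates through amide bonds,
losing one water per bond.  No stereochemistry is modelled (no computed
descriptor depends on it) and the molecule is kept neutral — ionisation
enters only the screening charge classifier.  The SMILES emitter walks the
graph depth-first with ring-closure digits; round-trip isomorphism is
checked in the tests against an independent cheminformatics toolkit.

Descriptors, all atom- or fragment-additive:

* **MW** — sum of average atomic masses (H, C, N, O, S: 1.008, 12.011,
  14.007, 15.999, 32.06 g/mol).
* **Fraction Csp3** — sp3 carbons over total carbons; reported to 2
  decimals.
* **Rotatable bonds** — non-ring single bonds whose two atoms each have at
  least two heavy neighbours, *including* amide C–N bonds.  The stricter
  amide-excluding convention underestimates every printed reference count;
  the inclusive rule reproduces them all.
* **HBA** — N + O count minus nitrogens adjacent to a carbonyl carbon;
  sulfur never counts.  This is the one descriptor whose convention differs
  from common toolkits (which count pharmacophore acceptors); the rule here
  reproduces the published screening tables, and the divergence is
  documented in the oracle tests.
* **HBD** — N or O atoms bearing at least one hydrogen; thiol S–H never
  counts.
* **TPSA** — Ertl fragment contributions summed over N/O/S environments
  (e.g. terminal NH2 26.02, backbone amide N–H 12.03, carbonyl O 17.07,
  carboxyl 37.30, hydroxyl 20.23, thiol 38.80, thioether 25.30 Å²); the
  bundled table covers every residue chemotype, including the aromatic
  nitrogens of histidine and tryptophan.  For an n-mer this decomposes as
  26.02 + (n−1)·29.10 + 37.30 + side-chain terms (proline's secondary
  backbone nitrogen is the one exception), an additivity identity the test
  suite verifies across all 400 dipeptides.
* **WLOGP** — Wildman–Crippen atom-type contributions (atoms plus implicit
  hydrogens) from the published 68-type table; the graph-based typing here
  covers every environment occurring in canonical peptides and agrees with
  an independent implementation to <0.02 on random peptides.
* **MLOGP** — the Moriguchi 13-parameter regression.  Three modelling
  choices were needed where the original publication is terse: the amide
  N/O proximity pair counts 2 (not 1), aromatic Kekulé double bonds count
  toward the unsaturation term, and the intramolecular H-bond dummy is 0
  for linear peptides.  MLOGP feeds only the rule-of-five bound
  (MLOGP > 4.15), which no short peptide approaches, so these choices do
  not affect any screening verdict.

```{r chem}
descriptor_table(c("AY", "GIL", "GM"))
```

## Screening cascade

* **GI absorption** — the BOILED-Egg human-intestinal-absorption ellipse in
  (TPSA, WLOGP) space, with the published coefficients shipped in the
  configuration: centre (71.051, 2.292), semi-axes (71.04, 4.37), rotation
  −1.03°.  A peptide is "high" iff its point lies inside.
* **Charge class** at pH 6.5 — +1 for the amino terminus and each K/R, −1
  for the carboxyl terminus and each D/E; histidine neutral (it gains +1
  only below pH 6).
* **Abbott bioavailability score** — anions: 0.11 (TPSA > 150), 0.56
  (75 < TPSA ≤ 150), 0.85 (TPSA ≤ 75); non-anions: 0.55 with at most one
  rule-of-five violation, else 0.17.
* **Lipinski rule-of-five** — violations among MW > 500, MLOGP > 4.15,
  HBA > 10, HBD > 5; pass = at most one.
* **Lead-likeness** — violations among MW < 250, MW > 350, logP > 3.5,
  RB > 7.  The reference implementation uses XLOGP3, which has no open
  parameterisation; WLOGP substitutes.  Every shortlisted peptide sits far
  below the 3.5 bound, so the substitution cannot flip a verdict.
* **Oral-peptide-drug resemblance** — fraction Csp3 ≤ 0.55, RB ≤ 20,
  HBA ≤ 50, HBD ≤ 25, TPSA ≤ 400, −5 ≤ WLOGP ≤ 8 (all inclusive), the
  characteristic ranges of FDA-approved oral peptide drugs.
* **Allergenicity / toxicity** — never recomputed: verdicts of external
  predictors are supplied as TSV predicate files.  Unknown peptides are
  excluded from safety-filtered shortlists but stay in the full report.

The filters are independent predicates over the descriptor vector, so the
final shortlist is invariant to the order in which they are applied (a
tested property).  By default only fragments of 2–4 residues enter
screening: digested protein is absorbed predominantly as di- and
tripeptides, and free amino acids are not drug candidates.

```{r screen}
screen_peptides(c("AY", "DL", "ASL"), predicates = read_predicates())[,
  c("peptide", "tpsa", "wlogp", "gi_absorption", "lipinski_violations",
    "bioavailability_score", "lead_violations", "oral_peptide_drug_like")]
```

## Synthetic data

`generate_paramyosin_like()` draws a length uniformly from 516–934 residues
and samples residues i.i.d. with glutamate at 20% (the paramyosin
signature) and the rest uniform.  This emulates composition and length
only: real paramyosins have coiled-coil periodicity, homology between
species and non-uniform local composition, so passing tests demonstrate
correctness of the machinery, not biological realism of the fragments.
`compose_from_fragments()` inverts digestion — it assembles a protein whose
digest is exactly a prescribed fragment list, after verifying that each
junction is cleavable and no fragment contains an internal site — and
`implant_motifs()` plants known bioactive dipeptides with cleavable flanks
so end-to-end recovery through the pipeline is guaranteed by construction.
All randomness flows through explicit integer seeds, and the caller's RNG
state is restored afterwards.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere; fragment `[start, end)`
  slices the parent exactly.
* Residue masses are the standard average monomer masses plus one water
  (18.0153 Da); protein masses are reported to integer Da, peptide
  descriptors to two decimals.  Printed reference weights occasionally
  differ by 0.01 from the unrounded sum (their source rounds differently),
  hence the ±0.01 tolerance on MW comparisons.
* Non-canonical residues (B, J, O, U, X, Z) are rejected at load with the
  offending position; an opt-in flag drops such records instead.  All
  downstream chemistry is undefined for them.
* Ring perception is exact bridge-finding (Tarjan) on the molecular graph;
  "in-ring" bonds are the non-bridges.
* Degenerate inputs are defined: a single residue digests to itself, an
  empty fragment table summarises to zeros, an empty catalog matches
  nothing, an empty predicate file makes every safety verdict unknown.

## Problem sizes and limitations

The test suite exercises the digestion invariants on 1000 seeded synthetic
proteins, TPSA additivity on all 400 dipeptides, and descriptor equivalence
against an independent toolkit on 200 random peptides of length 1–6 —
sizes chosen to cover every residue environment many times over while the
whole suite stays fast.

Known limitations: cleavage is all-or-none (no missed-cleavage enumeration
or kinetics); the catalog is a snapshot, not a live database; reverse
target-screening, docking and molecular dynamics are out of scope — their
published conclusions enter only as catalog annotations; allergenicity and
toxicity are external verdicts; and whole-proteome fragment counts depend
on the exact protease rule tables of the server being emulated, which is
why the rules are data, not code.
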