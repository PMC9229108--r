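# pepscreen

In silico gastrointestinal digestion and drug-likeness screening of
food-protein peptides, in R.

Short peptides released when dietary proteins are digested can inhibit
angiotensin-converting enzyme (ACE, a hypertension target) and dipeptidyl
peptidase IV (DPP-IV, a type-2-diabetes target). `pepscreen` implements the
full in silico discovery pipeline for such peptides — built around
glutamate-rich invertebrate paramyosins as the motivating protein family —
as a tested, reusable package for computational peptide-discovery work:

* **Digestion** — complete, concurrent cleavage by pepsin (pH 1.3, after
  F/L), trypsin (after K/R, not before P) and chymotrypsin A (after W/Y/F,
  not before P): a bond is cut iff some enzyme can cut it. Rules are data
  (TSV), not code.
* **Bioactivity matching** — exact-sequence lookup of released fragments in
  a bundled catalog of validated anti-ACE/anti-DPP-IV peptides, with
  occurrence counts, unique sets and the bifunctional intersection.
* **Peptide chemistry** — residue-template molecular graphs, SMILES
  emission, and the additive descriptor set: MW, fraction Csp3, rotatable
  bonds (amide C–N included), H-bond donors/acceptors, Ertl TPSA,
  Wildman–Crippen WLOGP and Moriguchi MLOGP, all from bundled published
  contribution tables.
* **Screening** — BOILED-Egg GI-absorption ellipse in (TPSA, WLOGP) space,
  Lipinski rule-of-five, lead-likeness, Abbott bioavailability score,
  oral-peptide-drug resemblance, and pluggable allergenicity/toxicity
  predicate files.
* **Synthetic data** — seeded paramyosin-like protein generators with
  ground-truth digests (`compose_from_fragments()`, `implant_motifs()`) so
  every stage is testable end to end without downloads.

## Worked example

```r
library(pepscreen)

fa <- tempfile(fileext = ".fasta")
write_fasta(protein_record("demo", "VYAKLE", label = "toy"), fa)
run <- run_pipeline(fa)
run
#> <pepscreen_run>
#>   proteins: 1   fragments: 4 (2 of >=2 residues)
#>   screened peptides (len 2-4): 2
#>   safe matched uniques: 2   bifunctional: VY
#>   drug-like: VY
```

The toy protein digests into VY, AK, L and E (cuts after Y by
chymotrypsin, after K by trypsin, after L by pepsin). The two dipeptides
enter screening; VY is a validated bifunctional anti-ACE/anti-DPP-IV
peptide and passes every drug-likeness filter, AK is a predicted anti-ACE
candidate.

```r
descriptor_table(c("AY", "VY", "GIL"))
#>   peptide     mw frac_csp3 rb hba hbd   tpsa wlogp mlogp
#> 1      AY 252.27      0.33  6   5   4 112.65 -0.15 -1.87
#> 2      VY 280.32      0.43  7   5   4 112.65  0.49 -1.34
#> 3     GIL 301.39      0.79 11   5   4 121.52  0.09 -1.38
```

Columns: molecular weight (g/mol), fraction of sp3 carbons, rotatable
bonds, H-bond acceptors/donors, topological polar surface area (Å²) and
the two logP estimates. `screen_peptides()` turns descriptor rows into the
full screening profile (GI absorption, charge class, Lipinski and
lead-likeness violations, Abbott score, oral-peptide-drug resemblance,
safety verdicts).

A command-line interface covering each stage is installed with the
package:

```sh
pepscreen=$(Rscript -e 'cat(system.file("exec", "pepscreen", package = "pepscreen"))')
Rscript "$pepscreen" digest --fasta proteins.fasta --out fragments.tsv
Rscript "$pepscreen" run    --fasta proteins.fasta --out report_dir
Rscript "$pepscreen" synth  --seed 1 --n 3 --motifs VY --out synthetic.fasta
```

## Package layout

| Path | Contents |
| --- | --- |
| `R/` | digestion engine, catalog, molecular graphs, descriptors, screening, pipeline, synthetic generators |
| `inst/extdata/` | enzyme rules, bioactivity catalog, safety predicates, residue templates, Ertl/Wildman–Crippen/Moriguchi tables, configuration |
| `inst/oracle/` | rdkit oracle script used by the tests |
| `exec/pepscreen` | command-line interface |
| `vignettes/pepscreen-methods.Rmd` | the methods vignette: models, conventions, design choices, limitations |
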