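Package: pepscreen
Title: In Silico Gastrointestinal Digestion and Drug-Likeness Screening of
    Food-Protein Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates concurrent gastrointestinal proteolysis (pepsin, trypsin,
    chymotrypsin) of dietary proteins such as invertebrate paramyosins, matches
    the released fragments against a catalog of known anti-ACE and anti-DPP-IV
    peptides, builds residue-template molecular graphs for candidate peptides,
    and computes fragment-additive physicochemical descriptors (Ertl topological
    polar surface area, Wildman-Crippen and Moriguchi logP, rotatable bonds,
    hydrogen-bond donors/acceptors) feeding a multi-rule screening cascade:
    BOILED-Egg gastrointestinal absorption, Lipinski rule-of-five, lead-likeness,
    Abbott bioavailability score and oral-peptide-drug resemblance.  Includes a
    seeded generator of paramyosin-like synthetic proteins with ground-truth
    digests for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
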