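test_that("charge classes follow the ionizable-residue bookkeeping", {
  expect_equal(charge_class("AY"), "neutral")  # termini cancel
  expect_equal(charge_class("DL"), "anion")
  expect_equal(charge_class("AK"), "cation")
  expect_equal(charge_class("KR"), "cation")
  expect_equal(charge_class("DE"), "anion")
  # histidine neutral at pH 6.5, cationic below pH 6
  expect_equal(charge_class("HA"), "neutral")
  expect_equal(charge_class("HA", ph = 5), "cation")
})

test_that("Abbott bioavailability score follows charge class and TPSA", {
  expect_equal(bioavailability_score(descriptors("DL"), charge_class("DL")),
               0.56)
  expect_equal(bioavailability_score(descriptors("AK"), charge_class("AK")),
               0.55)
  # an anion with TPSA 96.41 scores 0.56; extreme TPSA drops to 0.11
  fake <- structure(list(tpsa = 96.41), class = "descriptor_set")
  expect_equal(bioavailability_score(fake, "anion"), 0.56)
  fake$tpsa <- 160
  expect_equal(bioavailability_score(fake, "anion"), 0.11)
  fake$tpsa <- 60
  expect_equal(bioavailability_score(fake, "anion"), 0.85)
  # non-anion failing the rule-of-five scores 0.17
  bad <- structure(list(mw = 600, mlogp = 5, hba = 11, hbd = 6, tpsa = 50),
                   class = "descriptor_set")
  expect_equal(bioavailability_score(bad, "neutral"), 0.17)
  expect_true(all(vapply(table7$peptide, function(p)
    bioavailability_score(descriptors(p), charge_class(p)), 0) %in%
      c(0.11, 0.17, 0.55, 0.56, 0.85)))
})

test_that("Lipinski violations count the four rule-of-five bounds", {
  for (p in table7$peptide) {
    expect_equal(lipinski_violations(descriptors(p)), 0L, label = p)
  }
  expect_equal(lipinski_violations(descriptors("GG")), 0L)
  hypo <- structure(list(mw = 600, mlogp = 0, hba = 5, hbd = 6),
                    class = "descriptor_set")
  expect_equal(lipinski_violations(hypo), 2L)
})

test_that("lead-likeness violations match the printed screening table", {
  for (i in seq_len(nrow(table8))) {
    expect_equal(lead_violations(descriptors(table8$peptide[i])),
                 table8$lead_violations[i], label = table8$peptide[i])
  }
})

test_that("GI absorption is the BOILED-Egg ellipse membership", {
  far <- structure(list(tpsa = 300, wlogp = 0), class = "descriptor_set")
  expect_equal(classify_gi_absorption(far), "low")
  near <- structure(list(tpsa = 71.051, wlogp = 2.292),
                    class = "descriptor_set")
  expect_equal(classify_gi_absorption(near), "high")
})

test_that("oral-peptide-drug resemblance selects the aromatic-tail dipeptides", {
  got <- table7$peptide[vapply(table7$peptide, function(p)
    oral_peptide_drug_like(descriptors(p)), TRUE)]
  expect_setequal(got, drug_like7)
  expect_false(oral_peptide_drug_like(descriptors("IL")))  # Csp3 0.83
  # the Csp3 bound is inclusive ("up to 0.55")
  edge <- structure(list(frac_csp3 = 0.55, rb = 1, hba = 1, hbd = 1,
                         tpsa = 10, wlogp = 0), class = "descriptor_set")
  expect_true(oral_peptide_drug_like(edge))
})

test_that("external safety predicates attach verdicts and gate the shortlist", {
  preds <- read_predicates()
  prof <- screen_peptides(table7$peptide, predicates = preds)
  expect_true(all(!prof$allergenic & !prof$toxic))
  expect_setequal(safe_shortlist(prof), table7$peptide)

  # empty predicate file: verdicts unknown, shortlist empty, table intact
  empty <- tempfile()
  writeLines("sequence\tallergenic\ttoxic", empty)
  prof2 <- screen_peptides(c("AY", "VY"), predicates = read_predicates(empty))
  expect_true(all(is.na(prof2$allergenic)))
  expect_length(safe_shortlist(prof2), 0L)
  expect_equal(nrow(prof2), 2L)

  # a toxic verdict removes the peptide from the shortlist only
  tox <- tempfile()
  writeLines(c("sequence\tallergenic\ttoxic", "VY\t0\t1", "AY\t0\t0"), tox)
  prof3 <- screen_peptides(c("AY", "VY"), predicates = read_predicates(tox))
  expect_equal(safe_shortlist(prof3), "AY")
  expect_true("VY" %in% prof3$peptide)

  bad <- tempfile()
  writeLines(c("sequence\tallergenic\ttoxic", "VY\t2\t0"), bad)
  expect_error(read_predicates(bad), "0 or 1")
})

test_that("the shortlist is invariant to input order", {
  preds <- read_predicates()
  peps <- c(table7$peptide, low_absorption3)
  p1 <- screen_peptides(peps, predicates = preds)
  set.seed(4)
  p2 <- screen_peptides(sample(peps), predicates = preds)
  expect_setequal(safe_shortlist(p1), safe_shortlist(p2))
})
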