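trypsin <- enzyme_rule("trypsin", p1 = c("K", "R"), p1_prime_block = "P")

test_that("cleavage sites follow P1/P1' specificity with per-enzyme blocking", {
  expect_equal(find_cleavage_sites("AAAA", list(trypsin)), integer())
  # K at index 1 is blocked by the following P; cuts fall after R (0-based
  # cut position 4) and after the second K (position 6)
  expect_equal(find_cleavage_sites("AKPRGKF", list(trypsin)), c(4L, 6L))
  expect_equal(find_cleavage_sites("VYAKLE", default_enzyme_rules()),
               c(2L, 4L, 5L))
  expect_error(find_cleavage_sites("VYAKLE", list()), "at least one")
})

test_that("blocking is per-enzyme, not global", {
  # chymotrypsin is blocked by P after F, but pepsin (no block set) still cuts
  pepsin <- enzyme_rule("pepsin", p1 = c("F", "L"))
  chymo <- enzyme_rule("chymo", p1 = c("W", "Y", "F"), p1_prime_block = "P")
  expect_equal(find_cleavage_sites("AFPA", list(chymo)), integer())
  expect_equal(find_cleavage_sites("AFPA", list(chymo, pepsin)), 2L)
})

test_that("complete digestion yields maximal runs that reconstruct the parent", {
  rules <- default_enzyme_rules()
  expect_equal(digest("A", rules)$sequence, "A")
  frags <- digest(protein_record("demo", "VYAKLE"), rules)
  expect_equal(frags$sequence, c("VY", "AK", "L", "E"))
  expect_equal(frags$start, c(0L, 2L, 4L, 5L))
  expect_equal(frags$end, c(2L, 4L, 5L, 6L))
  expect_equal(as.character(frags$length_class), c("2", "2", "1", "1"))
  expect_equal(frags$parent_id, rep("demo", 4L))
})

test_that("digestion reconstructs and is idempotent on random proteins", {
  rules <- default_enzyme_rules()
  set.seed(99)
  for (k in 1:40) {
    seq <- random_peptide(sample(50:400, 1))
    frags <- digest(seq, rules)
    # reconstruction
    expect_equal(paste(frags$sequence, collapse = ""), seq)
    expect_equal(sum(nchar(frags$sequence)), nchar(seq))
    expect_equal(frags$sequence,
                 substring(seq, frags$start + 1L, frags$end))
    # idempotence: re-digesting any fragment returns it unchanged
    for (f in unique(frags$sequence)) {
      expect_equal(digest(f, rules)$sequence, f)
    }
  }
})

test_that("adding an enzyme rule never decreases the fragment count", {
  pepsin <- enzyme_rule("pepsin", p1 = c("F", "L"))
  chymo <- enzyme_rule("chymo", p1 = c("W", "Y", "F"), p1_prime_block = "P")
  set.seed(7)
  for (k in 1:25) {
    seq <- random_peptide(sample(30:200, 1))
    n1 <- nrow(digest(seq, list(trypsin)))
    n2 <- nrow(digest(seq, list(trypsin, pepsin)))
    n3 <- nrow(digest(seq, list(trypsin, pepsin, chymo)))
    expect_true(n1 <= n2 && n2 <= n3)
  }
})

test_that("digest summaries count length classes and dipeptide share", {
  rules <- default_enzyme_rules()
  s <- summarize_digest(digest(protein_record("demo", "VYAKLE"), rules))
  expect_equal(s$total, 4L)
  expect_equal(unname(s$counts[["2"]]), 2L)
  expect_equal(unname(s$n_multi), 2L)
  expect_equal(unname(s$shares[["2"]]), 0.5)

  empty <- summarize_digest(digest("A", rules)[0, ])
  expect_equal(empty$total, 0L)
  expect_equal(unname(empty$counts), rep(0L, 5L))

  two <- rbind(digest(protein_record("a", "VY"), rules),
               digest(protein_record("b", "VY"), rules))
  expect_error(summarize_digest(two), "multiple parents")
})

test_that("fragments longer than four residues fall in the >4 class", {
  frags <- digest("AAAAAAAA", list(trypsin))
  expect_equal(as.character(frags$length_class), ">4")
  s <- summarize_digest(frags)
  expect_equal(unname(s$counts[[">4"]]), 1L)
})

test_that("enzyme rules load from TSV and validate their residue sets", {
  rules <- default_enzyme_rules()
  expect_length(rules, 3L)
  names_ <- vapply(rules, `[[`, "", "name")
  expect_setequal(names_, c("pepsin_pH1.3", "trypsin", "chymotrypsin_A"))
  tr <- rules[[which(names_ == "trypsin")]]
  expect_setequal(tr$p1, c("K", "R"))
  expect_equal(tr$p1_prime_block, "P")
  pe <- rules[[which(names_ == "pepsin_pH1.3")]]
  expect_length(pe$p1_prime_block, 0L)
  expect_error(enzyme_rule("x", p1 = character()), "non-empty")
  expect_error(enzyme_rule("x", p1 = "B"), "canonical")
})
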