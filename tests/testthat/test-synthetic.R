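test_that("the composition generator is seeded and reproducible", {
  spec <- composition_spec(seed = 1)
  r1 <- generate_paramyosin_like(spec)
  r2 <- generate_paramyosin_like(spec)
  expect_equal(r1$sequence, r2$sequence)
  expect_true(nchar(r1$sequence) >= 516 && nchar(r1$sequence) <= 934)
  expect_match(r1$label, "synthetic\\|seed=1")
  # a different seed gives a different protein
  r3 <- generate_paramyosin_like(composition_spec(seed = 2))
  expect_false(identical(r1$sequence, r3$sequence))
})

test_that("degenerate compositions are honoured exactly", {
  rec <- generate_paramyosin_like(
    composition_spec(freqs = c(E = 1), length_range = c(10, 10), seed = 5))
  expect_equal(rec$sequence, strrep("E", 10))
})

test_that("the glutamate fraction concentrates near its 20% target", {
  rec <- generate_paramyosin_like(
    composition_spec(length_range = c(900, 900), seed = 7))
  e_frac <- mean(strsplit(rec$sequence, "")[[1]] == "E")
  expect_true(e_frac >= 0.17 && e_frac <= 0.23)
})

test_that("composition specs validate frequencies and length ranges", {
  expect_error(composition_spec(freqs = c(E = 0.5)), "sum to 1")
  expect_error(composition_spec(freqs = c(Z = 1)), "canonical")
  expect_error(composition_spec(length_range = c(0, 10)), "length_range")
  expect_error(composition_spec(length_range = c(100, 20000)), "length_range")
})

test_that("compose_from_fragments builds proteins whose digest is the input", {
  rules <- default_enzyme_rules()
  rec <- compose_from_fragments(c("VY", "AK", "L", "E"), rules)
  expect_equal(rec$sequence, "VYAKLE")
  expect_equal(digest(rec, rules)$sequence, c("VY", "AK", "L", "E"))

  one <- compose_from_fragments("AA", rules)
  expect_equal(digest(one, rules)$sequence, "AA")

  # a non-final fragment must end in a usable P1 residue
  expect_error(compose_from_fragments(c("AP", "K"), list(
    enzyme_rule("trypsin", p1 = c("K", "R"), p1_prime_block = "P"))),
    "junction")
  # fragments may not contain internal cleavage sites
  expect_error(compose_from_fragments(c("AKA", "K"), list(
    enzyme_rule("trypsin", p1 = c("K", "R")))),
    "internal cleavage site")
})

test_that("digest-identity recovery holds for fragment lists from random digests", {
  rules <- default_enzyme_rules()
  for (seed in 1:20) {
    host <- generate_paramyosin_like(
      composition_spec(length_range = c(100, 300), seed = seed))
    frags <- digest(host, rules)$sequence
    rec <- compose_from_fragments(frags, rules, seed = seed)
    expect_equal(digest(rec, rules)$sequence, frags)
  }
})

test_that("implanted motifs are excised intact by digestion", {
  rules <- default_enzyme_rules()
  host <- generate_paramyosin_like(
    composition_spec(length_range = c(600, 600), seed = 3))
  n_before <- sum(digest(host, rules)$sequence == "VY")
  rec <- implant_motifs(host, c("VY", "VY", "VY"), rules, seed = 11)
  frags <- digest(rec, rules)$sequence
  expect_gte(sum(frags == "VY"), n_before + 3L)
  imp <- attr(rec, "implants")
  expect_equal(nrow(imp), 3L)
  # recorded 0-based positions point at the motif in the final sequence
  for (i in seq_len(nrow(imp))) {
    expect_equal(substr(rec$sequence, imp$start[i] + 1L,
                        imp$start[i] + nchar(imp$motif[i])), imp$motif[i])
  }
})

test_that("implanting nothing returns the record unchanged", {
  rules <- default_enzyme_rules()
  host <- generate_paramyosin_like(composition_spec(seed = 8))
  expect_identical(implant_motifs(host, character(), rules), host)
})

test_that("unplaceable motifs are rejected", {
  trypsin_only <- list(enzyme_rule("trypsin", p1 = c("K", "R"),
                                   p1_prime_block = "P"))
  host <- protein_record("h", "AAAA")
  # internal site after K
  expect_error(implant_motifs(host, "KR", trypsin_only, seed = 1),
               "internal cleavage site")
  # motif not ending in a P1 residue cannot be excised
  expect_error(implant_motifs(host, "AA", trypsin_only, seed = 1),
               "P1 residue")
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_paramyosin_like(composition_spec(seed = 42)))
  expect_identical(.Random.seed, before)
})
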