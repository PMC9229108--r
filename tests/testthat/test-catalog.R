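test_that("the bundled catalog records the documented activities", {
  cat <- load_catalog()
  expect_true(any(cat$sequence == "VY" & cat$activity == "anti-ACE"))
  expect_true(any(cat$sequence == "VY" & cat$activity == "anti-DPP-IV"))
  # GM is an anti-ACE record only
  expect_false(any(cat$sequence == "GM" & cat$activity == "anti-DPP-IV"))
  # predicted entries carry their reverse-screen probabilities
  expect_equal(cat$probability[cat$sequence == "GIL"], 0.5345)
  expect_equal(cat$status[cat$sequence == "IAL"], "predicted")
})

test_that("catalog validation rejects duplicates and malformed rows", {
  dup <- tempfile()
  writeLines(c("sequence\tactivity\tstatus",
               "VY\tanti-ACE\tknown", "VY\tanti-ACE\tknown"), dup)
  expect_error(load_catalog(dup), "duplicate")
  bad <- tempfile()
  writeLines(c("sequence\tactivity\tstatus", "VY\tanti-X\tknown"), bad)
  expect_error(load_catalog(bad), "activity")
})

test_that("an empty catalog yields no matches", {
  empty <- tempfile()
  writeLines("sequence\tactivity\tstatus", empty)
  cat <- load_catalog(empty)
  expect_equal(nrow(cat), 0L)
  frags <- digest(protein_record("p", "VYAKLE"), default_enzyme_rules())
  expect_equal(nrow(match_fragments(frags, cat)), 0L)
})

test_that("catalog save/load round-trips", {
  cat <- load_catalog()
  path <- tempfile()
  save_catalog(cat, path)
  back <- load_catalog(path)
  expect_equal(as.data.frame(back)[c("sequence", "activity", "status")],
               as.data.frame(cat)[c("sequence", "activity", "status")])
  expect_equal(back$probability, cat$probability)
})

test_that("matching is exact, reports every occurrence, and is order-agnostic", {
  rules <- default_enzyme_rules()
  cat <- load_catalog()
  frags <- digest(protein_record("p", "VYAKLE"), rules)
  m <- match_fragments(frags, cat)
  vy <- m[m$sequence == "VY", ]
  expect_setequal(vy$activity, c("anti-ACE", "anti-DPP-IV"))
  ak <- m[m$sequence == "AK", ]
  expect_equal(ak$activity, "anti-ACE")
  expect_equal(ak$status, "predicted")
  expect_equal(nrow(match_fragments(frags[0, ], cat)), 0L)

  # repeated occurrences are distinct matches
  frags2 <- digest(protein_record("p", "VYVYAK"), rules)
  m2 <- match_fragments(frags2, cat)
  expect_equal(sum(m2$sequence == "VY" & m2$activity == "anti-ACE"), 2L)

  # permuting fragment order never changes the match multiset
  set.seed(2)
  m3 <- match_fragments(frags2[sample(nrow(frags2)), ], cat)
  key <- function(d) sort(paste(d$start, d$sequence, d$activity))
  expect_equal(key(m3), key(m2))
})

test_that("consolidation deduplicates per activity and intersects to bifunctional", {
  cat <- load_catalog()
  # fragments covering every known catalog sequence once, plus repeats
  seqs <- unique(cat$sequence)
  frags <- data.frame(parent_id = "x", start = 0L, end = nchar(seqs),
                      sequence = seqs, length_class = "2",
                      stringsAsFactors = FALSE)
  m <- match_fragments(frags, cat)
  cons <- consolidate(m, status = "known")
  expect_setequal(cons$by_activity[["anti-ACE"]],
                  c("AY", "CF", "EF", "GM", "IL", "TF", "VF", "VY",
                    "ASL", "ITF", "IVR"))
  expect_setequal(cons$by_activity[["anti-DPP-IV"]],
                  c("AY", "IL", "SL", "TF", "TY", "VF", "VL", "VY"))
  expect_setequal(cons$bifunctional, c("AY", "IL", "TF", "VF", "VY"))
  expect_lte(length(cons$bifunctional),
             min(lengths(cons$by_activity)))
  # per-parent views exist
  expect_true("x" %in% names(cons$by_parent))
})
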