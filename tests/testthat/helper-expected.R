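# Frozen expected values for the 15-peptide shortlist (printed descriptor
# and screening tables) and small shared fixtures.

table7 <- data.frame(
  peptide   = c("AK", "AY", "CF", "DL", "EF", "GIL", "GM", "IAL", "IL",
                "SL", "TF", "TY", "VF", "VL", "VY"),
  mw        = c(217.27, 252.27, 268.33, 246.26, 294.30, 301.38, 206.26,
                315.41, 244.33, 218.25, 266.29, 282.29, 264.32, 230.30,
                280.32),
  frac_csp3 = c(0.78, 0.33, 0.33, 0.70, 0.36, 0.79, 0.71, 0.80, 0.83,
                0.78, 0.38, 0.38, 0.43, 0.82, 0.43),
  rb        = c(8L, 6L, 7L, 8L, 9L, 11L, 7L, 11L, 8L, 7L, 7L, 7L, 7L, 7L, 7L),
  hba       = c(5L, 5L, 4L, 6L, 6L, 5L, 4L, 5L, 4L, 5L, 5L, 6L, 4L, 4L, 5L),
  hbd       = c(4L, 4L, 3L, 4L, 4L, 4L, 3L, 4L, 3L, 4L, 4L, 5L, 3L, 3L, 4L),
  tpsa      = c(118.44, 112.65, 131.22, 129.72, 129.72, 121.52, 117.72,
                121.52, 92.42, 112.65, 112.65, 132.88, 92.42, 92.42, 112.65),
  stringsAsFactors = FALSE)

table8 <- data.frame(
  peptide = table7$peptide,
  lipinski_violations = rep(0L, 15L),
  bioavailability_score = c(0.55, 0.55, 0.55, 0.56, 0.56, 0.55, 0.55, 0.55,
                            0.55, 0.55, 0.55, 0.55, 0.55, 0.55, 0.55),
  lead_violations = c(2L, 0L, 0L, 2L, 1L, 1L, 1L, 1L, 2L, 1L, 0L, 0L, 0L,
                      1L, 0L),
  stringsAsFactors = FALSE)

drug_like7 <- c("AY", "CF", "EF", "TF", "TY", "VF", "VY")
low_absorption3 <- c("ASL", "ITF", "IVR")

random_peptide <- function(len) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
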