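# Batch call to the independent cheminformatics oracle (python/rdkit) used
# for descriptor and SMILES round-trip equivalence checks.  One python
# process per batch of peptides.

oracle_descriptors <- function(peptides) {
  script <- system.file("oracle", "rdkit_oracle.py", package = "pepscreen")
  stopifnot(nzchar(script))
  inp <- tempfile(); out <- tempfile()
  smiles <- vapply(peptides, to_smiles, "")
  writeLines(paste(peptides, smiles, sep = "\t"), inp)
  status <- system2("python", script, stdout = out, stdin = inp)
  stopifnot(status == 0L)
  res <- utils::read.delim(out, stringsAsFactors = FALSE)
  stopifnot(nrow(res) == length(peptides))
  res
}
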