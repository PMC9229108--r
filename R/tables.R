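# Loaders for the bundled constant tables (published residue masses, Ertl
# polar-fragment contributions, Wildman-Crippen atom types, Moriguchi
# regression terms, residue graph templates).  Cached per session.

.pepscreen_cache <- new.env(parent = emptyenv())

pk_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pepscreen")
  if (!nzchar(path)) stop("bundled data file not found: ", file, call. = FALSE)
  path
}

read_tsv_file <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             comment.char = "#", quote = "", fill = TRUE,
             na.strings = character())
}

pk_cached <- function(name, loader) {
  if (!exists(name, envir = .pepscreen_cache, inherits = FALSE)) {
    assign(name, loader(), envir = .pepscreen_cache)
  }
  get(name, envir = .pepscreen_cache, inherits = FALSE)
}

residue_masses <- function() {
  pk_cached("residue_masses", function() {
    d <- read_tsv_file(pk_extdata("residue_masses.tsv"))
    setNames(d$mass, d$residue)
  })
}

atomic_masses <- function() {
  pk_cached("atomic_masses", function() {
    d <- read_tsv_file(pk_extdata("atomic_masses.tsv"))
    setNames(d$mass, d$element)
  })
}

ertl_table <- function() {
  pk_cached("ertl_table", function() read_tsv_file(pk_extdata("ertl_tpsa.tsv")))
}

wc_contributions <- function() {
  pk_cached("wc_contributions", function() {
    d <- read_tsv_file(pk_extdata("wildman_crippen.tsv"))
    setNames(d$logp, d$type)
  })
}

moriguchi_params <- function() {
  pk_cached("moriguchi_params", function() {
    d <- read_tsv_file(pk_extdata("moriguchi_params.tsv"))
    rownames(d) <- d$term
    d
  })
}

sidechain_templates <- function() {
  pk_cached("sidechain_templates", function() {
    atoms <- read_tsv_file(pk_extdata("residue_sidechain_atoms.tsv"))
    bonds <- read_tsv_file(pk_extdata("residue_sidechain_bonds.tsv"))
    out <- lapply(AA20, function(r) {
      list(atoms = atoms[atoms$residue == r, , drop = FALSE],
           bonds = bonds[bonds$residue == r, , drop = FALSE])
    })
    names(out) <- AA20
    out
  })
}

default_config_file <- function() pk_extdata("pepscreen_config.yml")
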