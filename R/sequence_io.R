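# Protein sequence input/output and per-protein summary statistics.

#' Create a protein record
#'
#' A protein record couples an identifier (typically a UniProtKB accession)
#' with a species label and an amino-acid sequence over the 20 canonical
#' one-letter codes.  Sequences are normalised to upper case and validated.
#'
#' @param id Non-empty identifier, unique within a collection.
#' @param sequence Amino-acid sequence (canonical residues only).
#' @param label Free-text species/short code (e.g. \code{"JS"} for Japanese
#'   scallop); may be empty.
#' @return An object of class \code{protein_record}.
#' @examples
#' protein_record("P1", "VYAKLE", label = "demo")
#' @export
protein_record <- function(id, sequence, label = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("'id' must be a non-empty character scalar", call. = FALSE)
  }
  sequence <- validate_peptide(sequence, context = id)
  structure(list(id = id, label = as.character(label), sequence = sequence),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s%s  (%d aa)\n", x$id,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              nchar(x$sequence)))
  seq <- x$sequence
  if (nchar(seq) > 60) seq <- paste0(substr(seq, 1, 57), "...")
  cat(" ", seq, "\n")
  invisible(x)
}

# Normalise and validate a peptide/protein sequence; reports the position of
# the first offending character.
validate_peptide <- function(sequence, context = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop("sequence must be a character scalar", call. = FALSE)
  }
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (!nzchar(sequence)) {
    stop("empty sequence in '", context, "'", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% AA20))
  if (length(bad)) {
    stop(sprintf("non-canonical residue '%s' at position %d in '%s'",
                 chars[bad[1L]], bad[1L], context), call. = FALSE)
  }
  sequence
}

parse_fasta_header <- function(header) {
  header <- trimws(header)
  first <- sub("\\s.*$", "", header)
  rest <- trimws(sub("^\\S+\\s*", "", header))
  # UniProt-style "db|ACC|NAME" headers yield the accession
  id <- if (grepl("^[A-Za-z]+\\|[^|]+\\|", first)) {
    strsplit(first, "|", fixed = TRUE)[[1L]][2L]
  } else {
    first
  }
  list(id = id, label = rest)
}

#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a list of [protein_record()] objects.  UniProt
#' style headers (\code{db|ACC|NAME ...}) yield \code{id = ACC}; any other
#' header yields the first whitespace-delimited token.  The remainder of the
#' header line becomes the record label.  Sequence lines are joined,
#' whitespace-stripped and upper-cased.  Records containing residues outside
#' the canonical 20-letter alphabet are rejected (strict mode) or dropped
#' with a warning when \code{drop_invalid = TRUE}.
#'
#' @param path Path to an existing FASTA file.
#' @param drop_invalid Drop records with non-canonical residues instead of
#'   failing.
#' @return A named list of \code{protein_record} objects (names are ids).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P1|X demo", "VYAK"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, drop_invalid = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  headers <- names(set)
  seqs <- unname(as.character(set))
  records <- vector("list", length(set))
  keep <- logical(length(set))
  for (i in seq_along(set)) {
    h <- parse_fasta_header(headers[i])
    rec <- tryCatch(protein_record(h$id, seqs[i], label = h$label),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      if (drop_invalid) {
        warning("dropping record '", h$id, "': ", conditionMessage(rec),
                call. = FALSE)
        next
      }
      stop(conditionMessage(rec), call. = FALSE)
    }
    records[[i]] <- rec
    keep[i] <- TRUE
  }
  records <- records[keep]
  ids <- vapply(records, `[[`, "", "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate record id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  names(records) <- ids
  records
}

#' Write protein records to a FASTA file
#'
#' Inverse of [read_fasta()]: headers are \code{">id label"} (label omitted
#' when empty), sequences wrapped at 60 columns.
#'
#' @param records A list of [protein_record()] objects (or a single record).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "protein_record")) records <- list(records)
  seqs <- vapply(records, `[[`, "", "sequence")
  ids <- vapply(records, `[[`, "", "id")
  labels <- vapply(records, `[[`, "", "label")
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- ifelse(nzchar(labels), paste(ids, labels), ids)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Residue count and average molecular mass of a protein or peptide
#'
#' The mass is the sum of the standard average residue (monomer) masses plus
#' one water (18.0153 Da), i.e. the average molecular mass of the neutral
#' linear chain.
#'
#' @param record A [protein_record()] or a plain sequence string.
#' @return A list with \code{n_residues} and \code{mass_da} (unrounded).
#' @examples
#' protein_stats("AY")  # 2 residues, 252.27 Da
#' @export
protein_stats <- function(record) {
  seq <- if (inherits(record, "protein_record")) record$sequence
         else validate_peptide(record)
  list(n_residues = nchar(seq), mass_da = peptide_mass(seq))
}

#' Average molecular mass of a peptide chain
#'
#' @param sequence Canonical amino-acid sequence.
#' @return Mass in Da (unrounded).
#' @export
peptide_mass <- function(sequence) {
  sequence <- validate_peptide(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  sum(residue_masses()[chars]) + WATER_MASS
}

#' Summary table of a protein collection
#'
#' One row per record with id, label, residue count and molecular mass
#' rounded to integer Da (the convention for whole proteins).
#'
#' @param records List of [protein_record()] objects.
#' @param path Optional path; when given the table is also written as TSV.
#' @return A data.frame with columns id, label, n_residues, mass_da.
#' @export
protein_summary <- function(records, path = NULL) {
  if (inherits(records, "protein_record")) records <- list(records)
  out <- data.frame(
    id = vapply(records, `[[`, "", "id"),
    label = vapply(records, `[[`, "", "label"),
    n_residues = vapply(records, function(r) nchar(r$sequence), 0L),
    mass_da = vapply(records, function(r) round(peptide_mass(r$sequence)), 0),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(path)) write_tsv(out, path)
  out
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
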