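# Rule-based simulation of complete, concurrent multi-protease digestion.
#
# A protease is modelled by its cleavage specificity: the set of P1 residues
# after which it cuts, and the set of P1' residues that suppress the cut when
# they sit immediately C-terminal to the bond (classically proline for
# trypsin and chymotrypsin).  All enzymes act simultaneously and digestion is
# complete: a bond is cut iff at least one enzyme can cut it.

LENGTH_CLASSES <- c("1", "2", "3", "4", ">4")

#' Define a protease cleavage rule
#'
#' @param name Enzyme name.
#' @param p1 Character vector of residues after which the enzyme cleaves.
#' @param p1_prime_block Residues that block cleavage when immediately
#'   C-terminal to the bond (may be empty).
#' @param ec EC number (informative only).
#' @return An object of class \code{enzyme_rule}.
#' @examples
#' enzyme_rule("trypsin", p1 = c("K", "R"), p1_prime_block = "P")
#' @export
enzyme_rule <- function(name, p1, p1_prime_block = character(), ec = "") {
  p1 <- toupper(p1)
  p1_prime_block <- toupper(p1_prime_block)
  p1_prime_block <- p1_prime_block[nzchar(p1_prime_block)]
  if (length(p1) == 0L || !all(p1 %in% AA20)) {
    stop("'p1' must be a non-empty set of canonical residues", call. = FALSE)
  }
  if (!all(p1_prime_block %in% AA20)) {
    stop("'p1_prime_block' must contain canonical residues", call. = FALSE)
  }
  structure(list(name = as.character(name), ec = as.character(ec),
                 p1 = unique(p1), p1_prime_block = unique(p1_prime_block)),
            class = "enzyme_rule")
}

#' @export
print.enzyme_rule <- function(x, ...) {
  cat(sprintf("<enzyme_rule> %s%s: cleaves after {%s}%s\n", x$name,
              if (nzchar(x$ec)) paste0(" (EC ", x$ec, ")") else "",
              paste(x$p1, collapse = ","),
              if (length(x$p1_prime_block))
                paste0(" unless before {", paste(x$p1_prime_block, collapse = ","), "}")
              else ""))
  invisible(x)
}

#' Read protease rules from a TSV file
#'
#' Expected columns: \code{name}, \code{ec}, \code{p1},
#' \code{p1_prime_block}; residue sets are comma-separated.
#'
#' @param path Path to the rules file.
#' @return A list of [enzyme_rule()] objects.
#' @export
read_enzyme_rules <- function(path) {
  if (!file.exists(path)) {
    stop("enzyme rules file not found: ", path, call. = FALSE)
  }
  d <- read_tsv_file(path)
  needed <- c("name", "p1")
  if (!all(needed %in% names(d))) {
    stop("rules file must have columns 'name' and 'p1'", call. = FALSE)
  }
  split_set <- function(x) {
    if (is.null(x) || is.na(x) || !nzchar(x)) character() else
      trimws(strsplit(x, ",", fixed = TRUE)[[1L]])
  }
  lapply(seq_len(nrow(d)), function(i) {
    enzyme_rule(d$name[i], p1 = split_set(d$p1[i]),
                p1_prime_block = split_set(if ("p1_prime_block" %in% names(d))
                  d$p1_prime_block[i] else ""),
                ec = if ("ec" %in% names(d)) d$ec[i] else "")
  })
}

#' Default gastrointestinal rule set
#'
#' Pepsin at pH 1.3 (cleaves after F or L), trypsin (after K or R, not
#' before P) and chymotrypsin A (after W, Y or F, not before P), applied
#' concurrently.  The set lives in a bundled, user-editable TSV file.
#'
#' @return A list of [enzyme_rule()] objects.
#' @export
default_enzyme_rules <- function() {
  read_enzyme_rules(pk_extdata("enzyme_rules.tsv"))
}

as_sequence <- function(x) {
  if (inherits(x, "protein_record")) x$sequence else validate_peptide(x)
}

#' Find cleavage sites under a set of concurrent protease rules
#'
#' A cut position \code{i} (0-based, meaning the bond between residues
#' \code{i-1} and \code{i} of the 0-based sequence) is reported iff some rule
#' has the preceding residue in its P1 set and the following residue outside
#' its P1' blocking set.  Blocking is per-enzyme: a bond blocked for one
#' enzyme may still be cut by another.
#'
#' @param sequence Sequence string or [protein_record()].
#' @param rules Non-empty list of [enzyme_rule()] objects.
#' @return Sorted integer vector of 0-based cut positions (possibly empty).
#' @examples
#' find_cleavage_sites("VYAKLE", default_enzyme_rules())  # 2, 4, 5
#' @export
find_cleavage_sites <- function(sequence, rules) {
  seq <- as_sequence(sequence)
  if (inherits(rules, "enzyme_rule")) rules <- list(rules)
  if (length(rules) == 0L) stop("at least one enzyme rule required", call. = FALSE)
  stopifnot(all(vapply(rules, inherits, TRUE, "enzyme_rule")))
  n <- nchar(seq)
  if (n < 2L) return(integer())
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  cut <- logical(n - 1L)
  for (r in rules) {
    cut <- cut | (chars[-n] %in% r$p1 & !(chars[-1L] %in% r$p1_prime_block))
  }
  which(cut)
}

length_class <- function(len) {
  factor(ifelse(len > 4L, ">4", as.character(len)), levels = LENGTH_CLASSES)
}

#' Digest a protein completely under concurrent protease rules
#'
#' Fragments are the maximal runs between consecutive cut positions; their
#' in-order concatenation reconstructs the parent.  Every occurrence of a
#' repeated sequence is a distinct fragment, and single free residues are
#' retained as class-1 fragments.
#'
#' @param record A [protein_record()] or sequence string (then the parent id
#'   is \code{"query"}).
#' @param rules List of [enzyme_rule()] objects.
#' @return A data.frame of fragments with columns \code{parent_id},
#'   \code{start}, \code{end} (0-based half-open coordinates in the parent),
#'   \code{sequence} and \code{length_class} (factor with levels
#'   1, 2, 3, 4, >4).
#' @examples
#' digest(protein_record("demo", "VYAKLE"), default_enzyme_rules())
#' @export
digest <- function(record, rules) {
  seq <- as_sequence(record)
  id <- if (inherits(record, "protein_record")) record$id else "query"
  sites <- find_cleavage_sites(seq, rules)
  starts <- c(0L, sites)
  ends <- c(sites, nchar(seq))
  data.frame(
    parent_id = id,
    start = starts,
    end = ends,
    sequence = substring(seq, starts + 1L, ends),
    length_class = length_class(ends - starts),
    stringsAsFactors = FALSE)
}

#' Digest a collection of proteins
#'
#' @param records List of [protein_record()] objects.
#' @inheritParams digest
#' @return Row-bound fragment data.frame (see [digest()]).
#' @export
digest_all <- function(records, rules) {
  if (inherits(records, "protein_record")) records <- list(records)
  do.call(rbind, lapply(records, digest, rules = rules))
}

#' Summarise a digest by fragment length class
#'
#' Counts fragments of one parent in the classes 1, 2, 3, 4 and >4 residues
#' (a free amino acid counts as one fragment), the total, the number of
#' fragments of at least two residues, and each class's share of the total.
#'
#' @param fragments Fragment data.frame from [digest()] for one parent (an
#'   empty data.frame yields an all-zero summary).
#' @return An object of class \code{digest_summary}.
#' @examples
#' frags <- digest(protein_record("demo", "VYAKLE"), default_enzyme_rules())
#' summarize_digest(frags)
#' @export
summarize_digest <- function(fragments) {
  parent <- unique(fragments$parent_id)
  if (length(parent) > 1L) {
    stop("fragments from multiple parents: ",
         paste(parent, collapse = ", "), call. = FALSE)
  }
  if (length(parent) == 0L) parent <- NA_character_
  counts <- table(factor(fragments$length_class, levels = LENGTH_CLASSES))
  counts <- setNames(as.integer(counts), LENGTH_CLASSES)
  total <- sum(counts)
  structure(list(
    parent_id = parent,
    counts = counts,
    total = total,
    n_multi = total - counts[["1"]],
    shares = if (total > 0) counts / total else counts * 0),
    class = "digest_summary")
}

#' @export
print.digest_summary <- function(x, ...) {
  cat(sprintf("<digest_summary> %s: %d fragments (%d of >=2 residues)\n",
              x$parent_id, x$total, x$n_multi))
  tab <- data.frame(length_class = names(x$counts),
                    n = unname(x$counts),
                    share = sprintf("%.1f%%", 100 * unname(x$shares)))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Barplot of fragment length-class counts
#'
#' @param x A \code{digest_summary}.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.digest_summary <- function(x, ...) {
  graphics::barplot(x$counts, xlab = "fragment length (residues)",
                    ylab = "fragments", main = x$parent_id, ...)
}

#' Write fragments or summaries as TSV
#'
#' @param fragments Fragment data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  write_tsv(fragments, path)
}
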