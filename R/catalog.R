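# Catalog of known/predicted bioactive peptides and fragment matching.
#
# The bundled default catalog records the experimentally validated anti-ACE
# and anti-DPP-IV dipeptides found in paramyosin digests, plus the four
# sequences whose activity was predicted by reverse target-screening
# (recorded as catalog annotations with their prediction probabilities; no
# similarity computation happens here).

CATALOG_ACTIVITIES <- c("anti-ACE", "anti-DPP-IV")

#' Load a bioactivity catalog
#'
#' TSV columns: \code{sequence}, \code{activity} (anti-ACE or anti-DPP-IV),
#' \code{status} (known or predicted), optional \code{source_id},
#' \code{probability}, \code{notes}.  (sequence, activity) pairs must be
#' unique.
#'
#' @param path Path to a catalog TSV; by default the bundled catalog.
#' @return data.frame of class \code{bioactivity_catalog}.
#' @examples
#' cat <- load_catalog()
#' subset(cat, sequence == "VY")
#' @export
load_catalog <- function(path = pk_extdata("bioactivity_catalog.tsv")) {
  if (!file.exists(path)) {
    stop("catalog file not found: ", path, call. = FALSE)
  }
  d <- read_tsv_file(path)
  needed <- c("sequence", "activity", "status")
  if (!all(needed %in% names(d))) {
    stop("catalog must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(d)) {
    d$sequence <- vapply(d$sequence, validate_peptide, "", USE.NAMES = FALSE)
    if (!all(d$activity %in% CATALOG_ACTIVITIES)) {
      stop("activity must be one of: ",
           paste(CATALOG_ACTIVITIES, collapse = ", "), call. = FALSE)
    }
    if (!all(d$status %in% c("known", "predicted"))) {
      stop("status must be 'known' or 'predicted'", call. = FALSE)
    }
    key <- paste(d$sequence, d$activity)
    if (anyDuplicated(key)) {
      stop("duplicate (sequence, activity) pair(s): ",
           paste(unique(key[duplicated(key)]), collapse = "; "),
           call. = FALSE)
    }
  }
  if (!"source_id" %in% names(d)) d$source_id <- rep("", nrow(d))
  if (!"probability" %in% names(d)) d$probability <- rep(NA_real_, nrow(d))
  d$probability <- suppressWarnings(as.numeric(d$probability))
  class(d) <- c("bioactivity_catalog", "data.frame")
  d
}

#' Write a bioactivity catalog as TSV
#'
#' @param catalog A catalog data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
save_catalog <- function(catalog, path) {
  out <- as.data.frame(catalog)
  out$probability[is.na(out$probability)] <- ""
  write_tsv(out, path)
}

#' Match digestion fragments against a bioactivity catalog
#'
#' Exact full-sequence equality matching (the "search for active fragments"
#' semantics): every fragment occurrence is reported separately, so a
#' repeated dipeptide contributes one match row per occurrence and per
#' activity.
#'
#' @param fragments Fragment data.frame from [digest()] / [digest_all()].
#' @param catalog A [load_catalog()] catalog.
#' @return data.frame with the fragment columns plus \code{activity},
#'   \code{status} and \code{source_id} (zero rows when nothing matches).
#' @examples
#' frags <- digest(protein_record("demo", "VYAKLE"), default_enzyme_rules())
#' match_fragments(frags, load_catalog())
#' @export
match_fragments <- function(fragments, catalog) {
  stopifnot(inherits(catalog, "bioactivity_catalog"))
  empty <- data.frame(parent_id = character(), start = integer(),
                      end = integer(), sequence = character(),
                      length_class = character(), activity = character(),
                      status = character(), source_id = character(),
                      stringsAsFactors = FALSE)
  if (is.null(fragments) || nrow(fragments) == 0L || nrow(catalog) == 0L) {
    return(empty)
  }
  m <- merge(fragments,
             as.data.frame(catalog)[c("sequence", "activity", "status",
                                      "source_id")],
             by = "sequence", sort = FALSE)
  if (nrow(m) == 0L) return(empty)
  m <- m[order(m$parent_id, m$start, m$activity), ]
  rownames(m) <- NULL
  m[c("parent_id", "start", "end", "sequence", "length_class", "activity",
      "status", "source_id")]
}

#' Per-parent match counts by activity
#'
#' Occurrence counts (every repeat counted) and unique-sequence counts per
#' parent protein and activity.
#'
#' @param matches Output of [match_fragments()].
#' @return data.frame with columns parent_id, activity, n_occurrences,
#'   n_unique.
#' @export
match_counts <- function(matches) {
  if (nrow(matches) == 0L) {
    return(data.frame(parent_id = character(), activity = character(),
                      n_occurrences = integer(), n_unique = integer(),
                      stringsAsFactors = FALSE))
  }
  sp <- split(matches, list(matches$parent_id, matches$activity), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(parent_id = g$parent_id[1L], activity = g$activity[1L],
               n_occurrences = nrow(g),
               n_unique = length(unique(g$sequence)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$parent_id, out$activity), ]
}

#' Consolidate matches into unique and bifunctional sequence sets
#'
#' Deduplicates matched sequences per activity, both globally and per parent
#' protein, and intersects the two activities into the bifunctional set.
#'
#' @param matches Output of [match_fragments()].
#' @param status Restrict to \code{"known"} or \code{"predicted"} catalog
#'   records, or \code{"all"}.
#' @return List with \code{by_activity} (named list of sorted unique
#'   sequence vectors), \code{by_parent} (per parent, per activity),
#'   and \code{bifunctional} (intersection across activities).
#' @examples
#' frags <- digest(protein_record("demo", "VYAKLE"), default_enzyme_rules())
#' consolidate(match_fragments(frags, load_catalog()))
#' @export
consolidate <- function(matches, status = c("all", "known", "predicted")) {
  status <- match.arg(status)
  if (status != "all") matches <- matches[matches$status == status, ]
  by_activity <- lapply(setNames(CATALOG_ACTIVITIES, CATALOG_ACTIVITIES),
                        function(a)
                          sort(unique(matches$sequence[matches$activity == a])))
  by_parent <- lapply(split(matches, matches$parent_id), function(g)
    lapply(setNames(CATALOG_ACTIVITIES, CATALOG_ACTIVITIES), function(a)
      sort(unique(g$sequence[g$activity == a]))))
  list(by_activity = by_activity,
       by_parent = by_parent,
       bifunctional = intersect(by_activity[[1L]], by_activity[[2L]]))
}
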