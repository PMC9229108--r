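# End-to-end orchestration: digest -> match -> chemistry -> screen -> report.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline.  Defaults come from the bundled
#' YAML configuration; any argument overrides it.  Relative file names are
#' resolved against the package's extdata directory.
#'
#' @param enzyme_rules Rules list or path to a rules TSV.
#' @param catalog Path to a bioactivity catalog TSV.
#' @param predicates Path to an allergenicity/toxicity predicate TSV, or
#'   \code{NA} to attach no safety verdicts.
#' @param screen_min_len,screen_max_len Fragment length window admitted to
#'   chemistry/screening (default 2-4 residues: the absorbable di- to
#'   tetra-peptides; free amino acids are never screened).
#' @param abbott_ph pH of the charge classification.
#' @param ellipse GI-absorption ellipse coefficients.
#' @param seed Integer recorded in reports (the pipeline itself is
#'   deterministic; the seed matters for synthetic inputs).
#' @param config_file YAML file supplying defaults.
#' @return List of class \code{pepscreen_config}.
#' @export
pepscreen_config <- function(enzyme_rules = NULL, catalog = NULL,
                             predicates = NULL, screen_min_len = NULL,
                             screen_max_len = NULL, abbott_ph = NULL,
                             ellipse = NULL, seed = NULL,
                             config_file = default_config_file()) {
  cfg <- yaml::read_yaml(config_file)
  resolve <- function(p) {
    if (is.null(p) || is.na(p)) return(p)
    if (file.exists(p)) p else pk_extdata(p)
  }
  rules <- enzyme_rules %||% cfg$enzyme_rules
  if (is.character(rules)) rules <- read_enzyme_rules(resolve(rules))
  ell <- ellipse %||% list(
    center = c(tpsa = cfg$gi_absorption$center_tpsa,
               wlogp = cfg$gi_absorption$center_wlogp),
    semi_axes = c(tpsa = cfg$gi_absorption$semi_axis_tpsa,
                  wlogp = cfg$gi_absorption$semi_axis_wlogp),
    rotation_deg = cfg$gi_absorption$rotation_deg)
  structure(list(
    enzyme_rules = rules,
    catalog = resolve(catalog %||% cfg$catalog),
    predicates = resolve(predicates %||% cfg$predicates),
    screen_min_len = screen_min_len %||% cfg$screen_min_len,
    screen_max_len = screen_max_len %||% cfg$screen_max_len,
    abbott_ph = abbott_ph %||% cfg$abbott_ph,
    ellipse = ell,
    seed = seed), class = "pepscreen_config")
}

#' Run the full digestion-to-screening pipeline
#'
#' Reads proteins from FASTA, digests them under the configured protease
#' rules, matches every released fragment against the bioactivity catalog,
#' computes descriptors and the screening cascade for the unique fragment
#' sequences inside the configured length window, consolidates matched
#' sequences into unique/bifunctional/drug-like sets, and assembles a
#' manifest of totals.  Deterministic for fixed inputs and configuration.
#'
#' @param fasta Path to a FASTA file, or a list of [protein_record()]s.
#' @param config A [pepscreen_config()].
#' @param out_dir Optional directory; when given, all tables are written
#'   there as TSV plus a JSON \code{manifest.json}.
#' @return Object of class \code{pepscreen_run}: list with
#'   \code{proteins}, \code{fragments}, \code{summaries}, \code{matches},
#'   \code{match_counts}, \code{profiles} (screening table),
#'   \code{consolidated}, \code{drug_like}, \code{manifest}, \code{config}.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' write_fasta(protein_record("demo", "VYAKLE"), fa)
#' run <- run_pipeline(fa)
#' run$manifest$n_fragments  # 4
#' @export
run_pipeline <- function(fasta, config = pepscreen_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pepscreen_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))
  }
  records <- stage("sequence_io", {
    if (is.character(fasta)) read_fasta(fasta)
    else if (inherits(fasta, "protein_record")) list(fasta)
    else fasta
  })
  proteins <- stage("sequence_io", protein_summary(records))

  fragments <- stage("digestion", digest_all(records, config$enzyme_rules))
  summaries <- stage("digestion", lapply(
    split(fragments, fragments$parent_id)[unique(fragments$parent_id)],
    summarize_digest))

  catalog <- stage("catalog", load_catalog(config$catalog))
  matches <- stage("catalog", match_fragments(fragments, catalog))
  counts <- stage("catalog", match_counts(matches))

  len <- fragments$end - fragments$start
  screen_set <- sort(unique(
    fragments$sequence[len >= config$screen_min_len &
                         len <= config$screen_max_len]))
  predicates <- if (is.null(config$predicates) || is.na(config$predicates))
    NULL else stage("screening", read_predicates(config$predicates))
  profiles <- stage("screening", screen_peptides(
    screen_set, predicates = predicates, ellipse = config$ellipse,
    ph = config$abbott_ph))

  safe <- safe_shortlist(profiles)
  safe_matches <- matches[matches$sequence %in% safe, ]
  cons_known <- consolidate(safe_matches, status = "known")
  cons_all <- consolidate(safe_matches, status = "all")
  drug_like <- profiles$peptide[profiles$oral_peptide_drug_like]
  screened_union <- sort(unique(safe_matches$sequence))
  bifunctional_drug_like <-
    intersect(cons_known$bifunctional, drug_like)

  manifest <- list(
    seed = config$seed,
    n_proteins = nrow(proteins),
    n_fragments = nrow(fragments),
    n_fragments_ge2 = sum(len >= 2L),
    per_protein = lapply(summaries, function(s)
      list(total = s$total, n_multi = unname(s$n_multi),
           by_class = as.list(s$counts))),
    n_screened = length(screen_set),
    n_matches = nrow(matches),
    match_occurrences_safe = list(
      "anti-ACE" = sum(safe_matches$activity == "anti-ACE" &
                         safe_matches$status == "known"),
      "anti-DPP-IV" = sum(safe_matches$activity == "anti-DPP-IV" &
                            safe_matches$status == "known")),
    unique_known = lapply(cons_known$by_activity, as.list),
    unique_screened = as.list(screened_union),
    n_unique_screened = length(screened_union),
    bifunctional_known = as.list(cons_known$bifunctional),
    drug_like = as.list(intersect(screened_union, drug_like)),
    bifunctional_drug_like = as.list(bifunctional_drug_like))

  run <- structure(list(
    proteins = proteins, fragments = fragments, summaries = summaries,
    matches = matches, match_counts = counts, profiles = profiles,
    consolidated = list(known = cons_known, all = cons_all),
    drug_like = drug_like, manifest = manifest, config = config),
    class = "pepscreen_run")

  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(run$proteins, file.path(out_dir, "proteins.tsv"))
  write_tsv(run$fragments, file.path(out_dir, "fragments.tsv"))
  summary_tab <- do.call(rbind, lapply(run$summaries, function(s)
    data.frame(parent_id = s$parent_id, t(s$counts), total = s$total,
               n_multi = unname(s$n_multi), check.names = FALSE)))
  write_tsv(summary_tab, file.path(out_dir, "digest_summary.tsv"))
  write_tsv(run$matches, file.path(out_dir, "matches.tsv"))
  write_tsv(run$match_counts, file.path(out_dir, "match_counts.tsv"))
  write_tsv(run$profiles, file.path(out_dir, "screening.tsv"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}

#' @export
print.pepscreen_run <- function(x, ...) {
  m <- x$manifest
  cat("<pepscreen_run>\n")
  cat(sprintf("  proteins: %d   fragments: %d (%d of >=2 residues)\n",
              m$n_proteins, m$n_fragments, m$n_fragments_ge2))
  cat(sprintf("  screened peptides (len %d-%d): %d\n",
              x$config$screen_min_len, x$config$screen_max_len, m$n_screened))
  cat(sprintf("  safe matched uniques: %d   bifunctional: %s\n",
              m$n_unique_screened,
              paste(unlist(m$bifunctional_known), collapse = ", ")))
  cat(sprintf("  drug-like: %s\n", paste(unlist(m$drug_like), collapse = ", ")))
  invisible(x)
}

#' @export
summary.pepscreen_run <- function(object, ...) {
  print(object)
  cat("\nPer-protein fragment counts:\n")
  for (s in object$summaries) {
    cat(sprintf("  %-14s total %4d  dipeptides %3d (%.1f%%)\n", s$parent_id,
                s$total, s$counts[["2"]], 100 * s$shares[["2"]]))
  }
  invisible(object)
}

#' Length-class distribution barplot of a pipeline run
#'
#' @param x A \code{pepscreen_run}.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.pepscreen_run <- function(x, ...) {
  mat <- vapply(x$summaries, function(s) s$counts, numeric(5L))
  graphics::barplot(mat, beside = TRUE, legend.text = LENGTH_CLASSES,
                    xlab = "protein", ylab = "fragments", ...)
}
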