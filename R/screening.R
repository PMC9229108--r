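# Drug-likeness and absorption screening of peptides.
#
# The cascade mirrors the oral-bioavailability screens applied to short
# food-derived peptides: BOILED-Egg gastrointestinal absorption in
# (TPSA, WLOGP) space, Lipinski rule-of-five, lead-likeness, the Abbott
# bioavailability score driven by charge class and TPSA, resemblance to
# FDA-approved oral peptide drugs, and pluggable allergenicity/toxicity
# verdicts supplied as external predicate files (never recomputed here).

#' Net-charge class of a peptide at mildly acidic-to-neutral pH
#'
#' Formal charges at the default pH 6.5: +1 for the free alpha-amino
#' terminus, +1 per lysine/arginine, -1 for the carboxyl terminus, -1 per
#' aspartate/glutamate.  Histidine is treated as neutral at pH 6.5 (it is
#' counted +1 only below pH 6).
#'
#' @param peptide Canonical peptide sequence.
#' @param ph pH of the classification (default 6.5).
#' @return One of \code{"anion"}, \code{"cation"}, \code{"neutral"}.
#' @examples
#' charge_class("DL")  # anion
#' @export
charge_class <- function(peptide, ph = 6.5) {
  peptide <- validate_peptide(peptide)
  chars <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  pos <- 1L + sum(chars %in% c("K", "R")) + if (ph < 6) sum(chars == "H") else 0L
  neg <- 1L + sum(chars %in% c("D", "E"))
  net <- pos - neg
  if (net < 0) "anion" else if (net > 0) "cation" else "neutral"
}

#' Number of Lipinski rule-of-five violations
#'
#' Violations among MW > 500, MLOGP > 4.15, HBA > 10, HBD > 5.  A compound
#' passes the rule with at most one violation.
#'
#' @param desc A [descriptors()] set.
#' @return Integer violation count (0-4).
#' @export
lipinski_violations <- function(desc) {
  sum(desc$mw > 500, desc$mlogp > 4.15, desc$hba > 10, desc$hbd > 5)
}

#' Abbott bioavailability score
#'
#' Estimates the probability of at least 10\% oral bioavailability from the
#' charge class, TPSA and rule-of-five status; the output is one of the
#' enumerated probabilities 0.11, 0.17, 0.55, 0.56, 0.85.
#'
#' @param desc A [descriptors()] set.
#' @param charge Charge class from [charge_class()].
#' @return One of 0.11, 0.17, 0.55, 0.56, 0.85.
#' @examples
#' bioavailability_score(descriptors("DL"), charge_class("DL"))  # 0.56
#' @export
bioavailability_score <- function(desc, charge) {
  charge <- match.arg(charge, c("anion", "cation", "neutral"))
  if (charge == "anion") {
    if (desc$tpsa > 150) 0.11 else if (desc$tpsa > 75) 0.56 else 0.85
  } else {
    if (lipinski_violations(desc) <= 1) 0.55 else 0.17
  }
}

#' Number of lead-likeness violations
#'
#' Violations among MW < 250, MW > 350, logP > 3.5 and RB > 7; the logP used
#' is WLOGP.  Zero violations means lead-like.
#'
#' @param desc A [descriptors()] set.
#' @return Integer violation count.
#' @examples
#' lead_violations(descriptors("AK"))  # 2 (MW < 250 and RB > 7)
#' @export
lead_violations <- function(desc) {
  sum(desc$mw < 250, desc$mw > 350, desc$wlogp > 3.5, desc$rb > 7)
}

#' Default human-intestinal-absorption ellipse
#'
#' Coefficients of the BOILED-Egg "white" region in (TPSA, WLOGP) space,
#' read from the bundled configuration: centre, semi-axes and anticlockwise
#' rotation (degrees).
#'
#' @return A list with \code{center}, \code{semi_axes} and
#'   \code{rotation_deg}.
#' @export
default_gi_ellipse <- function() {
  cfg <- yaml::read_yaml(default_config_file())$gi_absorption
  list(center = c(tpsa = cfg$center_tpsa, wlogp = cfg$center_wlogp),
       semi_axes = c(tpsa = cfg$semi_axis_tpsa, wlogp = cfg$semi_axis_wlogp),
       rotation_deg = cfg$rotation_deg)
}

#' Classify gastrointestinal absorption (BOILED-Egg)
#'
#' A peptide is predicted highly absorbed iff its (TPSA, WLOGP) point lies
#' inside the configured human-intestinal-absorption ellipse.
#'
#' @param desc A [descriptors()] set.
#' @param ellipse Ellipse coefficients (see [default_gi_ellipse()]).
#' @return \code{"high"} or \code{"low"}.
#' @examples
#' classify_gi_absorption(descriptors("VY"))   # high
#' classify_gi_absorption(descriptors("ASL"))  # low
#' @export
classify_gi_absorption <- function(desc, ellipse = default_gi_ellipse()) {
  th <- ellipse$rotation_deg * pi / 180
  dx <- desc$tpsa - ellipse$center[["tpsa"]]
  dy <- desc$wlogp - ellipse$center[["wlogp"]]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  inside <- (u / ellipse$semi_axes[["tpsa"]])^2 +
    (v / ellipse$semi_axes[["wlogp"]])^2 <= 1
  if (inside) "high" else "low"
}

#' Resemblance to FDA-approved oral peptide drugs
#'
#' True iff fraction Csp3 <= 0.55, RB <= 20, HBA <= 50, HBD <= 25,
#' TPSA <= 400 and -5 <= logP <= 8 (WLOGP); all bounds inclusive.
#'
#' @param desc A [descriptors()] set.
#' @return Logical.
#' @export
oral_peptide_drug_like <- function(desc) {
  desc$frac_csp3 <= 0.55 && desc$rb <= 20 && desc$hba <= 50 &&
    desc$hbd <= 25 && desc$tpsa <= 400 &&
    desc$wlogp >= -5 && desc$wlogp <= 8
}

#' Read an external allergenicity/toxicity predicate file
#'
#' The file is TSV with columns \code{sequence}, \code{allergenic} (0/1) and
#' \code{toxic} (0/1), recording verdicts of external predictors.  Peptides
#' absent from the file are "unknown" downstream.
#'
#' @param path Path to the predicate file (default: the bundled verdicts for
#'   the paramyosin-derived shortlist).
#' @return data.frame with logical columns \code{allergenic}, \code{toxic}.
#' @export
read_predicates <- function(path = pk_extdata("safety_predicates.tsv")) {
  if (!file.exists(path)) {
    stop("predicate file not found: ", path, call. = FALSE)
  }
  d <- read_tsv_file(path)
  if (!all(c("sequence", "allergenic", "toxic") %in% names(d))) {
    stop("predicate file needs columns sequence, allergenic, toxic",
         call. = FALSE)
  }
  if (!all(unlist(d[c("allergenic", "toxic")]) %in% c(0, 1))) {
    stop("allergenic/toxic must be 0 or 1", call. = FALSE)
  }
  data.frame(sequence = toupper(d$sequence),
             allergenic = d$allergenic == 1,
             toxic = d$toxic == 1, stringsAsFactors = FALSE)
}

#' Screen a set of peptides
#'
#' Computes the descriptor set and the full screening profile for each
#' peptide: charge class, GI absorption, Lipinski and lead-likeness
#' violation counts, Abbott bioavailability score, oral-peptide-drug
#' resemblance, and (when a predicate table is supplied) allergenicity and
#' toxicity verdicts (NA when the peptide is not covered).
#'
#' @param peptides Character vector of peptide sequences.
#' @param predicates Optional predicate data.frame from [read_predicates()].
#' @param ellipse GI-absorption ellipse (see [default_gi_ellipse()]).
#' @param ph pH for the charge classification.
#' @return data.frame with one row per peptide (a "screen profile").
#' @examples
#' screen_peptides(c("AY", "DL"), predicates = read_predicates())
#' @export
screen_peptides <- function(peptides, predicates = NULL,
                            ellipse = default_gi_ellipse(), ph = 6.5) {
  rows <- lapply(peptides, function(p) {
    d <- descriptors(p)
    ch <- charge_class(p, ph = ph)
    lv <- lipinski_violations(d)
    ldv <- lead_violations(d)
    data.frame(
      peptide = p,
      mw = round(d$mw, 2), frac_csp3 = round(d$frac_csp3, 2),
      rb = d$rb, hba = d$hba, hbd = d$hbd,
      tpsa = round(d$tpsa, 2), wlogp = round(d$wlogp, 2),
      mlogp = round(d$mlogp, 2),
      charge_class = ch,
      gi_absorption = classify_gi_absorption(d, ellipse),
      lipinski_violations = lv, lipinski_pass = lv <= 1,
      lead_violations = ldv, lead_pass = ldv == 0,
      bioavailability_score = bioavailability_score(d, ch),
      oral_peptide_drug_like = oral_peptide_drug_like(d),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(predicates)) {
    m <- match(out$peptide, predicates$sequence)
    out$allergenic <- predicates$allergenic[m]
    out$toxic <- predicates$toxic[m]
  } else {
    out$allergenic <- NA
    out$toxic <- NA
  }
  out
}

#' Safety-filtered shortlist of a screening table
#'
#' Keeps peptides predicted highly GI-absorbed, non-allergenic and
#' non-toxic.  Unknown (NA) safety verdicts exclude a peptide from the
#' shortlist while it remains in the full profile table.
#'
#' @param profiles Output of [screen_peptides()].
#' @return Character vector of retained peptide sequences.
#' @export
safe_shortlist <- function(profiles) {
  keep <- profiles$gi_absorption == "high" &
    !is.na(profiles$allergenic) & !profiles$allergenic &
    !is.na(profiles$toxic) & !profiles$toxic
  profiles$peptide[keep]
}
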