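# Physicochemical descriptors computed on the peptide molecular graph.
#
# All descriptors are fragment/atom-additive schemes from the literature,
# driven by bundled parameter tables:
#   - TPSA: Ertl polar-fragment contributions over N/O/S environments;
#   - WLOGP: Wildman-Crippen atom-type contributions (atoms + hydrogens);
#   - MLOGP: Moriguchi regression over 13 structural parameters;
# plus molecular weight, fraction Csp3, rotatable bonds and H-bond
# donor/acceptor counts.  The counting conventions follow the descriptor set
# used by oral-bioavailability screening tools: rotatable bonds are non-ring
# single bonds between atoms that each carry at least two heavy neighbours
# (amide C-N bonds included); H-bond acceptors are N + O minus nitrogens
# adjacent to a carbonyl carbon (sulfur never counts); H-bond donors are
# N/O atoms bearing at least one hydrogen (S-H never counts).

#' Compute the descriptor set of a peptide
#'
#' @param x A peptide sequence or a [build_molecule()] graph.
#' @return An object of class \code{descriptor_set}: list with unrounded
#'   \code{mw} (g/mol), \code{frac_csp3}, \code{rb}, \code{hba}, \code{hbd},
#'   \code{tpsa} (Angstrom^2), \code{wlogp}, \code{mlogp} and the
#'   \code{peptide} string (when known).
#' @examples
#' d <- descriptors("AY")
#' round(d$tpsa, 2)  # 112.65
#' @export
descriptors <- function(x) {
  graph <- if (is.character(x)) build_molecule(x) else x
  stopifnot(inherits(graph, "molecule_graph"))
  atoms <- graph$atoms
  adj <- graph_adjacency(graph)
  ring <- ring_bond_ids(graph)
  degree <- lengths(lapply(adj, `[[`, "nbr"))

  env <- atom_environments(graph, adj)

  # fraction Csp3: carbons that are neither aromatic nor multiply bonded
  is_c <- atoms$element == "C"
  sp3 <- is_c & !atoms$aromatic & env$ndouble == 0L & env$ntriple == 0L
  frac_csp3 <- if (any(is_c)) sum(sp3) / sum(is_c) else 0

  # rotatable bonds
  b <- graph$bonds
  rot <- b$order == "1" &
    !(seq_len(nrow(b)) %in% ring) &
    degree[b$from] >= 2L & degree[b$to] >= 2L
  rb <- sum(rot)

  # H-bond acceptors / donors
  polar <- atoms$element %in% c("N", "O")
  hba <- sum(polar) - sum(atoms$element == "N" & env$amide_n)
  hbd <- sum(polar & atoms$h > 0L)

  structure(list(
    peptide = graph$peptide,
    mw = molecule_mw(graph),
    frac_csp3 = frac_csp3,
    rb = rb,
    hba = hba,
    hbd = hbd,
    tpsa = tpsa_ertl(graph, env),
    wlogp = wlogp_wildman_crippen(graph, env),
    mlogp = mlogp_moriguchi(graph, env)),
    class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf(paste0("<descriptor_set> %s: MW %.2f, Csp3 %.2f, RB %d, ",
                     "HBA %d, HBD %d, TPSA %.2f, WLOGP %.2f, MLOGP %.2f\n"),
              x$peptide, x$mw, x$frac_csp3, x$rb, x$hba, x$hbd,
              x$tpsa, x$wlogp, x$mlogp))
  invisible(x)
}

# Per-atom bonding environment: counts of single/double/triple/aromatic
# bonds to heavy atoms, plus carbonyl/amide annotations.
atom_environments <- function(graph, adj = graph_adjacency(graph)) {
  atoms <- graph$atoms
  b <- graph$bonds
  n <- nrow(atoms)
  el <- atoms$element
  count_order <- function(ord) {
    sel <- b$order == ord
    tabulate(c(b$from[sel], b$to[sel]), nbins = n)
  }
  nsingle <- count_order("1")
  ndouble <- count_order("2")
  ntriple <- count_order("3")
  naromatic <- count_order("ar")
  # carbonyl carbon: C with a double bond to O
  carbonyl_c <- logical(n)
  d2 <- b[b$order == "2", , drop = FALSE]
  carbonyl_c[d2$from[el[d2$from] == "C" & el[d2$to] == "O"]] <- TRUE
  carbonyl_c[d2$to[el[d2$to] == "C" & el[d2$from] == "O"]] <- TRUE
  # amide nitrogen: N single-bonded to a carbonyl carbon
  amide_n <- logical(n)
  s1 <- b[b$order == "1", , drop = FALSE]
  amide_n[s1$from[el[s1$from] == "N" & carbonyl_c[s1$to]]] <- TRUE
  amide_n[s1$to[el[s1$to] == "N" & carbonyl_c[s1$from]]] <- TRUE
  list(nsingle = nsingle, ndouble = ndouble, ntriple = ntriple,
       naromatic = naromatic, carbonyl_c = carbonyl_c, amide_n = amide_n,
       adj = adj)
}

# ---- Ertl TPSA ------------------------------------------------------------

tpsa_ertl <- function(graph, env = atom_environments(graph)) {
  atoms <- graph$atoms
  tab <- ertl_table()
  idx <- which(atoms$element %in% c("N", "O", "S"))
  total <- 0
  for (i in idx) {
    hit <- tab$element == atoms$element[i] &
      tab$aromatic == as.integer(atoms$aromatic[i]) &
      tab$h == atoms$h[i] &
      tab$nsingle == env$nsingle[i] &
      tab$ndouble == env$ndouble[i] &
      tab$ntriple == env$ntriple[i] &
      tab$naromatic == env$naromatic[i]
    if (!any(hit)) {
      stop(sprintf("no polar-fragment contribution for %s atom '%s' (residue %s)",
                   atoms$element[i], atoms$name[i], atoms$residue[i]),
           call. = FALSE)
    }
    total <- total + tab$tpsa[which(hit)[1L]]
  }
  total
}

# ---- Wildman-Crippen WLOGP ------------------------------------------------

wc_type_heavy <- function(i, graph, env) {
  atoms <- graph$atoms
  adj <- env$adj[[i]]
  el <- atoms$element[i]
  h <- atoms$h[i]
  nbr <- adj$nbr
  nbr_el <- atoms$element[nbr]
  nbr_ar <- atoms$aromatic[nbr]
  single_nbr <- nbr[adj$order == "1"]
  double_nbr <- nbr[adj$order == "2"]

  if (el == "C") {
    if (atoms$aromatic[i]) {
      if (h > 0L) return("C18")
      if (length(single_nbr) == 0L && length(double_nbr) == 0L) return("C19")
      if (length(double_nbr)) return("C25")
      s <- single_nbr[1L]
      if (atoms$aromatic[s]) return("C20")
      return(switch(atoms$element[s],
                    C = "C21", N = "C22", O = "C23", S = "C24", "CS"))
    }
    if (env$ntriple[i] > 0L) return("C7")
    if (env$ndouble[i] > 0L) {
      het_dbl <- any(atoms$element[double_nbr] %in% c("N", "O", "S") &
                       !atoms$aromatic[double_nbr])
      return(if (het_dbl) "C5" else "C6")
    }
    het <- any(nbr_el %in% c("N", "O", "S") & !nbr_ar)
    if (het) return(if (h >= 2L) "C3" else "C4")
    if (any(nbr_ar)) {
      return(switch(as.character(h), "3" = if (atoms$element[nbr[nbr_ar][1L]] == "C") "C8" else "C9",
                    "2" = "C10", "1" = "C11", "0" = "C12", "CS"))
    }
    return(if (h >= 2L) "C1" else "C2")
  }
  if (el == "N") {
    if (atoms$aromatic[i]) return("N11")
    if (env$ntriple[i] > 0L) return("N9")
    if (env$ndouble[i] > 0L) return(if (h >= 1L) "N5" else "N6")
    arom_nbr <- any(nbr_ar)
    if (h >= 2L) return(if (arom_nbr) "N3" else "N1")
    if (h == 1L) return(if (arom_nbr) "N4" else "N2")
    return(if (arom_nbr) "N8" else "N7")
  }
  if (el == "O") {
    if (atoms$aromatic[i]) return("O1")
    if (h >= 1L) return("O2")
    if (env$ndouble[i] > 0L) {
      cc <- double_nbr[1L]
      if (atoms$aromatic[cc]) return("O8")
      subs <- setdiff(env$adj[[cc]]$nbr, i)
      if (any(atoms$aromatic[subs])) return("O10")
      if (any(atoms$element[subs] == "C")) return("O9")
      return("O11")
    }
    # ether
    return(if (any(nbr_ar)) "O4" else "O3")
  }
  if (el == "S") return(if (atoms$aromatic[i]) "S3" else "S1")
  "CS"
}

wc_type_hydrogen <- function(i, graph, env) {
  # type of the hydrogens attached to heavy atom i
  atoms <- graph$atoms
  el <- atoms$element[i]
  if (el == "C") return("H1")
  if (el == "N") return("H3")
  if (el == "O") {
    nbr <- env$adj[[i]]$nbr
    if (any(atoms$element[nbr] == "N")) return("H3")
    if (any(env$carbonyl_c[nbr])) return("H4")  # acid O-H
    return("H2")                                # alcohol / phenol
  }
  if (el == "S") return("H2")
  "HS"
}

wlogp_wildman_crippen <- function(graph, env = atom_environments(graph)) {
  contrib <- wc_contributions()
  total <- 0
  for (i in seq_len(nrow(graph$atoms))) {
    ty <- wc_type_heavy(i, graph, env)
    if (is.na(contrib[ty])) {
      stop("unparameterised Wildman-Crippen atom type: ", ty, call. = FALSE)
    }
    total <- total + contrib[[ty]]
    h <- graph$atoms$h[i]
    if (h > 0L) total <- total + h * contrib[[wc_type_hydrogen(i, graph, env)]]
  }
  total
}

# ---- Moriguchi MLOGP ------------------------------------------------------

# Connected aromatic components and their composition (used by UB and RNG).
aromatic_components <- function(graph) {
  atoms <- graph$atoms
  arom <- which(atoms$aromatic)
  if (!length(arom)) return(list())
  b <- graph$bonds[graph$bonds$order == "ar", , drop = FALSE]
  comp <- setNames(seq_along(arom), arom)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(b))) {
      f <- as.character(b$from[k]); t <- as.character(b$to[k])
      if (comp[f] != comp[t]) {
        comp[comp == max(comp[f], comp[t])] <- min(comp[f], comp[t])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(split(arom, comp[as.character(arom)]), identity)
}

mlogp_moriguchi <- function(graph, env = atom_environments(graph)) {
  p <- moriguchi_params()
  atoms <- graph$atoms
  adj <- env$adj

  cx <- sum(atoms$element == "C")
  no <- sum(atoms$element %in% c("N", "O"))

  # proximity of N/O pairs: bonded 2, one C/S/P apart 1, amide counted as 2
  polar <- which(atoms$element %in% c("N", "O"))
  prx <- 0
  if (length(polar) > 1L) {
    for (a in seq_along(polar)) {
      for (b in seq_along(polar)) {
        if (b <= a) next
        i <- polar[a]; j <- polar[b]
        if (j %in% adj[[i]]$nbr) {
          prx <- prx + 2
        } else {
          common <- intersect(adj[[i]]$nbr, adj[[j]]$nbr)
          if (any(atoms$element[common] %in% c("C", "S"))) prx <- prx + 1
        }
      }
    }
  }
  # amide special case: the O=C-N pair counts 2 rather than 1
  n_amide <- sum(vapply(which(env$carbonyl_c), function(cc) {
    sum(atoms$element[adj[[cc]]$nbr] == "N" & adj[[cc]]$order == "1")
  }, 0))
  prx <- prx + n_amide

  # unsaturated bonds: explicit doubles/triples plus Kekule doubles of each
  # aromatic component (floor(atoms/2))
  comps <- aromatic_components(graph)
  ub <- sum(graph$bonds$order == "2") + sum(graph$bonds$order == "3") +
    sum(vapply(comps, function(cc) length(cc) %/% 2L, 0L))

  # aromatic polar substituents: heteroatoms single-bonded to an aromatic atom
  pol <- sum(vapply(which(atoms$element %in% c("N", "O", "S") & !atoms$aromatic),
                    function(i) any(atoms$aromatic[adj[[i]]$nbr]), TRUE))

  # amphoteric: free (non-amide) amine plus carboxylic acid present
  has_amine <- any(atoms$element == "N" & !atoms$aromatic & atoms$h > 0L &
                     !env$amide_n & env$ndouble == 0L)
  has_cooh <- any(vapply(which(env$carbonyl_c), function(cc) {
    any(atoms$element[adj[[cc]]$nbr] == "O" & adj[[cc]]$order == "1" &
          atoms$h[adj[[cc]]$nbr] > 0L)
  }, TRUE))
  amp <- if (has_amine && has_cooh) 1 else 0

  # rings other than benzene/condensed aromatic carbocycles: any ring bond in
  # a non-aromatic ring, or an aromatic component containing a heteroatom
  ring <- ring_bond_ids(graph)
  nonarom_ring <- any(graph$bonds$order[ring] != "ar")
  hetero_arom <- any(vapply(comps, function(cc)
    any(atoms$element[cc] != "C"), TRUE))
  rng <- if (nonarom_ring || hetero_arom) 1 else 0

  hb <- 0    # intramolecular H-bond dummy: not modelled for linear peptides
  alk <- 0   # peptides are never pure hydrocarbons
  qn <- no2 <- ncs <- blm <- 0

  terms <- c(CX = cx, NO = no, PRX = prx, UB = ub, HB = hb, POL = pol,
             AMP = amp, ALK = alk, RNG = rng, QN = qn, NO2 = no2,
             NCS = ncs, BLM = blm)
  total <- p["intercept", "coefficient"]
  for (t in names(terms)) {
    total <- total + p[t, "coefficient"] * terms[[t]] ^ p[t, "exponent"]
  }
  total
}

#' Descriptor table for a set of peptides
#'
#' One row per peptide with report rounding: MW, fraction Csp3, TPSA and the
#' two logP estimates to two decimals; RB/HBA/HBD as integers.
#'
#' @param peptides Character vector of peptide sequences.
#' @param path Optional TSV output path.
#' @return data.frame with columns peptide, mw, frac_csp3, rb, hba, hbd,
#'   tpsa, wlogp, mlogp.
#' @examples
#' descriptor_table(c("AY", "VY"))
#' @export
descriptor_table <- function(peptides, path = NULL) {
  rows <- lapply(peptides, function(p) {
    d <- descriptors(p)
    data.frame(peptide = p, mw = round(d$mw, 2),
               frac_csp3 = round(d$frac_csp3, 2), rb = d$rb, hba = d$hba,
               hbd = d$hbd, tpsa = round(d$tpsa, 2),
               wlogp = round(d$wlogp, 2), mlogp = round(d$mlogp, 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) write_tsv(out, path)
  out
}
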