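# Molecular graph construction for linear peptides.
#
# Each canonical residue has a bundled heavy-atom template (free amino acid,
# neutral protonation).  A peptide graph is formed by condensing templates
# through amide bonds, losing one water per bond: the C-terminal hydroxyl of
# every residue but the last is dropped and one hydrogen is removed from the
# alpha-amino nitrogen of every residue but the first.  No stereochemistry
# and no ionisation: descriptors are defined on the neutral form.

#' Build the molecular graph of a linear peptide
#'
#' @param peptide Canonical amino-acid sequence (length >= 1).
#' @return An object of class \code{molecule_graph}: a list with
#'   \describe{
#'     \item{atoms}{data.frame of heavy atoms: \code{id}, \code{name}
#'       (PDB-style), \code{resno}, \code{residue}, \code{element},
#'       \code{aromatic}, \code{h} (attached hydrogens).}
#'     \item{bonds}{data.frame with \code{from}, \code{to}, \code{order}
#'       (\code{"1"}, \code{"2"} or \code{"ar"}).}
#'     \item{peptide}{the input sequence.}
#'   }
#' @examples
#' g <- build_molecule("AY")
#' nrow(g$atoms)  # heavy atoms
#' @export
build_molecule <- function(peptide) {
  peptide <- validate_peptide(peptide)
  chars <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  templates <- sidechain_templates()

  ids <- integer(); names_ <- character(); resno <- integer()
  residue <- character(); element <- character(); aromatic <- logical()
  h <- integer()
  bf <- integer(); bt <- integer(); border <- character()
  nid <- 0L
  add_atom <- function(name, res_i, res, elem, arom, hh) {
    nid <<- nid + 1L
    ids[nid] <<- nid; names_[nid] <<- name; resno[nid] <<- res_i
    residue[nid] <<- res; element[nid] <<- elem; aromatic[nid] <<- arom
    h[nid] <<- hh
    nid
  }
  add_bond <- function(a, b, ord) {
    bf[length(bf) + 1L] <<- a; bt[length(bt) + 1L] <<- b
    border[length(border) + 1L] <<- as.character(ord)
  }

  prev_C <- NA_integer_
  for (i in seq_len(n)) {
    res <- chars[i]
    # backbone: the alpha-amino N of proline is secondary already
    n_h <- (if (res == "P") 1L else 2L) - (if (i > 1L) 1L else 0L)
    aN <- add_atom("N", i, res, "N", FALSE, n_h)
    aCA <- add_atom("CA", i, res, "C", FALSE, if (res == "G") 2L else 1L)
    aC <- add_atom("C", i, res, "C", FALSE, 0L)
    aO <- add_atom("O", i, res, "O", FALSE, 0L)
    add_bond(aN, aCA, "1"); add_bond(aCA, aC, "1"); add_bond(aC, aO, "2")
    if (!is.na(prev_C)) add_bond(prev_C, aN, "1")  # amide bond
    tmpl <- templates[[res]]
    if (nrow(tmpl$atoms)) {
      local_ids <- c(N = aN, CA = aCA)
      for (k in seq_len(nrow(tmpl$atoms))) {
        ta <- tmpl$atoms[k, ]
        local_ids[[ta$atom]] <- add_atom(ta$atom, i, res, ta$element,
                                         ta$aromatic == 1L, as.integer(ta$h))
      }
      for (k in seq_len(nrow(tmpl$bonds))) {
        tb <- tmpl$bonds[k, ]
        add_bond(local_ids[[tb$from]], local_ids[[tb$to]], tb$order)
      }
    }
    if (i == n) {  # free carboxyl terminus
      aOXT <- add_atom("OXT", i, res, "O", FALSE, 1L)
      add_bond(aC, aOXT, "1")
    }
    prev_C <- aC
  }

  structure(list(
    atoms = data.frame(id = ids, name = names_, resno = resno,
                       residue = residue, element = element,
                       aromatic = aromatic, h = h, stringsAsFactors = FALSE),
    bonds = data.frame(from = bf, to = bt, order = border,
                       stringsAsFactors = FALSE),
    peptide = peptide), class = "molecule_graph")
}

#' @export
print.molecule_graph <- function(x, ...) {
  f <- molecular_formula(x)
  cat(sprintf("<molecule_graph> %s: %d heavy atoms, %d bonds, %s\n",
              x$peptide, nrow(x$atoms), nrow(x$bonds), f$string))
  invisible(x)
}

# adjacency list of heavy atoms: list over atoms of data.frame(nbr, order)
graph_adjacency <- function(graph) {
  n <- nrow(graph$atoms)
  adj <- rep(list(data.frame(nbr = integer(), order = character(),
                             stringsAsFactors = FALSE)), n)
  b <- graph$bonds
  both <- data.frame(at = c(b$from, b$to), nbr = c(b$to, b$from),
                     order = c(b$order, b$order), stringsAsFactors = FALSE)
  sp <- split(both[c("nbr", "order")], both$at)
  adj[as.integer(names(sp))] <- sp
  adj
}

#' Molecular formula of a peptide graph
#'
#' @param graph A \code{molecule_graph}.
#' @return List with \code{counts} (named vector incl. H) and \code{string}
#'   (Hill-order formula).
#' @export
molecular_formula <- function(graph) {
  counts <- tapply(rep(1L, nrow(graph$atoms)), graph$atoms$element, sum)
  counts <- setNames(as.integer(counts), names(counts))
  counts["H"] <- sum(graph$atoms$h)
  hill <- c("C", "H", setdiff(sort(names(counts)), c("C", "H")))
  hill <- hill[hill %in% names(counts) & counts[hill] > 0]
  string <- paste0(vapply(hill, function(e)
    paste0(e, if (counts[[e]] > 1L) counts[[e]] else ""), ""), collapse = "")
  list(counts = counts[hill], string = string)
}

# Average molecular mass from the graph (atoms + implicit hydrogens).
molecule_mw <- function(graph) {
  am <- atomic_masses()
  sum(am[graph$atoms$element]) + sum(graph$atoms$h) * am[["H"]]
}

# ids of bonds that lie on a cycle: every non-bridge bond (Tarjan low-link)
ring_bond_ids <- function(graph) {
  nb <- nrow(graph$bonds)
  if (nb == 0L) return(integer())
  n <- nrow(graph$atoms)
  # adjacency as parallel vectors: for atom v, bonds inc[ptr[v]:(ptr[v+1]-1)]
  ends <- c(graph$bonds$from, graph$bonds$to)
  other <- c(graph$bonds$to, graph$bonds$from)
  bid <- rep(seq_len(nb), 2L)
  ord <- order(ends)
  other <- other[ord]; bid <- bid[ord]
  ptr <- c(1L, cumsum(tabulate(ends[ord], nbins = n)) + 1L)

  disc <- integer(n); low <- integer(n)
  is_bridge <- logical(nb)
  timer <- 0L
  dfs <- function(u, parent_bond) {
    timer <<- timer + 1L
    disc[u] <<- low[u] <<- timer
    if (ptr[u] <= ptr[u + 1L] - 1L) {
      for (k in ptr[u]:(ptr[u + 1L] - 1L)) {
        v <- other[k]; e <- bid[k]
        if (e == parent_bond) next
        if (disc[v] > 0L) {
          low[u] <<- min(low[u], disc[v])
        } else {
          dfs(v, e)
          low[u] <<- min(low[u], low[v])
          if (low[v] > disc[u]) is_bridge[e] <<- TRUE
        }
      }
    }
  }
  for (u in seq_len(n)) if (disc[u] == 0L) dfs(u, 0L)
  which(!is_bridge)
}

#' Emit a SMILES string for a peptide graph
#'
#' Produces a syntactically valid, stereochemistry-free SMILES of the
#' neutral molecule.  Aromatic atoms are written in lower case (with
#' \code{[nH]} for pyrrole-type nitrogens); implicit hydrogen counts of the
#' organic subset coincide with the graph's hydrogen counts by construction.
#'
#' @param graph A \code{molecule_graph} (or a peptide sequence, which is
#'   built first).
#' @return A SMILES string.
#' @examples
#' to_smiles("G")  # "NCC(=O)O"
#' @export
to_smiles <- function(graph) {
  if (is.character(graph)) graph <- build_molecule(graph)
  atoms <- graph$atoms
  n <- nrow(atoms)
  adj <- graph_adjacency(graph)

  visited <- logical(n)
  parent <- rep(NA_integer_, n)
  # ring-closure bookkeeping: for each atom, list of (digit, order)
  closures <- rep(list(list()), n)
  seen_pairs <- character()
  digit <- 0L

  # iterative DFS recording tree children
  children <- rep(list(integer()), n)
  order_of <- function(a, b) {
    nb <- adj[[a]]
    nb$order[match(b, nb$nbr)]
  }
  stack <- 1L
  visited[1L] <- TRUE
  dfs_order <- integer()
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    dfs_order <- c(dfs_order, v)
    nbrs <- adj[[v]]$nbr
    for (w in sort(nbrs)) {
      key <- paste(sort(c(v, w)), collapse = "-")
      if (!visited[w]) {
        visited[w] <- TRUE
        parent[w] <- v
        children[[v]] <- c(children[[v]], w)
        stack <- c(stack, w)
        seen_pairs <- c(seen_pairs, key)
      } else if (!(key %in% seen_pairs) && w != parent[v]) {
        # back edge -> ring closure
        seen_pairs <- c(seen_pairs, key)
        digit <- digit + 1L
        ord <- order_of(v, w)
        closures[[v]] <- c(closures[[v]], list(list(d = digit, order = ord)))
        closures[[w]] <- c(closures[[w]], list(list(d = digit, order = ord)))
      }
    }
  }
  if (!all(visited)) stop("molecule graph is not connected", call. = FALSE)

  atom_token <- function(i) {
    el <- atoms$element[i]
    if (atoms$aromatic[i]) {
      if (el == "N" && atoms$h[i] > 0L) "[nH]" else tolower(el)
    } else el
  }
  bond_token <- function(ord) if (identical(ord, "2")) "=" else ""

  emit <- function(i) {
    out <- atom_token(i)
    for (cl in closures[[i]]) {
      out <- paste0(out, bond_token(cl$order), cl$d)
    }
    kids <- children[[i]]
    if (length(kids)) {
      for (k in seq_along(kids)) {
        sub <- paste0(bond_token(order_of(i, kids[k])), emit(kids[k]))
        out <- if (k < length(kids)) paste0(out, "(", sub, ")")
               else paste0(out, sub)
      }
    }
    out
  }
  emit(1L)
}
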