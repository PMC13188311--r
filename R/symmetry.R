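## Topological symmetry: atom-level graph automorphisms and their
## projection to the bit-permutation group G acting on TABS.

#' Atom automorphisms of a molecular graph
#'
#' Enumerates all permutations of the atom numbering that preserve atom
#' types (element, formal charge, aromaticity, implicit H count) and
#' connectivity (bond existence with order/aromaticity), i.e. the
#' topological symmetries of the molecule.  The search is a backtracking
#' enumeration seeded with canonical-rank symmetry classes: an atom may
#' only map to atoms of its own class, which prunes the search to
#' tractability for drug-like molecules.  Stereochemistry is deliberately
#' ignored (the symmetry is graph-topological), so enantiomeric torsion
#' states may be merged.
#'
#' @param mol a [Molecule-class].
#' @param maxOrder hard cap on the group order; exceeding it is an error,
#'   never a silent truncation.
#' @return list of integer mapping vectors (atom index -> image), always
#'   including the identity.
#' @examples
#' length(atomAutomorphisms(parseSmiles("CCCC")))      # 2
#' length(atomAutomorphisms(parseSmiles("c1ccccc1")))  # 12
#' @export
atomAutomorphisms <- function(mol, maxOrder = 1e5) {
  n <- nrow(mol@atoms)
  ranks <- canonicalAtomRanks(mol)
  adj <- .adjacency(mol)
  bm <- .bond_map(mol)
  bond_lab <- function(u, v) {
    k <- paste(min(u, v), max(u, v), sep = ":")
    if (k %in% names(bm)) bm[[k]] else ""
  }
  # process atoms in order of increasing class size for early pruning
  class_size <- table(ranks)[as.character(ranks)]
  ord <- order(class_size, seq_len(n))
  results <- list()
  mapping <- integer(n)
  used <- logical(n)
  recurse <- function(pos) {
    if (pos > n) {
      results[[length(results) + 1L]] <<- mapping
      if (length(results) > maxOrder)
        stop("automorphism group exceeds maxOrder = ", maxOrder, call. = FALSE)
      return(invisible())
    }
    i <- ord[pos]
    for (cand in which(ranks == ranks[i] & !used)) {
      ok <- TRUE
      nb <- adj[[i]]$nbr
      for (k in seq_along(nb)) {
        j <- nb[k]
        if (mapping[j] != 0L &&
            bond_lab(cand, mapping[j]) != adj[[i]]$label[k]) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      mapping[i] <<- cand
      used[cand] <<- TRUE
      recurse(pos + 1L)
      mapping[i] <<- 0L
      used[cand] <<- FALSE
    }
    invisible()
  }
  recurse(1L)
  results
}

#' Project an atom permutation to a bit permutation
#'
#' A topological symmetry maps the torsion bond of bit `i`, `{b, c}`, to
#' the bond `{g(b), g(c)}`, which must itself be a torsion bond; the
#' induced map of bit indices is the projected [BitPermutation-class].
#' An automorphism that maps a torsion bond to a non-torsion bond, or that
#' exchanges bits of unequal multiplicity, signals a library/matching
#' inconsistency and raises an error.
#'
#' @param atomPerm integer mapping vector (atom -> image atom).
#' @param bits a [TorsionBits-class].
#' @return a [BitPermutation-class].
#' @export
projectToBits <- function(atomPerm, bits) {
  n <- nrow(bits@bonds)
  if (n == 0L) return(identityPermutation(0L))
  keys <- paste(pmin(bits@bonds[, 1L], bits@bonds[, 2L]),
                pmax(bits@bonds[, 1L], bits@bonds[, 2L]), sep = ":")
  mapping <- integer(n)
  for (i in seq_len(n)) {
    u <- atomPerm[bits@bonds[i, 1L]]
    v <- atomPerm[bits@bonds[i, 2L]]
    k <- paste(min(u, v), max(u, v), sep = ":")
    j <- match(k, keys)
    if (is.na(j))
      stop("automorphism maps torsion bond ", keys[i],
           " to non-torsion bond ", k, call. = FALSE)
    mapping[i] <- j
  }
  if (anyDuplicated(mapping))
    stop("projected mapping is not a bijection", call. = FALSE)
  if (length(bits@multiplicity) &&
      any(bits@multiplicity[mapping] != bits@multiplicity))
    stop("automorphism exchanges bits of unequal multiplicity; ",
         "equivalent torsions were matched to different patterns",
         call. = FALSE)
  BitPermutation(mapping)
}

#' Build the bit-permutation group of a molecule
#'
#' Projects every atom automorphism onto the torsion bits, removes
#' duplicate bit permutations (several atom symmetries may act identically
#' on the bits), and returns the image group, re-verified to be closed and
#' to contain the identity.  This deduplicated image group is the G used
#' in the Burnside count.
#'
#' @param mol a [Molecule-class].
#' @param bits a [TorsionBits-class] for the same molecule.
#' @param automorphisms optionally, a precomputed list from
#'   [atomAutomorphisms()].
#' @param maxOrder cap on the atom group order.
#' @return a [SymmetryGroup-class].
#' @export
buildBitGroup <- function(mol, bits, automorphisms = NULL, maxOrder = 1e5) {
  if (is.null(automorphisms))
    automorphisms <- atomAutomorphisms(mol, maxOrder = maxOrder)
  n <- nrow(bits@bonds)
  projected <- lapply(automorphisms, function(g) projectToBits(g, bits)@mapping)
  keys <- vapply(projected, paste, character(1), collapse = ",")
  projected <- projected[!duplicated(keys)]
  # projections of a group form a group; SymmetryGroup re-verifies closure
  new("SymmetryGroup", nBits = as.integer(n), elements = projected)
}
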