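## Torsion-pattern library and matching of rotatable torsions.
##
## The full CSD-derived torsion library is not reproduced here: the package
## ships a small curated set of pattern classes (amide, aromatic-aromatic,
## conjugated, sp3-sp2, sp3-sp3, generic fallback) with explicit bin
## boundaries, and accepts user-supplied libraries in the same JSON format,
## so a published library can be dropped in.  Counting correctness is
## carried by the abstract Burnside/oracle machinery, not by the library.

#' Construct a torsion pattern
#'
#' @param id pattern identifier.
#' @param atomQueries list of 4 attribute queries for the mapped atoms
#'   a, b, c, d.  Each query is a named list with optional fields `elem`
#'   (element symbol, character vector, or `"*"`), `aromatic` (logical),
#'   `charge` (integer) and `neighbor` (a nested query with optional
#'   `elem` / `order`, requiring some other neighbor to match).
#' @param boundaries strictly increasing bin boundaries in degrees, all in
#'   (-period/2, period/2]; the number of boundaries is the multiplicity.
#' @param priority integer rank; lower = more specific, matched first.
#' @param bondOrder required b-c bond order (1, 2, 3, 1.5) or NA for any.
#' @param period local rotor period in degrees (divisor of 360); 180 for
#'   rotors with a degenerate half-turn (phenyl-type), 360 otherwise.
#' @return a [TorsionPattern-class].
#' @export
TorsionPattern <- function(id, atomQueries, boundaries, priority = 50L,
                           bondOrder = NA_real_, period = 360) {
  new("TorsionPattern", id = as.character(id), priority = as.integer(priority),
      atomQueries = atomQueries, bondOrder = as.numeric(bondOrder),
      boundaries = as.numeric(boundaries), period = as.numeric(period))
}

#' @describeIn TorsionPattern number of bins (the multiplicity m_i).
#' @param pattern a [TorsionPattern-class].
#' @export
patternMultiplicity <- function(pattern) length(pattern@boundaries)

#' Load a torsion library from JSON
#'
#' The file holds an array of objects with fields `id`, `priority`,
#' `atoms` (array of 4 atom queries), `bond_order` (optional) and
#' `boundaries`.  Patterns are validated and sorted by priority (file
#' order breaks ties).
#'
#' @param path path to a JSON torsion library.
#' @return a [TorsionLibrary-class].
#' @export
readTorsionLibrary <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  pats <- lapply(seq_along(raw), function(k) {
    p <- raw[[k]]
    stopifnot(!is.null(p$id), !is.null(p$atoms), !is.null(p$boundaries))
    if (length(p$atoms) != 4L)
      stop("pattern '", p$id, "' must query exactly 4 atoms", call. = FALSE)
    TorsionPattern(
      id = p$id,
      atomQueries = lapply(p$atoms, function(q) q),
      boundaries = unlist(p$boundaries),
      priority = if (is.null(p$priority)) 50L else p$priority,
      bondOrder = if (is.null(p$bond_order)) NA_real_ else p$bond_order,
      period = if (is.null(p$period)) 360 else p$period)
  })
  ord <- order(vapply(pats, function(p) p@priority, integer(1)), seq_along(pats))
  new("TorsionLibrary", patterns = pats[ord])
}

#' The torsion library shipped with the package
#'
#' Small curated JSON library under `inst/extdata/torsion_library.json`:
#' amide (2 bins), aromatic-aromatic (2), conjugated single bond between
#' sp2 centers (2), sp3 carbon to aromatic ring (2), sp3-sp3 carbon (3)
#' and a generic 3-bin fallback.
#'
#' @return a [TorsionLibrary-class].
#' @export
defaultTorsionLibrary <- function() {
  readTorsionLibrary(system.file("extdata", "torsion_library.json",
                                 package = "tabscount", mustWork = TRUE))
}

.query_field <- function(q, name) if (is.null(q[[name]])) NULL else q[[name]]

.atom_matches_query <- function(mol, adj, i, q, exclude = integer(0)) {
  if (is.null(q) || !length(q)) return(TRUE)
  a <- mol@atoms
  el <- .query_field(q, "elem")
  if (!is.null(el) && !identical(el, "*")) {
    if (!a$element[i] %in% unlist(el)) return(FALSE)
  }
  ar <- .query_field(q, "aromatic")
  if (!is.null(ar) && !identical(as.logical(ar), a$aromatic[i])) return(FALSE)
  ch <- .query_field(q, "charge")
  if (!is.null(ch) && as.integer(ch) != a$charge[i]) return(FALSE)
  nbq <- .query_field(q, "neighbor")
  if (!is.null(nbq)) {
    nb <- adj[[i]]$nbr; lab <- adj[[i]]$label
    ok <- FALSE
    for (k in seq_along(nb)) {
      j <- nb[k]
      if (j %in% exclude) next
      nel <- .query_field(nbq, "elem")
      if (!is.null(nel) && !identical(nel, "*") &&
          !a$element[j] %in% unlist(nel)) next
      nord <- .query_field(nbq, "order")
      if (!is.null(nord) &&
          lab[k] != .bond_label(as.numeric(nord), as.numeric(nord) == 1.5)) next
      ok <- TRUE
      break
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

# try to match one pattern at bond (b, c); checks both orientations
.pattern_matches_bond <- function(mol, adj, pattern, b, c, bond_lab) {
  if (!is.na(pattern@bondOrder)) {
    want <- .bond_label(pattern@bondOrder, pattern@bondOrder == 1.5)
    if (bond_lab != want) return(FALSE)
  }
  q <- pattern@atomQueries
  for (pair in list(c(b, c), c(c, b))) {
    bb <- pair[1L]; cc <- pair[2L]
    if (.atom_matches_query(mol, adj, bb, q[[2L]], exclude = cc) &&
        .atom_matches_query(mol, adj, cc, q[[3L]], exclude = bb)) {
      # a / d queries: some heavy neighbor on each side must match
      an <- .heavy_neighbors(mol, adj, bb); an <- an[an != cc]
      dn <- .heavy_neighbors(mol, adj, cc); dn <- dn[dn != bb]
      a_ok <- !length(.compact_query(q[[1L]])) ||
        any(vapply(an, function(j) .atom_matches_query(mol, adj, j, q[[1L]]),
                   logical(1)))
      d_ok <- !length(.compact_query(q[[4L]])) ||
        any(vapply(dn, function(j) .atom_matches_query(mol, adj, j, q[[4L]]),
                   logical(1)))
      if (a_ok && d_ok) return(TRUE)
    }
  }
  FALSE
}

.compact_query <- function(q) {
  if (is.null(q)) return(list())
  q <- q[!vapply(q, function(v) is.null(v) || identical(v, "*"), logical(1))]
  q
}

#' Match a rotatable bond against the torsion library
#'
#' Returns the first (most specific by priority, then file order) pattern
#' whose queries match the bond environment; the pattern's bin count
#' becomes the bit's multiplicity.
#'
#' @param mol a [Molecule-class].
#' @param bond integer pair of the bond atoms.
#' @param library a [TorsionLibrary-class].
#' @return the matched [TorsionPattern-class].
#' @export
matchPattern <- function(mol, bond, library = defaultTorsionLibrary()) {
  stopifnot(is(library, "TorsionLibrary"), length(bond) == 2L)
  adj <- .adjacency(mol)
  bm <- .bond_map(mol)
  key <- paste(min(bond), max(bond), sep = ":")
  if (!key %in% names(bm)) stop("no bond between atoms ", bond[1L], " and ",
                                bond[2L], call. = FALSE)
  for (p in library@patterns) {
    if (.pattern_matches_bond(mol, adj, p, bond[1L], bond[2L], bm[[key]]))
      return(p)
  }
  stop("no pattern matches bond ", key,
       " (is the generic fallback missing from the library?)", call. = FALSE)
}

#' Find the rotatable torsions of a molecule
#'
#' A bond qualifies as rotatable when it is not in a ring and each of its
#' atoms has at least one non-hydrogen neighbor besides the other bond
#' atom.  One torsion bit is produced per qualifying bond, with a
#' deterministic reference quadruple (the smallest-canonical-rank heavy
#' neighbor on each side) and a deterministic bit order (bonds sorted by
#' the canonical-rank pair of their atoms).
#'
#' @param mol a [Molecule-class].
#' @param library a [TorsionLibrary-class] used to assign a pattern and
#'   multiplicity to every bit, or `NULL` to skip matching.
#' @return a [TorsionBits-class].
#' @examples
#' nBits(findRotatableTorsions(parseSmiles("CCCC")))   # 1
#' nBits(findRotatableTorsions(parseSmiles("c1ccccc1")))  # 0
#' @export
findRotatableTorsions <- function(mol, library = defaultTorsionLibrary()) {
  stopifnot(is(mol, "Molecule"))
  adj <- .adjacency(mol)
  ranks <- canonicalAtomRanks(mol)
  b <- mol@bonds
  rows <- list()
  for (k in seq_len(nrow(b))) {
    if (b$ring[k]) next
    u <- b$from[k]; v <- b$to[k]
    if (mol@atoms$element[u] == "H" || mol@atoms$element[v] == "H") next
    hu <- .heavy_neighbors(mol, adj, u); hu <- hu[hu != v]
    hv <- .heavy_neighbors(mol, adj, v); hv <- hv[hv != u]
    if (!length(hu) || !length(hv)) next
    # orient: 'b' end is the smaller (rank, index) of the two bond atoms
    if (ranks[u] < ranks[v] || (ranks[u] == ranks[v] && u < v)) {
      bb <- u; cc <- v; bn <- hu; cn <- hv
    } else {
      bb <- v; cc <- u; bn <- hv; cn <- hu
    }
    aa <- bn[order(ranks[bn], bn)][1L]
    dd <- cn[order(ranks[cn], cn)][1L]
    rows[[length(rows) + 1L]] <- list(b = bb, c = cc, a = aa, d = dd)
  }
  if (length(rows)) {
    key_b <- vapply(rows, function(r) ranks[r$b], integer(1))
    key_c <- vapply(rows, function(r) ranks[r$c], integer(1))
    idx_b <- vapply(rows, function(r) r$b, integer(1))
    idx_c <- vapply(rows, function(r) r$c, integer(1))
    rows <- rows[order(key_b, key_c, idx_b, idx_c)]
  }
  n <- length(rows)
  bonds <- matrix(0L, n, 2L); quads <- matrix(0L, n, 4L)
  for (i in seq_len(n)) {
    r <- rows[[i]]
    bonds[i, ] <- c(r$b, r$c)
    quads[i, ] <- c(r$a, r$b, r$c, r$d)
  }
  pid <- character(n); mult <- integer(n); bnd <- vector("list", n)
  per <- rep(360, n)
  if (!is.null(library)) {
    for (i in seq_len(n)) {
      p <- matchPattern(mol, bonds[i, ], library)
      pid[i] <- p@id
      mult[i] <- patternMultiplicity(p)
      bnd[[i]] <- p@boundaries
      per[i] <- p@period
    }
  }
  new("TorsionBits", bonds = bonds, quadruples = quads, patternId = pid,
      multiplicity = mult, boundaries = bnd, period = per)
}

#' Assign the angular bin of a torsion angle
#'
#' The angle is first folded into `(-period/2, period/2]` (no-op for the
#' default period of 360), absorbing degenerate local rotations such as a
#' phenyl half-turn.  Bins are half-open `(lower, upper]` on the folded
#' circle; with boundaries `b_1 < ... < b_k`, bin `j < k` covers
#' `(b_j, b_{j+1}]` and bin `k` wraps across the fold ends, covering
#' `(b_k, period/2] U (-period/2, b_1]`.  Boundary angles are therefore
#' deterministic.
#'
#' @param angle torsion angle in degrees, normalized to (-180, 180].
#' @param pattern a [TorsionPattern-class], or a numeric vector of
#'   boundaries (then with `period`).
#' @param period rotor period in degrees when `pattern` is a plain
#'   boundary vector.
#' @return 1-based bin value in `[1, multiplicity]`.
#' @examples
#' assignBin(60, c(-120, 0, 120))   # 2
#' assignBin(180, c(-120, 0, 120))  # 3
#' assignBin(100, c(-45, 45), period = 180)  # same bin as -80
#' @export
assignBin <- function(angle, pattern, period = 360) {
  if (is(pattern, "TorsionPattern")) {
    bnd <- pattern@boundaries
    period <- pattern@period
  } else {
    bnd <- as.numeric(pattern)
  }
  stopifnot(length(bnd) >= 1L, !is.unsorted(bnd, strictly = TRUE))
  if (is.na(angle) || angle <= -180 || angle > 180)
    stop("angle ", angle, " is not normalized to (-180, 180]", call. = FALSE)
  r <- angle %% period
  if (r > period / 2) r <- r - period
  k <- length(bnd)
  j <- sum(r > bnd)
  if (j == 0L || j == k) k else j
}

#' Build the abstract TABS system of a molecule
#'
#' Runs the full perception pipeline: rotatable-torsion detection, pattern
#' matching (multiplicities), atom automorphisms and their projection to
#' the deduplicated bit-permutation group.
#'
#' @param mol a [Molecule-class].
#' @param library a [TorsionLibrary-class].
#' @param maxAutomorphisms cap on the atom automorphism group order.
#' @return list with elements `system` (a [TabsSystem-class]), `bits`
#'   (a [TorsionBits-class]) and `atomGroupOrder`.
#' @examples
#' tabsSystemFromMolecule(parseSmiles("CCCC"))$system
#' @export
tabsSystemFromMolecule <- function(mol, library = defaultTorsionLibrary(),
                                   maxAutomorphisms = 1e5) {
  bits <- findRotatableTorsions(mol, library)
  auts <- atomAutomorphisms(mol, maxOrder = maxAutomorphisms)
  group <- buildBitGroup(mol, bits, automorphisms = auts)
  system <- TabsSystem(bits@multiplicity, group)
  list(system = system, bits = bits, atomGroupOrder = length(auts))
}

setMethod("show", "TorsionBits", function(object) {
  cat("TorsionBits:", nrow(object@bonds), "rotatable torsion(s)\n")
  for (i in seq_len(nrow(object@bonds))) {
    cat(sprintf("  bit %d: bond %d-%d, quad (%s), pattern %s, m = %d\n",
                i, object@bonds[i, 1], object@bonds[i, 2],
                paste(object@quadruples[i, ], collapse = ", "),
                if (length(object@patternId)) object@patternId[i] else "?",
                if (length(object@multiplicity)) object@multiplicity[i] else NA))
  }
})

setMethod("show", "TorsionLibrary", function(object) {
  cat("TorsionLibrary with", length(object@patterns), "patterns:\n")
  for (p in object@patterns)
    cat(sprintf("  [%2d] %s (m = %d)\n", p@priority, p@id,
                patternMultiplicity(p)))
})
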