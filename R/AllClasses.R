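#' @import methods
NULL

#' BitPermutation: a permutation of TABS bit indices
#'
#' A topological symmetry of a molecule permutes the bits of its torsion
#' angular bin string.  `mapping[i]` is the image of bit `i`; the mapping
#' must be a bijection on `1..N`.
#'
#' @slot mapping integer vector; `mapping[i]` is the image of bit `i`.
#' @export
setClass("BitPermutation", representation(mapping = "integer"),
         validity = function(object) {
  m <- object@mapping
  if (length(m) && !identical(sort(m), seq_along(m)))
    return("mapping is not a bijection on 1..N")
  TRUE
})

#' SymmetryGroup: a finite group of bit permutations
#'
#' The image, on TABS bits, of the molecule's topological symmetry group.
#' Elements are stored as integer mapping vectors; the identity must be
#' present and the set must be closed under composition (verified at
#' construction, since Burnside's lemma silently fails on a non-closed set).
#'
#' @slot nBits number of bits the group acts on.
#' @slot elements list of integer mapping vectors, each a bijection on
#'   `1..nBits`; duplicates are not allowed.
#' @export
setClass("SymmetryGroup",
         representation(nBits = "integer", elements = "list"),
         validity = function(object) {
  n <- object@nBits
  els <- object@elements
  if (length(els) == 0L) return("group has no elements")
  keys <- vapply(els, function(e) paste0("p:", paste(e, collapse = ",")),
                 character(1))
  if (anyDuplicated(keys)) return("duplicate group elements")
  for (e in els) {
    if (length(e) != n || !identical(sort(e), seq_len(n)))
      return("element is not a bijection on 1..nBits")
  }
  if (!paste0("p:", paste(seq_len(n), collapse = ",")) %in% keys)
    return("identity element missing")
  # closure under composition
  keyset <- new.env(parent = emptyenv())
  for (k in keys) assign(k, TRUE, envir = keyset)
  for (a in els) for (b in els) {
    k <- paste0("p:", paste(a[b], collapse = ","))
    if (!exists(k, envir = keyset, inherits = FALSE))
      return("element set is not closed under composition")
  }
  TRUE
})

#' TabsSystem: the abstract bit system of a molecule
#'
#' Chemistry-free description of a molecule's torsion bits: the number of
#' bits N, their multiplicities m_i (number of angular bins per torsion),
#' and the symmetry group G acting on the bit indices.  The set S of all
#' raw TABS has cardinality M = prod(m_i).
#'
#' @slot nBits integer N >= 0.
#' @slot multiplicities integer vector of length N, each m_i >= 1.
#' @slot group a [SymmetryGroup-class] acting on the bits; every element
#'   may only exchange bits of identical multiplicity.
#' @export
setClass("TabsSystem",
         representation(nBits = "integer", multiplicities = "integer",
                        group = "SymmetryGroup"),
         validity = function(object) {
  n <- object@nBits
  m <- object@multiplicities
  if (length(n) != 1L || is.na(n) || n < 0L) return("nBits must be >= 0")
  if (length(m) != n) return("multiplicities length differs from nBits")
  if (n > 0L && any(is.na(m) | m < 1L)) return("multiplicities must be >= 1")
  if (object@group@nBits != n) return("group acts on wrong number of bits")
  for (g in object@group@elements) {
    if (n > 0L && any(m[g] != m))
      return("group permutes bits of unequal multiplicity")
  }
  TRUE
})

#' Molecule: a labeled molecular graph
#'
#' Heavy-atom molecular graph with implicit-hydrogen counts, as parsed from
#' SMILES or SDF.  Atom identity for symmetry purposes is element + formal
#' charge + aromaticity + implicit H count; bonds carry order (1, 2, 3, or
#' 1.5 for aromatic) and a ring flag.
#'
#' @slot atoms data.frame with columns `element`, `aromatic`, `charge`, `nH`.
#' @slot bonds data.frame with columns `from`, `to`, `order`, `aromatic`,
#'   `ring` (one row per bond, `from < to`).
#' @slot name molecule identifier.
#' @export
setClass("Molecule",
         representation(atoms = "data.frame", bonds = "data.frame",
                        name = "character"),
         validity = function(object) {
  a <- object@atoms; b <- object@bonds
  need_a <- c("element", "aromatic", "charge", "nH")
  need_b <- c("from", "to", "order", "aromatic", "ring")
  if (!all(need_a %in% names(a))) return("atoms table missing columns")
  if (!all(need_b %in% names(b))) return("bonds table missing columns")
  if (nrow(b) && (any(b$from < 1L) || any(b$to > nrow(a))))
    return("bond indices out of range")
  if (nrow(b) && any(b$from >= b$to)) return("bonds must have from < to")
  TRUE
})

#' Conformer: one 3D embedding of a molecule
#'
#' @slot molecule the parent [Molecule-class].
#' @slot coords numeric matrix, one row of (x, y, z) in Angstrom per atom.
#' @slot id conformer identifier.
#' @export
setClass("Conformer",
         representation(molecule = "Molecule", coords = "matrix",
                        id = "character"),
         validity = function(object) {
  if (nrow(object@coords) != nrow(object@molecule@atoms))
    return("coordinate count differs from atom count")
  if (ncol(object@coords) != 3L) return("coords must be n x 3")
  TRUE
})

#' TorsionPattern: a substructure pattern with angular bins
#'
#' One entry of the torsion library: attribute queries for the four mapped
#' atoms a-b-c-d around a rotatable bond, the b-c bond order, and the bin
#' boundaries.  Boundaries are strictly increasing angles in (-180, 180];
#' with k boundaries the circle is partitioned into k half-open bins
#' (lower, upper], the k-th wrapping across +/-180 degrees, so the
#' multiplicity equals the number of boundaries.
#'
#' @slot id pattern identifier.
#' @slot priority integer rank; lower = more specific, tried first.
#' @slot atomQueries list of 4 atom queries (named lists with optional
#'   fields `elem`, `aromatic`, `charge`, `neighbor`).
#' @slot bondOrder required b-c bond order, or NA for any.
#' @slot boundaries numeric vector of bin boundaries in degrees.
#' @slot period local rotor period in degrees (a divisor of 360; default
#'   360).  Angles are folded into (-period/2, period/2] before binning;
#'   180 encodes a locally two-fold-symmetric rotor such as a phenyl,
#'   whose flip must not change the bin.
#' @export
setClass("TorsionPattern",
         representation(id = "character", priority = "integer",
                        atomQueries = "list", bondOrder = "numeric",
                        boundaries = "numeric", period = "numeric"),
         validity = function(object) {
  b <- object@boundaries
  p <- object@period
  if (length(p) != 1L || is.na(p) || p <= 0 || 360 %% p != 0)
    return("period must be a positive divisor of 360")
  if (length(b) < 1L) return("at least one bin boundary required")
  if (any(b <= -p / 2 | b > p / 2))
    return("boundaries must lie in (-period/2, period/2]")
  if (is.unsorted(b, strictly = TRUE)) return("boundaries must strictly increase")
  if (length(object@atomQueries) != 4L) return("need 4 atom queries (a,b,c,d)")
  TRUE
})

#' TorsionLibrary: an ordered set of torsion patterns
#'
#' Patterns are matched in priority order (file order breaks ties); the
#' library must end in a catch-all generic pattern so every rotatable bond
#' receives a multiplicity.
#'
#' @slot patterns list of [TorsionPattern-class], sorted by priority.
#' @export
setClass("TorsionLibrary", representation(patterns = "list"),
         validity = function(object) {
  if (!length(object@patterns)) return("empty library")
  if (!all(vapply(object@patterns, is, logical(1), "TorsionPattern")))
    return("patterns must be TorsionPattern objects")
  TRUE
})

#' TorsionBits: the matched rotatable torsions of a molecule
#'
#' One entry per qualifying rotatable bond, in the canonical bit order
#' (sorted by the canonical atom ranks of the bond atoms).  Each bit
#' carries its bond, the reference atom quadruple used to measure the
#' dihedral, the matched pattern and its multiplicity and bin boundaries.
#'
#' @slot bonds integer matrix (n x 2), bond atoms, smaller rank first.
#' @slot quadruples integer matrix (n x 4), atoms (a, b, c, d).
#' @slot patternId character vector of matched pattern ids.
#' @slot multiplicity integer vector of bin counts m_i.
#' @slot boundaries list of numeric boundary vectors.
#' @slot period numeric vector of rotor periods (degrees).
#' @export
setClass("TorsionBits",
         representation(bonds = "matrix", quadruples = "matrix",
                        patternId = "character", multiplicity = "integer",
                        boundaries = "list", period = "numeric"),
         validity = function(object) {
  n <- nrow(object@bonds)
  if (nrow(object@quadruples) != n || ncol(object@quadruples) != 4L)
    return("quadruples must be n x 4")
  if (ncol(object@bonds) != 2L) return("bonds must be n x 2")
  if (length(object@multiplicity) != n && length(object@multiplicity) != 0L)
    return("multiplicity length mismatch")
  TRUE
})
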