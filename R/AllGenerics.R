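#' Number of TABS bits
#' @param x a TabsSystem, SymmetryGroup or TorsionBits object.
#' @return integer N.
#' @export
setGeneric("nBits", function(x) standardGeneric("nBits"))

#' Bit multiplicities
#' @param x a TabsSystem or TorsionBits object.
#' @return integer vector m_1..m_N.
#' @export
setGeneric("multiplicities", function(x) standardGeneric("multiplicities"))

#' Group order |G|
#' @param x a SymmetryGroup or TabsSystem.
#' @return integer |G|.
#' @export
setGeneric("groupOrder", function(x) standardGeneric("groupOrder"))

#' Group elements
#' @param x a SymmetryGroup or TabsSystem.
#' @return list of [BitPermutation-class] objects.
#' @export
setGeneric("groupElements", function(x) standardGeneric("groupElements"))

#' Cardinality M = |S| of the raw TABS set
#'
#' The number of raw (uncanonicalized) torsion bin strings of a system,
#' `M = prod(m_i)`, as an exact arbitrary-precision integer; 1 for N = 0
#' (the empty product).
#'
#' @param x a [TabsSystem-class].
#' @return a [bigInteger()] value.
#' @examples
#' cardinality(TabsSystem(c(3, 3)))  # 9
#' @export
setGeneric("cardinality", function(x) standardGeneric("cardinality"))

#' Exact nTABS by Burnside's lemma
#'
#' Counts the distinct TABS (orbits of raw TABS under the topological
#' symmetry group) as `nTABS = (1/|G|) * sum_g |Fix(g)|`, looping over the
#' |G| symmetries and computing each fixpoint count from the cycle
#' decomposition in O(N).  The division is asserted exact; a remainder
#' signals a corrupted (non-closed) group.
#'
#' @param x a [TabsSystem-class], or a [Molecule-class] (for which bits and
#'   group are derived first).
#' @param ... passed on; for molecules, `library` (a
#'   [TorsionLibrary-class], default [defaultTorsionLibrary()]).
#' @return a [bigInteger()] value.
#' @examples
#' s <- TabsSystem(c(3, 3), SymmetryGroup(list(c(2, 1)), nBits = 2))
#' nTabsBurnside(s)  # 6
#' @export
setGeneric("nTabsBurnside", function(x, ...) standardGeneric("nTabsBurnside"))

#' nTABS by exhaustive enumeration (brute-force oracle)
#'
#' Enumerates all of S, canonicalizes every raw TABS and counts distinct
#' canonical forms.  Exponential in N; used to cross-validate
#' [nTabsBurnside()] on small systems, never as a production path.
#'
#' @param x a [TabsSystem-class].
#' @param cap refuse to enumerate when M exceeds this safety cap.
#' @param ... unused.
#' @return a [bigInteger()] value.
#' @export
setGeneric("nTabsNaive", function(x, cap = 1e7, ...) standardGeneric("nTabsNaive"))
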