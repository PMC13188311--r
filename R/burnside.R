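## Exact nTABS via Burnside's lemma, plus the enumeration oracle and the
## orbit/stabilizer/fixpoint machinery used by the identity checks.

#' Fixpoint count of a symmetry
#'
#' A raw TABS is fixed by a bit permutation g iff it is constant on every
#' cycle of g, so `|Fix(g)|` is the product over cycles of the common
#' multiplicity of the bits in the cycle.  Runs in O(N); this is the inner
#' loop that makes Burnside counting scale as O(|G| N) instead of
#' O(|G| N M).
#'
#' @param g a [BitPermutation-class] or mapping vector.
#' @param multiplicities integer vector of bin counts m_i.
#' @return `|Fix(g)|` as a [bigInteger()].
#' @examples
#' fixpointCount(c(2L, 1L), c(3L, 3L))  # 3
#' @export
fixpointCount <- function(g, multiplicities) {
  g <- .as_mapping(g)
  m <- as.integer(multiplicities)
  if (length(g) != length(m))
    stop("permutation and multiplicities dimensions differ", call. = FALSE)
  cyc_m <- integer(0)
  for (cyc in permutationCycles(g)) {
    mc <- unique(m[cyc])
    if (length(mc) != 1L)
      stop("cycle (", paste(cyc, collapse = " "),
           ") spans bits of unequal multiplicity", call. = FALSE)
    cyc_m <- c(cyc_m, mc)
  }
  biProduct(cyc_m)
}

#' @rdname nTabsBurnside
#' @param .counter optional environment with a numeric field `calls`;
#'   incremented once per fixpoint evaluation.  Instrumentation hook used to
#'   verify the O(|G| N) complexity contract (the count must equal |G| and
#'   be independent of M).
#' @export
setMethod("nTabsBurnside", "TabsSystem", function(x, .counter = NULL) {
  m <- x@multiplicities
  acc <- bigInteger(0)
  for (g in x@group@elements) {
    if (!is.null(.counter)) .counter$calls <- .counter$calls + 1
    acc <- biAdd(acc, fixpointCount(g, m))
  }
  nG <- length(x@group@elements)
  out <- tryCatch(biDivSmallExact(acc, nG), error = function(e) {
    stop("Burnside sum ", as.character(acc), " is not divisible by |G| = ",
         nG, "; the group is corrupted (not closed)", call. = FALSE)
  })
  out
})

#' @rdname nTabsNaive
#' @export
setMethod("nTabsNaive", "TabsSystem", function(x, cap = 1e7, ...) {
  S <- enumerateRawTabs(x, cap = cap)
  m <- x@multiplicities
  if (ncol(S) == 0L) return(bigInteger(1))
  # canonical code per row = min over g of the mixed-radix encoding of g.s
  best <- .encode_rows(S, m)
  for (g in x@group@elements) {
    code <- .encode_rows(.apply_perm_rows(S, g), m)
    best <- pmin(best, code)
  }
  bigInteger(length(unique(best)))
})

#' @rdname nTabsBurnside
#' @export
setMethod("nTabsBurnside", "Molecule", function(x, library = defaultTorsionLibrary(), ...) {
  sys <- tabsSystemFromMolecule(x, library)$system
  nTabsBurnside(sys)
})

#' Stabilizer of a raw TABS
#'
#' The subgroup `Stab(s) = {g in G : g.s = s}`.  Always contains the
#' identity, and `|Orb(s)| * |Stab(s)| = |G|` (orbit-stabilizer theorem).
#'
#' @param s raw TABS (integer vector).
#' @param group a [SymmetryGroup-class] or [TabsSystem-class].
#' @return list of [BitPermutation-class] objects.
#' @export
tabsStabilizer <- function(s, group) {
  if (is(group, "TabsSystem")) group <- group@group
  stopifnot(is(group, "SymmetryGroup"))
  s <- as.integer(s)
  if (length(s) != group@nBits)
    stop("raw TABS and group dimensions differ", call. = FALSE)
  keep <- Filter(function(g) identical(applyPermutation(s, g), s),
                 group@elements)
  lapply(keep, BitPermutation)
}
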