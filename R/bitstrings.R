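## Raw TABS as multi-radix strings, the set S, and canonicalization.
##
## A raw TABS is represented as a plain 1-based integer vector of length N,
## with bit i in [1, m_i].  All user-facing I/O uses the hyphen-separated
## serialization, e.g. "1-3-2".

#' @rdname cardinality
#' @export
setMethod("cardinality", "TabsSystem", function(x) {
  biProduct(x@multiplicities)
})

.check_rawtabs <- function(s, system) {
  s <- as.integer(s)
  if (length(s) != system@nBits)
    stop("raw TABS length ", length(s), " does not match N = ",
         system@nBits, call. = FALSE)
  if (system@nBits > 0L && any(s < 1L | s > system@multiplicities))
    stop("raw TABS values out of the [1, m_i] ranges", call. = FALSE)
  s
}

#' Enumerate the full raw TABS set S
#'
#' Produces every element of S exactly once, in lexicographic order, as the
#' rows of an integer matrix.  Because M = prod(m_i) grows exponentially,
#' an explicit safety cap is required; this enumeration is the brute-force
#' oracle's input, not a production path.
#'
#' @param system a [TabsSystem-class].
#' @param cap refuse to enumerate when M exceeds this value (default 1e7).
#' @return integer matrix with M rows and N columns.
#' @examples
#' enumerateRawTabs(TabsSystem(c(2, 3)))
#' @export
enumerateRawTabs <- function(system, cap = 1e7) {
  stopifnot(is(system, "TabsSystem"))
  M <- cardinality(system)
  if (biCompare(M, bigInteger(cap)) > 0L)
    stop("cardinality ", as.character(M), " exceeds the safety cap ", cap,
         call. = FALSE)
  n <- system@nBits
  if (n == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  m <- system@multiplicities
  Mn <- as.numeric(M)
  out <- matrix(0L, nrow = Mn, ncol = n)
  reps_inner <- 1
  for (i in rev(seq_len(n))) {
    # lexicographic order: last bit varies fastest
    out[, i] <- rep(rep(seq_len(m[i]), each = reps_inner),
                    times = Mn / (reps_inner * m[i]))
    reps_inner <- reps_inner * m[i]
  }
  out
}

#' Apply a symmetry to a raw TABS
#'
#' Left action g.s: the value of bit `i` is placed at position `g(i)`, i.e.
#' `(g.s)[g(i)] = s[i]`.  The identity returns `s` unchanged.  The action
#' convention is invisible to orbit counting but is fixed so canonical
#' forms are reproducible.
#'
#' @param s raw TABS (integer vector).
#' @param g a [BitPermutation-class] or mapping vector.
#' @return the permuted raw TABS.
#' @examples
#' applyPermutation(c(1L, 2L, 3L), c(2L, 3L, 1L))  # 3 1 2
#' @export
applyPermutation <- function(s, g) {
  g <- .as_mapping(g)
  s <- as.integer(s)
  if (length(s) != length(g))
    stop("raw TABS and permutation dimensions differ", call. = FALSE)
  inv <- integer(length(g))
  inv[g] <- seq_along(g)
  s[inv]
}

#' Canonical TABS of a raw TABS
#'
#' The TABS of a conformer is the equivalence class of its raw TABS under
#' the topological symmetry group; the lexicographically smallest orbit
#' member is used as the canonical representative.  Two raw TABS have the
#' same canonical form iff they lie in the same orbit.
#'
#' @param s raw TABS (integer vector).
#' @param group a [SymmetryGroup-class] (or a [TabsSystem-class], whose
#'   group is used).
#' @return the canonical raw TABS (integer vector).
#' @examples
#' canonicalTabs(c(2L, 1L), SymmetryGroup(list(c(2L, 1L))))  # 1 2
#' @export
canonicalTabs <- function(s, group) {
  if (is(group, "TabsSystem")) group <- group@group
  stopifnot(is(group, "SymmetryGroup"))
  s <- as.integer(s)
  if (length(s) != group@nBits)
    stop("raw TABS and group dimensions differ", call. = FALSE)
  best <- s
  for (g in group@elements) {
    t <- applyPermutation(s, g)
    if (.lex_less(t, best)) best <- t
  }
  best
}

.lex_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0L && a[d[1L]] < b[d[1L]]
}

#' Orbit of a raw TABS
#'
#' The set of raw TABS reachable from `s` by the group, `{g.s : g in G}`.
#' Its size divides |G| (orbit-stabilizer theorem).
#'
#' @inheritParams canonicalTabs
#' @return integer matrix, one distinct orbit member per row, sorted
#'   lexicographically.
#' @export
tabsOrbit <- function(s, group) {
  if (is(group, "TabsSystem")) group <- group@group
  stopifnot(is(group, "SymmetryGroup"))
  s <- as.integer(s)
  if (length(s) != group@nBits)
    stop("raw TABS and group dimensions differ", call. = FALSE)
  imgs <- vapply(group@elements, function(g) applyPermutation(s, g),
                 integer(length(s)))
  imgs <- matrix(imgs, ncol = length(s), byrow = TRUE)
  imgs <- unique(imgs)
  imgs[do.call(order, as.data.frame(imgs)), , drop = FALSE]
}

#' Serialize / parse raw TABS strings
#'
#' Raw TABS travel through CLI output and CSV columns as hyphen-separated
#' 1-based integers, e.g. `"1-3-2"`; the empty string encodes N = 0.
#'
#' @param s raw TABS integer vector ([formatTabs()]) or its string form
#'   ([parseTabs()]).
#' @return the other representation.
#' @examples
#' formatTabs(c(1L, 3L, 2L))
#' parseTabs("1-3-2")
#' @export
formatTabs <- function(s) paste(as.integer(s), collapse = "-")

#' @rdname formatTabs
#' @export
parseTabs <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (!nzchar(s)) return(integer(0))
  as.integer(strsplit(s, "-", fixed = TRUE)[[1L]])
}

## ---- internal vectorized helpers (used by the naive oracle and the
## ---- identity checks): encode rows as mixed-radix numbers so that the
## ---- numeric order equals the lexicographic order of the strings.

.encode_rows <- function(mat, m) {
  if (ncol(mat) == 0L) return(rep(0, nrow(mat)))
  w <- rev(cumprod(rev(c(m[-1L], 1))))
  as.vector((mat - 1L) %*% w)
}

# apply permutation g to every row of mat at once
.apply_perm_rows <- function(mat, g) {
  inv <- integer(length(g))
  inv[g] <- seq_along(g)
  mat[, inv, drop = FALSE]
}
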