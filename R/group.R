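## Bit permutations and their groups.

.perm_key <- function(p) paste0("p:", paste(p, collapse = ","))

.as_mapping <- function(g) {
  if (is(g, "BitPermutation")) return(g@mapping)
  as.integer(g)
}

#' Create a bit permutation
#'
#' @param mapping integer vector; `mapping[i]` is the image of bit `i`.
#' @return a [BitPermutation-class].
#' @examples
#' BitPermutation(c(2L, 1L))  # swap of two bits
#' @export
BitPermutation <- function(mapping) {
  new("BitPermutation", mapping = as.integer(mapping))
}

#' @describeIn BitPermutation the identity on `n` bits.
#' @param n number of bits.
#' @export
identityPermutation <- function(n) BitPermutation(seq_len(n))

#' Compose two bit permutations
#'
#' Returns the permutation `g o h` mapping `i` to `g(h(i))`.
#'
#' @param g,h [BitPermutation-class] objects (or plain mapping vectors).
#' @return a [BitPermutation-class].
#' @export
composePermutations <- function(g, h) {
  g <- .as_mapping(g); h <- .as_mapping(h)
  stopifnot(length(g) == length(h))
  BitPermutation(g[h])
}

#' Invert a bit permutation
#' @param g a [BitPermutation-class] or mapping vector.
#' @return a [BitPermutation-class].
#' @export
invertPermutation <- function(g) {
  g <- .as_mapping(g)
  inv <- integer(length(g))
  inv[g] <- seq_along(g)
  BitPermutation(inv)
}

#' Cycle decomposition of a bit permutation
#'
#' @param g a [BitPermutation-class] or mapping vector.
#' @return list of integer vectors, one per cycle (fixed points included as
#'   length-1 cycles), each starting at its smallest element; cycles ordered
#'   by that element.
#' @examples
#' permutationCycles(c(2L, 3L, 1L, 4L))  # list(c(1,2,3), 4)
#' @export
permutationCycles <- function(g) {
  g <- .as_mapping(g)
  seen <- logical(length(g))
  cycles <- list()
  for (i in seq_along(g)) {
    if (seen[i]) next
    cyc <- i
    j <- g[i]
    seen[i] <- TRUE
    while (j != i) {
      seen[j] <- TRUE
      cyc <- c(cyc, j)
      j <- g[j]
    }
    cycles[[length(cycles) + 1L]] <- cyc
  }
  cycles
}

#' Construct a symmetry group from generators
#'
#' Builds the closure of the given bit permutations under composition,
#' always including the identity, and returns the resulting group.  Closure
#' is enforced at construction because Burnside's lemma silently gives wrong
#' answers on a non-closed element set; construction fails if the closure
#' exceeds `maxOrder`.
#'
#' @param generators list of [BitPermutation-class] objects or mapping
#'   vectors (may be empty for the trivial group).
#' @param nBits number of bits; inferred from the generators if omitted.
#' @param maxOrder abort if the closure grows beyond this many elements.
#' @return a [SymmetryGroup-class].
#' @examples
#' SymmetryGroup(list(c(2L, 1L)), nBits = 2)   # {I, swap}, order 2
#' SymmetryGroup(list(), nBits = 3)            # trivial group
#' @export
SymmetryGroup <- function(generators = list(), nBits = NULL,
                          maxOrder = 1e6) {
  gens <- lapply(generators, .as_mapping)
  if (is.null(nBits)) {
    if (!length(gens))
      stop("nBits must be given when there are no generators", call. = FALSE)
    nBits <- length(gens[[1L]])
  }
  nBits <- as.integer(nBits)
  for (g in gens) {
    if (length(g) != nBits || !identical(sort(g), seq_len(nBits)))
      stop("generator is not a bijection on 1..nBits", call. = FALSE)
  }
  elements <- groupClosure(gens, nBits, maxOrder)
  new("SymmetryGroup", nBits = nBits, elements = elements)
}

# closure of mapping vectors under composition, identity always included;
# returns a deduplicated list of mapping vectors
groupClosure <- function(gens, nBits, maxOrder = 1e6) {
  idx <- new.env(parent = emptyenv())
  elements <- list(seq_len(nBits))
  assign(.perm_key(elements[[1L]]), TRUE, envir = idx)
  queue <- list()
  for (g in gens) {
    k <- .perm_key(g)
    if (!exists(k, envir = idx, inherits = FALSE)) {
      assign(k, TRUE, envir = idx)
      elements[[length(elements) + 1L]] <- g
      queue[[length(queue) + 1L]] <- g
    }
  }
  while (length(queue)) {
    g <- queue[[1L]]
    queue[[1L]] <- NULL
    for (h in elements) {
      for (p in list(g[h], h[g])) {
        k <- .perm_key(p)
        if (!exists(k, envir = idx, inherits = FALSE)) {
          assign(k, TRUE, envir = idx)
          elements[[length(elements) + 1L]] <- p
          queue[[length(queue) + 1L]] <- p
          if (length(elements) > maxOrder)
            stop("group closure exceeds maxOrder = ", maxOrder, call. = FALSE)
        }
      }
    }
  }
  elements
}

#' Construct a TabsSystem
#'
#' @param multiplicities integer vector of bin counts m_i (length N).
#' @param group a [SymmetryGroup-class] on the same bits; defaults to the
#'   trivial group.
#' @return a [TabsSystem-class].
#' @examples
#' TabsSystem(c(3, 3), SymmetryGroup(list(c(2L, 1L)), nBits = 2))
#' @export
TabsSystem <- function(multiplicities = integer(0), group = NULL) {
  m <- as.integer(multiplicities)
  n <- length(m)
  if (is.null(group)) group <- SymmetryGroup(list(), nBits = n)
  new("TabsSystem", nBits = n, multiplicities = m, group = group)
}

#' @rdname nBits
#' @export
setMethod("nBits", "TabsSystem", function(x) x@nBits)

#' @rdname nBits
#' @export
setMethod("nBits", "SymmetryGroup", function(x) x@nBits)

#' @rdname nBits
#' @export
setMethod("nBits", "TorsionBits", function(x) nrow(x@bonds))

#' @rdname multiplicities
#' @export
setMethod("multiplicities", "TabsSystem", function(x) x@multiplicities)

#' @rdname multiplicities
#' @export
setMethod("multiplicities", "TorsionBits", function(x) x@multiplicity)

#' @rdname groupOrder
#' @export
setMethod("groupOrder", "SymmetryGroup", function(x) length(x@elements))

#' @rdname groupOrder
#' @export
setMethod("groupOrder", "TabsSystem", function(x) length(x@group@elements))

#' @rdname groupElements
#' @export
setMethod("groupElements", "SymmetryGroup",
          function(x) lapply(x@elements, BitPermutation))

#' @rdname groupElements
#' @export
setMethod("groupElements", "TabsSystem",
          function(x) groupElements(x@group))

setMethod("show", "BitPermutation", function(object) {
  cyc <- permutationCycles(object)
  cyc <- Filter(function(c) length(c) > 1L, cyc)
  txt <- if (!length(cyc)) "identity" else
    paste(vapply(cyc, function(c) paste0("(", paste(c, collapse = " "), ")"),
                 character(1)), collapse = "")
  cat("BitPermutation on", length(object@mapping), "bits:", txt, "\n")
})

setMethod("show", "SymmetryGroup", function(object) {
  cat("SymmetryGroup of order", length(object@elements),
      "on", object@nBits, "bits\n")
})

setMethod("show", "TabsSystem", function(object) {
  cat("TabsSystem: N =", object@nBits,
      "| m = (", paste(object@multiplicities, collapse = ", "), ")",
      "| |G| =", length(object@group@elements),
      "| M =", as.character(cardinality(object)), "\n")
})
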