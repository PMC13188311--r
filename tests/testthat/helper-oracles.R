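# Independent brute-force oracles, written from the definitions only
# (base R, no reuse of the package's enumeration/canonicalization paths).

# all strings with bit i in 1..m[i], rows in lexicographic order
oracle_enumerate <- function(m) {
  n <- length(m)
  if (n == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  grid <- do.call(expand.grid, lapply(rev(m), seq_len))
  mat <- as.matrix(grid)[, rev(seq_len(n)), drop = FALSE]
  dimnames(mat) <- NULL
  matrix(as.integer(mat), ncol = n)
}

# action from the definition: (g.s)[g(i)] = s[i]
oracle_apply <- function(s, g) {
  t <- integer(length(s))
  t[g] <- s
  t
}

# lexicographically smallest orbit member, by padded-string comparison
oracle_canonical <- function(s, elements) {
  imgs <- vapply(elements, function(g) {
    paste(formatC(oracle_apply(s, g), width = 3, flag = "0"), collapse = "")
  }, character(1))
  best <- which.min(rank(imgs, ties.method = "min"))
  oracle_apply(s, elements[[best]])
}

# orbit count by exhaustive enumeration + dedup of canonical forms
oracle_count_orbits <- function(m, elements) {
  S <- oracle_enumerate(m)
  keys <- vapply(seq_len(nrow(S)), function(r) {
    paste(oracle_canonical(S[r, ], elements), collapse = "-")
  }, character(1))
  length(unique(keys))
}

# |Fix(g)| by scanning all of S
oracle_fixpoints <- function(g, m) {
  S <- oracle_enumerate(m)
  sum(vapply(seq_len(nrow(S)), function(r) {
    identical(oracle_apply(S[r, ], g), S[r, ])
  }, logical(1)))
}

# the Fig. 2 system: N = 2, m_A = m_B = 3, G = {I, P(swap)}
fig2_system <- function() {
  TabsSystem(c(3L, 3L), SymmetryGroup(list(c(2L, 1L)), nBits = 2))
}

# relabel a molecule (and optionally conformer coordinates) by an atom
# permutation sigma: the atom with old index i gets new index sigma[i]
relabel_molecule <- function(mol, sigma, coords = NULL) {
  inv <- integer(length(sigma))
  inv[sigma] <- seq_along(sigma)
  atoms <- mol@atoms[inv, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol@bonds
  bonds$from <- sigma[mol@bonds$from]
  bonds$to <- sigma[mol@bonds$to]
  mol2 <- newMolecule(atoms, bonds[, c("from", "to", "order", "aromatic")],
                      name = paste0(mol@name, "_relabeled"))
  if (is.null(coords)) return(mol2)
  list(molecule = mol2, coords = coords[inv, , drop = FALSE])
}
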