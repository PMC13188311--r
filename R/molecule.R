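## Molecular-graph utilities: adjacency, canonical atom ranks.

# adjacency list: for each atom, data.frame(nbr, order, aromatic)
.adjacency <- function(mol) {
  n <- nrow(mol@atoms)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- list(nbr = integer(0), label = character(0))
  b <- mol@bonds
  for (k in seq_len(nrow(b))) {
    lab <- .bond_label(b$order[k], b$aromatic[k])
    f <- b$from[k]; t <- b$to[k]
    adj[[f]]$nbr <- c(adj[[f]]$nbr, t); adj[[f]]$label <- c(adj[[f]]$label, lab)
    adj[[t]]$nbr <- c(adj[[t]]$nbr, f); adj[[t]]$label <- c(adj[[t]]$label, lab)
  }
  adj
}

.bond_label <- function(order, aromatic) {
  if (aromatic) "ar" else format(order)
}

# label-indexed lookup of bonds: key "u:v" (u < v) -> bond label
.bond_map <- function(mol) {
  b <- mol@bonds
  keys <- paste(b$from, b$to, sep = ":")
  labs <- mapply(.bond_label, b$order, b$aromatic)
  stats::setNames(as.character(labs), keys)
}

.heavy_neighbors <- function(mol, adj, i) {
  nb <- adj[[i]]$nbr
  nb[mol@atoms$element[nb] != "H"]
}

#' Canonical atom ranks by iterative neighborhood refinement
#'
#' Morgan-style refinement: atoms start from an invariant built from
#' element, aromaticity, formal charge, implicit H count and degree, then
#' ranks are refined by the sorted multiset of (neighbor rank, bond label)
#' until the partition stabilizes.  Equal final ranks identify symmetry
#' candidates (atoms that can only map within their class); ranks are
#' invariant under atom relabeling, which makes bit ordering and reference
#' quadruples reproducible.
#'
#' @param mol a [Molecule-class].
#' @return integer vector of dense 1-based ranks, one per atom.
#' @export
canonicalAtomRanks <- function(mol) {
  n <- nrow(mol@atoms)
  a <- mol@atoms
  adj <- .adjacency(mol)
  deg <- vapply(adj, function(x) length(x$nbr), integer(1))
  key <- paste(a$element, a$aromatic, a$charge, a$nH, deg, sep = "|")
  rank <- match(key, sort(unique(key)))
  repeat {
    newkey <- vapply(seq_len(n), function(i) {
      nb <- paste(rank[adj[[i]]$nbr], adj[[i]]$label, sep = "@")
      paste(rank[i], paste(sort(nb), collapse = ","), sep = "#")
    }, character(1))
    newrank <- match(newkey, sort(unique(newkey)))
    if (length(unique(newrank)) == length(unique(rank))) {
      rank <- newrank
      break
    }
    rank <- newrank
  }
  as.integer(rank)
}
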