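## Symmetry-aware heavy-atom RMSD adapter.
##
## TABS treats conformers related by a topological symmetry as identical,
## so a fair RMSD comparison must minimize over the automorphism-induced
## atom mappings as well as over rigid-body superposition; a
## symmetry-naive RMSD would contradict the TABS labeling.

# Kabsch: optimal-rotation RMSD of two centered coordinate sets
.kabsch_rmsd <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  A <- sweep(A, 2L, colMeans(A))
  B <- sweep(B, 2L, colMeans(B))
  H <- crossprod(B, A)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Brot <- B %*% t(R)
  sqrt(mean(rowSums((A - Brot)^2)))
}

#' Heavy-atom RMSD of two conformers, minimized over symmetry mappings
#'
#' Superimposes conformer B onto conformer A (Kabsch) for every
#' automorphism-induced relabeling of the heavy atoms and returns the
#' minimum RMSD.
#'
#' @param confA,confB [Conformer-class] objects of the same molecule.
#' @param automorphisms optional precomputed list from
#'   [atomAutomorphisms()]; computed from `confA`'s molecule if missing.
#' @return RMSD in Angstrom.
#' @export
pairRmsd <- function(confA, confB, automorphisms = NULL) {
  mol <- confA@molecule
  stopifnot(nrow(confA@coords) == nrow(confB@coords))
  if (is.null(automorphisms)) automorphisms <- atomAutomorphisms(mol)
  heavy <- which(mol@atoms$element != "H")
  A <- confA@coords[heavy, , drop = FALSE]
  best <- Inf
  for (g in automorphisms) {
    # atom i of A is compared against atom g(i) of B
    B <- confB@coords[g[heavy], , drop = FALSE]
    best <- min(best, .kabsch_rmsd(A, B))
  }
  best
}

#' Pairwise score table of an ensemble under the built-in RMSD metric
#'
#' @param conformers list of [Conformer-class] objects of one molecule.
#' @return data.frame with columns `i`, `j`, `value` (RMSD in Angstrom;
#'   a distance metric: higher = more different), one row per unordered
#'   pair.
#' @export
rmsdScoreTable <- function(conformers) {
  n <- length(conformers)
  stopifnot(n >= 2L)
  auts <- atomAutomorphisms(conformers[[1L]]@molecule)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      rows[[length(rows) + 1L]] <- data.frame(
        i = conformers[[i]]@id, j = conformers[[j]]@id,
        value = pairRmsd(conformers[[i]], conformers[[j]], auts),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
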