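## Synthetic inputs: random abstract bit systems, hard-coded molecule
## fixtures, analytically built 3D conformers and label-level ensembles.
## These make every module testable without external data.

#' Random abstract TABS system
#'
#' Draws N, multiplicities and a symmetry group from the current RNG
#' state (use `set.seed()` for reproducibility).  Group generators are
#' built by partitioning the bits into equal-multiplicity classes and
#' shuffling within classes only, so every generator respects
#' multiplicities by construction; the group is the closure of the
#' generators plus the identity.
#'
#' @param nBitsRange integer range `c(min, max)` for N.
#' @param multiplicityRange integer range for the m_i.
#' @param nGenerators number of random generators (0 gives the trivial
#'   group).
#' @param maxOrder closure cap passed to [SymmetryGroup()].
#' @return a [TabsSystem-class].
#' @examples
#' set.seed(1)
#' randomTabsSystem()
#' @export
randomTabsSystem <- function(nBitsRange = c(1L, 6L),
                             multiplicityRange = c(1L, 4L),
                             nGenerators = 2L, maxOrder = 1e4) {
  stopifnot(nBitsRange[1L] >= 0L, multiplicityRange[1L] >= 1L)
  n <- sample(nBitsRange[1L]:nBitsRange[2L], 1L)
  m <- sample(multiplicityRange[1L]:multiplicityRange[2L], n, replace = TRUE)
  gens <- list()
  for (k in seq_len(nGenerators)) {
    perm <- seq_len(n)
    for (mult in unique(m)) {
      cls <- which(m == mult)
      if (length(cls) >= 2L) perm[cls] <- sample(cls)
    }
    gens[[length(gens) + 1L]] <- as.integer(perm)
  }
  TabsSystem(m, SymmetryGroup(gens, nBits = n, maxOrder = maxOrder))
}

#' Hard-coded molecule fixtures
#'
#' A small named set of SMILES with hand-derived expectations for the
#' number of torsion bits and the order of the projected bit-permutation
#' group (the brute-force paths re-derive these in the tests):
#' n-butane (1 bit, trivial bit group), benzene (no bits), aspirin (an
#' asymmetric drug-like molecule, trivial group) and 1,2-diphenylethane
#' (three bits of which the two phenyl-CH2 torsions are exchangeable, bit
#' group of order 2).
#'
#' @return named list of entries with fields `smiles`, `nBits`,
#'   `bitGroupOrder`.
#' @export
moleculeFixtures <- function() {
  list(
    butane = list(smiles = "CCCC", nBits = 1L, bitGroupOrder = 1L),
    benzene = list(smiles = "c1ccccc1", nBits = 0L, bitGroupOrder = 1L),
    aspirin = list(smiles = "CC(=O)Oc1ccccc1C(=O)O", nBits = 3L,
                   bitGroupOrder = 1L),
    diphenylethane = list(smiles = "c1ccccc1CCc2ccccc2", nBits = 3L,
                          bitGroupOrder = 2L)
  )
}

#' Label-level synthetic conformer ensemble
#'
#' Samples `nConformers` raw TABS uniformly from S, canonicalizes them to
#' TABS labels, and draws a pairwise similarity score for every unordered
#' pair from one normal distribution for equal-TABS pairs and another for
#' unequal pairs (clamped to [0, 1]).  With the default means the two
#' distributions are well separated, emulating the statistical structure a
#' well-behaved shape metric shows; increase the spreads or move the means
#' together to emulate a poor metric.
#'
#' @param system a [TabsSystem-class].
#' @param nConformers number of conformers (>= 2).
#' @param sameMean,sameSd score distribution for equal-TABS pairs.
#' @param diffMean,diffSd score distribution for unequal-TABS pairs.
#' @return list with `labels` (named character, conformer id -> TABS
#'   string), `scores` (data.frame `i`, `j`, `value`) and
#'   `direction = "similarity"`.
#' @export
syntheticEnsemble <- function(system, nConformers,
                              sameMean = 0.95, sameSd = 0.02,
                              diffMean = 0.65, diffSd = 0.08) {
  stopifnot(is(system, "TabsSystem"), nConformers >= 2L)
  n <- system@nBits
  m <- system@multiplicities
  ids <- paste0("conf", seq_len(nConformers))
  labels <- character(nConformers)
  for (k in seq_len(nConformers)) {
    raw <- vapply(seq_len(n), function(i) sample.int(m[i], 1L), integer(1))
    labels[k] <- formatTabs(canonicalTabs(raw, system@group))
  }
  names(labels) <- ids
  pr <- utils::combn(nConformers, 2L)
  same <- labels[pr[1L, ]] == labels[pr[2L, ]]
  value <- ifelse(same,
                  stats::rnorm(ncol(pr), sameMean, sameSd),
                  stats::rnorm(ncol(pr), diffMean, diffSd))
  value <- pmin(1, pmax(0, value))
  list(labels = labels,
       scores = data.frame(i = ids[pr[1L, ]], j = ids[pr[2L, ]],
                           value = value, stringsAsFactors = FALSE),
       direction = "similarity")
}

## ---- analytic 3D builders -------------------------------------------------

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given positions of atoms A, B, C, returns the position D bonded to C
#' with bond length `dist`, angle B-C-D `angle` and dihedral A-B-C-D
#' `dihedral` (degrees, IUPAC sign convention as measured by
#' [measureDihedral()]).
#'
#' @param A,B,C numeric length-3 positions.
#' @param dist C-D distance.
#' @param angle B-C-D angle in degrees.
#' @param dihedral A-B-C-D dihedral in degrees.
#' @return numeric length-3 position of D.
#' @export
placeAtom <- function(A, B, C, dist, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  b1 <- B - A
  b2 <- C - B
  bc <- b2 / sqrt(sum(b2^2))
  n <- .cross3(b1, b2)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d2 <- dist * c(-cos(ang), sin(ang) * cos(dih), -sin(ang) * sin(dih))
  C + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Analytic n-butane conformer with a prescribed central dihedral
#'
#' Heavy-atom butane (from the fixture SMILES) with the C1-C2-C3-C4
#' dihedral set exactly to `dihedral`; used as a hand-built 3D fixture for
#' bin assignment.
#'
#' @param dihedral central torsion in degrees.
#' @param id conformer id.
#' @return a [Conformer-class].
#' @export
butaneConformer <- function(dihedral, id = sprintf("butane_%g", dihedral)) {
  mol <- parseSmiles("CCCC", name = "n-butane")
  ang <- 111
  C2 <- c(0, 0, 0)
  C3 <- c(1.53, 0, 0)
  C1 <- C2 + 1.53 * c(cos(ang * pi / 180), sin(ang * pi / 180), 0)
  C4 <- placeAtom(C1, C2, C3, 1.53, ang, dihedral)
  Conformer(mol, rbind(C1, C2, C3, C4), id = id)
}

#' Analytic 1,2-diphenylethane conformer
#'
#' Heavy-atom 1,2-diphenylethane built from internal coordinates with the
#' three rotatable torsions set to (approximately, for the ring-adjacent
#' ones, exactly for the central one) the given values.  The symmetric
#' fixture exercising end-to-end invariance of TABS assignment.
#'
#' @param t1,t2,t3 torsions in degrees about the ring1-CH2, CH2-CH2 and
#'   CH2-ring2 bonds.
#' @param id conformer id.
#' @return a [Conformer-class].
#' @export
diphenylethaneConformer <- function(t1 = 90, t2 = 180, t3 = 90,
                                    id = "dpe") {
  mol <- parseSmiles("c1ccccc1CCc2ccccc2", name = "1,2-diphenylethane")
  xyz <- matrix(0, nrow = 14L, ncol = 3L)
  # ring 1: regular hexagon of side 1.4 in the z = 0 plane
  for (k in 1:6) {
    th <- (k - 1) * pi / 3
    xyz[k, ] <- 1.4 * c(cos(th), sin(th), 0)
  }
  xyz[7L, ] <- placeAtom(xyz[4L, ], xyz[5L, ], xyz[6L, ], 1.51, 120, 180)
  xyz[8L, ] <- placeAtom(xyz[5L, ], xyz[6L, ], xyz[7L, ], 1.53, 111, t1)
  xyz[9L, ] <- placeAtom(xyz[6L, ], xyz[7L, ], xyz[8L, ], 1.51, 111, t2)
  xyz[10L, ] <- placeAtom(xyz[7L, ], xyz[8L, ], xyz[9L, ], 1.4, 120, t3)
  xyz[11L, ] <- placeAtom(xyz[8L, ], xyz[9L, ], xyz[10L, ], 1.4, 120, 180)
  xyz[12L, ] <- placeAtom(xyz[9L, ], xyz[10L, ], xyz[11L, ], 1.4, 120, 0)
  xyz[13L, ] <- placeAtom(xyz[10L, ], xyz[11L, ], xyz[12L, ], 1.4, 120, 0)
  xyz[14L, ] <- placeAtom(xyz[11L, ], xyz[12L, ], xyz[13L, ], 1.4, 120, 0)
  Conformer(mol, xyz, id = id)
}

#' Oracle-equivalence self-test battery
#'
#' Generates `nSystems` random systems and checks Burnside counting
#' against the brute-force enumeration oracle on each; used by the CLI
#' `selftest` command and the acceptance checks.
#'
#' @param nSystems number of random systems.
#' @param seed RNG seed.
#' @param cap enumeration safety cap per system.
#' @return invisibly, a data.frame with one row per system (N, |G|, M,
#'   burnside, naive, ok); prints a short report.
#' @export
selfTest <- function(nSystems = 500L, seed = 1L, cap = 1e6) {
  set.seed(seed)
  rows <- vector("list", nSystems)
  for (k in seq_len(nSystems)) {
    sys <- randomTabsSystem(nGenerators = sample(0:3, 1L))
    nb <- nTabsBurnside(sys)
    nn <- nTabsNaive(sys, cap = cap)
    rows[[k]] <- data.frame(N = sys@nBits, G = groupOrder(sys),
                            M = as.numeric(cardinality(sys)),
                            burnside = as.numeric(nb), naive = as.numeric(nn),
                            ok = biCompare(nb, nn) == 0L)
  }
  out <- do.call(rbind, rows)
  cat(sprintf("selftest: %d/%d systems agree (Burnside vs enumeration)\n",
              sum(out$ok), nSystems))
  invisible(out)
}
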