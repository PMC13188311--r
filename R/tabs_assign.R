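## Assigning TABS to 3D conformers.

#' Construct a Conformer
#'
#' @param molecule a [Molecule-class].
#' @param coords numeric n x 3 matrix of positions in Angstrom.
#' @param id conformer identifier.
#' @return a [Conformer-class].
#' @export
Conformer <- function(molecule, coords, id = "conf1") {
  new("Conformer", molecule = molecule, coords = as.matrix(coords),
      id = as.character(id))
}

#' Measure a signed dihedral angle
#'
#' Standard IUPAC convention: the angle between the plane of (a, b, c) and
#' the plane of (b, c, d), signed by the handedness about the b-c axis,
#' returned in degrees in (-180, 180] (cis = 0, trans = 180).  A geometry
#' where three consecutive atoms are collinear has no defined dihedral and
#' raises an error rather than returning an arbitrary bin.
#'
#' @param conformer a [Conformer-class], or a plain n x 3 coordinate matrix.
#' @param quadruple integer vector of 4 distinct atom indices (a, b, c, d).
#' @param tol collinearity tolerance on the normal-vector norms.
#' @return the dihedral angle in degrees.
#' @export
measureDihedral <- function(conformer, quadruple, tol = 1e-8) {
  xyz <- if (is(conformer, "Conformer")) conformer@coords else
    as.matrix(conformer)
  q <- as.integer(quadruple)
  stopifnot(length(q) == 4L, !anyDuplicated(q))
  p <- xyz[q, , drop = FALSE]
  b1 <- p[2L, ] - p[1L, ]
  b2 <- p[3L, ] - p[2L, ]
  b3 <- p[4L, ] - p[3L, ]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < tol || sqrt(sum(n2^2)) < tol)
    stop("degenerate geometry: three of the four atoms are collinear, ",
         "dihedral undefined", call. = FALSE)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Assign the raw TABS of a conformer
#'
#' Bit `i` takes the bin value of the measured dihedral of its reference
#' quadruple under its matched pattern's boundaries.  A molecule without
#' rotatable torsions has the empty raw TABS.
#'
#' @param conformer a [Conformer-class].
#' @param bits a [TorsionBits-class] built from the same molecule, with
#'   patterns assigned.
#' @return integer vector (raw TABS).
#' @export
assignRawTabs <- function(conformer, bits) {
  stopifnot(is(conformer, "Conformer"), is(bits, "TorsionBits"))
  n <- nrow(bits@bonds)
  if (n && !length(bits@boundaries))
    stop("bits carry no bin boundaries; match patterns first", call. = FALSE)
  out <- integer(n)
  for (i in seq_len(n)) {
    ang <- measureDihedral(conformer, bits@quadruples[i, ])
    out[i] <- assignBin(ang, bits@boundaries[[i]], period = bits@period[i])
  }
  out
}

#' Assign the canonical TABS of a conformer
#'
#' The raw TABS canonicalized under the molecule's bit-permutation group:
#' conformers related by a topological symmetry of the molecule (e.g. a
#' different but equivalent atom numbering) receive the same TABS label.
#'
#' @param conformer a [Conformer-class].
#' @param system the molecule's [TabsSystem-class].
#' @param bits the molecule's [TorsionBits-class].
#' @return integer vector (canonical raw TABS).
#' @seealso [tabsSystemFromMolecule()] to build `system` and `bits`.
#' @export
assignTabs <- function(conformer, system, bits) {
  raw <- assignRawTabs(conformer, bits)
  raw <- .check_rawtabs(raw, system)
  canonicalTabs(raw, system@group)
}

#' Label every conformer of an ensemble with its TABS
#'
#' @param conformers list of [Conformer-class] objects of one molecule.
#' @param library a [TorsionLibrary-class].
#' @return data.frame with columns `conformer_id`, `rawTABS`, `TABS`
#'   (hyphen-serialized strings).
#' @export
labelEnsemble <- function(conformers, library = defaultTorsionLibrary()) {
  stopifnot(length(conformers) >= 1L)
  mol <- conformers[[1L]]@molecule
  parts <- tabsSystemFromMolecule(mol, library)
  raw <- vapply(conformers, function(cf) {
    formatTabs(assignRawTabs(cf, parts$bits))
  }, character(1))
  canon <- vapply(conformers, function(cf) {
    formatTabs(assignTabs(cf, parts$system, parts$bits))
  }, character(1))
  data.frame(conformer_id = vapply(conformers, function(cf) cf@id, character(1)),
             rawTABS = raw, TABS = canon, stringsAsFactors = FALSE)
}
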