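## A small SMILES reader.
##
## No cheminformatics package is available in this R stack, so the subset
## of SMILES needed for torsion counting is parsed here: organic-subset and
## bracket atoms, single/double/triple/aromatic bonds, branches, ring
## closures (including %nn), charges, explicit H counts and '.'-separated
## fragments.  Stereo markers (/ \ @ @@) and isotopes are accepted and
## ignored: the topological symmetry group is stereo-blind by design.

.ORGANIC_SUBSET <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")
.AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")
.DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1, H = 1)
# connections (not bond-order sum) an unsubstituted aromatic atom carries
.AROMATIC_CONNECTIONS <- c(b = 3, c = 3, n = 2, o = 2, p = 2, s = 2)

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles a single SMILES string.
#' @param name molecule identifier (defaults to the SMILES itself).
#' @return a [Molecule-class].
#' @examples
#' parseSmiles("CCCC")        # n-butane
#' parseSmiles("c1ccccc1")    # benzene
#' @export
parseSmiles <- function(smiles, name = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  chars <- strsplit(smiles, "")[[1L]]
  n <- length(chars)
  atoms <- list()
  bonds <- list()
  stack <- integer(0)      # open-branch atom stack
  prev <- NA_integer_      # last atom emitted at current level
  pending_bond <- NA       # bond symbol awaiting the next atom
  ring <- list()           # ring-closure bookkeeping: label -> (atom, bond)
  i <- 1L

  add_atom <- function(element, aromatic, charge, nH_explicit) {
    atoms[[length(atoms) + 1L]] <<- list(element = element,
                                         aromatic = aromatic,
                                         charge = charge,
                                         nH = nH_explicit)
    length(atoms)
  }
  add_bond <- function(a, b, sym) {
    if (identical(sym, ".")) return(invisible())
    aro_a <- atoms[[a]]$aromatic; aro_b <- atoms[[b]]$aromatic
    if (is.na(sym)) sym <- if (aro_a && aro_b) ":" else "-"
    if (sym %in% c("/", "\\")) sym <- "-"
    order <- switch(sym, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5,
                    stop("unsupported bond symbol '", sym, "'", call. = FALSE))
    bonds[[length(bonds) + 1L]] <<- list(from = min(a, b), to = max(a, b),
                                         order = order,
                                         aromatic = identical(sym, ":"))
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES", call. = FALSE)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- ch; i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pending_bond <- NA; i <- i + 1L
    } else if (grepl("[0-9%]", ch)) {
      if (ch == "%") {
        if (i + 2L > n) stop("truncated %nn ring closure", call. = FALSE)
        lab <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else {
        lab <- ch; i <- i + 1L
      }
      if (is.na(prev)) stop("ring closure before any atom", call. = FALSE)
      if (!is.null(ring[[lab]])) {
        op <- ring[[lab]]
        sym <- if (!is.na(pending_bond)) pending_bond else op$bond
        add_bond(op$atom, prev, sym)
        ring[[lab]] <- NULL
      } else {
        ring[[lab]] <- list(atom = prev, bond = pending_bond)
      }
      pending_bond <- NA
    } else if (ch == "[") {
      close <- i
      while (close <= n && chars[close] != "]") close <- close + 1L
      if (close > n) stop("unbalanced '[' in SMILES", call. = FALSE)
      body <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      at <- .parse_bracket_atom(body)
      idx <- add_atom(at$element, at$aromatic, at$charge, at$nH)
      if (!is.na(prev)) add_bond(prev, idx, pending_bond)
      prev <- idx; pending_bond <- NA
      i <- close + 1L
    } else {
      # organic-subset atom, possibly two letters (Cl, Br)
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% .ORGANIC_SUBSET) {
        sym <- two; i <- i + 2L
      } else if (ch %in% .ORGANIC_SUBSET || ch %in% .AROMATIC_ORGANIC) {
        sym <- ch; i <- i + 1L
      } else {
        stop("unexpected character '", ch, "' in SMILES", call. = FALSE)
      }
      aromatic <- sym %in% .AROMATIC_ORGANIC
      element <- if (aromatic) toupper(sym) else sym
      idx <- add_atom(element, aromatic, 0L, NA_integer_)
      if (!is.na(prev)) add_bond(prev, idx, pending_bond)
      prev <- idx; pending_bond <- NA
    }
  }
  if (length(ring)) stop("unclosed ring bond(s) in SMILES", call. = FALSE)
  if (length(stack)) stop("unbalanced '(' in SMILES", call. = FALSE)

  atom_df <- data.frame(
    element = vapply(atoms, `[[`, character(1), "element"),
    aromatic = vapply(atoms, `[[`, logical(1), "aromatic"),
    charge = vapply(atoms, function(a) as.integer(a$charge), integer(1)),
    nH = vapply(atoms, function(a) as.integer(a$nH), integer(1)),
    stringsAsFactors = FALSE)
  bond_df <- if (length(bonds)) data.frame(
    from = vapply(bonds, function(b) as.integer(b$from), integer(1)),
    to = vapply(bonds, function(b) as.integer(b$to), integer(1)),
    order = vapply(bonds, `[[`, numeric(1), "order"),
    aromatic = vapply(bonds, `[[`, logical(1), "aromatic")
  ) else data.frame(from = integer(0), to = integer(0), order = numeric(0),
                    aromatic = logical(0))
  newMolecule(atom_df, bond_df, name = name)
}

.parse_bracket_atom <- function(body) {
  # [isotope? symbol chirality? Hcount? charge?]
  rx <- "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?$"
  m <- regmatches(body, regexec(rx, body))[[1L]]
  if (!length(m)) stop("cannot parse bracket atom [", body, "]", call. = FALSE)
  sym <- m[3L]
  aromatic <- sym %in% .AROMATIC_ORGANIC
  element <- if (aromatic) toupper(sym) else sym
  hspec <- m[5L]
  nH <- if (!nzchar(hspec)) 0L
        else if (hspec == "H") 1L
        else as.integer(sub("^H", "", hspec))
  cspec <- m[6L]
  charge <- if (!nzchar(cspec)) 0L
            else if (grepl("^[+]+$", cspec)) nchar(cspec)
            else if (grepl("^[-]+$", cspec)) -nchar(cspec)
            else if (cspec == "+") 1L else if (cspec == "-") -1L
            else as.integer(cspec)
  list(element = element, aromatic = aromatic, charge = as.integer(charge),
       nH = as.integer(nH))
}

#' Construct a Molecule from atom and bond tables
#'
#' Fills in implicit hydrogen counts (where not given explicitly) from a
#' standard valence model and flags ring bonds (a bond is in a ring iff it
#' is not a bridge of the graph).
#'
#' @param atoms data.frame with columns `element`, `aromatic`, `charge`,
#'   `nH` (NA = derive from valence).
#' @param bonds data.frame with columns `from`, `to`, `order`, `aromatic`.
#' @param name molecule identifier.
#' @return a [Molecule-class].
#' @export
newMolecule <- function(atoms, bonds, name = "molecule") {
  stopifnot(nrow(atoms) > 0L)
  if (nrow(bonds)) {
    swap <- bonds$from > bonds$to
    tmp <- bonds$from[swap]; bonds$from[swap] <- bonds$to[swap]
    bonds$to[swap] <- tmp
    bonds$from <- as.integer(bonds$from); bonds$to <- as.integer(bonds$to)
  }
  # ring flags: non-bridge bonds lie on a cycle
  bonds$ring <- logical(nrow(bonds))
  if (nrow(bonds)) {
    g <- igraph::graph_from_edgelist(cbind(bonds$from, bonds$to),
                                     directed = FALSE)
    if (igraph::vcount(g) < nrow(atoms))
      g <- igraph::add_vertices(g, nrow(atoms) - igraph::vcount(g))
    br <- igraph::bridges(g)
    bridge_idx <- as.integer(br)
    bonds$ring <- !(seq_len(nrow(bonds)) %in% bridge_idx)
  }
  # implicit hydrogens where unspecified
  na_h <- which(is.na(atoms$nH))
  if (length(na_h)) {
    deg <- numeric(nrow(atoms)); osum <- numeric(nrow(atoms))
    for (k in seq_len(nrow(bonds))) {
      f <- bonds$from[k]; t <- bonds$to[k]
      deg[f] <- deg[f] + 1; deg[t] <- deg[t] + 1
      osum[f] <- osum[f] + bonds$order[k]; osum[t] <- osum[t] + bonds$order[k]
    }
    for (i in na_h) {
      el <- atoms$element[i]
      if (atoms$aromatic[i]) {
        conn <- .AROMATIC_CONNECTIONS[[tolower(el)]]
        atoms$nH[i] <- as.integer(max(0, conn - deg[i]))
      } else if (el %in% names(.DEFAULT_VALENCE)) {
        val <- .DEFAULT_VALENCE[[el]] + atoms$charge[i]
        atoms$nH[i] <- as.integer(max(0, round(val - osum[i])))
      } else {
        atoms$nH[i] <- 0L
      }
    }
  }
  new("Molecule", atoms = atoms, bonds = bonds, name = as.character(name))
}

#' Read molecules from a SMILES file
#'
#' One molecule per line: a SMILES string optionally followed by
#' whitespace and an identifier.
#'
#' @param path file path.
#' @return list of [Molecule-class] objects.
#' @export
readSmilesFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    parts <- strsplit(lines[k], "[ \t]+")[[1L]]
    nm <- if (length(parts) >= 2L) parts[2L] else paste0("mol", k)
    out[[k]] <- parseSmiles(parts[1L], name = nm)
  }
  out
}

setMethod("show", "Molecule", function(object) {
  cat("Molecule '", object@name, "': ", nrow(object@atoms), " heavy/explicit atoms, ",
      nrow(object@bonds), " bonds\n", sep = "")
})

setMethod("show", "Conformer", function(object) {
  cat("Conformer '", object@id, "' of '", object@molecule@name, "' (",
      nrow(object@coords), " atoms)\n", sep = "")
})
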