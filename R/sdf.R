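## SDF (MDL mol / SD file) reading, V2000 and basic V3000.
##
## Multi-record files are treated as conformer ensembles: every record
## yields a Conformer whose Molecule is rebuilt from its own connection
## table.  Aromatic bonds should be encoded as bond type 4; kekulized
## input is accepted but its alternating single/double bonds are then
## taken at face value by the symmetry perception.

#' Read an SDF file as a conformer ensemble
#'
#' @param path path to an SDF/MOL file (V2000 or V3000, uncompressed).
#' @return list of [Conformer-class] objects; conformer ids are the record
#'   titles (first line), made unique, or `conf<k>` when blank.
#' @export
readSdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  start <- 1L
  for (i in seq_along(lines)) {
    if (trimws(lines[i]) == "$$$$") {
      recs[[length(recs) + 1L]] <- lines[start:(i - 1L)]
      start <- i + 1L
    }
  }
  if (start <= length(lines) && any(nzchar(trimws(lines[start:length(lines)]))))
    recs[[length(recs) + 1L]] <- lines[start:length(lines)]
  if (!length(recs)) stop("no records found in ", path, call. = FALSE)
  out <- vector("list", length(recs))
  ids <- character(length(recs))
  for (k in seq_along(recs)) {
    parsed <- .parse_molblock(recs[[k]])
    id <- trimws(parsed$title)
    if (!nzchar(id)) id <- paste0("conf", k)
    ids[k] <- id
    out[[k]] <- new("Conformer", molecule = parsed$molecule,
                    coords = parsed$coords, id = id)
  }
  ids <- make.unique(ids)
  for (k in seq_along(out)) out[[k]]@id <- ids[k]
  out
}

.parse_molblock <- function(lines) {
  if (length(lines) < 4L) stop("truncated mol block", call. = FALSE)
  title <- lines[1L]
  counts <- lines[4L]
  if (grepl("V3000", counts)) {
    p <- .parse_v3000(lines)
  } else {
    p <- .parse_v2000(lines)
  }
  atoms <- data.frame(element = p$element, aromatic = logical(length(p$element)),
                      charge = p$charge, nH = rep(NA_integer_, length(p$element)),
                      stringsAsFactors = FALSE)
  bonds <- data.frame(from = p$from, to = p$to, order = p$order,
                      aromatic = p$order == 1.5)
  atoms$aromatic[unique(c(bonds$from[bonds$aromatic], bonds$to[bonds$aromatic]))] <- TRUE
  # explicit hydrogens carry no implicit ones
  atoms$nH[atoms$element == "H"] <- 0L
  mol <- newMolecule(atoms, bonds, name = trimws(title))
  list(title = title, molecule = mol,
       coords = cbind(p$x, p$y, p$z))
}

.parse_v2000 <- function(lines) {
  counts <- lines[4L]
  natoms <- as.integer(substr(counts, 1L, 3L))
  nbonds <- as.integer(substr(counts, 4L, 6L))
  if (is.na(natoms) || is.na(nbonds))
    stop("cannot parse V2000 counts line", call. = FALSE)
  at <- lines[4L + seq_len(natoms)]
  x <- as.numeric(substr(at, 1L, 10L))
  y <- as.numeric(substr(at, 11L, 20L))
  z <- as.numeric(substr(at, 21L, 30L))
  element <- trimws(substr(at, 31L, 34L))
  charge <- integer(natoms)
  from <- to <- integer(nbonds); order <- numeric(nbonds)
  if (nbonds) {
    bl <- lines[4L + natoms + seq_len(nbonds)]
    from <- as.integer(substr(bl, 1L, 3L))
    to <- as.integer(substr(bl, 4L, 6L))
    code <- as.integer(substr(bl, 7L, 9L))
    order <- ifelse(code == 4L, 1.5, as.numeric(code))
  }
  for (ln in lines[grepl("^M  CHG", lines)]) {
    f <- as.integer(strsplit(trimws(substr(ln, 7L, nchar(ln))), "[ ]+")[[1L]])
    cnt <- f[1L]
    for (j in seq_len(cnt)) charge[f[2L * j]] <- f[2L * j + 1L]
  }
  list(element = element, charge = charge, x = x, y = y, z = z,
       from = from, to = to, order = order)
}

.parse_v3000 <- function(lines) {
  v30 <- sub("^M  V30 ", "", lines[grepl("^M  V30 ", lines)])
  in_atoms <- FALSE; in_bonds <- FALSE
  element <- character(0); charge <- integer(0)
  x <- y <- z <- numeric(0)
  from <- to <- integer(0); order <- numeric(0)
  for (ln in v30) {
    if (grepl("^BEGIN ATOM", ln)) { in_atoms <- TRUE; next }
    if (grepl("^END ATOM", ln)) { in_atoms <- FALSE; next }
    if (grepl("^BEGIN BOND", ln)) { in_bonds <- TRUE; next }
    if (grepl("^END BOND", ln)) { in_bonds <- FALSE; next }
    f <- strsplit(trimws(ln), "[ ]+")[[1L]]
    if (in_atoms) {
      element <- c(element, f[2L])
      x <- c(x, as.numeric(f[3L])); y <- c(y, as.numeric(f[4L]))
      z <- c(z, as.numeric(f[5L]))
      chg <- regmatches(ln, regexec("CHG=(-?[0-9]+)", ln))[[1L]]
      charge <- c(charge, if (length(chg)) as.integer(chg[2L]) else 0L)
    } else if (in_bonds) {
      code <- as.numeric(f[2L])
      from <- c(from, as.integer(f[3L])); to <- c(to, as.integer(f[4L]))
      order <- c(order, if (code == 4) 1.5 else code)
    }
  }
  if (!length(element)) stop("no atoms found in V3000 block", call. = FALSE)
  list(element = element, charge = charge, x = x, y = y, z = z,
       from = from, to = to, order = order)
}

#' Write a conformer ensemble to an SDF file (V2000)
#'
#' Mainly used to round-trip fixtures in tests and examples.
#'
#' @param conformers list of [Conformer-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSdf <- function(conformers, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in conformers) {
    mol <- cf@molecule
    na <- nrow(mol@atoms); nb <- nrow(mol@bonds)
    writeLines(c(cf@id, "  tabscount", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb), con)
    for (i in seq_len(na)) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         cf@coords[i, 1], cf@coords[i, 2], cf@coords[i, 3],
                         mol@atoms$element[i]), con)
    }
    for (k in seq_len(nb)) {
      code <- if (mol@bonds$aromatic[k]) 4L else as.integer(mol@bonds$order[k])
      writeLines(sprintf("%3d%3d%3d  0", mol@bonds$from[k], mol@bonds$to[k],
                         code), con)
    }
    chg <- which(mol@atoms$charge != 0L)
    for (i in chg)
      writeLines(sprintf("M  CHG  1 %3d %3d", i, mol@atoms$charge[i]), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}
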