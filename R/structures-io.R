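#' @include AllClasses.R
NULL

# covalent radii (Angstrom) for distance-based bond perception
.COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                     P = 1.07, F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39,
                     Na = 1.66, Mg = 1.41, K = 2.03, Ca = 1.76, Fe = 1.32,
                     Zn = 1.22)
.COVALENT_DEFAULT <- 0.77

.SOLVENT_RESNAMES <- c("HOH", "WAT", "TIP3", "TIP3P", "SPC", "SOL")

#' Default solvent/counterion residue blocklist
#'
#' Residue names removed by [stripSolventIons()]: common water models plus
#' monatomic counterions. Configurable; the default mirrors the usual
#' MM/GBSA preparation step of stripping waters and neutralizing ions.
#'
#' @return character vector of residue names.
#' @export
defaultSolventBlocklist <- function()
  c(.SOLVENT_RESNAMES, "NA+", "NA", "CL-", "CL", "K+", "K", "MG", "MG2",
    "CA2", "ZN2", "ION")

.normElement <- function(x) {
  x <- gsub("[^A-Za-z]", "", x)
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, 2)))
}

# guess element from a PDB/PQR atom name; two-letter symbols only accepted
# when unambiguous (ion residues) to avoid CA(calcium)/CA(alpha-carbon) traps
.elementFromName <- function(atomName, resname) {
  nm <- gsub("[^A-Za-z]", "", atomName)
  two <- .normElement(substr(nm, 1, 2))
  ionish <- toupper(resname) %in% c("ION", "NA+", "CL-", "MG", "ZN", "CA2",
                                    "MG2", "ZN2", "K+") ||
    toupper(resname) == toupper(nm)
  if (nchar(nm) >= 2 && two %in% names(.COVALENT_RADII) && ionish) return(two)
  one <- toupper(substr(nm, 1, 1))
  if (one %in% c("H", "C", "N", "O", "S", "P", "F", "K", "I", "B")) return(one)
  .normElement(nm)
}

#' Perceive bonds from interatomic distances
#'
#' Two atoms are bonded when their distance is below `scale` times the sum
#' of their covalent radii. Used as a fallback for files lacking CONECT
#' records.
#'
#' @param structure a [ParameterizedStructure-class].
#' @param scale tolerance factor on the covalent-radius sum (default 1.3).
#' @param subset optional integer vector: perceive bonds only among these
#'   atoms (others keep their existing bonds).
#' @return two-column integer matrix of bonded index pairs (i < j).
#' @export
perceiveBonds <- function(structure, scale = 1.3, subset = NULL) {
  a <- structure@atoms
  idx <- if (is.null(subset)) seq_len(nrow(a)) else as.integer(subset)
  if (length(idx) < 2) return(matrix(integer(0), ncol = 2))
  xyz <- as.matrix(a[idx, c("x", "y", "z")])
  el <- a$element[idx]
  cov <- .COVALENT_RADII[el]
  cov[is.na(cov)] <- .COVALENT_DEFAULT
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(cov, cov, "+") * scale
  hit <- which(d < thr & upper.tri(d), arr.ind = TRUE)
  if (nrow(hit) == 0) return(matrix(integer(0), ncol = 2))
  cbind(idx[hit[, 1]], idx[hit[, 2]])
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records via \pkg{bio3d} and CONECT records directly.
#' Atoms of water residues (HOH/WAT/TIP3/...) are flagged as solvent.
#' Charges and Lennard-Jones parameters are left unset (charge 0, radius/LJ
#' `NA`) until [assignParameters()]. Atoms not covered by any CONECT record
#' get distance-perceived bonds ([perceiveBonds()]).
#'
#' @param path PDB file path.
#' @param name structure name (default: file base name).
#' @param role structure role, see [ParameterizedStructure-class].
#' @param perceive logical, run distance-based bond perception for atoms
#'   lacking CONECT coverage (default `TRUE`).
#' @return A [ParameterizedStructure-class].
#' @export
readPDB <- function(path, name = NULL, role = "complex", perceive = TRUE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  atomLines <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(atomLines)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed coordinate field in PDB line ", i, ": ", lines[i])
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  el <- .normElement(at$elesy)
  noEl <- is.na(el) | el == "" | el == "?"
  if (any(noEl))
    el[noEl] <- vapply(which(noEl), function(i)
      .elementFromName(at$elety[i], at$resid[i]), character(1))
  atoms <- .emptyAtoms(nrow(at))
  atoms$element <- el
  atoms$x <- at$x; atoms$y <- at$y; atoms$z <- at$z
  atoms$resname <- toupper(trimws(at$resid))
  atoms$isSolvent <- atoms$resname %in% .SOLVENT_RESNAMES
  serialMap <- stats::setNames(seq_len(nrow(at)), at$eleno)

  bonds <- matrix(integer(0), ncol = 2)
  conectLines <- lines[grepl("^CONECT", lines)]
  inConect <- integer(0)
  if (length(conectLines) > 0) {
    prs <- lapply(conectLines, function(ln) {
      f <- suppressWarnings(as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))),
                                                "\\s+")[[1]]))
      f <- f[!is.na(f)]
      if (length(f) < 2) return(NULL)
      cbind(f[1], f[-1])
    })
    prs <- do.call(rbind, prs)
    if (!is.null(prs) && nrow(prs) > 0) {
      i <- serialMap[as.character(prs[, 1])]
      j <- serialMap[as.character(prs[, 2])]
      ok <- !is.na(i) & !is.na(j) & i != j
      bonds <- unique(cbind(pmin(i[ok], j[ok]), pmax(i[ok], j[ok])))
      inConect <- unique(as.integer(bonds))
    }
  }
  st <- .newStructure(atoms, bonds, role = role,
                      name = if (is.null(name))
                        sub("\\.[^.]*$", "", basename(path)) else name)
  if (perceive) {
    uncovered <- setdiff(seq_len(nrow(atoms)), inConect)
    extra <- perceiveBonds(st, subset = uncovered)
    if (nrow(extra) > 0)
      st@bonds <- unique(rbind(st@bonds, extra))
  }
  validObject(st)
  st
}

#' Read a PQR file
#'
#' Accepts both the whitespace-separated and the fixed-column PQR dialects
#' (fields are whitespace-split, with or without a chain identifier).
#' Per-atom partial charges (e) and radii (Angstrom) are taken from the
#' file's last two fields.
#'
#' @param path PQR file path.
#' @param name structure name (default: file base name).
#' @param role structure role.
#' @param perceive logical, distance-based bond perception (default `TRUE`).
#' @return A [ParameterizedStructure-class] with charges and radii set.
#' @export
readPQR <- function(path, name = NULL, role = "complex", perceive = TRUE) {
  if (!file.exists(path)) stop("PQR file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(ATOM|HETATM)", lines)
  rows <- lapply(which(keep), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 10)
      stop("PQR line ", i, " lacks charge/radius columns: ", lines[i])
    # fields: rec serial name resname [chain] resnum x y z charge radius
    hasChain <- length(f) >= 11 && is.na(suppressWarnings(as.numeric(f[5])))
    off <- if (hasChain) 1L else 0L
    vals <- suppressWarnings(as.numeric(f[(6 + off):(10 + off)]))
    if (any(is.na(vals)))
      stop("malformed numeric field in PQR line ", i, ": ", lines[i])
    list(name = f[3], resname = toupper(f[4]), vals = vals)
  })
  if (length(rows) == 0) stop("no ATOM/HETATM records in PQR file: ", path)
  atoms <- .emptyAtoms(length(rows))
  atoms$element <- vapply(rows, function(r)
    .elementFromName(r$name, r$resname), character(1))
  v <- t(vapply(rows, function(r) r$vals, numeric(5)))
  atoms$x <- v[, 1]; atoms$y <- v[, 2]; atoms$z <- v[, 3]
  atoms$charge <- v[, 4]; atoms$radius <- v[, 5]
  atoms$resname <- vapply(rows, function(r) r$resname, character(1))
  atoms$isSolvent <- atoms$resname %in% .SOLVENT_RESNAMES
  st <- .newStructure(atoms, role = role,
                      name = if (is.null(name))
                        sub("\\.[^.]*$", "", basename(path)) else name)
  if (perceive) st@bonds <- perceiveBonds(st)
  validObject(st)
  st
}

#' Write a structure as a PDB file with CONECT records
#'
#' Coordinates are written at PDB's 3-decimal precision; [readPDB()]
#' round-trips the result (atom count, elements, bonds preserved).
#'
#' @param structure a [ParameterizedStructure-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(structure, path) {
  a <- structure@atoms
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  for (i in seq_len(nrow(a))) {
    el <- a$element[i]
    nm <- sprintf("%-4s", substr(paste0(el, i %% 100), 1, 4))
    resn <- if (nzchar(a$resname[i])) a$resname[i] else "UNK"
    writeLines(sprintf(
      "ATOM  %5d %4s %-4sA%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, nm, substr(resn, 1, 4), 1L, a$x[i], a$y[i], a$z[i], 1, 0,
      toupper(el)), con)
  }
  b <- structure@bonds
  if (nrow(b) > 0) {
    nb <- split(c(b[, 2], b[, 1]), c(b[, 1], b[, 2]))
    for (i in names(nb)) {
      part <- sort(unique(nb[[i]]))
      for (chunk in split(part, ceiling(seq_along(part) / 4)))
        writeLines(paste0("CONECT",
                          paste0(sprintf("%5d", c(as.integer(i), chunk)),
                                 collapse = "")), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a structure as a whitespace-delimited PQR file
#'
#' Emits per-atom charges (e) and intrinsic radii (Angstrom) at 1e-4
#' precision; [readPQR()] round-trips the result. Lennard-Jones parameters
#' are not part of the PQR format and must be re-assigned on read
#' ([assignParameters()]).
#'
#' @param structure a [ParameterizedStructure-class] with charges and radii.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePQR <- function(structure, path) {
  a <- structure@atoms
  if (any(is.na(a$radius)))
    stop("all atoms need radii before writing a PQR file")
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  for (i in seq_len(nrow(a))) {
    resn <- if (nzchar(a$resname[i])) a$resname[i] else "UNK"
    writeLines(sprintf("ATOM %6d %-4s %-4s %5d %10.4f %10.4f %10.4f %8.4f %8.4f",
                       i, substr(paste0(a$element[i], i %% 100), 1, 4),
                       substr(resn, 1, 4), 1L, a$x[i], a$y[i], a$z[i],
                       a$charge[i], a$radius[i]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Default per-element parameter table
#'
#' Element-keyed intrinsic radii (Angstrom, Bondi-like) and 12-6
#' Lennard-Jones parameters (rmin/2 in Angstrom, epsilon in kcal/mol,
#' Amber-like). Used by [assignParameters()] for structures read from bare
#' PDB files.
#'
#' @return data.frame with columns `element`, `charge`, `radius`,
#'   `ljRminHalf`, `ljEpsilon`.
#' @export
defaultParameterTable <- function() {
  data.frame(
    element    = c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I",
                   "Na", "Mg", "K", "Ca", "Zn"),
    charge     = 0,
    radius     = c(1.20, 1.70, 1.55, 1.50, 1.80, 1.80, 1.47, 1.75, 1.85,
                   1.98, 1.868, 1.45, 2.27, 1.98, 1.39),
    ljRminHalf = c(0.60, 1.908, 1.824, 1.6612, 2.00, 2.10, 1.75, 1.948,
                   2.22, 2.35, 1.868, 0.7926, 2.658, 1.7131, 1.10),
    ljEpsilon  = c(0.0157, 0.086, 0.17, 0.21, 0.25, 0.20, 0.061, 0.265,
                   0.32, 0.40, 0.00277, 0.8947, 0.000328, 0.4598, 0.0125),
    stringsAsFactors = FALSE)
}

# carbon-like fallback for elements missing from the parameter table
.FALLBACK_PARAMS <- c(radius = 1.70, ljRminHalf = 1.908, ljEpsilon = 0.086)

#' Assign per-atom parameters from an element-keyed table
#'
#' Fills unset (`NA`) radii and Lennard-Jones parameters by element lookup.
#' Already-set values are kept, so re-running with any table is a no-op on a
#' fully parameterized structure. Elements missing from the table receive a
#' carbon-like fallback (radius 1.70 A, rmin/2 1.908 A, epsilon 0.086
#' kcal/mol) with one warning naming the affected elements. Charges are only
#' overwritten when `setCharges = TRUE` (PQR charges are authoritative
#' otherwise).
#'
#' @param structure a [ParameterizedStructure-class].
#' @param table parameter data.frame as from [defaultParameterTable()].
#' @param setCharges logical; also set charges from the table.
#' @return the parameterized [ParameterizedStructure-class].
#' @export
assignParameters <- function(structure, table = defaultParameterTable(),
                             setCharges = FALSE) {
  if (is.null(table) || nrow(table) == 0)
    stop("parameter table is empty: configuration error")
  need <- c("element", "radius", "ljRminHalf", "ljEpsilon")
  if (!all(need %in% names(table)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  a <- structure@atoms
  m <- match(a$element, table$element)
  anyUnset <- is.na(a$radius) | is.na(a$ljRminHalf) | is.na(a$ljEpsilon)
  fallback <- is.na(m) & anyUnset
  for (col in c("radius", "ljRminHalf", "ljEpsilon")) {
    unset <- is.na(a[[col]])
    hit <- which(unset & !fallback)
    a[[col]][hit] <- table[[col]][m[hit]]
    a[[col]][unset & fallback] <- .FALLBACK_PARAMS[[col]]
  }
  if (setCharges && "charge" %in% names(table)) {
    ok <- !is.na(m)
    a$charge[ok] <- table$charge[m[ok]]
    a$charge[!ok] <- 0
  }
  if (any(fallback))
    warning(sum(fallback), " atom(s) with element(s) ",
            paste(unique(a$element[fallback]), collapse = ", "),
            " not in parameter table; carbon-like fallback applied")
  structure@atoms <- a
  validObject(structure)
  structure
}

#' Remove solvent and counterion atoms
#'
#' Drops atoms whose residue name is on the blocklist or which carry the
#' `isSolvent` flag; bonds are re-indexed. Idempotent. An empty result is
#' allowed (with a warning).
#'
#' @param structure a [ParameterizedStructure-class].
#' @param blocklist residue names to remove
#'   (default [defaultSolventBlocklist()]).
#' @return the stripped [ParameterizedStructure-class].
#' @export
stripSolventIons <- function(structure, blocklist = defaultSolventBlocklist()) {
  a <- structure@atoms
  drop <- a$isSolvent | a$resname %in% blocklist
  if (!any(drop)) return(structure)
  keep <- which(!drop)
  if (length(keep) == 0)
    warning("all atoms removed by solvent/ion stripping")
  structure@atoms <- a[keep, , drop = FALSE]
  rownames(structure@atoms) <- NULL
  structure@bonds <- .remapBonds(structure@bonds, keep)
  validObject(structure)
  structure
}

# keep bonds whose endpoints survive subsetting to `keep`, re-indexed
.remapBonds <- function(bonds, keep) {
  if (nrow(bonds) == 0) return(matrix(integer(0), ncol = 2))
  map <- integer(max(c(bonds, keep)))
  map[keep] <- seq_along(keep)
  ok <- bonds[, 1] %in% keep & bonds[, 2] %in% keep
  b <- bonds[ok, , drop = FALSE]
  matrix(as.integer(cbind(map[b[, 1]], map[b[, 2]])), ncol = 2)
}

# subset a structure to atom indices `keep` (order preserved)
.subsetStructure <- function(structure, keep, role, name) {
  st <- .newStructure(structure@atoms[keep, , drop = FALSE],
                      .remapBonds(structure@bonds, keep),
                      role = role, name = name)
  st
}

#' Split a complex into receptor and ligand
#'
#' The ligand is selected by residue name(s) or explicit 1-based atom
#' indices; the receptor is everything else. Both parts keep the exact
#' coordinates and parameters they have inside the complex
#' (single-conformation bound-state convention).
#'
#' @param complex a [ParameterizedStructure-class] with role `"complex"`.
#' @param ligandSelector character vector of residue names, or integer
#'   vector of atom indices.
#' @param ddgExp optional experimental binding free energy, kcal/mol.
#' @return A [LabeledComplex-class].
#' @export
splitComplex <- function(complex, ligandSelector, ddgExp = NA_real_) {
  a <- complex@atoms
  if (is.character(ligandSelector)) {
    lig <- which(a$resname %in% toupper(ligandSelector))
  } else {
    lig <- sort(unique(as.integer(ligandSelector)))
    if (length(lig) > 0 && (min(lig) < 1 || max(lig) > nrow(a)))
      stop("ligand atom indices out of range")
  }
  if (length(lig) == 0) stop("ligand selector matched no atoms")
  if (length(lig) == nrow(a)) stop("ligand selector matched all atoms")
  rec <- setdiff(seq_len(nrow(a)), lig)
  new("LabeledComplex",
      complexStructure = complex,
      receptor = .subsetStructure(complex, rec, "receptor",
                                  paste0(complex@name, ":receptor")),
      ligand = .subsetStructure(complex, lig, "ligand",
                                paste0(complex@name, ":ligand")),
      receptorIndices = as.integer(rec), ligandIndices = as.integer(lig),
      ddgExp = ddgExp, name = complex@name)
}

#' Read a label table
#'
#' CSV with columns `name` and `ddg_exp` (kcal/mol).
#'
#' @param path CSV path.
#' @return data.frame with columns `name`, `ddg_exp`.
#' @export
readLabels <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "ddg_exp") %in% names(tab)))
    stop("label table must have columns 'name' and 'ddg_exp'")
  tab[, c("name", "ddg_exp")]
}
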