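# PDB-format structure input/output and crystal-content arithmetic.
#
# The internal model is a flat atom table (one row per atom, bio3d-style)
# carrying author chain/residue numbering, plus an optional crystal cell.
# Author numbering is the only numbering exposed anywhere in the package.

#' @keywords internal
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "U", PYL = "O", UNK = "X"
)

#' Van der Waals radii by element (Angstrom)
#' @keywords internal
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
DEFAULT_VDW <- 1.7

new_structure <- function(id, atoms, cell = NULL) {
  structure(list(id = id, atoms = atoms, cell = cell), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  rk <- residue_table(x)
  cat(sprintf("<structure3d> %s: %d atoms, %d residues (%d polymer, %d hetero, %d water), chains: %s\n",
              x$id, nrow(x$atoms), nrow(rk),
              sum(rk$kind == "polymer"), sum(rk$kind == "hetero"),
              sum(rk$kind == "water"),
              paste(unique(x$atoms$chain), collapse = ",")))
  if (!is.null(x$cell))
    cat(sprintf("  cell: %.2f %.2f %.2f  %.1f %.1f %.1f  %s  Z=%d\n",
                x$cell$a, x$cell$b, x$cell$c, x$cell$alpha, x$cell$beta,
                x$cell$gamma, x$cell$spacegroup, x$cell$z))
  invisible(x)
}

res_key <- function(chain, resno, icode = "") {
  paste0(chain, ":", resno, ifelse(is.na(icode) | icode == " ", "", icode))
}

classify_residue <- function(record, resname) {
  ifelse(resname == "HOH", "water",
         ifelse(record == "ATOM" | resname %in% names(AA3TO1), "polymer", "hetero"))
}

#' One row per residue of a structure
#'
#' @param structure a `structure3d` object
#' @return data.frame with chain, resno, icode, resname, kind and key,
#'   in file order.
#' @export
residue_table <- function(structure) {
  at <- structure$atoms
  key <- res_key(at$chain, at$resno, at$icode)
  first <- !duplicated(key)
  data.frame(chain = at$chain[first], resno = at$resno[first],
             icode = at$icode[first], resname = at$resname[first],
             kind = at$kind[first], key = key[first],
             stringsAsFactors = FALSE)
}

infer_element <- function(name, record) {
  # atom-name columns: element is usually the first alphabetic character;
  # two-letter metals only occur as HETATM with the full name (e.g. "FE", "ZN")
  nm <- gsub("[^A-Za-z]", "", name)
  two <- toupper(substr(nm, 1, 2))
  el <- ifelse(record == "HETATM" & two %in% c("FE", "ZN", "MG", "CL", "BR", "SE", "NA", "MN", "CU"),
               two, toupper(substr(nm, 1, 1)))
  el
}

#' Read a PDB-format structure
#'
#' Parses ATOM/HETATM/CRYST1/MODEL records of a PDB-format file into the
#' package's atom-table model.  Alternate locations are collapsed per atom
#' according to `altloc_policy`; author chain/residue numbering is preserved
#' untouched.  Residues are classified as `water` (HOH), `polymer` (ATOM
#' records or standard amino acids) or `hetero`.
#'
#' @param source path to a PDB file, or PDB text (a string containing
#'   newlines).
#' @param altloc_policy `"highest-occupancy"` (default; ties broken by file
#'   order) or `"first"`.
#' @param model_index which MODEL to read from a multi-model file (default 1).
#' @param id identifier stored on the returned object (defaults to the file
#'   name).
#' @return a `structure3d` object: list with `id`, `atoms` (data.frame with
#'   record, chain, resno, icode, resname, kind, atom, altloc, x, y, z, occ,
#'   b, element) and `cell` (NULL or list a, b, c, alpha, beta, gamma,
#'   spacegroup, z).
#' @export
read_structure <- function(source, altloc_policy = c("highest-occupancy", "first"),
                           model_index = 1L, id = NULL) {
  altloc_policy <- match.arg(altloc_policy)
  if (length(source) == 1 && grepl("\n", source, fixed = TRUE)) {
    lines <- strsplit(source, "\n", fixed = TRUE)[[1]]
    if (is.null(id)) id <- "structure"
  } else {
    if (!file.exists(source)) stop("no such file: ", source)
    lines <- readLines(source, warn = FALSE)
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(source))
  }
  rec <- substr(lines, 1, 6)

  cell <- NULL
  ic <- which(trimws(rec) == "CRYST1")
  if (length(ic) > 0) {
    cl <- sprintf("%-80s", lines[ic[1]])
    num <- function(a, b) suppressWarnings(as.numeric(substr(cl, a, b)))
    cell <- list(a = num(7, 15), b = num(16, 24), c = num(25, 33),
                 alpha = num(34, 40), beta = num(41, 47), gamma = num(48, 54),
                 spacegroup = trimws(substr(cl, 56, 66)),
                 z = suppressWarnings(as.integer(substr(cl, 67, 70))))
    if (any(is.na(unlist(cell[1:6]))))
      stop("malformed CRYST1 record at line ", ic[1])
    if (any(unlist(cell[c("a", "b", "c")]) <= 0) ||
        any(unlist(cell[c("alpha", "beta", "gamma")]) <= 0) ||
        any(unlist(cell[c("alpha", "beta", "gamma")]) >= 180))
      stop("invalid cell dimensions in CRYST1 at line ", ic[1])
  }

  # MODEL handling: restrict to the requested model when MODEL records exist
  model_starts <- which(trimws(rec) == "MODEL")
  keep <- rep(TRUE, length(lines))
  if (length(model_starts) > 0) {
    if (model_index > length(model_starts))
      stop("model ", model_index, " not present (file has ",
           length(model_starts), " models)")
    model_ends <- which(trimws(rec) == "ENDMDL")
    s <- model_starts[model_index]
    e <- model_ends[model_ends > s][1]
    if (is.na(e)) e <- length(lines)
    keep <- seq_along(lines) >= s & seq_along(lines) <= e
  } else if (model_index != 1L) {
    stop("model ", model_index, " not present (single-model file)")
  }

  sel <- which((rec == "ATOM  " | rec == "HETATM") & keep)
  if (length(sel) == 0) stop("no ATOM/HETATM records found")
  al <- sprintf("%-80s", lines[sel])

  numcol <- function(a, b, what, required = TRUE) {
    txt <- trimws(substr(al, a, b))
    v <- suppressWarnings(as.numeric(txt))
    bad <- is.na(v) & (required | txt != "")
    if (any(bad))
      stop("malformed ", what, " field in PDB record at line ", sel[which(bad)[1]])
    v
  }
  x <- numcol(31, 38, "x")
  y <- numcol(39, 46, "y")
  z <- numcol(47, 54, "z")
  occ <- numcol(55, 60, "occupancy", required = FALSE)
  occ[is.na(occ)] <- 1
  b <- numcol(61, 66, "B-factor", required = FALSE)
  b[is.na(b)] <- 0
  resno <- suppressWarnings(as.integer(trimws(substr(al, 23, 26))))
  if (any(is.na(resno)))
    stop("malformed residue number in PDB record at line ", sel[which(is.na(resno))[1]])
  if (any(occ < 0 | occ > 1))
    stop("occupancy outside [0,1] at line ", sel[which(occ < 0 | occ > 1)[1]])

  record <- trimws(substr(al, 1, 6))
  name <- trimws(substr(al, 13, 16))
  altloc <- substr(al, 17, 17)
  altloc[altloc == " "] <- ""
  resname <- trimws(substr(al, 18, 20))
  chain <- substr(al, 22, 22)
  icode <- substr(al, 27, 27)
  icode[icode == " "] <- ""
  element <- toupper(trimws(substr(al, 77, 78)))
  miss <- element == ""
  element[miss] <- infer_element(name[miss], record[miss])

  atoms <- data.frame(record = record, chain = chain, resno = resno,
                      icode = icode, resname = resname,
                      kind = classify_residue(record, resname),
                      atom = name, altloc = altloc, x = x, y = y, z = z,
                      occ = occ, b = b, element = element,
                      stringsAsFactors = FALSE)

  # collapse alternate locations per (residue, atom name)
  akey <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$atom, sep = "\r")
  if (anyDuplicated(akey)) {
    ord <- if (altloc_policy == "highest-occupancy") {
      order(akey, -atoms$occ, seq_len(nrow(atoms)))
    } else {
      order(akey, seq_len(nrow(atoms)))
    }
    keep_rows <- sort(ord[!duplicated(akey[ord])])
    atoms <- atoms[keep_rows, , drop = FALSE]
  }
  rownames(atoms) <- NULL
  new_structure(id = id, atoms = atoms, cell = cell)
}

fmt_atom_name <- function(name, element) {
  # PDB convention: element symbol occupies columns 13-14
  ifelse(nchar(name) < 4 & nchar(element) == 1,
         sprintf("%-4s", paste0(" ", name)), sprintf("%-4s", name))
}

#' Write a structure in PDB format
#'
#' @param structure a `structure3d`
#' @param path optional output file; when NULL the PDB text is returned.
#' @param bfactor_override optional named numeric vector of per-residue
#'   B-factor values keyed by residue key (`"chain:resno"`, see
#'   [residue_table()]); used e.g. to colour a structure by conservation.
#' @return PDB text, invisibly when `path` is given.
#' @export
write_structure <- function(structure, path = NULL, bfactor_override = NULL) {
  at <- structure$atoms
  if (any(at$resno > 9999 | at$resno < -999))
    stop("residue number outside PDB column width")
  b <- at$b
  if (!is.null(bfactor_override)) {
    key <- res_key(at$chain, at$resno, at$icode)
    hit <- match(key, names(bfactor_override))
    b[!is.na(hit)] <- unname(bfactor_override[hit[!is.na(hit)]])
  }
  out <- character(0)
  if (!is.null(structure$cell)) {
    cl <- structure$cell
    out <- c(out, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                          cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma,
                          cl$spacegroup, if (is.null(cl$z) || is.na(cl$z)) 1L else cl$z))
  }
  lines <- sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   at$record, seq_len(nrow(at)) %% 100000,
                   fmt_atom_name(at$atom, at$element), at$altloc, at$resname,
                   at$chain, at$resno, ifelse(at$icode == "", " ", at$icode),
                   at$x, at$y, at$z, at$occ, b,
                   sprintf("%2s", at$element))
  out <- c(out, lines, "END")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(txt))
  }
  txt
}

#' Extract the polymer sequence of a chain
#'
#' Returns the one-letter sequence of the polymer residues of a chain in file
#' order, together with the parallel list of author residue numbers.
#' Selenomethionine (MSE) maps to M; unknown three-letter codes map to X.
#'
#' @param structure a `structure3d`
#' @param chain chain identifier
#' @return list with `sequence` (single string) and `numbers` (integer
#'   vector, parallel to the sequence).
#' @export
extract_sequence <- function(structure, chain) {
  rt <- residue_table(structure)
  if (!chain %in% rt$chain) stop("chain '", chain, "' not present")
  rt <- rt[rt$chain == chain & rt$kind == "polymer", , drop = FALSE]
  aa <- AA3TO1[rt$resname]
  aa[is.na(aa)] <- "X"
  list(sequence = paste(aa, collapse = ""), numbers = rt$resno)
}

cell_volume <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  cell$a * cell$b * cell$c * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
}

#' Matthews coefficient and solvent content
#'
#' Computes the Matthews coefficient Vm = V_cell / (Z * n_mol * MW) (cubic
#' Angstrom per Dalton) and the derived solvent fraction
#' 1 - 1.23 / Vm, the standard crystal-content estimate (1.23 being the
#' reciprocal protein partial specific volume in the same units).  A
#' pre-computed `vm` may be supplied instead of a cell.
#'
#' @param cell crystal cell as returned by [read_structure()] (fields a, b,
#'   c, alpha, beta, gamma, z = symmetry copies per cell); ignored when `vm`
#'   is given.
#' @param molecular_weight protein mass per molecule in Dalton.
#' @param n_mol_per_asu molecules per asymmetric unit.
#' @param vm optional Matthews coefficient supplied directly.
#' @return list with `vm` and `solvent_fraction` (clipped at 0, with a
#'   warning, when Vm <= 1.23).
#' @export
matthews_solvent <- function(cell = NULL, molecular_weight = NULL,
                             n_mol_per_asu = 1L, vm = NULL) {
  if (is.null(vm)) {
    if (is.null(cell) || is.null(molecular_weight))
      stop("either vm, or cell plus molecular_weight, must be given")
    if (molecular_weight <= 0) stop("molecular weight must be positive")
    z_total <- cell$z * n_mol_per_asu
    if (is.null(z_total) || is.na(z_total) || z_total <= 0)
      stop("cell must carry a positive symmetry copy number z")
    vm <- cell_volume(cell) / (z_total * molecular_weight)
  }
  solvent <- 1 - 1.23 / vm
  if (solvent <= 0) {
    if (vm < 1.23) warning("Vm below 1.23 A^3/Da: solvent fraction clipped to 0")
    solvent <- 0
  }
  list(vm = vm, solvent_fraction = solvent)
}
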