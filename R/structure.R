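#' @title All-atom structure model
#' @description S3 class `tcr_structure`: an atom table plus optional
#'   crystallographic metadata. Atoms are stored as a data frame with one row
#'   per atom, ordered by chain, then residue number and insertion code, then
#'   file order. Coordinates are in Angstrom.
#' @name structure_model
NULL

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Construct a structure object from an atom table
#'
#' @param atoms data frame with columns `serial`, `name`, `element`,
#'   `alt_loc`, `chain_id`, `res_name`, `res_seq`, `insertion_code`,
#'   `x`, `y`, `z`, `occupancy`, `b_factor`.
#' @param id label for the structure.
#' @param cell named numeric vector `c(a, b, c, alpha, beta, gamma)`
#'   (Angstrom / degrees) or `NULL`.
#' @param space_group Hermann-Mauguin symbol or `NULL`.
#' @return An object of class `tcr_structure`.
#' @export
new_structure <- function(atoms, id = "structure", cell = NULL, space_group = NULL) {
  required <- c("serial", "name", "element", "alt_loc", "chain_id", "res_name",
                "res_seq", "insertion_code", "x", "y", "z", "occupancy", "b_factor")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("empty structure: no atoms")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table")
  }
  if (any(atoms$element == "")) stop("atoms with empty element symbol")
  key <- paste(atoms$chain_id, atoms$res_seq, atoms$insertion_code,
               atoms$name, atoms$alt_loc)
  if (anyDuplicated(key)) {
    stop("duplicate atom identity (chain, res_seq, insertion_code, name, alt_loc)")
  }
  # canonical ordering: chain (file order), residue number, insertion code
  chain_order <- match(atoms$chain_id, unique(atoms$chain_id))
  atoms <- atoms[order(chain_order, atoms$res_seq, atoms$insertion_code), ,
                 drop = FALSE]
  rownames(atoms) <- NULL
  if (!is.null(cell)) {
    cell <- as.numeric(cell)
    if (length(cell) != 6 || any(!is.finite(cell)) || any(cell[1:3] <= 0)) {
      stop("cell must be six finite numbers (a, b, c, alpha, beta, gamma)")
    }
    names(cell) <- c("a", "b", "c", "alpha", "beta", "gamma")
  }
  structure(list(id = id, atoms = atoms, cell = cell, space_group = space_group),
            class = "tcr_structure")
}

#' @export
print.tcr_structure <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain_id", "res_seq", "insertion_code")]))
  cat(sprintf("<tcr_structure '%s': %d atoms, %d residues, chains %s>\n",
              x$id, nrow(x$atoms), nres,
              paste(unique(x$atoms$chain_id), collapse = ",")))
  if (!is.null(x$cell)) {
    cat(sprintf("  cell %.1f %.1f %.1f  %.1f %.1f %.1f  [%s]\n",
                x$cell[1], x$cell[2], x$cell[3], x$cell[4], x$cell[5], x$cell[6],
                if (is.null(x$space_group)) "?" else x$space_group))
  }
  invisible(x)
}

#' Read a PDB-format file
#'
#' Parses ATOM/HETATM fixed-column records plus the CRYST1 header. Policy
#' choices: hydrogens are dropped (deposited X-ray models here are heavy-atom
#' and the constraint network treats donors implicitly); for alternate
#' locations only the highest-occupancy conformer of each atom is kept (ties
#' broken by first occurrence). Residue numbering is taken verbatim.
#'
#' @param path file path.
#' @param id structure label; defaults to the file base name.
#' @param keep_hydrogens keep element-H atoms (default `FALSE`).
#' @return A [new_structure()] object.
#' @export
read_pdb <- function(path, id = NULL, keep_hydrogens = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  cell <- NULL
  space_group <- NULL
  ic <- which(rec == "CRYST1")
  if (length(ic) >= 1) {
    cl <- lines[ic[1]]
    cell <- suppressWarnings(as.numeric(c(
      substr(cl, 7, 15), substr(cl, 16, 24), substr(cl, 25, 33),
      substr(cl, 34, 40), substr(cl, 41, 47), substr(cl, 48, 54)
    )))
    if (any(is.na(cell))) {
      stop("unparsable CRYST1 record at line ", ic[1])
    }
    sg <- trimws(substr(cl, 56, 66))
    if (nzchar(sg)) space_group <- sg
    # a placeholder 1x1x1 P1 cell means "no crystal information"
    if (all(cell[1:3] == 1)) {
      cell <- NULL
      space_group <- NULL
    }
  }
  # only the first MODEL of a multi-model file is read
  im <- which(rec == "ENDMDL")
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(im) >= 1) idx <- idx[idx < im[1]]
  if (length(idx) == 0) stop("empty structure: no ATOM records in ", path)
  ln <- lines[idx]
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & nzchar(trimws(s)))
    blank <- which(!nzchar(trimws(s)))
    v[blank] <- NA_real_
    if (length(bad) > 0) {
      stop(sprintf("unparsable %s field at line %d", what, idx[bad[1]]))
    }
    v
  }
  x <- num(substr(ln, 31, 38), "x-coordinate")
  y <- num(substr(ln, 39, 46), "y-coordinate")
  z <- num(substr(ln, 47, 54), "z-coordinate")
  if (any(is.na(x) | is.na(y) | is.na(z))) {
    stop(sprintf("unparsable coordinate field at line %d",
                 idx[which(is.na(x) | is.na(y) | is.na(z))[1]]))
  }
  occ <- num(substr(ln, 55, 60), "occupancy")
  occ[is.na(occ)] <- 1
  bf <- num(substr(ln, 61, 66), "b-factor")
  bf[is.na(bf)] <- 0
  name <- trimws(substr(ln, 13, 16))
  element <- trimws(substr(ln, 77, 78))
  # fall back on the first letter of the atom name when the element column
  # is absent (common in minimal files)
  noel <- !nzchar(element)
  element[noel] <- sub("^[0-9]*", "", name[noel])
  element[noel] <- toupper(substr(element[noel], 1, 1))
  atoms <- data.frame(
    serial = num(substr(ln, 7, 11), "serial"),
    name = name,
    element = toupper(element),
    alt_loc = trimws(substr(ln, 17, 17)),
    chain_id = substr(ln, 22, 22),
    res_name = trimws(substr(ln, 18, 20)),
    res_seq = num(substr(ln, 23, 26), "residue number"),
    insertion_code = trimws(substr(ln, 27, 27)),
    x = x, y = y, z = z, occupancy = occ, b_factor = bf,
    stringsAsFactors = FALSE
  )
  if (!keep_hydrogens) {
    atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  }
  if (nrow(atoms) == 0) stop("empty structure: only hydrogen atoms in ", path)
  # alternate locations: keep highest-occupancy conformer, ties -> first seen
  key <- paste(atoms$chain_id, atoms$res_seq, atoms$insertion_code, atoms$name)
  if (anyDuplicated(key)) {
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
      i[which.max(atoms$occupancy[i])]
    }), use.names = FALSE)
    atoms <- atoms[sort(keep), , drop = FALSE]
  }
  atoms$alt_loc <- ""
  new_structure(atoms, id = id, cell = cell, space_group = space_group)
}

#' Write a structure as a PDB-format file
#'
#' Emits standard fixed-column ATOM/HETATM records (HETATM for non-standard
#' residues), a CRYST1 record when cell metadata is present, and TER records
#' at chain ends. When `multi_model` is given, each coordinate set is written
#' as a MODEL/ENDMDL block over the same atom list, producing a conformer
#' ensemble readable by standard viewers.
#'
#' @param structure a `tcr_structure`.
#' @param path output file path.
#' @param multi_model optional list of N x 3 coordinate matrices (one per
#'   conformer, rows in atom-table order).
#' @export
write_pdb <- function(structure, path, multi_model = NULL) {
  stopifnot(inherits(structure, "tcr_structure"))
  at <- structure$atoms
  fmt_atom <- function(i, xyz, serial) {
    if (any(abs(xyz) >= 10000)) {
      stop("coordinate magnitude exceeds PDB field width (|coord| >= 10000)")
    }
    nm <- at$name[i]
    # single-letter elements with short names are indented one column
    nm_fmt <- if (nchar(nm) < 4 && nchar(at$element[i]) == 1) {
      sprintf(" %-3s", nm)
    } else {
      sprintf("%-4s", nm)
    }
    recname <- if (at$res_name[i] %in% c(STANDARD_AA, WATER_NAMES)) "ATOM  " else "HETATM"
    sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            recname, serial %% 100000, nm_fmt, at$alt_loc[i], at$res_name[i],
            at$chain_id[i], at$res_seq[i], at$insertion_code[i],
            xyz[1], xyz[2], xyz[3], at$occupancy[i], at$b_factor[i],
            at$element[i])
  }
  block <- function(coords) {
    out <- character(0)
    serial <- 0L
    chains <- unique(at$chain_id)
    for (ch in chains) {
      ii <- which(at$chain_id == ch)
      for (i in ii) {
        serial <- serial + 1L
        out <- c(out, fmt_atom(i, coords[i, ], serial))
      }
      serial <- serial + 1L
      last <- ii[length(ii)]
      out <- c(out, sprintf("TER   %5d      %-3s %1s%4d%1s", serial %% 100000,
                            at$res_name[last], ch, at$res_seq[last],
                            at$insertion_code[last]))
    }
    out
  }
  lines <- character(0)
  if (!is.null(structure$cell)) {
    sg <- if (is.null(structure$space_group)) "P 1" else structure$space_group
    lines <- c(lines, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
      structure$cell[1], structure$cell[2], structure$cell[3],
      structure$cell[4], structure$cell[5], structure$cell[6], sg, 1L))
  }
  if (is.null(multi_model)) {
    lines <- c(lines, block(as.matrix(at[, c("x", "y", "z")])), "END")
  } else {
    for (m in seq_along(multi_model)) {
      coords <- multi_model[[m]]
      if (!is.matrix(coords) || nrow(coords) != nrow(at) || ncol(coords) != 3) {
        stop("multi_model entry ", m, " is not an n_atoms x 3 matrix")
      }
      lines <- c(lines, sprintf("MODEL     %4d", m), block(coords), "ENDMDL")
    }
    lines <- c(lines, "END")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Extract Calpha coordinates for a chain
#'
#' @param structure a `tcr_structure`.
#' @param chain_id chain identifier.
#' @param range optional inclusive residue-number interval `c(start, end)`.
#' @return Data frame `(res_seq, x, y, z)`, one row per residue that has a CA
#'   atom, in residue order. Residues lacking a CA are skipped; their numbers
#'   are recorded in the `"skipped"` attribute (and reported as a warning).
#' @export
extract_calpha <- function(structure, chain_id, range = NULL) {
  stopifnot(inherits(structure, "tcr_structure"))
  at <- structure$atoms
  if (!(chain_id %in% at$chain_id)) stop("unknown chain: ", chain_id)
  sel <- at$chain_id == chain_id & !(at$res_name %in% WATER_NAMES)
  if (!is.null(range)) {
    stopifnot(length(range) == 2)
    sel <- sel & at$res_seq >= range[1] & at$res_seq <= range[2]
  }
  sub <- at[sel, , drop = FALSE]
  resk <- paste(sub$res_seq, sub$insertion_code)
  res_order <- unique(resk)
  ca <- sub[sub$name == "CA", , drop = FALSE]
  skipped <- setdiff(res_order, paste(ca$res_seq, ca$insertion_code))
  if (length(skipped) > 0) {
    warning("residues lacking CA skipped in chain ", chain_id, ": ",
            paste(skipped, collapse = ", "))
  }
  ca <- ca[match(intersect(res_order, paste(ca$res_seq, ca$insertion_code)),
                 paste(ca$res_seq, ca$insertion_code)), , drop = FALSE]
  out <- data.frame(res_seq = ca$res_seq, x = ca$x, y = ca$y, z = ca$z)
  attr(out, "skipped") <- skipped
  out
}

#' Keep protein atoms only
#'
#' Drops waters and non-protein HETATM residues; every downstream stage
#' (networks, rigidity, modes, simulation) operates on the protein chains.
#'
#' @param structure a `tcr_structure`.
#' @return Filtered `tcr_structure`.
#' @export
filter_protein <- function(structure) {
  at <- structure$atoms
  keep <- at$res_name %in% STANDARD_AA
  if (!any(keep)) stop("no standard protein residues in structure ", structure$id)
  new_structure(at[keep, , drop = FALSE], id = structure$id,
                cell = structure$cell, space_group = structure$space_group)
}

#' Read a loop-definition table
#'
#' Tab-separated with columns `loop_name`, `chain_id`, `start`, `end`
#' (inclusive bounds, author residue numbering).
#'
#' @param path TSV file path.
#' @return Data frame of loop definitions.
#' @export
read_loop_definitions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("loop_name", "chain_id", "start", "end")
  if (!all(required %in% names(df))) {
    stop("loop table must have columns: ", paste(required, collapse = ", "))
  }
  validate_loops(df)
  df
}

validate_loops <- function(loops, structure = NULL) {
  if (any(loops$end < loops$start)) stop("empty loop range in loop table")
  if (!is.null(structure)) {
    at <- structure$atoms
    for (i in seq_len(nrow(loops))) {
      rr <- at$res_seq[at$chain_id == loops$chain_id[i]]
      if (!any(rr >= loops$start[i] & rr <= loops$end[i])) {
        stop("loop ", loops$loop_name[i], " has no residues in chain ",
             loops$chain_id[i])
      }
    }
  }
  invisible(loops)
}

#' @keywords internal
coords_matrix <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param structure a `tcr_structure`.
#' @param coords n_atoms x 3 matrix in atom-table order.
#' @return The structure with new coordinates.
#' @export
set_coords <- function(structure, coords) {
  stopifnot(nrow(coords) == nrow(structure$atoms), ncol(coords) == 3)
  structure$atoms$x <- coords[, 1]
  structure$atoms$y <- coords[, 2]
  structure$atoms$z <- coords[, 3]
  structure
}
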