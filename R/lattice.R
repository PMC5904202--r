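#' @title Crystal lattice contacts
#' @description Symmetry expansion of the asymmetric unit and detection of
#'   lattice contacts, defined as intermolecular distances strictly below
#'   4.0 Angstrom between the asymmetric unit and any symmetry/lattice image.
#' @name lattice
NULL

# fractional -> Cartesian orthogonalisation matrix (PDB convention: a along x)
orth_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c_ <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 + 2 * cos(al) * cos(be) * cos(ga))
  matrix(c(
    a, b * cos(ga), c_ * cos(be),
    0, b * sin(ga), c_ * (cos(al) - cos(be) * cos(ga)) / sin(ga),
    0, 0, c_ * v / sin(ga)
  ), nrow = 3, byrow = TRUE)
}

#' Parse a symmetry-operator triplet
#'
#' Accepts the conventional `"x,y,z"` notation, e.g. `"1/2-x,1/2+y,-z"`.
#'
#' @param triplet character string with three comma-separated terms.
#' @return List with `R` (3 x 3 fractional rotation) and `t` (length-3
#'   fractional translation).
#' @export
parse_operator <- function(triplet) {
  parts <- strsplit(gsub("[[:space:]]", "", tolower(triplet)), ",")[[1]]
  if (length(parts) != 3) stop("operator triplet must have 3 components: ", triplet)
  R <- matrix(0, 3, 3)
  t_vec <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # split into signed terms
    terms <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (tm in terms) {
      sign <- if (substr(tm, 1, 1) == "-") -1 else 1
      body <- sub("^[+-]", "", tm)
      if (body %in% c("x", "y", "z")) {
        R[i, match(body, c("x", "y", "z"))] <- sign
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        f <- as.numeric(strsplit(body, "/")[[1]])
        t_vec[i] <- t_vec[i] + sign * f[1] / f[2]
      } else if (grepl("^[0-9.]+$", body)) {
        t_vec[i] <- t_vec[i] + sign * as.numeric(body)
      } else {
        stop("cannot parse operator term '", tm, "' in ", triplet)
      }
    }
  }
  list(R = R, t = t_vec)
}

# the space groups occurring in this analysis; anything else must be given
# as explicit operator triplets
BUILTIN_SPACE_GROUPS <- list(
  "P 1" = c("x,y,z"),
  "P 21 21 2" = c("x,y,z", "-x,-y,z", "1/2-x,1/2+y,-z", "1/2+x,1/2-y,-z"),
  "P 1 21 1" = c("x,y,z", "-x,1/2+y,-z")
)

normalize_sg <- function(name) {
  n <- toupper(gsub("[[:space:]]+", " ", trimws(name)))
  if (n %in% c("P1", "P 1")) return("P 1")
  if (n %in% c("P 21 21 2", "P21 21 2", "P 21212", "P21212")) return("P 21 21 2")
  if (n %in% c("P 1 21 1", "P1 21 1", "P 21", "P21", "P121 1", "P 121 1")) return("P 1 21 1")
  n
}

#' Symmetry operators for a space group
#'
#' Built-in coverage is limited to the groups needed here (P 1, P 21 21 2,
#' P 1 21 1); for any other setting supply explicit triplets via
#' `read_operator_file()` or `parse_operator()`.
#'
#' @param space_group Hermann-Mauguin symbol.
#' @return List of operators (each a list with `R`, `t`).
#' @export
space_group_operators <- function(space_group) {
  key <- normalize_sg(space_group)
  if (!(key %in% names(BUILTIN_SPACE_GROUPS))) {
    stop("no built-in operators for space group '", space_group,
         "'; supply explicit operator triplets (see read_operator_file)")
  }
  lapply(BUILTIN_SPACE_GROUPS[[key]], parse_operator)
}

#' Read symmetry operators from a file
#'
#' One operator triplet per line, `#` comments allowed.
#' @param path file path.
#' @return List of operators.
#' @export
read_operator_file <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("no operators in ", path)
  lapply(lines, parse_operator)
}

is_identity_op <- function(op) {
  all(abs(op$R - diag(3)) < 1e-9) && all(abs(op$t) < 1e-9)
}

#' Generate symmetry/lattice images of a structure
#'
#' Applies every operator combined with every lattice translation in
#' `-translations..+translations` unit cells per axis, returning Cartesian
#' coordinate images. The identity operator with zero translation is tagged
#' `self`.
#'
#' @param structure a `tcr_structure` with cell metadata.
#' @param operators list of fractional-coordinate operators (must include the
#'   identity); defaults to the built-in set for the structure's space group.
#' @param translations integer range of lattice translations per axis
#'   (default 1, i.e. the 3x3x3 block of neighbouring cells).
#' @return List of images, each a list with `coords` (n x 3 Cartesian),
#'   `operator_index`, `translation` (integer 3-vector), and `self` flag.
#' @export
apply_symmetry <- function(structure, operators = NULL, translations = 1) {
  if (is.null(structure$cell)) stop("structure has no unit-cell metadata")
  if (is.null(operators)) {
    if (is.null(structure$space_group)) stop("structure has no space group")
    operators <- space_group_operators(structure$space_group)
  }
  if (!any(vapply(operators, is_identity_op, logical(1)))) {
    stop("operator list must include the identity")
  }
  M <- orth_matrix(structure$cell)
  Minv <- solve(M)
  xyz <- coords_matrix(structure)
  frac <- t(Minv %*% t(xyz))
  shifts <- seq(-translations, translations)
  images <- list()
  for (k in seq_along(operators)) {
    op <- operators[[k]]
    base <- t(op$R %*% t(frac)) + matrix(op$t, nrow(frac), 3, byrow = TRUE)
    for (nx in shifts) for (ny in shifts) for (nz in shifts) {
      fr <- base + matrix(c(nx, ny, nz), nrow(frac), 3, byrow = TRUE)
      images[[length(images) + 1]] <- list(
        coords = t(M %*% t(fr)),
        operator_index = k,
        translation = c(nx, ny, nz),
        self = is_identity_op(op) && nx == 0 && ny == 0 && nz == 0
      )
    }
  }
  images
}

#' Find crystal lattice contacts
#'
#' A lattice contact is an atom pair with distance strictly below `cutoff`
#' (default 4.0 Angstrom) between the asymmetric unit and a non-self
#' symmetry/lattice image. Each physical contact is reported once.
#'
#' @param structure a `tcr_structure` with cell and space-group (or explicit
#'   `operators`).
#' @param operators optional list of operators (default: built-in table for
#'   the structure's space group).
#' @param cutoff contact distance in Angstrom, strict inequality (default 4.0).
#' @param translations lattice translation range per axis (default 1; a 4 A
#'   cutoff cannot span more than one cell for protein-sized cells).
#' @return Data frame of `contact_record`s: `atom_a`, `atom_b` (atom-table row
#'   indices), serials, chain/residue identities of both partners,
#'   `operator_index`, `lattice_translation`, `distance`.
#' @export
find_crystal_contacts <- function(structure, operators = NULL, cutoff = 4.0,
                                  translations = 1) {
  if (cutoff <= 0) stop("cutoff must be positive")
  images <- apply_symmetry(structure, operators, translations)
  xyz <- coords_matrix(structure)
  at <- structure$atoms
  rows <- list()
  for (img in images) {
    if (img$self) next
    # pairwise distances asymmetric unit vs image, vectorised
    d2 <- outer(rowSums(xyz^2), rowSums(img$coords^2), "+") -
      2 * xyz %*% t(img$coords)
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    d <- sqrt(pmax(d2[hit], 0))
    keep <- d < cutoff - 1e-9  # strict, robust to rounding at the boundary
    hit <- hit[keep, , drop = FALSE]
    d <- d[keep]
    if (nrow(hit) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      atom_a = hit[, 1], atom_b = hit[, 2],
      serial_a = at$serial[hit[, 1]], serial_b = at$serial[hit[, 2]],
      chain_a = at$chain_id[hit[, 1]], res_seq_a = at$res_seq[hit[, 1]],
      chain_b = at$chain_id[hit[, 2]], res_seq_b = at$res_seq[hit[, 2]],
      operator_index = img$operator_index,
      trans_x = img$translation[1], trans_y = img$translation[2],
      trans_z = img$translation[3],
      distance = d
    )
  }
  if (length(rows) == 0) {
    return(data.frame(atom_a = integer(0), atom_b = integer(0),
                      serial_a = integer(0), serial_b = integer(0),
                      chain_a = character(0), res_seq_a = integer(0),
                      chain_b = character(0), res_seq_b = integer(0),
                      operator_index = integer(0), trans_x = integer(0),
                      trans_y = integer(0), trans_z = integer(0),
                      distance = numeric(0)))
  }
  out <- do.call(rbind, rows)
  # deduplicate: the contact (a, image of b) and (b, inverse image of a) are
  # the same physical contact; canonicalise on the unordered atom pair plus
  # the distance
  key <- paste(pmin(out$atom_a, out$atom_b), pmax(out$atom_a, out$atom_b),
               round(out$distance, 4))
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$distance), , drop = FALSE]
}

#' Loop freedom from lattice contacts
#'
#' A loop is free iff no lattice contact involves any atom of any residue in
#' its range (on its chain), on either side of the contact.
#'
#' @param contacts data frame from [find_crystal_contacts()].
#' @param loops loop-definition data frame.
#' @return Data frame `(loop_name, chain_id, start, end, n_contacts, free)`.
#' @export
loop_contact_freedom <- function(contacts, loops) {
  res <- lapply(seq_len(nrow(loops)), function(i) {
    lp <- loops[i, ]
    rng <- seq(lp$start, lp$end)
    inv <- (contacts$chain_a == lp$chain_id & contacts$res_seq_a %in% rng) |
           (contacts$chain_b == lp$chain_id & contacts$res_seq_b %in% rng)
    data.frame(loop_name = lp$loop_name, chain_id = lp$chain_id,
               start = lp$start, end = lp$end,
               n_contacts = sum(inv), free = !any(inv))
  })
  do.call(rbind, res)
}
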