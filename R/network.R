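#' @title Constraint network
#' @description All-atom bonding-constraint network for rigidity analysis:
#'   covalent bonds from amino-acid templates, polar interactions (hydrogen
#'   bonds and salt bridges) scored 0 to -10 kcal/mol from heavy-atom
#'   geometry, and hydrophobic tethers between nonpolar atoms in van der
#'   Waals contact. The polar set entering the rigidity analysis is selected
#'   by the energy cutoff `e_cut` (default -3.0 kcal/mol).
#' @name constraint_network
NULL

# heavy-atom side-chain connectivity; "|" marks non-rotatable (locked) bonds:
# aromatic rings and the delocalised carboxylate / guanidinium / amide groups
AA_SIDECHAIN_BONDS <- list(
  ALA = character(0),
  ARG = c("CB-CG", "CG-CD", "CD-NE", "NE-CZ|", "CZ-NH1|", "CZ-NH2|"),
  ASN = c("CB-CG", "CG-OD1|", "CG-ND2|"),
  ASP = c("CB-CG", "CG-OD1|", "CG-OD2|"),
  CYS = c("CB-SG"),
  GLN = c("CB-CG", "CG-CD", "CD-OE1|", "CD-NE2|"),
  GLU = c("CB-CG", "CG-CD", "CD-OE1|", "CD-OE2|"),
  GLY = character(0),
  HIS = c("CB-CG", "CG-ND1|", "CG-CD2|", "ND1-CE1|", "CD2-NE2|", "CE1-NE2|"),
  ILE = c("CB-CG1", "CB-CG2", "CG1-CD1"),
  LEU = c("CB-CG", "CG-CD1", "CG-CD2"),
  LYS = c("CB-CG", "CG-CD", "CD-CE", "CE-NZ"),
  MET = c("CB-CG", "CG-SD", "SD-CE"),
  PHE = c("CB-CG", "CG-CD1|", "CG-CD2|", "CD1-CE1|", "CD2-CE2|", "CE1-CZ|", "CE2-CZ|"),
  PRO = c("CB-CG", "CG-CD", "CD-N"),
  SER = c("CB-OG"),
  THR = c("CB-OG1", "CB-CG2"),
  TRP = c("CB-CG", "CG-CD1|", "CG-CD2|", "CD1-NE1|", "NE1-CE2|", "CD2-CE2|",
          "CD2-CE3|", "CE2-CZ2|", "CE3-CZ3|", "CZ2-CH2|", "CZ3-CH2|"),
  TYR = c("CB-CG", "CG-CD1|", "CG-CD2|", "CD1-CE1|", "CD2-CE2|", "CE1-CZ|",
          "CE2-CZ|", "CZ-OH"),
  VAL = c("CB-CG1", "CB-CG2")
)

# polar-atom roles for heavy-atom hydrogen-bond detection. Donor antecedents
# are the covalent neighbours used to measure donor linearity.
HB_DONORS <- list(
  backbone = list(name = "N", antecedent = "CA", skip_res = "PRO"),
  ARG = list(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  ASN = list(ND2 = "CG"),
  GLN = list(NE2 = "CD"),
  HIS = list(ND1 = "CG", NE2 = "CE1"),
  LYS = list(NZ = "CE"),
  TRP = list(NE1 = "CD1"),
  SER = list(OG = "CB"),
  THR = list(OG1 = "CB"),
  TYR = list(OH = "CZ"),
  CYS = list(SG = "CB")
)

HB_ACCEPTORS <- list(
  backbone = c("O", "OXT"),
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1", GLU = c("OE1", "OE2"),
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"),
  MET = "SD", CYS = "SG"
)

CHARGED_DONORS <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
CHARGED_ACCEPTORS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

VDW_RADII <- c(C = 1.7, S = 1.8, N = 1.55, O = 1.52, P = 1.8)

#' Constraint-network parameters
#'
#' @param e_cut polar-interaction energy cutoff, kcal/mol (default -3.0; a
#'   hydrogen bond enters the network iff its energy is <= `e_cut`).
#' @param hbond_dist_cutoff donor-acceptor candidate distance cutoff in
#'   Angstrom (default 3.6, the edge of the scoring well).
#' @param tether_gap allowance added to the van der Waals sum for hydrophobic
#'   tethers, Angstrom (default 0.25).
#' @param vdw_radii named per-element radius table, Angstrom.
#' @return List of class `network_params`.
#' @export
network_params <- function(e_cut = -3.0, hbond_dist_cutoff = 3.6,
                           tether_gap = 0.25, vdw_radii = VDW_RADII) {
  if (e_cut > 0) stop("e_cut must be <= 0")
  structure(list(e_cut = e_cut, hbond_dist_cutoff = hbond_dist_cutoff,
                 tether_gap = tether_gap, vdw_radii = vdw_radii),
            class = "network_params")
}

vdw_radius <- function(element, params) {
  r <- params$vdw_radii[element]
  r[is.na(r)] <- 1.7
  unname(r)
}

atom_index <- function(structure) {
  at <- structure$atoms
  paste(at$chain_id, at$res_seq, at$insertion_code, at$name)
}

#' Infer covalent bonds from residue templates
#'
#' Intra-residue bonds come from standard amino-acid connectivity templates;
#' peptide bonds C(i)-N(i+1) are added when the distance is below 1.7
#' Angstrom, disulfides SG-SG below 2.3 Angstrom. Peptide bonds, carbonyls,
#' aromatic rings and carboxylate/guanidinium/amide groups are labelled
#' `covalent_locked` (non-rotatable); all other bonds `covalent_single`.
#'
#' @param structure a protein `tcr_structure`.
#' @return Data frame of edges: `i`, `j` (atom-table row indices), `kind`,
#'   `length` (Angstrom in the input structure).
#' @export
infer_covalent_bonds <- function(structure) {
  at <- structure$atoms
  unknown <- setdiff(unique(at$res_name), STANDARD_AA)
  if (length(unknown) > 0) {
    stop("no covalent template for residue(s): ", paste(unknown, collapse = ", "))
  }
  reskey <- paste(at$chain_id, at$res_seq, at$insertion_code)
  res_list <- split(seq_len(nrow(at)), factor(reskey, levels = unique(reskey)))
  edges_i <- integer(0); edges_j <- integer(0); locked <- logical(0)
  add <- function(i, j, lk) {
    edges_i <<- c(edges_i, i); edges_j <<- c(edges_j, j); locked <<- c(locked, lk)
  }
  find_atom <- function(rows, nm) rows[match(nm, at$name[rows])]
  # intra-residue
  for (rows in res_list) {
    rn <- at$res_name[rows[1]]
    bonds <- c("N-CA", "CA-C", "C-O|", "C-OXT|",
               if (rn != "GLY") "CA-CB", AA_SIDECHAIN_BONDS[[rn]])
    for (b in bonds) {
      lk <- grepl("\\|$", b)
      nm <- strsplit(sub("\\|$", "", b), "-")[[1]]
      i <- find_atom(rows, nm[1]); j <- find_atom(rows, nm[2])
      if (!is.na(i) && !is.na(j)) add(i, j, lk)
    }
  }
  xyz <- coords_matrix(structure)
  # peptide bonds between consecutive residues of the same chain
  for (k in seq_len(length(res_list) - 1)) {
    r1 <- res_list[[k]]; r2 <- res_list[[k + 1]]
    if (at$chain_id[r1[1]] != at$chain_id[r2[1]]) next
    ci <- find_atom(r1, "C"); ni <- find_atom(r2, "N")
    if (is.na(ci) || is.na(ni)) next
    d <- sqrt(sum((xyz[ci, ] - xyz[ni, ])^2))
    if (d < 1.7) {
      add(ci, ni, TRUE)  # peptide bond: planar, non-rotatable
    } else {
      warning("chain break between residues ",
              at$res_seq[r1[1]], " and ", at$res_seq[r2[1]],
              " of chain ", at$chain_id[r1[1]],
              sprintf(" (C-N distance %.2f A)", d))
    }
  }
  # disulfides
  sg <- which(at$name == "SG" & at$res_name == "CYS")
  if (length(sg) >= 2) {
    for (a in seq_len(length(sg) - 1)) for (b in seq(a + 1, length(sg))) {
      d <- sqrt(sum((xyz[sg[a], ] - xyz[sg[b], ])^2))
      if (d < 2.3) add(sg[a], sg[b], FALSE)
    }
  }
  if (length(edges_i) == 0) return(empty_edges())
  len <- sqrt(rowSums((xyz[edges_i, , drop = FALSE] - xyz[edges_j, , drop = FALSE])^2))
  data.frame(i = edges_i, j = edges_j,
             kind = ifelse(locked, "covalent_locked", "covalent_single"),
             energy = NA_real_, length = len, stringsAsFactors = FALSE)
}

# adjacency list and 1-2/1-3 exclusion from a covalent edge table
covalent_adjacency <- function(bonds, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

excluded_pairs_key <- function(adj) {
  n <- length(adj)
  keys <- character(0)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    if (length(nb) == 0) next
    # 1-2
    keys <- c(keys, paste(pmin(i, nb), pmax(i, nb)))
    # 1-3: neighbours of neighbours
    for (j in nb) {
      nb2 <- setdiff(adj[[j]], i)
      if (length(nb2) > 0) keys <- c(keys, paste(pmin(i, nb2), pmax(i, nb2)))
    }
  }
  unique(keys)
}

#' Score one hydrogen bond from heavy-atom geometry
#'
#' Energy = -10 * f_dist(d) * f_ang(theta), where d is the donor-acceptor
#' distance and theta the antecedent-donor-acceptor angle. `f_dist` is a
#' clamped parabolic well, value 1 at d0 = 2.9 Angstrom and 0 beyond
#' d0 + 0.6; `f_ang` = cos^2 of the deviation from linear donor geometry
#' (zero beyond 60 degrees). Salt bridges (charged donor and acceptor) use
#' d0 = 3.0 Angstrom and a 20% depth bonus capped at -10 kcal/mol, the floor
#' of the scoring range.
#'
#' @param donor,acceptor,donor_antecedent length-3 coordinate vectors.
#' @param acceptor_antecedent coordinates of the acceptor's covalent
#'   neighbour (kept for interface symmetry; not used by the score).
#' @param salt_bridge logical: score as a salt bridge.
#' @return Energy in kcal/mol (in [-10, 0)), or `NULL` when either geometric
#'   factor vanishes.
#' @export
score_hydrogen_bond <- function(donor, acceptor, donor_antecedent,
                                acceptor_antecedent = NULL,
                                salt_bridge = FALSE) {
  if (is.null(donor_antecedent) || any(!is.finite(donor_antecedent))) {
    stop("missing donor antecedent atom")
  }
  d0 <- if (salt_bridge) 3.0 else 2.9
  d <- sqrt(sum((donor - acceptor)^2))
  f_dist <- 1 - ((d - d0) / 0.6)^2
  if (f_dist <= 0) return(NULL)
  v1 <- donor_antecedent - donor
  v2 <- acceptor - donor
  ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  theta <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
  dev <- 180 - theta  # deviation from linear antecedent-donor-acceptor
  if (dev > 60) return(NULL)
  f_ang <- cos(dev * pi / 180)^2
  if (f_ang <= 0) return(NULL)
  e <- -10 * f_dist * f_ang
  if (salt_bridge) e <- max(-10, 1.2 * e)
  e
}

polar_atom_table <- function(structure, adj) {
  at <- structure$atoms
  n <- nrow(at)
  donors <- integer(0); d_ant <- integer(0); d_charged <- logical(0)
  acceptors <- integer(0); a_charged <- logical(0)
  find_in_res <- function(i, nm) {
    rows <- which(at$chain_id == at$chain_id[i] & at$res_seq == at$res_seq[i] &
                  at$insertion_code == at$insertion_code[i])
    rows[match(nm, at$name[rows])]
  }
  for (i in seq_len(n)) {
    nm <- at$name[i]; rn <- at$res_name[i]
    # donors
    ant <- NA_integer_
    if (nm == "N" && rn != "PRO") {
      ant <- find_in_res(i, "CA")
    } else if (!is.null(HB_DONORS[[rn]]) && nm %in% names(HB_DONORS[[rn]])) {
      ant <- find_in_res(i, HB_DONORS[[rn]][[nm]])
    }
    if (!is.na(ant)) {
      donors <- c(donors, i); d_ant <- c(d_ant, ant)
      d_charged <- c(d_charged,
                     !is.null(CHARGED_DONORS[[rn]]) && nm %in% CHARGED_DONORS[[rn]])
    }
    # acceptors
    acc <- nm %in% HB_ACCEPTORS$backbone ||
      (!is.null(HB_ACCEPTORS[[rn]]) && nm %in% HB_ACCEPTORS[[rn]])
    if (acc) {
      acceptors <- c(acceptors, i)
      a_charged <- c(a_charged,
                     nm == "OXT" ||
                       (!is.null(CHARGED_ACCEPTORS[[rn]]) && nm %in% CHARGED_ACCEPTORS[[rn]]))
    }
  }
  list(donors = donors, d_ant = d_ant, d_charged = d_charged,
       acceptors = acceptors, a_charged = a_charged)
}

#' Detect hydrogen bonds and salt bridges
#'
#' Scores every donor-acceptor pair within the candidate distance cutoff with
#' [score_hydrogen_bond()]; pairs that are covalently bonded or 1-3 bonded
#' are excluded.
#'
#' @param structure a protein `tcr_structure`.
#' @param params [network_params()].
#' @param bonds covalent edge table from [infer_covalent_bonds()] (computed
#'   if missing).
#' @return Edge data frame with `kind = "hbond"` and `energy` in kcal/mol.
#' @export
detect_hydrogen_bonds <- function(structure, params = network_params(),
                                  bonds = NULL) {
  if (is.null(bonds)) bonds <- infer_covalent_bonds(structure)
  at <- structure$atoms
  xyz <- coords_matrix(structure)
  adj <- covalent_adjacency(bonds, nrow(at))
  excl <- excluded_pairs_key(adj)
  pol <- polar_atom_table(structure, adj)
  if (length(pol$donors) == 0 || length(pol$acceptors) == 0) {
    return(empty_edges())
  }
  dx <- xyz[pol$donors, , drop = FALSE]
  ax <- xyz[pol$acceptors, , drop = FALSE]
  d2 <- outer(rowSums(dx^2), rowSums(ax^2), "+") - 2 * dx %*% t(ax)
  hit <- which(d2 < params$hbond_dist_cutoff^2, arr.ind = TRUE)
  out_i <- integer(0); out_j <- integer(0); out_e <- numeric(0)
  for (k in seq_len(nrow(hit))) {
    di <- pol$donors[hit[k, 1]]; ai <- pol$acceptors[hit[k, 2]]
    if (di == ai) next
    if (paste(min(di, ai), max(di, ai)) %in% excl) next
    sb <- pol$d_charged[hit[k, 1]] && pol$a_charged[hit[k, 2]]
    e <- score_hydrogen_bond(xyz[di, ], xyz[ai, ], xyz[pol$d_ant[hit[k, 1]], ],
                             salt_bridge = sb)
    if (is.null(e)) next
    out_i <- c(out_i, di); out_j <- c(out_j, ai); out_e <- c(out_e, e)
  }
  if (length(out_i) == 0) return(empty_edges())
  # one edge per unordered pair: keep the strongest scoring direction
  key <- paste(pmin(out_i, out_j), pmax(out_i, out_j))
  best <- vapply(split(seq_along(key), key), function(ii) ii[which.min(out_e[ii])],
                 integer(1))
  best <- sort(unname(best))
  len <- sqrt(rowSums((xyz[out_i[best], , drop = FALSE] -
                         xyz[out_j[best], , drop = FALSE])^2))
  data.frame(i = out_i[best], j = out_j[best], kind = "hbond",
             energy = out_e[best], length = len, stringsAsFactors = FALSE)
}

#' Detect hydrophobic tethers
#'
#' Pairs of hydrophobic atoms from different residues closer than the sum of
#' their van der Waals radii plus the tether gap, excluding covalently
#' connected (1-2 / 1-3) pairs. A hydrophobic atom is a carbon or sulfur
#' with no covalently bonded nitrogen or oxygen (the standard rule of
#' rigidity analysis: polar-substituted carbons such as backbone CA/C do not
#' tether).
#'
#' @inheritParams detect_hydrogen_bonds
#' @return Edge data frame with `kind = "tether"`.
#' @export
detect_hydrophobic_tethers <- function(structure, params = network_params(),
                                       bonds = NULL) {
  if (is.null(bonds)) bonds <- infer_covalent_bonds(structure)
  at <- structure$atoms
  xyz <- coords_matrix(structure)
  adj0 <- covalent_adjacency(bonds, nrow(at))
  polar_neighbour <- vapply(seq_len(nrow(at)), function(i) {
    any(at$element[adj0[[i]]] %in% c("N", "O"))
  }, logical(1))
  idx <- which(at$element %in% c("C", "S") & !polar_neighbour)
  if (length(idx) < 2) return(empty_edges())
  adj <- covalent_adjacency(bonds, nrow(at))
  excl <- excluded_pairs_key(adj)
  reskey <- paste(at$chain_id, at$res_seq, at$insertion_code)
  sub <- xyz[idx, , drop = FALSE]
  rad <- vdw_radius(at$element[idx], params)
  d2 <- outer(rowSums(sub^2), rowSums(sub^2), "+") - 2 * sub %*% t(sub)
  thr <- outer(rad, rad, "+") + params$tether_gap
  hit <- which(d2 < thr^2 & upper.tri(d2), arr.ind = TRUE)
  out_i <- integer(0); out_j <- integer(0)
  for (k in seq_len(nrow(hit))) {
    a <- idx[hit[k, 1]]; b <- idx[hit[k, 2]]
    if (reskey[a] == reskey[b]) next
    if (paste(min(a, b), max(a, b)) %in% excl) next
    out_i <- c(out_i, a); out_j <- c(out_j, b)
  }
  if (length(out_i) == 0) return(empty_edges())
  len <- sqrt(rowSums((xyz[out_i, , drop = FALSE] - xyz[out_j, , drop = FALSE])^2))
  data.frame(i = out_i, j = out_j, kind = "tether", energy = NA_real_,
             length = len, stringsAsFactors = FALSE)
}

empty_edges <- function() {
  data.frame(i = integer(0), j = integer(0), kind = character(0),
             energy = numeric(0), length = numeric(0), stringsAsFactors = FALSE)
}

#' Build the full constraint network
#'
#' @param structure a protein `tcr_structure`.
#' @param params [network_params()].
#' @return Object of class `constraint_network`: list with `structure`,
#'   `edges` (covalent + hbond + tether data frame), `params`, `n_atoms`.
#' @export
build_constraint_network <- function(structure, params = network_params()) {
  structure <- filter_protein(structure)
  bonds <- infer_covalent_bonds(structure)
  hb <- detect_hydrogen_bonds(structure, params, bonds)
  th <- detect_hydrophobic_tethers(structure, params, bonds)
  edges <- rbind(bonds, hb, th)
  rownames(edges) <- NULL
  structure(list(structure = structure, edges = edges, params = params,
                 n_atoms = nrow(structure$atoms)),
            class = "constraint_network")
}

#' @export
print.constraint_network <- function(x, ...) {
  tab <- table(x$edges$kind)
  cat(sprintf("<constraint_network: %d atoms; %s>\n", x$n_atoms,
              paste(names(tab), as.integer(tab), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Filter polar interactions at an energy cutoff
#'
#' Retains hydrogen-bond edges with energy <= `e_cut` (boundary inclusive);
#' covalent bonds and tethers are unchanged. Raising `|e_cut|` removes
#' constraints monotonically.
#'
#' @param network a `constraint_network`.
#' @param e_cut energy cutoff in kcal/mol (must be <= 0).
#' @return The filtered `constraint_network` (with `params$e_cut` updated).
#' @export
apply_energy_cutoff <- function(network, e_cut = network$params$e_cut) {
  if (e_cut > 0) stop("e_cut must be <= 0")
  keep <- network$edges$kind != "hbond" | network$edges$energy <= e_cut
  network$edges <- network$edges[keep, , drop = FALSE]
  rownames(network$edges) <- NULL
  network$params$e_cut <- e_cut
  network
}

#' Write a network edge table as TSV
#' @param network a `constraint_network`.
#' @param path output path.
#' @export
write_network_tsv <- function(network, path) {
  at <- network$structure$atoms
  lab <- function(i) paste0(at$chain_id[i], at$res_seq[i], ":", at$name[i])
  df <- data.frame(atom_i = lab(network$edges$i), atom_j = lab(network$edges$j),
                   kind = network$edges$kind, energy = network$edges$energy)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
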