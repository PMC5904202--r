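#' @title Calpha elastic network model
#' @description One site per residue, springs of equal constant between all
#'   site pairs within an interaction cutoff of 12 Angstrom (anisotropic
#'   network model). The six zero-frequency eigenvectors are rigid-body
#'   motions; the low-frequency nontrivial modes (7-16 by default) provide
#'   the collective motion directions used to bias geometric simulation.
#' @name enm
NULL

#' Elastic-network parameters
#' @param cutoff spring interaction cutoff in Angstrom (default 12, inclusive).
#' @param spring_constant uniform spring constant (arbitrary units, default 1).
#' @param n_nontrivial_modes number of nontrivial modes to keep (default 10,
#'   i.e. modes 7-16).
#' @return List of class `enm_params`.
#' @export
enm_params <- function(cutoff = 12, spring_constant = 1, n_nontrivial_modes = 10) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (n_nontrivial_modes < 1) stop("n_nontrivial_modes must be >= 1")
  structure(list(cutoff = cutoff, spring_constant = spring_constant,
                 n_nontrivial_modes = n_nontrivial_modes),
            class = "enm_params")
}

#' Build the anisotropic-network Hessian
#'
#' For each site pair (i, j) with centre distance <= cutoff, the off-diagonal
#' 3x3 block is `-k * rhat %*% t(rhat)` (rhat the unit inter-site vector);
#' diagonal blocks are minus the sum of the row's off-diagonal blocks, making
#' the matrix symmetric positive semi-definite with every row of blocks
#' summing to zero (translational invariance).
#'
#' @param calpha_coords N x 3 matrix of site coordinates.
#' @param params [enm_params()].
#' @return 3N x 3N symmetric Hessian.
#' @export
build_hessian <- function(calpha_coords, params = enm_params()) {
  X <- as.matrix(calpha_coords)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 sites")
  d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * X %*% t(X)
  d2[d2 < 0] <- 0
  if (any(d2[upper.tri(d2)] < 0.1^2)) stop("coincident sites (distance < 0.1 A)")
  H <- matrix(0, 3 * n, 3 * n)
  k <- params$spring_constant
  within <- d2 <= params$cutoff^2
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (!within[i, j]) next
      r <- X[j, ] - X[i, ]
      rhat <- r / sqrt(sum(r^2))
      blk <- -k * tcrossprod(rhat)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- blk
      H[jj, ii] <- blk
      H[ii, ii] <- H[ii, ii] - blk
      H[jj, jj] <- H[jj, jj] - blk
    }
  }
  H
}

# connected components of the spring network, for the disconnection error
spring_components <- function(calpha_coords, cutoff) {
  X <- as.matrix(calpha_coords)
  n <- nrow(X)
  d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * X %*% t(X)
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(d2[v, ] <= cutoff^2 & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Diagonalise the Hessian and select nontrivial modes
#'
#' Verifies that exactly six eigenvalues are numerically zero (rigid-body
#' translations/rotations of a connected network) and returns the next
#' `n_nontrivial_modes` modes in ascending eigenvalue order (mode indices
#' 7..6+n by default). Each eigenvector's sign is fixed so that its
#' largest-magnitude component is positive, making parallel/antiparallel
#' directions reproducible.
#'
#' @param hessian 3N x 3N symmetric matrix from [build_hessian()].
#' @param params [enm_params()].
#' @param sites optional data frame `(chain_id, res_seq)` describing the
#'   sites, carried through for bookkeeping.
#' @param coords optional N x 3 site coordinates (used only to name
#'   disconnected components in the error message).
#' @return Object of class `mode_set`: `eigenvalues` (ascending, length n),
#'   `vectors` (3N x n orthonormal columns), `mode_indices` (1-based),
#'   `sites`.
#' @export
compute_modes <- function(hessian, params = enm_params(), sites = NULL,
                          coords = NULL) {
  if (!isSymmetric(unname(hessian), tol = 1e-8)) stop("Hessian must be symmetric")
  n3 <- nrow(hessian)
  eig <- eigen(hessian, symmetric = TRUE)
  vals <- rev(eig$values)
  vecs <- eig$vectors[, rev(seq_len(n3)), drop = FALSE]
  vals[abs(vals) < 1e-12] <- 0
  nm <- params$n_nontrivial_modes
  if (n3 < 6 + nm) stop("network too small for ", nm, " nontrivial modes")
  # rigid-body zeros are identified relative to the softest genuine mode:
  # the first six eigenvalues must be < 1e-8 * lambda_7. A lambda_7 at
  # numerical-noise level means a mechanism (disconnection or degenerate
  # geometry), not a genuine mode.
  scale <- max(vals[n3], 1e-12)
  near_zero <- sum(abs(vals) < max(1e-8 * abs(vals[7]), 1e-11 * scale))
  if (vals[7] < 1e-9 * scale) near_zero <- 7L
  if (near_zero > 6) {
    msg <- "more than 6 near-zero modes"
    if (!is.null(coords)) {
      comp <- spring_components(coords, params$cutoff)
      tab <- table(comp)
      if (length(tab) > 1) {
        msg <- paste0("disconnected spring network: ", msg, " (",
                      length(tab), " components of sizes ",
                      paste(as.integer(tab), collapse = ", "), ")")
      } else {
        msg <- paste0("degenerate site geometry (coplanar/collinear): ", msg)
      }
    } else {
      msg <- paste0("disconnected or degenerate spring network: ", msg)
    }
    stop(msg)
  }
  idx <- seq(7, 6 + nm)
  vecs_sel <- vecs[, idx, drop = FALSE]
  for (c in seq_len(ncol(vecs_sel))) {
    mx <- which.max(abs(vecs_sel[, c]))
    if (vecs_sel[mx, c] < 0) vecs_sel[, c] <- -vecs_sel[, c]
  }
  structure(list(eigenvalues = vals[idx], all_eigenvalues = vals,
                 vectors = vecs_sel, mode_indices = idx, sites = sites),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("<mode_set: modes %d-%d, eigenvalues %.4g .. %.4g>\n",
              min(x$mode_indices), max(x$mode_indices),
              min(x$eigenvalues), max(x$eigenvalues)))
  invisible(x)
}

#' Elastic-network modes of a structure
#'
#' Convenience wrapper: extracts all Calpha sites (all chains, one connected
#' network with inter-chain springs allowed within the cutoff), builds the
#' Hessian and computes modes.
#'
#' @param structure a protein `tcr_structure`.
#' @param params [enm_params()].
#' @return A `mode_set` with `sites` describing `(chain_id, res_seq)`.
#' @export
enm_modes <- function(structure, params = enm_params()) {
  structure <- filter_protein(structure)
  chains <- unique(structure$atoms$chain_id)
  site_list <- lapply(chains, function(ch) {
    ca <- extract_calpha(structure, ch)
    if (nrow(ca) == 0) return(NULL)  # e.g. a lone obstacle body
    cbind(data.frame(chain_id = ch), ca)
  })
  sites <- do.call(rbind, site_list)
  coords <- as.matrix(sites[, c("x", "y", "z")])
  H <- build_hessian(coords, params)
  compute_modes(H, params, sites = sites[, c("chain_id", "res_seq")],
                coords = coords)
}

#' Expand a Calpha mode to an all-atom displacement field
#'
#' Every atom receives its residue's Calpha mode vector; the field is
#' renormalised to unit overall norm.
#'
#' @param mode_set a `mode_set` with `sites`.
#' @param mode_index which returned mode to expand (1-based position in the
#'   mode set, or a mode index present in `mode_indices`).
#' @param structure the all-atom `tcr_structure`.
#' @param allow_missing give atoms of residues without a Calpha site a zero
#'   vector instead of raising an error (used for obstacle bodies that sit
#'   outside the elastic network).
#' @return n_atoms x 3 matrix with unit Frobenius norm.
#' @export
expand_mode_to_atoms <- function(mode_set, mode_index, structure,
                                 allow_missing = FALSE) {
  if (is.null(mode_set$sites)) stop("mode_set has no site table")
  pos <- if (mode_index %in% mode_set$mode_indices) {
    match(mode_index, mode_set$mode_indices)
  } else if (mode_index >= 1 && mode_index <= ncol(mode_set$vectors)) {
    mode_index
  } else {
    stop("mode index ", mode_index, " not in mode set")
  }
  v <- matrix(mode_set$vectors[, pos], ncol = 3, byrow = TRUE)
  at <- structure$atoms
  key_site <- paste(mode_set$sites$chain_id, mode_set$sites$res_seq)
  key_atom <- paste(at$chain_id, at$res_seq)
  idx <- match(key_atom, key_site)
  if (any(is.na(idx)) && !allow_missing) {
    bad <- unique(key_atom[is.na(idx)])
    stop("residue(s) without a Calpha site in the mode: ",
         paste(bad, collapse = ", "))
  }
  field <- v[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
  field[is.na(idx), ] <- 0
  field / sqrt(sum(field^2))
}

#' Serialise a mode set as TSV
#' @param mode_set a `mode_set`.
#' @param path output path (eigenvalue table written alongside as
#'   `<path>.eigenvalues.tsv`).
#' @export
write_modes_tsv <- function(mode_set, path) {
  n <- nrow(mode_set$sites)
  rows <- list()
  for (m in seq_along(mode_set$mode_indices)) {
    v <- matrix(mode_set$vectors[, m], ncol = 3, byrow = TRUE)
    rows[[m]] <- data.frame(chain_id = mode_set$sites$chain_id,
                            res_seq = mode_set$sites$res_seq,
                            mode_index = mode_set$mode_indices[m],
                            dx = v[, 1], dy = v[, 2], dz = v[, 3])
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ev <- data.frame(mode_index = mode_set$mode_indices,
                   eigenvalue = mode_set$eigenvalues)
  utils::write.table(ev, paste0(path, ".eigenvalues.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
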