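#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD of
#' `R %*% mobile + t` against `reference`.
#'
#' @param mobile,reference n x 3 coordinate matrices, rows paired.
#' @return Object of class `superposition`: list with `rotation` (3 x 3,
#'   det = +1), `translation` (length 3), `rmsd` (Angstrom), `n_atoms`, and
#'   `fitted` (the transformed mobile coordinates).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) {
    stop("mobile and reference have different numbers of points")
  }
  if (nrow(mobile) < 3) stop("need at least 3 points to superpose")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)  # 3x3 covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1)) {
    stop("degenerate point set (rank < 2): cannot superpose")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cr - as.vector(R %*% cm)
  fitted <- t(R %*% t(mobile)) + matrix(t_vec, nrow(mobile), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd,
                 n_atoms = nrow(mobile), fitted = fitted),
            class = "superposition")
}

#' Apply a superposition transform to coordinates
#' @param fit a `superposition` object.
#' @param coords n x 3 matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(fit, coords) {
  coords <- as.matrix(coords)
  t(fit$rotation %*% t(coords)) +
    matrix(fit$translation, nrow(coords), 3, byrow = TRUE)
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: %d atoms, rmsd %.4f A>\n", x$n_atoms, x$rmsd))
  invisible(x)
}

ca_for_residues <- function(structure, chain_id, residues) {
  ca <- extract_calpha(structure, chain_id)
  ca[ca$res_seq %in% residues, , drop = FALSE]
}

#' Per-residue Calpha displacement between two structures
#'
#' Superposes structure `a` onto `b` using the CA atoms of `fit_selection`,
#' then reports the CA displacement of each residue in `measure_selection`.
#' This is the measurement behind "loop X shifts by up to d Angstrom between
#' crystals": fit on the framework, measure on the loop.
#'
#' @param a,b `tcr_structure` objects sharing chain `chain_id`.
#' @param fit_selection,measure_selection residue-number vectors.
#' @param chain_id chain to analyse.
#' @return Object of class `displacement_profile`: data frame
#'   `(res_seq, displacement)` plus `max_displacement` and `argmax`
#'   attributes.
#' @export
per_residue_displacement <- function(a, b, fit_selection, measure_selection,
                                     chain_id) {
  ca_a_fit <- ca_for_residues(a, chain_id, fit_selection)
  ca_b_fit <- ca_for_residues(b, chain_id, fit_selection)
  shared_fit <- intersect(ca_a_fit$res_seq, ca_b_fit$res_seq)
  if (length(shared_fit) < 3) stop("empty or degenerate fit selection after intersection")
  fit <- kabsch_superpose(
    as.matrix(ca_a_fit[match(shared_fit, ca_a_fit$res_seq), c("x", "y", "z")]),
    as.matrix(ca_b_fit[match(shared_fit, ca_b_fit$res_seq), c("x", "y", "z")])
  )
  ca_a <- ca_for_residues(a, chain_id, measure_selection)
  ca_b <- ca_for_residues(b, chain_id, measure_selection)
  shared <- intersect(ca_a$res_seq, ca_b$res_seq)
  if (length(shared) == 0) stop("empty measure selection after intersection")
  pa <- apply_transform(fit, as.matrix(ca_a[match(shared, ca_a$res_seq),
                                            c("x", "y", "z")]))
  pb <- as.matrix(ca_b[match(shared, ca_b$res_seq), c("x", "y", "z")])
  disp <- sqrt(rowSums((pa - pb)^2))
  out <- data.frame(res_seq = shared, displacement = disp)
  attr(out, "max_displacement") <- max(disp)
  attr(out, "argmax") <- shared[which.max(disp)]
  attr(out, "fit_rmsd") <- fit$rmsd
  class(out) <- c("displacement_profile", "data.frame")
  out
}

#' Pairwise maximum loop shift across a structure ensemble
#'
#' Entry (i, j) is the maximum CA displacement over the loop's residues after
#' fitting structure i onto structure j on `fit_selection`. The maximising
#' pair identifies the two extreme conformations of the loop.
#'
#' @param structures list of `tcr_structure` objects of the same protein.
#' @param loop one-row loop definition (`loop_name`, `chain_id`, `start`, `end`).
#' @param fit_selection residue numbers used for the superposition (framework
#'   residues of the same domain).
#' @return Symmetric matrix of maximal loop CA shifts with attributes
#'   `max_shift` and `extreme_pair` (indices of the two extreme conformers).
#' @export
pairwise_loop_shift_matrix <- function(structures, loop, fit_selection) {
  n <- length(structures)
  if (n < 2) stop("need at least 2 structures")
  loop_res <- seq(loop$start, loop$end)
  for (k in seq_len(n)) {
    ca <- ca_for_residues(structures[[k]], loop$chain_id, loop_res)
    if (nrow(ca) == 0) {
      stop("loop ", loop$loop_name, " residues missing in structure ",
           structures[[k]]$id)
    }
  }
  M <- matrix(0, n, n)
  labels <- vapply(structures, function(s) s$id, character(1))
  dimnames(M) <- list(labels, labels)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      prof <- per_residue_displacement(structures[[i]], structures[[j]],
                                       fit_selection, loop_res, loop$chain_id)
      M[i, j] <- M[j, i] <- attr(prof, "max_displacement")
    }
  }
  idx <- which(M == max(M), arr.ind = TRUE)[1, ]
  attr(M, "max_shift") <- max(M)
  attr(M, "extreme_pair") <- sort(unname(idx))
  M
}
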