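#' @title Template-based geometric simulation of flexible motion
#' @description Mode-biased exploration of conformational space without a
#'   force field: at each frame every atom is displaced a small step along a
#'   normal-mode direction, then the structure is relaxed back onto its
#'   constraints (rigid-cluster templates, hydrogen-bond/tether distance
#'   windows, steric floors). Motion is "easy" while the constraint network
#'   can accommodate it and terminates by jamming when relaxation can no
#'   longer reach tolerance, defining the natural amplitude limit of that
#'   mode direction.
#' @name geomsim
NULL

#' Geometric-simulation parameters
#'
#' @param step_size perturbation step in Angstrom per atom per frame (the
#'   unit mode field is scaled by `sqrt(n_atoms)` so the typical per-atom
#'   displacement per frame is about `step_size`). Default 0.01.
#' @param relax_tolerance constraint tolerance in Angstrom (default 0.1).
#' @param max_relax_iters relaxation cycles per frame before the run is
#'   declared jammed (default 200).
#' @param max_frames frame cap (default 2000).
#' @param steric_scale fraction of the van der Waals sum treated as a hard
#'   floor for nonbonded pairs (default 0.85).
#' @param stall_frames,stall_tol jamming detector: the run terminates as
#'   jammed when the cumulative amplitude has grown by less than
#'   `stall_tol` Angstrom over the last `stall_frames` frames (defaults
#'   0.01 A over 100 frames), i.e. the constraints have brought the motion
#'   to a standstill. Relaxation failure within `max_relax_iters` also jams.
#' @param seed integer seed (the relaxation itself is deterministic; the seed
#'   is fixed at run start for reproducibility of any degenerate tie-breaks).
#' @return List of class `sim_params`.
#' @export
sim_params <- function(step_size = 0.01, relax_tolerance = 0.1,
                       max_relax_iters = 200, max_frames = 2000,
                       steric_scale = 0.85, stall_frames = 100,
                       stall_tol = 0.01, seed = 1L) {
  stopifnot(step_size > 0, relax_tolerance > 0, max_relax_iters > 0,
            max_frames > 0, steric_scale > 0, steric_scale <= 1,
            stall_frames > 0, stall_tol >= 0)
  structure(list(step_size = step_size, relax_tolerance = relax_tolerance,
                 max_relax_iters = max_relax_iters, max_frames = max_frames,
                 steric_scale = steric_scale, stall_frames = stall_frames,
                 stall_tol = stall_tol, seed = as.integer(seed)),
            class = "sim_params")
}

#' Build rigid-unit templates from a decomposition
#'
#' One template per rigid cluster, extended by the cluster's direct covalent
#' neighbours. A neighbour atom shared with an adjacent template is the
#' articulation: its position relative to each template fixes bond lengths
#' and bond angles across the rotatable bond while leaving the dihedral
#' free. Clusters of size 1-2 reduce to minimal angle-preserving units (atom
#' plus covalent neighbours) under the same rule.
#'
#' @param structure the protein `tcr_structure` the network was built from.
#' @param decomposition a `rigid_decomposition`.
#' @param network the `constraint_network`.
#' @return List of class `template_set`; each template has `atoms` (row
#'   indices) and `ref` (reference coordinates). The `membership` attribute
#'   maps atoms to the templates containing them.
#' @export
build_templates <- function(structure, decomposition, network) {
  n <- network$n_atoms
  xyz <- coords_matrix(network$structure)
  cov <- network$edges[network$edges$kind %in% c("covalent_single", "covalent_locked"), ]
  adj <- covalent_adjacency(cov, n)
  clusters <- split(seq_len(n), decomposition$cluster_of)
  templates <- lapply(clusters, function(cl) {
    halo <- unique(unlist(adj[cl]))
    atoms <- sort(unique(as.integer(c(cl, halo))))
    list(atoms = atoms, ref = xyz[atoms, , drop = FALSE])
  })
  covered <- sort(unique(as.integer(unlist(lapply(templates, `[[`, "atoms")))))
  if (!identical(covered, seq_len(n))) {
    stop("atom(s) missing from all templates: ",
         paste(setdiff(seq_len(n), covered), collapse = ", "))
  }
  membership <- vector("list", n)
  for (t in seq_along(templates)) {
    for (a in templates[[t]]$atoms) membership[[a]] <- c(membership[[a]], t)
  }
  structure(templates, membership = membership, class = "template_set")
}

# Kabsch fit tolerant of degenerate (1-, 2-point, collinear) templates:
# falls back on translation-only alignment of centroids.
fit_template <- function(ref, cur) {
  m <- nrow(ref)
  if (m == 1) return(cur)
  cm <- colMeans(ref); cc <- colMeans(cur)
  A <- sweep(ref, 2, cm); B <- sweep(cur, 2, cc)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t(R %*% t(A)) + matrix(cc, m, 3, byrow = TRUE)
}

# precomputed relaxation workspace
make_relax_data <- function(structure, templates, network, params) {
  n <- network$n_atoms
  at <- network$structure$atoms
  edges <- network$edges
  cov <- edges[edges$kind %in% c("covalent_single", "covalent_locked"), ]
  noncov <- edges[edges$kind %in% c("hbond", "tether"), ]
  # steric candidate pairs: all pairs except network neighbours (1-2, 1-3,
  # and hbond/tether partners)
  adj <- covalent_adjacency(cov, n)
  excl <- excluded_pairs_key(adj)
  if (nrow(noncov) > 0) {
    excl <- unique(c(excl, paste(pmin(noncov$i, noncov$j),
                                 pmax(noncov$i, noncov$j))))
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  key <- paste(pairs[, 1], pairs[, 2])
  pairs <- pairs[!(key %in% excl), , drop = FALSE]
  rad <- vdw_radius(at$element, params_net(network))
  # steric floor per pair: the scaled van der Waals sum, but never more
  # than the input-structure distance — contacts already present in the
  # input are grandfathered (they may not get tighter, but do not count as
  # violations), so the input conformation is always feasible
  X0 <- coords_matrix(network$structure)
  d0 <- sqrt(rowSums((X0[pairs[, 1], , drop = FALSE] -
                        X0[pairs[, 2], , drop = FALSE])^2))
  floor_d <- pmin(params$steric_scale * (rad[pairs[, 1]] + rad[pairs[, 2]]),
                  0.999 * d0)
  list(
    n = n,
    cov_i = cov$i, cov_j = cov$j, cov_len = cov$length,
    nc_i = noncov$i, nc_j = noncov$j, nc_len = noncov$length,
    st_i = pairs[, 1], st_j = pairs[, 2], st_floor = floor_d,
    membership = attr(templates, "membership"),
    templates = templates
  )
}

params_net <- function(network) network$params

relax_violations <- function(X, rd, params) {
  cov_d <- sqrt(rowSums((X[rd$cov_i, , drop = FALSE] - X[rd$cov_j, , drop = FALSE])^2))
  max_cov <- if (length(cov_d)) max(abs(cov_d - rd$cov_len)) else 0
  if (length(rd$nc_i)) {
    nc_d <- sqrt(rowSums((X[rd$nc_i, , drop = FALSE] - X[rd$nc_j, , drop = FALSE])^2))
    win <- abs(nc_d - rd$nc_len) - params$relax_tolerance
    max_win <- max(0, win)
  } else max_win <- 0
  if (length(rd$st_i)) {
    st_d <- sqrt(rowSums((X[rd$st_i, , drop = FALSE] - X[rd$st_j, , drop = FALSE])^2))
    pen <- rd$st_floor - st_d
    max_pen <- max(0, pen)
    min_gap <- min(st_d - rd$st_floor)
  } else { max_pen <- 0; min_gap <- Inf }
  list(max_cov = max_cov, max_win = max_win, max_pen = max_pen,
       min_gap = min_gap,
       worst = max(max_cov, max_win, max_pen))
}

# one relaxation cycle: template fits -> position averaging -> pair projections
relax_cycle <- function(X, rd, params) {
  n <- rd$n
  acc <- matrix(0, n, 3)
  cnt <- numeric(n)
  for (t in seq_along(rd$templates)) {
    tpl <- rd$templates[[t]]
    fitted <- fit_template(tpl$ref, X[tpl$atoms, , drop = FALSE])
    acc[tpl$atoms, ] <- acc[tpl$atoms, ] + fitted
    cnt[tpl$atoms] <- cnt[tpl$atoms] + 1
  }
  X <- acc / cnt
  # steric floors: push apart pairs below the hard floor
  if (length(rd$st_i)) {
    dvec <- X[rd$st_i, , drop = FALSE] - X[rd$st_j, , drop = FALSE]
    d <- sqrt(rowSums(dvec^2))
    floor_d <- rd$st_floor
    bad <- which(d < floor_d)
    for (b in bad) {
      i <- rd$st_i[b]; j <- rd$st_j[b]
      if (d[b] < 1e-9) {
        u <- c(1, 0, 0)  # coincident atoms: arbitrary fixed direction
      } else {
        u <- dvec[b, ] / d[b]
      }
      push <- (floor_d[b] + 0.002 - d[b]) / 2
      X[i, ] <- X[i, ] + push * u
      X[j, ] <- X[j, ] - push * u
    }
  }
  # hydrogen-bond / tether windows: project back to initial length +- tol
  if (length(rd$nc_i)) {
    dvec <- X[rd$nc_i, , drop = FALSE] - X[rd$nc_j, , drop = FALSE]
    d <- sqrt(rowSums(dvec^2))
    lo <- rd$nc_len - params$relax_tolerance
    hi <- rd$nc_len + params$relax_tolerance
    out <- which(d < lo | d > hi)
    for (b in out) {
      i <- rd$nc_i[b]; j <- rd$nc_j[b]
      target <- if (d[b] < lo[b]) lo[b] else hi[b]
      u <- dvec[b, ] / max(d[b], 1e-9)
      corr <- (target - d[b]) / 2
      X[i, ] <- X[i, ] + corr * u
      X[j, ] <- X[j, ] - corr * u
    }
  }
  X
}

#' Check a conformer against the constraint network
#'
#' @param conformer n_atoms x 3 coordinate matrix (or `tcr_structure`).
#' @param network the `constraint_network`.
#' @param templates a `template_set` (used for the atom count contract).
#' @param params [sim_params()].
#' @return List: `max_covalent_deviation`, `max_window_violation`,
#'   `min_steric_gap` (distance above the steric floor; negative =
#'   penetration), `n_violations` above tolerance.
#' @export
check_constraints <- function(conformer, network, templates,
                              params = sim_params()) {
  X <- if (inherits(conformer, "tcr_structure")) coords_matrix(conformer) else as.matrix(conformer)
  if (nrow(X) != network$n_atoms) stop("conformer atom count != network atom count")
  rd <- make_relax_data(network$structure, templates, network, params)
  v <- relax_violations(X, rd, params)
  n_viol <- 0L
  cov_d <- sqrt(rowSums((X[rd$cov_i, , drop = FALSE] - X[rd$cov_j, , drop = FALSE])^2))
  n_viol <- n_viol + sum(abs(cov_d - rd$cov_len) > params$relax_tolerance)
  if (length(rd$nc_i)) {
    nc_d <- sqrt(rowSums((X[rd$nc_i, , drop = FALSE] - X[rd$nc_j, , drop = FALSE])^2))
    n_viol <- n_viol + sum(abs(nc_d - rd$nc_len) - params$relax_tolerance >
                             params$relax_tolerance)
  }
  if (length(rd$st_i)) {
    st_d <- sqrt(rowSums((X[rd$st_i, , drop = FALSE] - X[rd$st_j, , drop = FALSE])^2))
    n_viol <- n_viol + sum(rd$st_floor - st_d > params$relax_tolerance)
  }
  list(max_covalent_deviation = v$max_cov,
       max_window_violation = v$max_win,
       max_steric_penetration = v$max_pen,
       min_steric_gap = v$min_gap,
       n_violations = n_viol)
}

#' Run one mode-biased geometric simulation
#'
#' Per frame: displace all atoms by `direction * step_size * sqrt(n) *
#' mode_field`, then relax with repeated cycles (template fitting and
#' position averaging, steric push-apart, hydrogen-bond/tether window
#' projection) until the worst violation is below `relax_tolerance`. If
#' relaxation fails within `max_relax_iters` cycles the run reverts to the
#' last valid frame and terminates as jammed; otherwise it runs to
#' `max_frames` and terminates as completed.
#'
#' @param structure the protein `tcr_structure` (must match the network).
#' @param templates a `template_set` from [build_templates()].
#' @param network the (cutoff-filtered) `constraint_network`.
#' @param mode_field n_atoms x 3 unit-norm displacement field from
#'   [expand_mode_to_atoms()].
#' @param direction +1 (parallel) or -1 (antiparallel).
#' @param params [sim_params()].
#' @param mode_index bookkeeping label for the ensemble.
#' @param anchors optional atom indices pinned to their input positions after
#'   every relaxation cycle (e.g. an obstacle body).
#' @return Object of class `conformer_ensemble`: `frames` (coordinate
#'   matrices stored every 100 frames plus the final frame), `diagnostics`
#'   (per stored frame: frame number, amplitude, max bond deviation, min
#'   steric gap), `termination` ("completed" or "jammed"), `n_frames` run,
#'   `amplitude` (final cumulative mode projection, Angstrom), `mode_index`,
#'   `direction`.
#' @export
run_geometric_simulation <- function(structure, templates, network, mode_field,
                                     direction = 1, params = sim_params(),
                                     mode_index = NA_integer_, anchors = NULL) {
  mode_field <- as.matrix(mode_field)
  nrm <- sqrt(sum(mode_field^2))
  if (nrm > 0 && abs(nrm - 1) > 1e-6) stop("mode field must have unit norm (or be zero)")
  stopifnot(direction %in% c(-1, 1))
  set.seed(params$seed)
  rd <- make_relax_data(structure, templates, network, params)
  n <- rd$n
  if (nrow(mode_field) != n) stop("mode field size != atom count")
  X0 <- coords_matrix(network$structure)
  X <- X0
  step_vec <- direction * params$step_size * sqrt(n) * mode_field
  mf_flat <- as.vector(mode_field)
  frames <- list()
  diag_rows <- list()
  store <- function(X, frame, amp) {
    v <- relax_violations(X, rd, params)
    frames[[length(frames) + 1]] <<- X
    diag_rows[[length(diag_rows) + 1]] <<- data.frame(
      frame = frame, amplitude = amp,
      max_bond_deviation = max(v$max_cov, v$max_win),
      min_steric_gap = v$min_gap)
  }
  amplitude_of <- function(X) direction * sum((X - X0) * mode_field)
  last_valid <- X
  last_amp <- 0
  amp_history <- numeric(params$max_frames)
  termination <- "completed"
  frame <- 0L
  store(X, 0L, 0)
  while (frame < params$max_frames) {
    frame <- frame + 1L
    X <- X + step_vec
    ok <- FALSE
    for (it in seq_len(params$max_relax_iters)) {
      X <- relax_cycle(X, rd, params)
      if (!is.null(anchors)) X[anchors, ] <- X0[anchors, , drop = FALSE]
      if (any(!is.finite(X))) stop("NaN coordinates at frame ", frame)
      v <- relax_violations(X, rd, params)
      if (v$worst < params$relax_tolerance) { ok <- TRUE; break }
    }
    if (!ok) {
      termination <- "jammed"
      X <- last_valid
      frame <- frame - 1L
      break
    }
    last_valid <- X
    last_amp <- max(last_amp, amplitude_of(X))
    amp_history[frame] <- last_amp
    if (frame %% 100 == 0) store(X, frame, last_amp)
    if (nrm > 0 && frame > params$stall_frames &&
        last_amp - amp_history[frame - params$stall_frames] < params$stall_tol) {
      termination <- "jammed"
      break
    }
  }
  # final frame (if not already stored at a 100-frame boundary)
  if (length(diag_rows) == 0 || diag_rows[[length(diag_rows)]]$frame != frame) {
    store(last_valid, frame, last_amp)
  }
  structure(list(frames = frames,
                 diagnostics = do.call(rbind, diag_rows),
                 termination = termination, n_frames = frame,
                 amplitude = last_amp,
                 mode_index = mode_index, direction = direction),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble: mode %s dir %+d, %d frames, %s, amplitude %.2f A>\n",
              x$mode_index, x$direction, x$n_frames, x$termination, x$amplitude))
  invisible(x)
}

#' Run the full set of mode-biased simulations
#'
#' One run per (mode, direction): 10 modes x 2 directions = 20 ensembles at
#' the defaults.
#'
#' @param structure protein `tcr_structure`.
#' @param network cutoff-filtered `constraint_network`.
#' @param templates a `template_set`.
#' @param mode_set a `mode_set`.
#' @param params [sim_params()].
#' @return List of `conformer_ensemble`s.
#' @export
run_all_modes <- function(structure, network, templates, mode_set,
                          params = sim_params()) {
  out <- list()
  for (m in mode_set$mode_indices) {
    field <- expand_mode_to_atoms(mode_set, m, network$structure)
    for (dir in c(1, -1)) {
      out[[length(out) + 1]] <- run_geometric_simulation(
        structure, templates, network, field, dir, params, mode_index = m)
    }
  }
  out
}

#' Select the extreme variant of each ensemble
#'
#' The final valid frame of each (mode, direction) run: the conformer at the
#' natural amplitude limit of that motion. 10 modes x 2 directions gives the
#' 20 structural variants.
#'
#' @param ensembles list of `conformer_ensemble`s covering each
#'   (mode, direction) pair once.
#' @return List of variants: each has `coords`, `mode_index`, `direction`,
#'   `amplitude`, `termination`.
#' @export
select_extreme_variants <- function(ensembles) {
  keys <- vapply(ensembles, function(e) paste(e$mode_index, e$direction),
                 character(1))
  if (anyDuplicated(keys)) stop("duplicate (mode, direction) pair in ensembles")
  modes <- unique(vapply(ensembles, function(e) e$mode_index, numeric(1)))
  for (m in modes) {
    dirs <- vapply(ensembles[vapply(ensembles, function(e) e$mode_index == m,
                                    logical(1))],
                   function(e) e$direction, numeric(1))
    if (!setequal(dirs, c(-1, 1))) {
      stop("missing direction for mode ", m)
    }
  }
  lapply(ensembles, function(e) {
    list(coords = e$frames[[length(e$frames)]], mode_index = e$mode_index,
         direction = e$direction, amplitude = e$amplitude,
         termination = e$termination)
  })
}
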