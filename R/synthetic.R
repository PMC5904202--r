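#' @title Synthetic structure generators
#' @description Seed-deterministic toy structures with known ground truth:
#'   a two-strand hairpin scaffold whose backbone hydrogen-bond ladder is
#'   built at ideal scoring geometry, conformer pairs with an exactly known
#'   loop apex displacement, a two-domain chain with a flexible linker, and
#'   a P1 lattice fixture with one designed inter-image contact. These stand
#'   in for deposited structures so the whole pipeline is testable offline.
#' @name synthetic_data
NULL

# ideal backbone geometry used by all generators. The template angles and
# the inter-strand placement (x-slip DX, z-separation TZ, residue-plane
# tilt RHO) were chosen together so that each narrow rung's two backbone
# hydrogen bonds score -6.5 kcal/mol (donor-acceptor distance 2.98 A,
# donor deviation 35.5 degrees) while cross-strand atom clearances stay
# near the scaled van der Waals floors.
BB <- list(n_ca = 1.46, ca_c = 1.52, c_n = 1.33, c_o = 1.23,
           a1 = 36.16 * pi / 180, a2 = 40.78 * pi / 180)
BB$a3 <- asin((BB$ca_c * sin(BB$a2) - BB$n_ca * sin(BB$a1)) / BB$c_n)
BB$pitch <- BB$n_ca * cos(BB$a1) + BB$ca_c * cos(BB$a2) + BB$c_n * cos(BB$a3)
BB$rho <- 87.06 * pi / 180  # tilt of the residue plane out of the sheet plane
BB$dx <- 1.39               # rung x-slip
BB$tz <- 4.19               # strand separation along z
HB_IDEAL <- 2.9             # centre of the hydrogen-bond scoring well

#' Specification for a synthetic structure
#'
#' @param n_core_residues residues in the hydrogen-bonded core (two strands
#'   of `n_core_residues / 2`); must be even and >= 6.
#' @param loop_length residues in the connecting loop (>= 2).
#' @param loop_displacement Angstrom, used by [make_conformer_pair()].
#' @param two_domain build a two-domain chain.
#' @param cell optional unit-cell tuple for lattice fixtures.
#' @param seed integer seed (generators are deterministic; the seed is
#'   recorded and fixed for reproducibility of any stochastic extensions).
#' @return List of class `toy_spec`.
#' @export
toy_spec <- function(n_core_residues = 8, loop_length = 4,
                     loop_displacement = 2.5, two_domain = FALSE,
                     cell = NULL, seed = 1L) {
  stopifnot(n_core_residues >= 6, n_core_residues %% 2 == 0, loop_length >= 2)
  structure(list(n_core_residues = n_core_residues, loop_length = loop_length,
                 loop_displacement = loop_displacement, two_domain = two_domain,
                 cell = cell, seed = as.integer(seed)),
            class = "toy_spec")
}

# place one glycine backbone residue; returns atom coordinates and the next
# residue's N position (exact bond lengths by construction)
place_residue <- function(N, t, nvec) {
  t <- t / sqrt(sum(t^2))
  nvec <- nvec - sum(nvec * t) * t
  nvec <- nvec / sqrt(sum(nvec^2))
  CA <- N + BB$n_ca * (cos(BB$a1) * t + sin(BB$a1) * nvec)
  C <- CA + BB$ca_c * (cos(BB$a2) * t - sin(BB$a2) * nvec)
  O <- C + BB$c_o * (-nvec)
  next_N <- C + BB$c_n * (cos(BB$a3) * t + sin(BB$a3) * nvec)
  list(N = N, CA = CA, C = C, O = O, next_N = next_N)
}

atoms_df <- function(res_list, chain_id = "A", res_name = "GLY", start_res = 1L) {
  rows <- list()
  serial <- 0L
  for (r in seq_along(res_list)) {
    rr <- res_list[[r]]
    for (nm in c("N", "CA", "C", "O")) {
      serial <- serial + 1L
      rows[[length(rows) + 1]] <- data.frame(
        serial = serial, name = nm,
        element = substr(nm, 1, 1), alt_loc = "", chain_id = chain_id,
        res_name = res_name, res_seq = start_res + r - 1L, insertion_code = "",
        x = rr[[nm]][1], y = rr[[nm]][2], z = rr[[nm]][3],
        occupancy = 1, b_factor = 0, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df$serial <- seq_len(nrow(df))
  df
}

# gentle uniform twist about an axis parallel to x: rotates the (y, z)
# plane by tau radians per Angstrom of x. Planar builds would give the
# elastic network a singular out-of-plane block; the twist makes the
# geometry genuinely three-dimensional while distorting the designed
# hydrogen-bond geometry only locally (by ~tau * pair-x-offset).
TWIST_RATE <- 1.5 * pi / 180  # rad per Angstrom

twist_about_x <- function(X, center = c(0, 0), tau = TWIST_RATE) {
  th <- tau * X[, 1]
  y <- X[, 2] - center[1]
  z <- X[, 3] - center[2]
  X[, 2] <- center[1] + cos(th) * y - sin(th) * z
  X[, 3] <- center[2] + sin(th) * y + cos(th) * z
  X
}

# quadratic Bezier point
bezier <- function(p0, p1, p2, s) {
  (1 - s)^2 * p0 + 2 * s * (1 - s) * p1 + s^2 * p2
}

# build `L` residues chasing a Bezier curve from start N to a target N
# position; returns residues plus the final next_N
chase_curve <- function(N0, target, L, bulge, out_dir) {
  mid <- (N0 + target) / 2 + bulge * out_dir
  res <- vector("list", L)
  N <- N0
  for (k in seq_len(L)) {
    aim <- bezier(N0, mid, target, k / L)
    t <- aim - N
    if (sqrt(sum(t^2)) < 1e-6) t <- target - N0
    up <- c(0, 0, 1)
    nvec <- up - sum(up * t) * t / sum(t^2)
    if (sqrt(sum(nvec^2)) < 1e-6) nvec <- c(0, 1, 0)
    res[[k]] <- place_residue(N, t, nvec)
    N <- res[[k]]$next_N
  }
  list(residues = res, final_N = N)
}

# closest point on the intersection circle of two spheres (or the best
# compromise on the centre line when they do not intersect)
solve_two_spheres <- function(p, c1, r1, c2, r2) {
  d <- c2 - c1
  D <- sqrt(sum(d^2))
  if (D < 1e-9) return(p)
  u <- d / D
  if (D > r1 + r2) return(c1 + u * (r1 + (D - r1 - r2) / 2))
  a <- (D^2 + r1^2 - r2^2) / (2 * D)
  h <- sqrt(max(0, r1^2 - a^2))
  center <- c1 + a * u
  w <- p - center
  w <- w - sum(w * u) * u
  nw <- sqrt(sum(w^2))
  if (nw < 1e-9) {
    w <- c(u[2], -u[1], 0)
    if (sum(w^2) < 1e-9) w <- c(0, u[3], -u[2])
    nw <- sqrt(sum(w^2))
  }
  center + h * w / nw
}

# Gauss-Seidel bond-length restoration; `pinned` atoms never move. Movable
# atoms bonded to exactly two pinned partners (loop-junction backbone atoms)
# are placed exactly on the intersection of the two bond spheres, where
# plain relaxation converges too slowly near tangency.
restore_bonds <- function(X, bonds_i, bonds_j, lens, pinned, iters = 400) {
  pin <- rep(FALSE, nrow(X))
  pin[pinned] <- TRUE
  for (a in setdiff(seq_len(nrow(X)), pinned)) {
    kb <- which(bonds_i == a | bonds_j == a)
    partners <- ifelse(bonds_i[kb] == a, bonds_j[kb], bonds_i[kb])
    pp <- kb[pin[partners]]
    if (length(pp) == 2) {
      q <- ifelse(bonds_i[pp] == a, bonds_j[pp], bonds_i[pp])
      X[a, ] <- solve_two_spheres(X[a, ], X[q[1], ], lens[pp[1]],
                                  X[q[2], ], lens[pp[2]])
    }
  }
  for (it in seq_len(iters)) {
    for (b in seq_along(bonds_i)) {
      i <- bonds_i[b]; j <- bonds_j[b]
      if (pin[i] && pin[j]) next
      dvec <- X[i, ] - X[j, ]
      d <- sqrt(sum(dvec^2))
      if (d < 1e-9) next
      err <- d - lens[b]
      if (abs(err) < 1e-6) next
      u <- dvec / d
      if (pin[i]) {
        X[j, ] <- X[j, ] + err * u
      } else if (pin[j]) {
        X[i, ] <- X[i, ] - err * u
      } else {
        X[i, ] <- X[i, ] - err / 2 * u
        X[j, ] <- X[j, ] + err / 2 * u
      }
    }
  }
  X
}

build_hairpin_residues <- function(n_strand, loop_length) {
  p <- BB$pitch
  m <- c(0, cos(BB$rho), sin(BB$rho))  # residue-plane normal direction
  # strand residues alternate orientation as in a real antiparallel sheet:
  # odd residues present both their carbonyl O and their N-H side to the
  # partner strand, even residues face away
  s1 <- vector("list", n_strand)
  N <- c(0, 0, 0)
  for (i in seq_len(n_strand)) {
    sig <- if (i %% 2 == 1) 1 else -1
    s1[[i]] <- place_residue(N, c(1, 0, 0), sig * m)
    N <- s1[[i]]$next_N
  }
  loop_start_N <- N
  # strand 2 = strand 1 rotated half a turn about y and shifted along x and
  # -z: the rotation is an involution that maps each narrow-rung hydrogen
  # bond onto its partner in the opposite direction, so both ladders share
  # the designed geometry. Facing odd-residue pairs (i, c_rung - i) carry
  # two bonds each.
  c_rung <- 2 * ceiling(n_strand / 2)  # even pairing constant
  Tx <- (c_rung - 2) * p + BB$dx
  rot_y <- function(v) c(-v[1], v[2], -v[3])
  shift <- c(Tx, 0, -BB$tz)
  s2 <- lapply(s1, function(r) lapply(r, function(v) rot_y(v) + shift))
  target <- s2[[1]]$N  # N of strand 2 residue 1
  out_dir <- c(1, 0.6, 0) / sqrt(1.36)  # bulge out of the sheet plane (+y)
  gap_of <- function(b) {
    cc <- chase_curve(loop_start_N, target, loop_length, b, out_dir)
    sqrt(sum((cc$final_N - target)^2))
  }
  opt <- stats::optimize(gap_of, interval = c(0, 8 + 2 * loop_length))
  cc <- chase_curve(loop_start_N, target, loop_length, opt$minimum, out_dir)
  rungs_i <- seq(max(1, c_rung - n_strand), n_strand, by = 2)
  rungs_i <- rungs_i[rungs_i %% 2 == 1 & (c_rung - rungs_i) >= 1 &
                       (c_rung - rungs_i) <= n_strand]
  list(s1 = s1, loop = cc$residues, s2 = s2, closure_gap = opt$objective,
       Tx = Tx, Tz = BB$tz, c_rung = c_rung, rungs_i = rungs_i)
}

#' Build a hairpin scaffold with a designed hydrogen-bond ladder
#'
#' Two antiparallel glycine strands at ideal backbone geometry joined by a
#' loop. Odd-numbered residues of facing strands form "narrow rungs"
#' carrying two backbone hydrogen bonds each, both at the ideal scoring
#' distance (2.9 Angstrom) perpendicular to the strand axis, scoring about
#' -7.5 kcal/mol in the clamped-well model. The loop closes the chain with
#' near-ideal peptide bonds and, carrying no strong polar partners, stays
#' flexible at any sensible energy cutoff.
#'
#' @param spec a [toy_spec()].
#' @return A `tcr_structure` with a `"ground_truth"` attribute: designed
#'   hydrogen-bond count and donor/acceptor residue pairs (chain numbering),
#'   loop residue range, closure gap.
#' @export
make_hairpin_scaffold <- function(spec = toy_spec()) {
  set.seed(spec$seed)
  n_strand <- spec$n_core_residues / 2
  hp <- build_hairpin_residues(n_strand, spec$loop_length)
  res_list <- c(hp$s1, hp$loop, hp$s2)
  at <- atoms_df(res_list)
  s <- new_structure(at, id = sprintf("hairpin_n%d_l%d", spec$n_core_residues,
                                      spec$loop_length))
  # distribute any residual loop-closure error: re-idealise bonds and push
  # apart any scrunched loop atoms, strand atoms pinned throughout
  bonds <- infer_covalent_bonds_geometryless(s)
  X <- coords_matrix(s)
  strand_atoms <- which(at$res_seq <= n_strand |
                          at$res_seq > n_strand + spec$loop_length)
  X <- repair_loop_geometry(X, bonds, strand_atoms, at)
  s <- set_coords(s, X)
  s <- set_coords(s, twist_about_x(coords_matrix(s), center = c(0, -hp$Tz / 2)))
  loop_res <- c(n_strand + 1, n_strand + spec$loop_length)
  s2_offset <- n_strand + spec$loop_length
  pairs <- rbind(
    data.frame(donor_res = hp$rungs_i,                      # s1 N -> s2 O
               acceptor_res = s2_offset + hp$c_rung - hp$rungs_i),
    data.frame(donor_res = s2_offset + hp$c_rung - hp$rungs_i,  # s2 N -> s1 O
               acceptor_res = hp$rungs_i)
  )
  attr(s, "ground_truth") <- list(
    designed_hbonds = nrow(pairs),
    hbond_pairs = pairs,
    loop_range = loop_res,
    closure_gap = hp$closure_gap,
    n_strand = n_strand
  )
  s
}

# bond restoration interleaved with steric separation for the loop region;
# pinned atoms (the strands) never move
repair_loop_geometry <- function(X, bonds, pinned, at, rounds = 6) {
  n <- nrow(X)
  free <- setdiff(seq_len(n), pinned)
  if (length(free) == 0) return(X)
  floors <- outer(ifelse(at$element == "N", 1.55,
                  ifelse(at$element == "O", 1.52, 1.7)),
                  ifelse(at$element == "N", 1.55,
                  ifelse(at$element == "O", 1.52, 1.7)), "+") * 0.9
  near_bond <- matrix(FALSE, n, n)
  for (b in seq_along(bonds$i)) near_bond[bonds$i[b], bonds$j[b]] <-
    near_bond[bonds$j[b], bonds$i[b]] <- TRUE
  # extend exclusion to 1-3 pairs
  nb13 <- near_bond %*% near_bond > 0
  excl <- near_bond | nb13 | diag(TRUE, n)
  for (r in seq_len(rounds)) {
    X <- restore_bonds(X, bonds$i, bonds$j, bonds$len, pinned, iters = 30)
    d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * X %*% t(X)
    hit <- which(d2 < floors^2 & !excl & upper.tri(d2), arr.ind = TRUE)
    if (nrow(hit) == 0 && r > 1) break
    for (h in seq_len(nrow(hit))) {
      i <- hit[h, 1]; j <- hit[h, 2]
      if (i %in% pinned && j %in% pinned) next
      dvec <- X[i, ] - X[j, ]
      d <- sqrt(sum(dvec^2))
      u <- if (d < 1e-9) c(0, 0, 1) else dvec / d
      push <- floors[i, j] - d
      if (i %in% pinned) {
        X[j, ] <- X[j, ] - push * u
      } else if (j %in% pinned) {
        X[i, ] <- X[i, ] + push * u
      } else {
        X[i, ] <- X[i, ] + push / 2 * u
        X[j, ] <- X[j, ] - push / 2 * u
      }
    }
  }
  restore_bonds(X, bonds$i, bonds$j, bonds$len, pinned, iters = 50)
}

# template bond list with ideal lengths, independent of coordinates (used
# during construction, before geometry is final)
infer_covalent_bonds_geometryless <- function(structure) {
  at <- structure$atoms
  idx <- function(res, nm) {
    which(at$res_seq == res & at$name == nm)[1]
  }
  bi <- integer(0); bj <- integer(0); bl <- numeric(0)
  for (r in unique(at$res_seq)) {
    add <- function(n1, n2, l) {
      i <- idx(r, n1); j <- idx(r, n2)
      if (!is.na(i) && !is.na(j)) { bi <<- c(bi, i); bj <<- c(bj, j); bl <<- c(bl, l) }
    }
    add("N", "CA", BB$n_ca); add("CA", "C", BB$ca_c); add("C", "O", BB$c_o)
    jn <- idx(r + 1, "N"); jc <- idx(r, "C")
    if (!is.na(jn) && !is.na(jc)) { bi <- c(bi, jc); bj <- c(bj, jn); bl <- c(bl, BB$c_n) }
  }
  list(i = bi, j = bj, len = bl)
}

#' Displace a loop to build a conformer pair with known apex shift
#'
#' The second conformer displaces the loop's residues perpendicular to the
#' sheet plane with a sine-bump profile (endpoints fixed, apex moving
#' exactly `displacement` Angstrom); backbone bond lengths along the loop
#' are then re-idealised with all CA atoms pinned, so the designed CA
#' displacements are exact.
#'
#' @param base a `tcr_structure`.
#' @param loop one-row loop definition on `base`.
#' @param displacement apex CA displacement in Angstrom.
#' @param seed recorded seed (construction is deterministic).
#' @return List of two `tcr_structure`s (`base`, displaced copy).
#' @export
make_conformer_pair <- function(base, loop, displacement, seed = 1L) {
  set.seed(seed)
  at <- base$atoms
  rng <- seq(loop$start, loop$end)
  L <- length(rng)
  # apex = median loop residue (lower median for even length)
  apex_pos <- if (L %% 2 == 0) L / 2 else ceiling(L / 2)
  w <- sin(pi * seq_len(L) / (L + 1))
  w <- w / w[apex_pos]
  # reachability: consecutive CA separations after the bump must stay within
  # the span of the three connecting bonds
  steps <- abs(diff(c(0, w, 0))) * displacement
  max_span <- BB$ca_c + BB$c_n + BB$n_ca - 0.08
  if (displacement > 0 &&
      any(sqrt(BB$pitch^2 + steps^2) > max_span)) {
    stop("displacement ", displacement,
         " A geometrically unreachable for a ", L, "-residue loop")
  }
  X <- coords_matrix(base)
  sel_chain <- at$chain_id == loop$chain_id
  for (k in seq_len(L)) {
    rows <- which(sel_chain & at$res_seq == rng[k])
    X[rows, 2] <- X[rows, 2] + w[k] * displacement
  }
  if (displacement > 0) {
    bonds <- infer_covalent_bonds(base)
    # the loop relaxes back onto ideal bond lengths with the apex CA (the
    # designed displacement) and every base atom pinned; edge loop residues
    # may adjust slightly where the bump would overstretch a junction
    apex_ca <- which(sel_chain & at$res_seq == rng[apex_pos] & at$name == "CA")
    pinned <- c(apex_ca, which(!(sel_chain & at$res_seq %in% rng)))
    X <- restore_bonds(X, bonds$i, bonds$j, bonds$length, pinned = pinned)
  }
  moved <- set_coords(base, X)
  moved$id <- paste0(base$id, "_shift", displacement)
  list(base, moved)
}

#' Build a two-domain chain with a flexible linker
#'
#' Two hairpin domains joined by an extended ten-residue glycine linker.
#' The linker acts as a hinge: the lowest nontrivial elastic-network mode
#' is dominated by relative domain motion.
#'
#' @param spec a [toy_spec()] with `two_domain = TRUE`.
#' @param loop_length2 loop length of the second domain (defaults to the
#'   first domain's); a longer second loop emulates the longer somatically
#'   rearranged CDR3 loops next to short germline loops.
#' @return A `tcr_structure`; the `"ground_truth"` attribute records the
#'   residue ranges of the two domains, their loops, and the linker.
#' @export
make_two_domain_chain <- function(spec = toy_spec(two_domain = TRUE),
                                  loop_length2 = spec$loop_length) {
  if (!spec$two_domain) stop("spec$two_domain must be TRUE")
  set.seed(spec$seed)
  n_strand <- spec$n_core_residues / 2
  n_linker <- 10L
  hp <- build_hairpin_residues(n_strand, spec$loop_length)
  d1 <- c(hp$s1, hp$loop, hp$s2)
  # extended linker continuing from domain 1's C terminus along -x; a
  # gentle helical wiggle keeps the thin chain elastically well-conditioned
  # in all three directions while leaving it the softest part of the chain
  N <- d1[[length(d1)]]$next_N
  linker <- vector("list", n_linker)
  for (k in seq_len(n_linker)) {
    phase <- 1.6 * k
    t_k <- c(-1, 1.2 * cos(phase), 1.2 * sin(phase))
    n_k <- c(0, -sin(phase), cos(phase))
    linker[[k]] <- place_residue(N, t_k, n_k)
    N <- linker[[k]]$next_N
  }
  # domain 2: a hairpin rotated half a turn about z so it extends away
  # from domain 1, translated so its first N continues the chain exactly
  rot <- function(v) c(-v[1], -v[2], v[3])
  hp2 <- build_hairpin_residues(n_strand, loop_length2)
  d2_raw <- c(hp2$s1, hp2$loop, hp2$s2)
  origin <- rot(d2_raw[[1]]$N)
  shift <- N - origin
  d2 <- lapply(d2_raw, function(r) {
    lapply(r, function(v) rot(v) + shift)
  })
  res_list <- c(d1, linker, d2)
  at <- atoms_df(res_list)
  s <- new_structure(at, id = "two_domain")
  s <- set_coords(s, twist_about_x(coords_matrix(s), center = c(0, -hp$Tz / 2)))
  nd <- 2 * n_strand + spec$loop_length
  nd2 <- 2 * n_strand + loop_length2
  d2_start <- nd + n_linker + 1
  attr(s, "ground_truth") <- list(
    domain1 = c(1, nd), linker = c(nd + 1, nd + n_linker),
    domain2 = c(d2_start, nd + n_linker + nd2),
    loop1 = c(n_strand + 1, n_strand + spec$loop_length),
    loop2 = c(d2_start + n_strand, d2_start + n_strand + loop_length2 - 1)
  )
  s
}

#' Place a scaffold in a P1 cell with one designed lattice contact
#'
#' The cell's a-axis is solved so the closest atom pair between the
#' asymmetric unit and its +a lattice image sits at exactly the designed
#' distance (3.8 Angstrom by default, inside the 4.0 Angstrom contact rule);
#' the b and c axes are padded so no other image approaches within 4.5
#' Angstrom.
#'
#' @param spec a [toy_spec()]; the generated scaffold is the hairpin.
#' @param contact_distance designed inter-image distance (default 3.8).
#' @return A `tcr_structure` with P1 cell metadata; `"ground_truth"` records
#'   the designed pair and distance.
#' @export
make_lattice_fixture <- function(spec = toy_spec(), contact_distance = 3.8) {
  s <- make_hairpin_scaffold(spec)
  # add a C-terminal carboxylate oxygen protruding away from the molecule:
  # it carries the designed contact and separates it cleanly (> 0.7 A) from
  # the next-closest inter-image pair
  at <- s$atoms
  last_c <- which(at$res_seq == max(at$res_seq) & at$name == "C")
  ctr <- colMeans(as.matrix(at[, c("x", "y", "z")]))
  u <- unlist(at[last_c, c("x", "y", "z")]) - ctr
  u <- u / sqrt(sum(u^2))
  oxt <- at[last_c, ]
  oxt$serial <- max(at$serial) + 1L
  oxt$name <- "OXT"; oxt$element <- "O"
  oxt[, c("x", "y", "z")] <- at[last_c, c("x", "y", "z")] + 1.25 * u
  s <- new_structure(rbind(at, oxt), id = s$id, cell = s$cell,
                     space_group = s$space_group)
  attr(s, "ground_truth") <- attr(make_hairpin_scaffold(spec), "ground_truth")
  X <- coords_matrix(s)
  # shift into the positive octant
  X <- sweep(X, 2, apply(X, 2, min) - 5)
  s <- set_coords(s, X)
  min_image_dist <- function(a) {
    shifted <- X
    shifted[, 1] <- shifted[, 1] + a
    d2 <- outer(rowSums(X^2), rowSums(shifted^2), "+") - 2 * X %*% t(shifted)
    sqrt(max(0, min(d2)))
  }
  span <- max(X[, 1]) - min(X[, 1])
  f <- function(a) min_image_dist(a) - contact_distance
  a_cell <- stats::uniroot(f, c(span - 2, span + 2 * contact_distance + 10),
                           tol = 1e-10)$root
  b_cell <- max(X[, 2]) - min(X[, 2]) + 12
  c_cell <- max(X[, 3]) - min(X[, 3]) + 12
  s$cell <- c(a = a_cell, b = b_cell, c = c_cell,
              alpha = 90, beta = 90, gamma = 90)
  s$space_group <- "P 1"
  # identify the designed pair
  shifted <- X
  shifted[, 1] <- shifted[, 1] + a_cell
  d2 <- outer(rowSums(X^2), rowSums(shifted^2), "+") - 2 * X %*% t(shifted)
  pair <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
  gt <- attr(s, "ground_truth")
  gt$contact_pair <- unname(pair)
  gt$contact_distance <- sqrt(min(d2))
  attr(s, "ground_truth") <- gt
  s
}

#' Write the ground-truth sidecar of a synthetic structure
#' @param structure a structure carrying a `"ground_truth"` attribute.
#' @param path output TSV path.
#' @export
write_ground_truth_tsv <- function(structure, path) {
  gt <- attr(structure, "ground_truth")
  if (is.null(gt)) stop("structure carries no ground truth")
  flat <- lapply(gt, function(v) {
    if (is.data.frame(v)) paste(apply(v, 1, paste, collapse = ":"), collapse = ";")
    else paste(v, collapse = ";")
  })
  df <- data.frame(key = names(flat), value = unlist(flat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
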