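# shared fixtures (cached: the pipeline stages are reused by many tests)
# and independent oracles

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

hairpin_fx <- function(n_core = 8, loop = 4, seed = 1) {
  cached(sprintf("hairpin_%d_%d_%d", n_core, loop, seed),
         make_hairpin_scaffold(toy_spec(n_core, loop, seed = seed)))
}

# network -> decomposition -> templates for a structure, cached by id
flex_stack <- function(structure, e_cut = -3, key = structure$id) {
  cached(paste0("stack_", key, "_", e_cut), {
    net <- apply_energy_cutoff(build_constraint_network(structure,
                                                        network_params()), e_cut)
    dec <- pebble_game(net)
    tpl <- build_templates(structure, dec, net)
    list(net = net, dec = dec, tpl = tpl)
  })
}

# --- independent oracle: quaternion (Horn) absolute-orientation fit --------
quaternion_superpose_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(A, B)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  ss <- sum(A^2) + sum(B^2) - 2 * lam
  sqrt(max(0, ss) / nrow(mobile))
}

# --- independent oracle: body-bar constraint-matrix numerical rank ---------
# each bar between bodies u, v is realised as a generic bar between random
# attachment points; the generic rank of the resulting Jacobian equals the
# body-bar matroid rank, so floppy modes = 6 N - rank
bar_multiplicity_tbl <- c(covalent_single = 5L, covalent_locked = 6L,
                          hbond = 5L, tether = 2L)

body_bar_floppy_oracle <- function(n, edges_i, edges_j, bars, seed = 1,
                                   coords = NULL) {
  set.seed(seed)
  if (is.null(coords)) coords <- matrix(rnorm(3 * n, sd = 5), n, 3)
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  rows <- list()
  for (k in seq_along(edges_i)) {
    u <- edges_i[k]; v <- edges_j[k]
    for (b in seq_len(bars[k])) {
      a <- coords[u, ] + rnorm(3)
      p <- coords[v, ] + rnorm(3)
      d <- a - p
      row <- numeric(6 * n)
      row[(6 * u - 5):(6 * u)] <- c(d, cross3(a, d))
      row[(6 * v - 5):(6 * v)] <- -c(d, cross3(p, d))
      rows[[length(rows) + 1]] <- row
    }
  }
  M <- do.call(rbind, rows)
  6L * n - qr(M, tol = 1e-7)$rank
}

floppy_oracle_for_network <- function(net, seed = 1) {
  body_bar_floppy_oracle(net$n_atoms, net$edges$i, net$edges$j,
                         bar_multiplicity_tbl[net$edges$kind], seed = seed,
                         coords = as.matrix(net$structure$atoms[, c("x", "y", "z")]))
}

# --- small handcrafted structures ------------------------------------------
atom_row <- function(serial, name, element, chain, res_name, res_seq, x, y, z,
                     occupancy = 1, b = 0) {
  data.frame(serial = serial, name = name, element = element, alt_loc = "",
             chain_id = chain, res_name = res_name, res_seq = res_seq,
             insertion_code = "", x = x, y = y, z = z,
             occupancy = occupancy, b_factor = b, stringsAsFactors = FALSE)
}

# single glycine at plausible geometry
glycine_structure <- function() {
  new_structure(rbind(
    atom_row(1, "N", "N", "A", "GLY", 1, 0, 0, 0),
    atom_row(2, "CA", "C", "A", "GLY", 1, 1.46, 0, 0),
    atom_row(3, "C", "C", "A", "GLY", 1, 2.0, 1.4, 0),
    atom_row(4, "O", "O", "A", "GLY", 1, 1.5, 2.5, 0)
  ), id = "gly")
}

# anchored obstacle cage in the path of the most mobile core atom of a
# baseline run; returns structure + obstacle atom indices (in the filtered
# network ordering, chain B sorts after chain A with equal safety)
obstacle_fixture <- function() {
  cached("obstacle_fixture", {
    s <- hairpin_fx(8, 4)
    st <- flex_stack(s)
    ms <- enm_modes(st$net$structure, enm_params(n_nontrivial_modes = 4))
    field <- expand_mode_to_atoms(ms, 7, st$net$structure)
    p <- sim_params(max_frames = 400, step_size = 0.05)
    base <- run_geometric_simulation(s, st$tpl, st$net, field, 1, p,
                                     mode_index = 7)
    X0 <- as.matrix(st$net$structure$atoms[, c("x", "y", "z")])
    XF <- base$frames[[length(base$frames)]]
    disp <- sqrt(rowSums((XF - X0)^2))
    core <- which(st$dec$cluster_of == 1)
    ia <- core[which.max(disp[core])]
    ctr <- X0[ia, ] + 0.5 * (XF[ia, ] - X0[ia, ])
    offs <- as.matrix(expand.grid(x = c(-1.5, 0, 1.5), y = c(-1.5, 0, 1.5),
                                  z = c(-1.5, 0, 1.5)))
    obs <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k) {
      atom_row(max(s$atoms$serial) + k, "SG", "S", "B", "CYS", k,
               ctr[1] + offs[k, 1], ctr[2] + offs[k, 2], ctr[3] + offs[k, 3])
    }))
    s2 <- new_structure(rbind(s$atoms, obs), id = "hairpin_obstructed")
    net <- apply_energy_cutoff(build_constraint_network(s2, network_params()), -3)
    dec <- pebble_game(net)
    tpl <- build_templates(s2, dec, net)
    ms2 <- suppressWarnings(enm_modes(net$structure,
                                      enm_params(n_nontrivial_modes = 4)))
    f2 <- expand_mode_to_atoms(ms2, 7, net$structure, allow_missing = TRUE)
    list(structure = s2, net = net, dec = dec, tpl = tpl, field = f2,
         anchors = which(net$structure$atoms$chain_id == "B"),
         free = list(structure = s, net = st$net, tpl = st$tpl, field = field),
         sim = p)
  })
}

# published reference tables bundled with the package
ref_table <- function(name) {
  utils::read.delim(system.file("extdata", name, package = "tcrflex"),
                    stringsAsFactors = FALSE)
}
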