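# brute-force violation recomputation used as oracle for check_constraints
brute_violations <- function(X, net, params) {
  edges <- net$edges
  X0 <- as.matrix(net$structure$atoms[, c("x", "y", "z")])
  dist_of <- function(i, j, M) sqrt(sum((M[i, ] - M[j, ])^2))
  cov <- edges[edges$kind %in% c("covalent_single", "covalent_locked"), ]
  max_cov <- 0
  for (k in seq_len(nrow(cov))) {
    max_cov <- max(max_cov, abs(dist_of(cov$i[k], cov$j[k], X) - cov$length[k]))
  }
  nc <- edges[edges$kind %in% c("hbond", "tether"), ]
  max_win <- 0
  for (k in seq_len(nrow(nc))) {
    max_win <- max(max_win, abs(dist_of(nc$i[k], nc$j[k], X) - nc$length[k]) -
                     params$relax_tolerance)
  }
  list(max_cov = max_cov, max_win = max(0, max_win))
}

test_that("a fully rigid toy yields a single template containing all atoms", {
  net <- structure(list(
    structure = glycine_structure(),
    edges = data.frame(i = c(1, 2, 3), j = c(2, 3, 4), kind = "covalent_locked",
                       energy = NA_real_, length = c(1.46, 1.51, 1.22)),
    params = network_params(), n_atoms = 4), class = "constraint_network")
  dec <- pebble_game(net)
  expect_equal(length(dec$cluster_sizes), 1)
  tpl <- build_templates(net$structure, dec, net)
  expect_length(tpl, 1)
  expect_equal(tpl[[1]]$atoms, 1:4)
})

test_that("a dipeptide with one rotatable bond gives two templates sharing its atoms", {
  # two rigid bodies (locked triangles) joined by one rotatable bond 3-4
  at <- do.call(rbind, lapply(1:6, function(i) {
    atom_row(i, "CA", "C", "A", "GLY", i, i * 1.4, (i %% 2) * 1.1, (i %% 3) * 0.4)
  }))
  s <- new_structure(at, id = "hinge")
  mklen <- function(i, j) sqrt(sum((as.matrix(at[, c("x", "y", "z")])[i, ] -
                                      as.matrix(at[, c("x", "y", "z")])[j, ])^2))
  e <- data.frame(i = c(1, 2, 1, 3, 4, 5, 4),
                  j = c(2, 3, 3, 4, 5, 6, 6),
                  kind = c(rep("covalent_locked", 3), "covalent_single",
                           rep("covalent_locked", 3)),
                  energy = NA_real_, length = NA_real_)
  e$length <- mapply(mklen, e$i, e$j)
  net <- structure(list(structure = s, edges = e, params = network_params(),
                        n_atoms = 6), class = "constraint_network")
  dec <- pebble_game(net)
  tpl <- build_templates(s, dec, net)
  expect_length(tpl, 2)
  shared <- intersect(tpl[[1]]$atoms, tpl[[2]]$atoms)
  expect_setequal(shared, c(3, 4))  # the rotatable bond's atoms
  # template internal distances equal the input-structure distances
  for (t in tpl) {
    expect_equal(as.matrix(dist(t$ref)),
                 as.matrix(dist(as.matrix(at[t$atoms, c("x", "y", "z")]))),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("a zero mode field leaves the structure unchanged and completes", {
  s <- hairpin_fx(8, 4)
  st <- flex_stack(s)
  field <- matrix(0, nrow(s$atoms), 3)
  ens <- run_geometric_simulation(s, st$tpl, st$net, field, 1,
                                  sim_params(max_frames = 120), mode_index = 0)
  expect_equal(ens$termination, "completed")
  expect_equal(ens$amplitude, 0)
  X0 <- as.matrix(st$net$structure$atoms[, c("x", "y", "z")])
  for (f in ens$frames) expect_equal(f, X0, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("every stored frame satisfies the constraints within tolerance", {
  s <- hairpin_fx(8, 4)
  st <- flex_stack(s)
  ms <- enm_modes(st$net$structure, enm_params(n_nontrivial_modes = 4))
  p <- sim_params(max_frames = 250)
  for (dir in c(1, -1)) {
    field <- expand_mode_to_atoms(ms, 7, st$net$structure)
    ens <- run_geometric_simulation(s, st$tpl, st$net, field, dir, p,
                                    mode_index = 7)
    expect_true(all(ens$diagnostics$max_bond_deviation < p$relax_tolerance))
    expect_true(all(ens$diagnostics$min_steric_gap >= 0))
    expect_true(all(diff(ens$diagnostics$amplitude) >= 0))
    for (f in ens$frames) {
      chk <- check_constraints(f, st$net, st$tpl, p)
      expect_lt(chk$max_covalent_deviation, p$relax_tolerance)
      expect_lte(chk$max_steric_penetration, 0 + 1e-9)
    }
  }
})

test_that("runs are deterministic for fixed seed and inputs", {
  s <- hairpin_fx(8, 4)
  st <- flex_stack(s)
  ms <- enm_modes(st$net$structure, enm_params(n_nontrivial_modes = 4))
  field <- expand_mode_to_atoms(ms, 8, st$net$structure)
  p <- sim_params(max_frames = 150, seed = 11)
  a <- run_geometric_simulation(s, st$tpl, st$net, field, 1, p, mode_index = 8)
  b <- run_geometric_simulation(s, st$tpl, st$net, field, 1, p, mode_index = 8)
  expect_identical(a$termination, b$termination)
  expect_identical(a$n_frames, b$n_frames)
  expect_identical(a$frames, b$frames)
})

test_that("parallel and antiparallel amplitudes agree within 5% on the hairpin", {
  s <- hairpin_fx(8, 4)
  st <- flex_stack(s)
  ms <- enm_modes(st$net$structure, enm_params(n_nontrivial_modes = 4))
  field <- expand_mode_to_atoms(ms, 7, st$net$structure)
  p <- sim_params(max_frames = 250)
  plus <- run_geometric_simulation(s, st$tpl, st$net, field, 1, p, mode_index = 7)
  minus <- run_geometric_simulation(s, st$tpl, st$net, field, -1, p, mode_index = 7)
  expect_lt(abs(plus$amplitude - minus$amplitude) /
              max(plus$amplitude, minus$amplitude), 0.05)
})

test_that("an anchored obstacle in the motion path jams the run at smaller amplitude", {
  fx <- obstacle_fixture()
  free <- run_geometric_simulation(fx$free$structure, fx$free$tpl, fx$free$net,
                                   fx$free$field, 1,
                                   sim_params(max_frames = 1200, step_size = 0.05),
                                   mode_index = 7)
  blocked <- run_geometric_simulation(fx$structure, fx$tpl, fx$net, fx$field, 1,
                                      sim_params(max_frames = 1200, step_size = 0.05),
                                      mode_index = 7, anchors = fx$anchors)
  expect_equal(blocked$termination, "jammed")
  expect_lt(blocked$amplitude, free$amplitude)
})

test_that("variant selection returns the final frame of each (mode, direction) run", {
  s <- hairpin_fx(8, 4)
  st <- flex_stack(s)
  ms <- enm_modes(st$net$structure, enm_params(n_nontrivial_modes = 3))
  ens <- run_all_modes(st$net$structure, st$net, st$tpl, ms,
                       sim_params(max_frames = 60))
  expect_length(ens, 6)  # 3 modes x 2 directions
  variants <- select_extreme_variants(ens)
  expect_length(variants, 6)
  for (k in seq_along(ens)) {
    expect_identical(variants[[k]]$coords, ens[[k]]$frames[[length(ens[[k]]$frames)]])
    expect_identical(variants[[k]]$amplitude, ens[[k]]$amplitude)
  }
  expect_error(select_extreme_variants(ens[-1]), "missing direction")
  expect_error(select_extreme_variants(c(ens, ens[1])), "duplicate")
})

test_that("check_constraints reports the input structure as violation-free", {
  s <- hairpin_fx(8, 4)
  st <- flex_stack(s)
  X0 <- as.matrix(st$net$structure$atoms[, c("x", "y", "z")])
  chk <- check_constraints(X0, st$net, st$tpl, sim_params())
  expect_equal(chk$n_violations, 0L)
  expect_equal(chk$max_covalent_deviation, 0, tolerance = 1e-12)
  expect_equal(chk$max_window_violation, 0)
})

test_that("a single stretched bond is reported as exactly one covalent violation", {
  s <- hairpin_fx(8, 4)
  st <- flex_stack(s)
  X <- as.matrix(st$net$structure$atoms[, c("x", "y", "z")])
  at <- st$net$structure$atoms
  # stretch the terminal carbonyl C=O by +0.5 A along the bond
  ci <- which(at$res_seq == 12 & at$name == "C")
  oi <- which(at$res_seq == 12 & at$name == "O")
  u <- (X[oi, ] - X[ci, ]) / sqrt(sum((X[oi, ] - X[ci, ])^2))
  X[oi, ] <- X[oi, ] + 0.5 * u
  chk <- check_constraints(X, st$net, st$tpl, sim_params())
  expect_equal(chk$max_covalent_deviation, 0.5, tolerance = 1e-9)
  cov <- st$net$edges[st$net$edges$kind %in% c("covalent_single", "covalent_locked"), ]
  dists <- sqrt(rowSums((X[cov$i, ] - X[cov$j, ])^2))
  expect_equal(sum(abs(dists - cov$length) > 0.1), 1)
  # and the report agrees with an independent recomputation
  bv <- brute_violations(X, st$net, sim_params())
  expect_equal(chk$max_covalent_deviation, bv$max_cov, tolerance = 1e-12)
  expect_equal(chk$max_window_violation, bv$max_win, tolerance = 1e-12)
})
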