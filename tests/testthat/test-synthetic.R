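test_that("generators are seed-deterministic and PDB round-trippable", {
  a <- make_hairpin_scaffold(toy_spec(8, 4, seed = 3))
  b <- make_hairpin_scaffold(toy_spec(8, 4, seed = 3))
  expect_identical(a$atoms, b$atoms)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(a, f)
  rt <- read_pdb(f)
  expect_lt(max(abs(as.matrix(rt$atoms[, c("x", "y", "z")]) -
                      as.matrix(a$atoms[, c("x", "y", "z")]))), 1e-3 + 1e-9)
  td1 <- make_two_domain_chain(toy_spec(8, 3, two_domain = TRUE, seed = 5))
  td2 <- make_two_domain_chain(toy_spec(8, 3, two_domain = TRUE, seed = 5))
  expect_identical(td1$atoms, td2$atoms)
})

test_that("the hairpin scaffold has the designed size and bond counts", {
  s <- make_hairpin_scaffold(toy_spec(8, 4))
  expect_equal(length(unique(s$atoms$res_seq)), 12)  # 2 x 4 strand + 4 loop
  gt <- attr(s, "ground_truth")
  expect_equal(gt$designed_hbonds, 4)  # two bonds per narrow rung, two rungs
  bonds <- infer_covalent_bonds(s)
  # every consecutive residue pair is peptide-bonded (closed chain)
  pept <- bonds[bonds$kind == "covalent_locked" &
                  s$atoms$name[bonds$i] == "C" & s$atoms$name[bonds$j] == "N", ]
  expect_equal(nrow(pept), 11)
})

test_that("conformer pairs realise the designed displacement exactly", {
  s <- make_hairpin_scaffold(toy_spec(12, 7))
  loop <- data.frame(loop_name = "L1", chain_id = "A", start = 7, end = 13)
  pair <- make_conformer_pair(s, loop, 2.5)
  prof <- per_residue_displacement(pair[[1]], pair[[2]], c(1:6, 14:19), 7:13, "A")
  expect_equal(attr(prof, "max_displacement"), 2.5, tolerance = 0.01)
  # zero displacement leaves the structure identical
  same <- make_conformer_pair(s, loop, 0)
  expect_equal(same[[1]]$atoms, same[[2]]$atoms, ignore_attr = TRUE)
  # base residues never move
  at <- s$atoms
  base_rows <- which(!(at$res_seq %in% 7:13))
  expect_equal(as.matrix(pair[[2]]$atoms[base_rows, c("x", "y", "z")]),
               as.matrix(at[base_rows, c("x", "y", "z")]), tolerance = 1e-12,
               ignore_attr = TRUE)
  # bond lengths along the loop are re-idealised
  b0 <- infer_covalent_bonds(pair[[1]])
  b1 <- infer_covalent_bonds(pair[[2]])
  expect_equal(b1$length, b0$length, tolerance = 0.02)
})

test_that("unreachable displacements raise a reachability error", {
  s <- make_hairpin_scaffold(toy_spec(8, 4))
  loop <- data.frame(loop_name = "L1", chain_id = "A", start = 5, end = 8)
  expect_error(make_conformer_pair(s, loop, 25), "unreachable")
})

test_that("the two-domain chain is a connected network whose softest mode is interdomain", {
  td <- cached("td_syn", make_two_domain_chain(toy_spec(8, 3, two_domain = TRUE)))
  gt <- attr(td, "ground_truth")
  ms <- enm_modes(td, enm_params())
  expect_true(all(abs(ms$all_eigenvalues[1:6]) < 1e-8 * ms$all_eigenvalues[7]))
  # project mode 7 onto the joint rigid-motion space of the two domains:
  # most of its norm is relative domain motion
  sites <- ms$sites
  ca <- extract_calpha(td, "A")
  X <- as.matrix(ca[match(sites$res_seq, ca$res_seq), c("x", "y", "z")])
  n <- nrow(sites)
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  rigid_basis <- function(sel) {
    B <- matrix(0, 3 * n, 6)
    ctr <- colMeans(X[sel, , drop = FALSE])
    for (k in 1:3) {
      v <- matrix(0, n, 3); v[sel, k] <- 1
      B[, k] <- as.vector(t(v))
    }
    ax <- diag(3)
    for (k in 1:3) {
      v <- matrix(0, n, 3)
      v[sel, ] <- t(apply(X[sel, , drop = FALSE], 1,
                          function(p) cross3(ax[k, ], p - ctr)))
      B[, 3 + k] <- as.vector(t(v))
    }
    B
  }
  d1 <- sites$res_seq <= gt$domain1[2]
  d2 <- sites$res_seq >= gt$domain2[1]
  Q <- qr.Q(qr(cbind(rigid_basis(d1), rigid_basis(d2))))
  proj <- sum((t(Q) %*% ms$vectors[, 1])^2)
  expect_gt(proj, 0.5)
})

test_that("simulation along the hinge mode moves the linker more than the domain cores", {
  td <- cached("td_syn", make_two_domain_chain(toy_spec(8, 3, two_domain = TRUE)))
  gt <- attr(td, "ground_truth")
  st <- flex_stack(td, key = "td_syn")
  ms <- enm_modes(st$net$structure, enm_params(n_nontrivial_modes = 2))
  field <- expand_mode_to_atoms(ms, 7, st$net$structure)
  ens <- run_geometric_simulation(td, st$tpl, st$net, field, 1,
                                  sim_params(max_frames = 200), mode_index = 7)
  X0 <- as.matrix(st$net$structure$atoms[, c("x", "y", "z")])
  XF <- ens$frames[[length(ens$frames)]]
  # remove the net rigid drift of domain 1 before comparing local motion
  at <- st$net$structure$atoms
  d1_rows <- which(at$res_seq <= gt$domain1[2])
  fit <- kabsch_superpose(XF[d1_rows, ], X0[d1_rows, ])
  XF <- apply_transform(fit, XF)
  disp <- sqrt(rowSums((XF - X0)^2))
  linker_rows <- which(at$res_seq %in% seq(gt$linker[1], gt$linker[2]))
  core1 <- which(at$res_seq <= 5)  # strand interior of domain 1
  expect_gt(mean(disp[linker_rows]) + mean(disp[which(at$res_seq >= gt$domain2[1])]),
            2 * mean(disp[core1]))
})

test_that("the lattice fixture yields its designed contact and nothing else", {
  lf <- make_lattice_fixture(toy_spec(8, 4))
  gt <- attr(lf, "ground_truth")
  # designed distance recomputed through the fractional symmetry machinery
  ct <- find_crystal_contacts(lf, cutoff = 4.0)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$distance, 3.8, tolerance = 0.01)
  expect_equal(gt$contact_distance, 3.8, tolerance = 0.01)
  # next-closest inter-image pair is beyond 4.5
  ct45 <- find_crystal_contacts(lf, cutoff = 4.5)
  expect_equal(nrow(ct45), 1)
})
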