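test_that("a single glycine yields exactly the backbone template edges", {
  bonds <- infer_covalent_bonds(glycine_structure())
  pairs <- sort(paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j)))
  expect_equal(nrow(bonds), 3)           # N-CA, CA-C, C-O (no CB in glycine)
  expect_equal(pairs, c("1 2", "2 3", "3 4"))
  expect_equal(bonds$kind[bonds$i == 3 & bonds$j == 4], "covalent_locked")
})

test_that("a dipeptide at standard geometry gets one locked peptide bond", {
  s <- hairpin_fx(8, 4)
  two <- new_structure(s$atoms[s$atoms$res_seq %in% 1:2, ], id = "dipeptide")
  bonds <- infer_covalent_bonds(two)
  pept <- bonds[bonds$i == 3 & bonds$j == 5, ]   # C(1) - N(2)
  expect_equal(nrow(pept), 1)
  expect_equal(pept$kind, "covalent_locked")
})

test_that("close SG pairs become disulfide edges and chain breaks warn", {
  at <- rbind(
    atom_row(1, "CA", "C", "A", "CYS", 1, 0, 0, 0),
    atom_row(2, "C", "C", "A", "CYS", 1, 1.0, 1.2, 0),
    atom_row(3, "CB", "C", "A", "CYS", 1, 1.5, -0.2, 0),
    atom_row(4, "SG", "S", "A", "CYS", 1, 2.6, 1.0, 0),
    atom_row(5, "N", "N", "A", "CYS", 10, 8.0, 3.0, 0),
    atom_row(6, "CA", "C", "A", "CYS", 10, 7.0, 3.6, 0),
    atom_row(7, "CB", "C", "A", "CYS", 10, 5.6, 3.1, 0),
    atom_row(8, "SG", "S", "A", "CYS", 10, 4.65, 1.0, 0)
  )
  s <- new_structure(at, id = "ss")
  bonds <- suppressWarnings(infer_covalent_bonds(s))
  ss <- bonds[bonds$i == 4 & bonds$j == 8, ]
  expect_equal(nrow(ss), 1)   # SG-SG at 2.05 A
  expect_lt(abs(ss$length - 2.05), 0.01)
  expect_warning(infer_covalent_bonds(s), "chain break")
  expect_error(infer_covalent_bonds(
    new_structure(atom_row(1, "X1", "C", "A", "LIG", 1, 0, 0, 0))),
    "no covalent template|no standard protein")
})

test_that("hydrogen-bond scoring follows the clamped geometric well", {
  ant <- c(-1.46, 0, 0)
  don <- c(0, 0, 0)
  # ideal: 2.9 A, perfectly linear -> the -10 floor
  expect_equal(score_hydrogen_bond(don, c(2.9, 0, 0), ant), -10)
  # beyond the well -> none
  expect_null(score_hydrogen_bond(don, c(3.6, 0, 0), ant))
  # 45-degree deviation at ideal distance -> -10 cos^2(45) = -5
  acc45 <- 2.9 * c(cos(pi / 4), sin(pi / 4), 0)
  expect_equal(score_hydrogen_bond(don, acc45, ant), -5, tolerance = 1e-9)
  # beyond 60 degrees -> none
  acc70 <- 2.9 * c(cos(70 * pi / 180), sin(70 * pi / 180), 0)
  expect_null(score_hydrogen_bond(don, acc70, ant))
  # salt bridges use a 3.0 A optimum and a 20% bonus capped at -10
  expect_equal(score_hydrogen_bond(don, c(3.0, 0, 0), ant, salt_bridge = TRUE), -10)
  e_sb <- score_hydrogen_bond(don, c(3.3, 0, 0), ant, salt_bridge = TRUE)
  e_hb <- score_hydrogen_bond(don, c(3.2, 0, 0), ant)  # same offset from optimum
  expect_equal(e_sb, max(-10, 1.2 * e_hb), tolerance = 1e-9)
  expect_error(score_hydrogen_bond(don, c(2.9, 0, 0), NULL), "antecedent")
})

test_that("the hairpin's designed ladder is detected with strong energies", {
  s <- hairpin_fx(8, 4)
  gt <- attr(s, "ground_truth")
  hb <- detect_hydrogen_bonds(s)
  at <- s$atoms
  res_of <- function(i) at$res_seq[i]
  in_s1 <- function(r) r <= gt$n_strand
  in_s2 <- function(r) r > gt$loop_range[2]
  ri <- res_of(hb$i); rj <- res_of(hb$j)
  cross <- hb[(in_s1(ri) & in_s2(rj)) | (in_s2(ri) & in_s1(rj)), ]
  # every designed rung bond present, strongly scored; nothing else crosses
  # the strands
  expect_equal(nrow(cross), gt$designed_hbonds)
  expect_true(all(cross$energy <= -5))
  got <- sort(paste(pmin(res_of(cross$i), res_of(cross$j)),
                    pmax(res_of(cross$i), res_of(cross$j))))
  want <- sort(paste(pmin(gt$hbond_pairs$donor_res, gt$hbond_pairs$acceptor_res),
                     pmax(gt$hbond_pairs$donor_res, gt$hbond_pairs$acceptor_res)))
  expect_equal(got, want)
  expect_true(all(hb$energy >= -10 & hb$energy < 0))
})

test_that("a fully extended isolated strand has no hydrogen bonds", {
  s <- hairpin_fx(8, 4)
  strand <- new_structure(s$atoms[s$atoms$res_seq %in% 1:4, ], id = "strand")
  expect_equal(nrow(detect_hydrogen_bonds(strand)), 0)
})

test_that("moving a donor away weakens its bond monotonically to none", {
  s <- hairpin_fx(8, 4)
  gt <- attr(s, "ground_truth")
  donor_res <- gt$hbond_pairs$donor_res[1]
  acceptor_res <- gt$hbond_pairs$acceptor_res[1]
  at <- s$atoms
  di <- which(at$res_seq == donor_res & at$name == "N")
  ai <- which(at$res_seq == acceptor_res & at$name == "O")
  away <- unlist(at[di, c("x", "y", "z")]) - unlist(at[ai, c("x", "y", "z")])
  away <- away / sqrt(sum(away^2))
  energies <- sapply(seq(0, 1, 0.25), function(shift) {
    s2 <- s
    s2$atoms[di, c("x", "y", "z")] <- at[di, c("x", "y", "z")] + shift * away
    hb <- detect_hydrogen_bonds(s2)
    hit <- hb$i == di & hb$j == ai | hb$i == ai & hb$j == di
    if (any(hit)) hb$energy[hit] else 0
  })
  expect_true(all(diff(energies) >= -1e-9))  # |energy| decreasing
  expect_equal(energies[length(energies)], 0)  # gone at +1.0 A
})

test_that("hydrophobic tethers follow the vdW + gap rule for hydrophobic atoms", {
  mk <- function(d) new_structure(rbind(
    atom_row(1, "CD1", "C", "A", "LEU", 1, 0, 0, 0),
    atom_row(2, "CD1", "C", "A", "LEU", 5, d, 0, 0)
  ), id = "pair")
  expect_equal(nrow(detect_hydrophobic_tethers(mk(3.5))), 1)  # 3.5 < 3.65
  expect_equal(nrow(detect_hydrophobic_tethers(mk(3.7))), 0)
})

test_that("leucine side-chain tether count equals a brute-force pair scan", {
  # two leucine side chains interdigitated
  leu <- function(res, base) rbind(
    atom_row(res * 10 + 1, "CB", "C", "A", "LEU", res, base[1], base[2], base[3]),
    atom_row(res * 10 + 2, "CG", "C", "A", "LEU", res, base[1] + 1.3, base[2] + 0.8, base[3]),
    atom_row(res * 10 + 3, "CD1", "C", "A", "LEU", res, base[1] + 2.6, base[2], base[3]),
    atom_row(res * 10 + 4, "CD2", "C", "A", "LEU", res, base[1] + 1.3, base[2] + 2.3, base[3])
  )
  s <- new_structure(rbind(leu(1, c(0, 0, 0)), leu(5, c(0.5, 3.4, 1.2))), id = "leupair")
  th <- detect_hydrophobic_tethers(s)
  # brute force: cross-residue carbon pairs under 2 * 1.7 + 0.25
  X <- as.matrix(s$atoms[, c("x", "y", "z")])
  res <- s$atoms$res_seq
  cnt <- 0
  for (i in 1:7) for (j in (i + 1):8) {
    if (res[i] != res[j] && sqrt(sum((X[i, ] - X[j, ])^2)) < 3.65) cnt <- cnt + 1
  }
  expect_equal(nrow(th), cnt)
  expect_gt(cnt, 0)
})

test_that("the energy cutoff retains hbonds at or below the threshold only", {
  s <- hairpin_fx(8, 4)
  net <- build_constraint_network(s, network_params())
  fake <- net
  hb_rows <- which(fake$edges$kind == "hbond")[1:3]
  fake$edges$energy[hb_rows] <- c(-2.5, -3.0, -4.1)
  fake$edges <- fake$edges[c(which(fake$edges$kind != "hbond"), hb_rows), ]
  cut <- apply_energy_cutoff(fake, -3.0)
  expect_equal(sum(cut$edges$kind == "hbond"), 2)  # boundary inclusive
  expect_equal(sum(apply_energy_cutoff(fake, 0)$edges$kind == "hbond"), 3)
  expect_equal(sum(apply_energy_cutoff(fake, -11)$edges$kind == "hbond"), 0)
  expect_error(apply_energy_cutoff(net, 0.5), "<= 0")
})

test_that("cutoff filtration is monotone and construction deterministic", {
  s <- hairpin_fx(12, 5)
  net <- build_constraint_network(s, network_params())
  edge_key <- function(n) paste(n$edges$i, n$edges$j, n$edges$kind)
  k2 <- edge_key(apply_energy_cutoff(net, -2))
  k4 <- edge_key(apply_energy_cutoff(net, -4))
  expect_true(all(k4 %in% k2))
  net_b <- build_constraint_network(make_hairpin_scaffold(toy_spec(12, 5)),
                                    network_params())
  expect_identical(net$edges, net_b$edges)
})
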