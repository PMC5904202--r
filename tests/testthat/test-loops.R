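toy_loops <- data.frame(loop_name = c("L1", "L2"), chain_id = "A",
                        start = c(20, 60), end = c(26, 66))

test_that("the stable base is the domain interval minus the loop intervals", {
  base <- stable_base(toy_loops, "A", c(6, 110))
  expect_false(any(base %in% c(20:26, 60:66)))
  expect_equal(length(base), 105 - 7 - 7)
  all_loop <- data.frame(loop_name = "L", chain_id = "A", start = 6, end = 110)
  expect_error(stable_base(all_loop, "A", c(6, 110)), "empty")
})

test_that("alignment on the stable base undoes a rigid transform exactly", {
  s <- hairpin_fx(12, 7)
  X <- as.matrix(s$atoms[, c("x", "y", "z")])
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
              byrow = TRUE)
  moved <- t(R %*% t(X)) + matrix(c(5, 5, 5), nrow(X), 3, byrow = TRUE)
  base <- c(1:6, 14:19)
  aligned <- align_on_stable_base(list(moved, X), s, "A", base)
  expect_equal(aligned[[1]], X, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(aligned[[2]], X, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("loop-only displacement survives base alignment untouched", {
  s <- hairpin_fx(12, 7)
  loop <- data.frame(loop_name = "L1", chain_id = "A", start = 7, end = 13)
  pair <- make_conformer_pair(s, loop, 2.5)
  moved <- as.matrix(pair[[2]]$atoms[, c("x", "y", "z")])
  base <- c(1:6, 14:19)
  aligned <- align_on_stable_base(list(moved), pair[[1]], "A", base)[[1]]
  X0 <- as.matrix(pair[[1]]$atoms[, c("x", "y", "z")])
  at <- pair[[1]]$atoms
  base_rows <- which(at$res_seq %in% base & at$name == "CA")
  expect_lt(max(abs(aligned[base_rows, ] - X0[base_rows, ])), 1e-6)
  apex_rows <- which(at$res_seq == 10 & at$name == "CA")
  expect_equal(sqrt(sum((aligned[apex_rows, ] - X0[apex_rows, ])^2)), 2.5,
               tolerance = 0.01)
})

test_that("apex amplitude reproduces designed displacements and basic cases", {
  s <- hairpin_fx(12, 7)
  loop <- data.frame(loop_name = "L1", chain_id = "A", start = 7, end = 13)
  # no variants: amplitude 0
  expect_equal(as.numeric(apex_amplitude(list(), s, loop)), 0)
  # two conformers displaced +-d/2 around the reference
  at <- s$atoms
  apex_rows <- which(at$res_seq == 10 & at$name == "CA")
  X <- as.matrix(at[, c("x", "y", "z")])
  up <- X; up[apex_rows, 2] <- up[apex_rows, 2] + 1.5
  dn <- X; dn[apex_rows, 2] <- dn[apex_rows, 2] - 1.5
  amp <- apex_amplitude(list(up, dn), s, loop)
  expect_equal(as.numeric(amp), 3.0, tolerance = 1e-9)
  expect_equal(attr(amp, "apex_res"), 10)
  # max excursion from the reference is half the pairwise spread here
  amp2 <- apex_amplitude(list(up, dn), s, loop, method = "max_excursion")
  expect_equal(as.numeric(amp2), 1.5, tolerance = 1e-9)
  # full designed-displacement pipeline
  pair <- make_conformer_pair(s, loop, 5.0)
  aligned <- align_on_stable_base(
    list(as.matrix(pair[[2]]$atoms[, c("x", "y", "z")])), pair[[1]], "A",
    c(1:6, 14:19))
  expect_equal(as.numeric(apex_amplitude(aligned, pair[[1]], loop)), 5.0,
               tolerance = 0.01)
})

test_that("amplitudes never decrease when conformers are added", {
  s <- hairpin_fx(12, 7)
  loop <- data.frame(loop_name = "L1", chain_id = "A", start = 7, end = 13)
  X <- as.matrix(s$atoms[, c("x", "y", "z")])
  set.seed(20)
  confs <- lapply(1:4, function(k) X + rnorm(length(X), sd = 0.3))
  amps <- sapply(1:4, function(k) {
    as.numeric(apex_amplitude(confs[1:k], s, loop))
  })
  expect_true(all(diff(amps) >= -1e-12))
})

test_that("amplitude reports recompute the published means within rounding", {
  defs <- ref_table("tcr_loop_definitions.tsv")
  pub <- ref_table("tcr_published_means.tsv")
  A <- matrix(NA_real_, 8, 3,
              dimnames = list(unique(defs$loop_name), unique(defs$tcr)))
  for (k in seq_len(nrow(defs))) A[defs$loop_name[k], defs$tcr[k]] <- defs$amplitude[k]
  rep <- amplitude_report(A)
  # means over the eight loops of each TCR and over the three TCRs per loop;
  # the published cells are 1-decimal rounded, so recomputed means carry up
  # to 0.1 of rounding slack
  for (k in which(pub$kind == "tcr")) {
    expect_lt(abs(rep$structure_means[pub$name[k]] - pub$mean[k]), 0.1 + 1e-9)
  }
  for (k in which(pub$kind == "loop")) {
    expect_lt(abs(rep$loop_means[pub$name[k]] - pub$mean[k]), 0.1 + 1e-9)
  }
  # exact check of the display arithmetic on one column
  expect_equal(round(mean(A[, "F11"]), 1), 8.7)
  expect_equal(round(mean(A["CDR1a", ]), 1), 7.2)
  # degenerate all-zero table
  zero <- amplitude_report(matrix(0, 8, 3, dimnames = dimnames(A)))
  expect_true(all(zero$structure_means == 0) && all(zero$loop_means == 0))
  expect_error(amplitude_report(A * -1), ">= 0")
})

test_that("amplitudes are invariant to a joint rigid transform of all conformers", {
  s <- hairpin_fx(12, 7)
  loop <- data.frame(loop_name = "L1", chain_id = "A", start = 7, end = 13)
  pair <- make_conformer_pair(s, loop, 2.5)
  base <- c(1:6, 14:19)
  amp1 <- measure_loop_amplitudes(
    list(as.matrix(pair[[2]]$atoms[, c("x", "y", "z")])), pair[[1]],
    cbind(loop, domain_start = 1, domain_end = 19))
  th <- 0.4
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3,
              byrow = TRUE)
  mv <- function(M) t(R %*% t(M)) + matrix(c(-3, 7, 1), nrow(M), 3, byrow = TRUE)
  ref2 <- set_coords(pair[[1]], mv(as.matrix(pair[[1]]$atoms[, c("x", "y", "z")])))
  amp2 <- measure_loop_amplitudes(
    list(mv(as.matrix(pair[[2]]$atoms[, c("x", "y", "z")]))), ref2,
    cbind(loop, domain_start = 1, domain_end = 19))
  expect_equal(amp1, amp2, tolerance = 1e-8)
})
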