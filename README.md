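# tcrflex

Tools for asking whether the antigen-binding loops of an unbound T cell
receptor (TCR) are intrinsically flexible, or whether the conformations seen
in crystal structures are artefacts of crystallisation. The package serves
structural immunologists and anyone analysing loop mobility in multi-crystal
ensembles: it implements both the *crystallographic* half of the question
(do independent crystals of the same protein show the same loop
conformations, and are the loops pinned by lattice contacts?) and the
*computational* half (how far could each loop move if only bonding and
steric constraints restrained it?).

## What it computes

**Multi-crystal comparison.** Structures of the same TCR are superposed by
least-squares (Kabsch) on the non-loop framework residues of each chain;
the per-loop shift between crystals *i* and *j* is

    shift_ij(loop) = max over loop residues of |CA_i − CA_j|  after the framework fit,

reported as a symmetric matrix whose maximising pair identifies the two
extreme conformations. Crystal lattice contacts are intermolecular
distances < 4.0 Å between the asymmetric unit and any symmetry/lattice
image (built-in operators for P 1, P 21 21 2, P 1 21 1; explicit triplets
otherwise); a loop is "free" if no contact touches any of its residues.

**Flexibility pipeline.** The all-atom constraint network contains covalent
bonds (template-derived; peptide/ring/carboxylate/guanidinium/amide bonds
locked), hydrogen bonds and salt bridges scored 0 to −10 kcal/mol from
heavy-atom geometry (E = −10 · f_dist(d) · f_ang(θ), a clamped well centred
at 2.9 Å times cos² of the donor-linearity deviation), and hydrophobic
tethers. Polar edges with E ≤ E_cut (default −3 kcal/mol) are kept. The
(6,6) body-bar pebble game (5 bars per rotatable bond or hydrogen bond, 6
per locked bond, 2 per tether) yields rigid clusters and the floppy-mode
count. A Cα elastic network (unit springs within 12 Å) provides the ten
lowest nontrivial normal modes (7–16); a template-based geometric
simulation displaces all atoms along ± each mode and relaxes onto the
constraints each frame until the motion jams or 2000 frames are reached.
The 20 extreme variants are aligned per chain on the stable base (residues
6–110 minus the loops) and each loop's apex amplitude — the maximal
pairwise spread of its median-residue CA — is tabulated per loop and per
structure, with means matching the layout of the published amplitude table
for the F11, HA1.7 and 003 TCRs (bundled in `inst/extdata/`).

## Worked example

```r
library(tcrflex)

# a two-domain chain: one short "germline-like" loop, one long "CDR3-like" loop
td <- make_two_domain_chain(toy_spec(8, 3, two_domain = TRUE), loop_length2 = 6)
gt <- attr(td, "ground_truth")
loops <- data.frame(
  loop_name = c("germline_like", "cdr3_like"), chain_id = "A",
  start = c(gt$loop1[1], gt$loop2[1]), end = c(gt$loop1[2], gt$loop2[2]),
  domain_start = c(gt$domain1[1], gt$domain2[1]),
  domain_end = c(gt$domain1[2], gt$domain2[2]))

cfg <- pipeline_config(n_modes = 4, sim = sim_params(max_frames = 150), seed = 7)
res <- cmd_flex(td, loops, cfg, out_dir = "flex_out")
res$report
#>               two_domain mean
#> germline_like        0.1  0.1
#> cdr3_like            1.2  1.2
#> mean                 0.7   NA
res$decomposition
#> <rigid_decomposition: 38 clusters (largest 41 of 140 atoms), 38 floppy modes, 38 rotatable dihedrals>
```

The short loop is rigidly attached to its domain (amplitude ≈ 0.1 Å over
the 8 mode-biased variants at this small frame budget), while the long
loop explores ≈ 1.2 Å — the qualitative signature of long
somatically-rearranged loops out-moving short germline ones. `flex_out/`
contains the network, cluster and mode tables, per-run diagnostics, the
20-variant multi-MODEL PDB, the amplitude table, and a `run_log.tsv`
recording every parameter, seed and input checksum.

Comparing two "crystals" built with a known 2.5 Å loop displacement:

```r
s <- make_hairpin_scaffold(toy_spec(12, 7))
loop <- data.frame(loop_name = "CDR_like", chain_id = "A", start = 7, end = 13,
                   domain_start = 1, domain_end = 19)
pair <- make_conformer_pair(s, loop, 2.5)
cmd_compare(pair, loop, pipeline_config(domain_range = c(1, 19)), "cmp_out")$summary
#>   loop_name chain_id max_shift    conformer_1 conformer_2
#> 1  CDR_like        A       2.5 hairpin_n12_l7   crystal_2
```

A thin command-line front end (`inst/cli/tcrflex.R`) exposes the same two
entry points over PDB files and a loop TSV.

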