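---
title: "Rigidity, elastic-network modes, and geometric simulation of TCR CDR loop flexibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigidity, elastic-network modes, and geometric simulation of TCR CDR loop flexibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

T cell receptors (TCRs) recognise peptide–MHC ligands through six
complementarity determining region (CDR) loops plus two framework (Fw)
loops. Crystal structures of unbound TCRs are routinely compared with
ligand-bound ones to infer binding mechanisms, but a crystal is a single
snapshot: the same protein crystallised under different conditions can show
CDR loops in conformations several Angstrom apart, and lattice contacts can
pin loops artificially. `tcrflex` implements the two complementary analyses
that address this:

1. **Multi-crystal comparison** — superpose many structures of the same
   unbound TCR, measure per-loop Cα shifts relative to the stable framework,
   and annotate which loops touch crystal-lattice neighbours (an
   intermolecular distance below 4.0 Å).
2. **Intrinsic-flexibility simulation** — build the all-atom bonding
   constraint network, decompose it into rigid clusters with the pebble
   game, compute coarse-grained elastic-network modes, and push the
   structure along each low-frequency mode with a template-based geometric
   simulation until the motion jams. Aligning the resulting conformer
   variants on each chain's stable base and measuring the spread of each
   loop's apex yields a per-loop amplitude table.

## The constraint network

Atoms are vertices; edges are typed constraints:

* **Covalent bonds** come from amino-acid connectivity templates;
  inter-residue peptide bonds are added when the C–N distance is below
  1.7 Å and disulfides when SG–SG is below 2.3 Å. Peptide bonds, carbonyls,
  aromatic rings and the delocalised carboxylate/guanidinium/amide groups
  are *locked* (non-rotatable); all other bonds are rotatable single bonds.
* **Polar interactions** (hydrogen bonds and salt bridges) are scored from
  heavy-atom geometry on a 0 to −10 kcal/mol scale:
  `E = −10 · f_dist(d) · f_ang(θ)`, where `d` is the donor–acceptor
  distance and `θ` the antecedent–donor–acceptor angle. `f_dist` is a
  clamped parabolic well centred at `d₀ = 2.9 Å` (exactly 1 at `d₀`, 0
  beyond `d₀ + 0.6 Å`); `f_ang = cos²` of the deviation from linearity,
  zero beyond 60°. Salt bridges (charged donor and acceptor) use
  `d₀ = 3.0 Å` and a 20% depth bonus capped at the −10 floor. Deposited
  X-ray models carry no hydrogens, so donor linearity is measured through
  the donor's covalent antecedent; this keeps the score deterministic at
  the cost of penalising geometries whose N–H would in fact be linear.
* **Hydrophobic tethers** (2 bars) connect carbon/sulfur atoms from
  different residues within the sum of their van der Waals radii plus
  0.25 Å. Following standard rigidity-analysis practice, only genuinely
  hydrophobic atoms participate: a carbon bonded to nitrogen or oxygen
  (e.g. backbone Cα or the carbonyl carbon) does not tether, otherwise the
  backbone itself would be spuriously rigidified.

The **energy cutoff** `E_cut` selects the polar edges entering the rigidity
analysis; an edge is retained when its energy is ≤ `E_cut` (boundary
inclusive). The default is −3.0 kcal/mol; raising `|E_cut|` removes
constraints monotonically, so the edge set at −4 is always a subset of that
at −2.

## Pebble-game rigidity

Each atom is a body with 6 degrees of freedom. Constraints are bars:
5 bars for a rotatable covalent bond or a retained hydrogen bond (leaving
one dihedral), 6 for a locked bond, 2 for a tether. The (6,6) pebble game
matches degrees of freedom against bars: a bar is independent if 7 pebbles
can be gathered on its endpoints, and the number of unmatched pebbles at
the end is the floppy-mode count (including the 6 rigid-body motions of a
connected molecule). Two atoms share a rigid cluster when no 7th pebble can
be freed on them; because rigid sets that share an atom merge, the maximal
rigid clusters partition the atom set. Clusters are labelled by decreasing
size (ties by smallest member serial) so reports are reproducible, and the
decomposition is a matroid property of the edge set — it does not depend on
edge insertion order, which the test suite verifies by shuffling.

The floppy-mode count is cross-checked in the tests against an independent
oracle: the numerical rank of a generic body-bar constraint matrix with
random bar placements, over 50 random graphs of up to 12 bodies.

## Elastic-network modes

One site per residue at the Cα position; unit springs between all site
pairs within 12 Å (inclusive); the anisotropic-network Hessian has
off-diagonal blocks `−k r̂ r̂ᵀ`. All chains form one network (inter-chain
springs allowed), consistent with the interdomain hinge motion the method
is meant to capture. A connected network has exactly six zero modes
(rigid-body translations/rotations), verified against the seventh
eigenvalue; more near-zero modes raise an error naming the disconnected
components, or a degenerate-geometry error when the sites are coplanar or
collinear (a genuine pathology of central-force networks). Modes 7–16 are
returned by default, signs fixed so each eigenvector's largest component
is positive, making "parallel" and "antiparallel" reproducible. Sites are
not mass-weighted — only equal springs and Cα geometry enter the model.

## Geometric simulation and jamming

Rigid clusters become *templates* (the cluster plus its directly bonded
neighbour atoms, so adjacent templates share the atoms of each rotatable
bond: bond lengths and angles across the articulation are preserved while
the dihedral stays free). The Cα mode is expanded to all atoms of each
residue and normalised. Per frame, every atom moves by
`direction · step_size · √N · field` (so a typical atom moves about
`step_size` = 0.01 Å), then the structure is relaxed by repeated cycles of

1. least-squares fitting each template to the current positions and moving
   each atom to the average of its templates' fitted positions,
2. pushing apart non-bonded pairs below the steric floor, and
3. projecting hydrogen-bond/tether lengths back into their ±0.1 Å windows,

until the worst violation is below the 0.1 Å tolerance (at most 200 cycles
per frame). The steric floor for a pair is 85% of the van der Waals sum,
but never more than the pair's distance in the input structure: contacts
already present in the crystal model are grandfathered (they may not
tighten further but are not treated as violations), so the input
conformation is always feasible — the same convention template-based
geometric simulation codes use.

A run terminates as **jammed** either when relaxation fails to converge or
when the cumulative amplitude (the projection of the displacement onto the
mode field) grows by less than 0.01 Å over 100 consecutive frames: the
constraints have brought the motion to a standstill, which operationalises
the "natural limit" of easy motion. With small steps the relaxation almost
always converges and the stall detector is what fires in practice; both
are reported identically. Otherwise the run completes at the frame cap
(2000 by default). The final valid frame of each of the 2 × 10
(direction × mode) runs is its extreme variant, giving the 20-variant
ensemble the amplitude analysis consumes.

## Loop amplitudes

For each chain, variants are aligned onto the reference using the CA atoms
of the *stable base* — the N-terminal-domain interval (residues 6–110 for
the real TCRs) minus the loop intervals; each chain (and, for the
synthetic two-domain fixtures, each domain) is aligned independently so
interdomain hinge motion does not contaminate the loop measurements. The
loop *apex* is the CA of the median loop residue (lower median for
even-length loops) — the paper-style tables do not define the apex, and
the median residue matches the visual apex for loops of these lengths. The
*amplitude* is by default the maximum pairwise distance between apex
positions over the reference plus all variants; the maximum excursion from
the reference is available as an alternative (`method = "max_excursion"`),
and reports record which definition was used. The max-pairwise default
reflects that parallel and antiparallel variants bracket the crystal
conformation symmetrically. Per-structure means (over the 8 loops) and
per-loop means (over structures) are reported unrounded and displayed at
one decimal.

## Synthetic structures

All stages are testable offline through seed-deterministic generators:

* `make_hairpin_scaffold()` builds two antiparallel glycine strands at
  ideal bond lengths whose facing odd-numbered residues form "narrow
  rungs" carrying two backbone hydrogen bonds each at the ideal scoring
  distance (−6.5 kcal/mol after the design tilt), joined by a
  curve-following loop with near-ideal peptide bonds. A gentle 1.5°/Å
  twist about the long axis keeps the site geometry genuinely
  three-dimensional (a perfectly planar build would make the
  elastic-network out-of-plane block singular). The designed ladder makes
  the core one dominant rigid cluster at `E_cut = −3` while the loop
  fragments.
* `make_conformer_pair()` displaces a loop with a sine bump (endpoints
  fixed, apex moving exactly the requested distance) and re-idealises bond
  lengths with the apex CA and all base atoms pinned — the designed apex
  shift is exact by construction, which is what makes it a useful oracle.
* `make_two_domain_chain()` joins two hairpin domains (optionally with
  different loop lengths, emulating short germline loops next to long
  CDR3 loops) by a ten-residue extended linker with a gentle helical
  wiggle; the linker is the softest part of the chain, so the lowest
  nontrivial mode is dominated by relative domain motion. The wiggle is
  needed because a perfectly straight single-file linker has no torsional
  stiffness in a central-force network.
* `make_lattice_fixture()` solves the P1 cell edge so that exactly one
  designed atom pair (a protruding C-terminal carboxylate oxygen against
  the +a lattice image) sits at 3.8 Å while every other inter-image pair
  exceeds 4.5 Å.

What the toys deliberately do not emulate: side chains and rotamers, real
secondary-structure hydrogen-bond geometry (donor linearity is designed
for the heavy-atom score, not for an N–H), solvent, crystallographic
disorder, and TCR-scale system size. Passing tests therefore demonstrate
the correctness of the machinery — superposition, scoring, constraint
counting, mode computation, constraint-preserving motion, amplitude
bookkeeping — not the numerical amplitudes of any real TCR.

## Problem sizes and defaults

The default configuration reproduces the study settings: `E_cut` −3.0
kcal/mol, 12 Å elastic-network cutoff, 10 nontrivial modes (7–16), 2000
frame cap, 4.0 Å lattice-contact rule, stable base 6–110. The test suite
and the acceptance script run the full pipeline on two-domain chains of
30–40 residues with 4–6 modes and 120–250 frames per run: amplitudes there
are a few Angstrom (the toys are an order of magnitude smaller than a TCR
variable domain), and a full two-system analysis takes well under a minute
on one core. Simulation parameters (step 0.01 Å, tolerance 0.1 Å, 200
relaxation cycles, 0.85 steric scale, 0.01 Å/100-frame stall rule) are
package defaults exposed via `sim_params()`; below jamming they affect
amplitudes only weakly, and all of them are recorded in every run log.

## Known limitations

* Heavy-atom hydrogen-bond scoring penalises real backbone N–H···O
  geometry; on deposited structures the retained-bond set at a given
  `E_cut` will differ from codes that place explicit hydrogens.
* The relaxation is first-order (Gauss–Seidel projections); near-tangent
  constraint intersections converge slowly, which is why jamming is
  detected by stalling as well as by outright failure.
* The built-in space-group table covers only the settings occurring in
  this analysis (P 1, P 21 21 2, P 1 21 1); anything else requires
  explicit operator triplets (`read_operator_file()`), including the
  non-standard "P 21 21 1" setting that appears in one of the published
  crystal tables.
* Rigid-cluster decompositions are combinatorial (generic rigidity): a
  geometrically singular arrangement that happens to be flexible would
  still be reported rigid.
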