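---
title: "Inverse molecular docking with invdock: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse molecular docking with invdock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invdock)
```

## The problem

Conventional virtual screening docks many candidate molecules into one
protein. Inverse (reverse) docking turns the telescope around: one small
molecule of interest — a natural product, a drug, a suspected toxicant —
is docked into a large collection of protein binding sites, and the
proteins are ranked by their best docking score. The top of that ranking
is a list of candidate targets for the molecule, a starting point for
experimental follow-up. `invdock` implements the full protocol at desk
scale: binding-site database construction, hierarchical fragment docking
with a knowledge-based pair potential, score-distribution thresholding,
geometric interaction profiling, and early-recognition validation
metrics.

## Binding-site database

`build_site_database()` composes the preparation pipeline:

1. **Ligand extraction.** Co-crystallized HET groups with strictly more
   than 7 heavy atoms (`min_heavy_atoms = 8`) and at least one heavy atom
   strictly closer than 3.0 Å to the protein chain are candidate
   ligands. Waters are always excluded; a configurable cofactor code list
   (heme, nucleotide cofactors, etc.) is excluded as well, because such
   groups occupy pockets without being screening-relevant ligands. All
   distance filters use heavy atoms and strict inequalities.
2. **Binding residues.** Residues with any heavy atom strictly closer
   than 5.0 Å to any ligand heavy atom define the site.
3. **Sequence clustering.** Chains are grouped at 100% sequence identity
   (exact sequence match; the cutoff is a parameter).
4. **Site clustering.** Within each sequence cluster, sites whose
   structural-similarity z-score reaches 2.0 join the same single-linkage
   cluster.
5. **Representatives.** Each cluster is reduced to one site: the member
   with the most source ligands, ties broken by lexicographic site id.
   This particular tie-break is our choice; any deterministic rule would
   do, and determinism is what the pipeline tests assert.
6. **Centroid cover.** The docking search volume is a union of spheres
   covering the source-ligand atoms: greedy cover, sphere radius capped
   at 4.0 Å with a 0.5 Å pad.
7. **Taxon filter.** Entries whose SOURCE organism does not match the
   configured taxon (default `"Homo sapiens"`) are dropped.

**Site similarity.** The published pipelines treat site comparison as a
black box that emits a z-score with a 2.0 threshold. We supply a defined,
self-contained surrogate rather than a re-implementation of a local
structural alignment server: the raw similarity of two sites is the size
of the largest residue-label-compatible, distance-consistent
correspondence between their Cα sets (maximum clique of the product
graph, distance tolerance 1.5 Å), and the z-score standardizes that raw
value against ≥100 seeded random permutations of one site's residue
labels. Two degenerate cases are defined explicitly: when the null has
zero variance (e.g. a homopolymer site, where permuting identical labels
changes nothing), the z-score is `Inf` if the observed value exceeds the
null and 0 otherwise.

**Ligand pooling.** When sites cluster, ligands of member sites are
pooled into the representative only if they lie on the representative's
own entry and chain. Transposing ligands between chains would require a
structural superposition, which is out of scope; at desk scale the
clustered sites come from identical chains and nothing is lost.

## The docking engine

**Fragmentation.** A bond is rotatable iff it is a single, non-aromatic,
acyclic (bridge) bond whose two atoms each have at least two heavy
neighbors, and it is not an amide C–N bond. Cutting all rotatable bonds
partitions the heavy atoms into rigid fragments; for bridge-only cuts the
fragment count is always the cut count plus one, an identity the tests
assert. Each cut is recorded as a link with its reference bond length.

**Pair potential.** `derive_pair_potential()` builds a knowledge-based
score from observed protein–ligand complexes:

\[
V(t_1, t_2, r) \;=\; -\log\frac{N_{\mathrm{obs}}(t_1,t_2,r) + 1}
{N_{\mathrm{ref}}(t_1,t_2,r) + 1},
\]

with element-based atom types (C, N, O, S, P, pooled halogens), 0.5 Å
distance bins and a 6 Å cutoff. The reference state is the *radial mean*:
the per-type-pair total count redistributed over the bins in proportion
to spherical-shell volume (∝ r²Δr), so a bin scores negative exactly when
contacts are enriched over that geometric expectation. Two conventions
complete the definition:

* *Excluded volume*: bins below the shortest observed contact of a type
  pair are set to a fixed repulsive value (+3). A pure −log(obs/ref)
  table scores unseen short approaches as neutral-to-weak, which lets
  poses bury into the receptor; statistical potentials conventionally
  add a steep short-range repulsion, and so do we.
* *Interpolation*: the binned table is a staircase, on which a local
  minimizer cannot sense sub-bin slopes. The engine therefore evaluates
  poses on the piecewise-linear interpolation of the table (nodes at bin
  centers, tapered to zero at the cutoff). `score_pose()` defaults to the
  plain binned lookup; the engine passes `interpolate = TRUE`
  consistently, so a docked pose's reported score is the interpolated
  score of its final coordinates.

Scores are linear in the potential, so scaling the table by λ > 0 scales
every pose score by λ and cannot change any ranking — a property the
tests assert and a reminder that the absolute numbers are arbitrary
units.

**Grid and fragment poses.** The search volume is an axis-aligned lattice
(default spacing 1.0 Å, anchored at integer multiples of the spacing)
clipped to the centroid union. Each rigid fragment is centered at every
grid point under `n_rot = 24` seeded uniform rotations; poses with any
heavy atom closer than 2.0 Å to the protein are discarded, geometric
duplicates are removed, and the best `k_keep = 20` by score are retained.

**Maximum-clique linking.** Fragment poses are nodes of a compatibility
graph; an edge joins poses of distinct fragments when (i) no heavy-atom
pair is closer than 1.5 Å (the cut-bond atom pair itself is exempt) and
(ii) every cut bond between the two fragments sits within 1.0 Å of its
reference length. Full reconstructions are cliques containing one pose
per fragment. For graphs of at most 64 nodes the cliques are enumerated
exactly (Bron–Kerbosch with pivoting); above that a deterministic beam
search over the fragment tree (beam 50, ranked by summed fragment score)
stands in. Each reconstruction is then *snapped*: walking the fragment
tree, every child subtree is translated along its cut-bond axis so the
bond takes exactly its reference length, guaranteeing chemically sane
connectivity before refinement.

**Minimization.** `minimize_pose()` runs coordinate descent over three
translations, three rotations about the ligand centroid, and one torsion
per cut bond. Each degree of freedom uses a step-halving line search (a
ladder of step sizes from 2.0 Å / 1.0 rad downward, first improving step
taken); when the axis-aligned moves stall, an escape sweep adds diagonal
translation directions and diagonal rotation axes, which lets the
descent cut across valleys that axis zigzagging cannot follow. Sweeps
stop after 200 iterations or when a full sweep improves the score by
less than 10⁻⁴ at the smallest step size. Only improving moves are ever
accepted, so the returned score is never worse than the input score.

**Docking score.** `dock_ligand()` refines the best `n_refine = 20`
reconstructions and returns poses sorted ascending; the first score is
the protein's docking score (arbitrary units, lower is better). A site
in which no clash-free, linkable pose exists yields the documented
no-pose outcome (`n_poses = 0`, `best_score = NA`) and is excluded from
screen tables.

## Target prioritization

Screen-wide best scores are treated as approximately normal, a choice
made on the evidence of the normal Q-Q plot (`qq_points()`, plotting
positions (i−0.5)/n) rather than a formal test. `fit_normal()` is the
maximum-likelihood fit; the population standard deviation is the
default, the unbiased estimator a flag, and at screen scale (n in the
thousands) the two differ negligibly. The selection threshold is the
lower bound of the central 95% probability interval of the fitted
normal, mean ± 1.96·sd. We read the published "95% confidence interval"
this way deliberately: an interval of roughly ±26 units around the mean
is far too wide to be a confidence interval *of the mean* at n ≈ 13,500,
so the central probability interval is the only reading consistent with
the numbers; both interpretations remain available through the exposed
level parameter. Selection is strict — a protein scoring exactly at the
threshold is not selected — and the ranked report breaks ties by protein
id.

## Interaction profiling

`profile_interactions()` detects seven interaction types from geometry
alone, with every window a configuration key: hydrogen bonds
(donor–acceptor ≤ 3.5 Å, D–H…A ≥ 120° when an explicit hydrogen is
present; with implicit hydrogens the distance criterion decides and the
hydrogen is taken as inferable along the donor–acceptor axis),
hydrophobic contacts (apolar C…C in 3.3–4.0 Å), π-stacking (ring
centroids ≤ 5.0 Å, interplanar angle ≤ 30° or 60–90°), π-cation
(centroid–cation ≤ 5.0 Å), salt bridges (charged-group centroids ≤
5.0 Å; Asp/Glu negative, Lys/Arg/His positive, ligand charges from
formal charges), water bridges (a water oxygen within hydrogen-bond
range of both partners), and halogen bonds (C–X…A with X…A ≤ 3.8 Å and
angle ≥ 140°). Tryptophan contributes its two rings separately, so a
ligand stacked on both naturally produces two records. Records
re-validate against their windows (a self-audit the tests run) and the
output is invariant to ligand atom order.

## Screen validation

All metrics operate on a `labeled_ranking()`: entries sorted ascending
by score with ties broken by id, so every metric sees a deterministic
total order.

* **ROC/AUC** — trapezoid rule on the TPF/FPF steps; identical to the
  normalized Mann–Whitney statistic on the same order.
* **Enrichment factor** — EF(χ) = (actives in top ⌈χN⌉ / ⌈χN⌉)/(n/N),
  bounded by min(1/χ, N/n).
* **RIE** — exponentially weighted early recognition,
  RIE = Σᵢ e^(−α·rankᵢ/N) / [ (n/N)(1−e^(−α))/(e^(α/N)−1) ].
* **BEDROC** — the analytic rescaling of RIE to [0, 1]:
  BEDROC = RIE·Ra·sinh(α/2)/(cosh(α/2) − cosh(α/2 − α·Ra)) +
  1/(1 − e^(α(1−Ra))). The package computes BEDROC only through this
  conversion, and a tolerance-10⁻⁹ test keeps the two consistent.
* **Predictiveness curve / total gain** — a logistic regression of the
  label on the score supplies calibrated activity probabilities; TG =
  mean|p̂ᵢ − p̄| / (2p̄(1−p̄)) is 0 when scores carry no information and 1
  at perfect separation. Perfect separation makes the ML fit diverge in
  the coefficients while the fitted probabilities converge to 0/1; the
  fit is capped at 100 IRLS iterations and flagged, and TG is computed
  from the capped probabilities.

**Why α = 20.** The exponential weight is not stated alongside the
published early-recognition numbers, but the printed RIE/BEDROC pair is
mutually consistent under the conversion above only near α = 20 — the
conventional default — with 21 actives among 13,553 entries (7.288
converts to 0.3701). That consistency check is both the rationale for
the default and a standing test.

## Synthetic fixtures

Every input is generated in code, seeded and byte-stable.

* `make_toy_complex()` emits PDB text for an *imprint pocket*: across
  each ligand heavy atom sits a wall atom of complementary polarity (a
  hydrogen-bond partner at 2.8 Å across N/O, an apolar carbon at 3.6 Å
  across C), carried by a pseudo-residue whose Cα lies 1.5 Å further
  out, plus an outer Cα/Cβ shell for bulk. The design makes the
  co-crystallized placement the contact-optimal pose, which is what
  turns re-docking recovery into a well-posed check: in earlier
  homogeneous-shell designs we verified numerically that the potential's
  optimum was legitimately elsewhere, so recovery failures said nothing
  about the engine. The ligand's rigid core is a distorted box (edges
  1.4/1.5/1.6 Å) plus a protruding atom: every vertex has three
  neighbors at bond range (so the perceived graph is cyclic and the core
  rigid), and no proper rotation maps the element pattern onto itself
  (so plain heavy-atom RMSD is a valid recovery measure). Sizes above 9
  grow a flexible tail, adding a rotatable bond; an all-carbon element
  pattern yields apolar decoy pockets for planted-binder screens.
* `make_labeled_scores()` draws n active and N−n inactive scores from
  two normals. The defaults mimic the published screen's shape: N =
  13,553 entries, n = 21 actives, inactives centered at −27.47 with sd
  13.13 (the fitted screen-wide distribution) and actives centered at
  the −53.21 selection threshold. Under those defaults the implied AUC
  is ≈ 0.92, close to the published full-screen discrimination, which we
  consider the realistic operating point; none of these numbers is
  tuned per test.
* `make_curcumin()` returns the stored curcumin structure: the enol
  tautomer (the form favored at physiological pH), neutral — the
  protonation state is not stated in the source protocol, so neutral
  enol is our recorded assumption — with a fixed 3D conformation
  generated once and shipped as text. 27 heavy atoms, two methoxylated
  phenol rings, 7 rotatable bonds under the fragmentation rule, hence 8
  rigid fragments.

What the fixtures do *not* emulate: real protein folds, sequence
realism, solvation, or the chemistry of real binding sites. A passing
suite therefore demonstrates that the algorithms are implemented
correctly and behave as specified on controlled geometry — not that the
scores are accurate for real proteins, and not that the published
absolute score values (−63.30 and so on, which depend on the original
program's exact parameterization and the real PDB) are reproduced.

## Numerical and policy choices

* 3D embedding of coordinate-free input (SMILES) is a seeded
  distance-restraint stress minimization: ideal bond lengths, 1–3
  distances from idealized angles (120° at sp² centers, 109.5°
  otherwise), a soft 2.5 Å floor between unbonded heavy atoms, BFGS from
  a seeded jitter of the 2D layout. It is reproducible per seed and
  adequate for defining rigid fragment shapes; it is not a conformer
  search. (External 3D generators were rejected for this role because
  their output is not reproducible run-to-run.)
* Alternate locations: the highest-occupancy conformer wins, ties by
  altloc letter. Insertion codes ride along in residue keys. Biological
  assembly operators from REMARK 350 are applied when present (chain
  copies suffixed by operator index); identity otherwise. First NMR
  model only; no mmCIF.
* Degenerate inputs have defined outcomes rather than crashes: empty
  candidate lists, single-site screens (no threshold report below two
  scores), all-no-pose screens, zero-variance score vectors (an error in
  `fit_normal`), degenerate permutation nulls (`Inf`/0 z-scores).
* Problem sizes in the tests are chosen for a desk-scale machine: toy
  complexes of ~20 residues and 9-atom ligands, five-complex recovery
  studies, rankings up to N = 13,553 for the metric suite, 100-repetition
  null simulations for AUC/EF/TG. The full published screen (13,553 real
  sites, ~310,000 chains) is explicitly out of scope.
* Re-docking recovery is reported success-rate style: with engine
  defaults, the crystal pose is recovered within 2 Å on at least three
  of the first five seeded complexes. Recovery within a narrow basin on
  a piecewise-linear landscape is genuinely seed-sensitive; the suite
  asserts the rate, not each seed.

## Limitations

* Docking scores are internally consistent arbitrary units; they are not
  comparable to the published absolute values, which depend on a
  differently parameterized potential trained on the real PDB.
* Receptor flexibility is honored only through ligand-pose minimization
  against a rigid receptor.
* The site-similarity surrogate is not a local structural alignment; it
  is a defined stand-in honoring the z ≥ 2.0 clustering contract.
* The interaction profiler approximates, and does not replicate, the
  exact parameter set of established profiling tools.
* Tautomer and protonation enumeration, stereo-aware conformer
  generation, metal coordination and covalent binding are out of scope.
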