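---
title: "Probabilistic backbone assignment from solid-state NMR peak lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic backbone assignment from solid-state NMR peak lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Magic-angle-spinning solid-state NMR of uniformly labelled proteins yields
carbon/nitrogen-detected 2D and 3D spectra whose cross-peaks encode
covalent connectivities within a residue and to its predecessor. Sequential
resonance assignment — deciding which residue every peak belongs to — is
the gate through which all downstream structural analysis passes. This
package automates that step for picked peak lists: it is aimed at
spectroscopists who have peak lists from a standard set of
carbon-detected experiments (N–CA, N–CO, N–CA–CX, N–CO–CX, CA–N–CO
families, and the 2D carbon–carbon correlation) plus the protein sequence,
and want per-residue chemical-shift assignments with calibrated
probabilities rather than a single take-it-or-leave-it answer.

## The model, in outline

1. **Spin-system matrix.** Every residue *i* (except the first) is anchored
   by a *root triple* — the CO(i−1), N(i), CA(i) coordinates. Roots are
   read directly from experiments that carry all three roles, and joined
   from (N, CO−1) × (N, CA) evidence on the shared nitrogen otherwise.
   Strips from every other experiment are matched to the root anchors
   within a per-nucleus tolerance and their remaining axes fill the
   system's own-residue and preceding-residue shift slots
   ({CA, CB, CO} plus an unclassified side-chain carbon pool).
2. **Typing.** For a candidate residue type, the likelihood of a system's
   shifts is a product of independent Gaussians with per-(type, atom)
   means and standard deviations from a bundled reference table. Atoms the
   type lacks veto it (a CB observation excludes glycine); unclassified
   carbons are matched one-to-one to the type's remaining carbons, with a
   noise floor so a stray value penalizes rather than annihilates.
3. **Linking.** System A precedes system B when A's own carbons agree with
   B's preceding-residue carbons: every atom named on both sides must
   agree within tolerance, remaining values are greedily paired, and the
   link score is `exp(-sum(delta^2) / (2 sigma^2))` with `sigma = tol/2`.
4. **Pentapeptides and belief propagation.** Chains of up to five linked
   systems are scored against every sequence window; surviving placements
   define each system's candidate positions. A factor graph — unary typing
   potentials, link factors rewarding consecutive placement, soft
   exclusion factors discouraging two systems on one position — is solved
   by damped loopy sum-product. Each system's marginal over positions
   (plus an explicit "unassigned" state) is the reported probability.
5. **Offsets and iteration.** Per-experiment referencing errors are
   estimated from the assignment and applied, and the pipeline re-runs
   until the assignment map is stable (at most 5 rounds).
6. **Side chains.** For each confidently assigned residue the pooled
   unclassified carbons (own strips, the successor's preceding-residue
   pool, anchored carbon–carbon peaks) are matched one-to-one to the
   type's open side-chain atoms by maximum summed log density; each
   atom's probability is the backbone probability times its normalized
   match posterior.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `tol_c_grid` | 0.2, 0.35, 0.5 ppm | carbon matching tolerances searched |
| `tol_n_grid` | 0.3, 0.55, 0.8 ppm | nitrogen matching tolerances searched |
| `quality_threshold` | 0.3 | matrix quality below which the run terminates |
| `link_weight` | 10 | pairwise boost for consecutive placement of linked systems |
| `exclusion_penalty` | 1e-3 | soft penalty for two systems claiming one position |
| `cx_floor` | 1e-3 | noise density for a carbon the type cannot explain |
| `bp_max_iters`, `bp_damping`, `bp_tol_msg` | 200, 0.5, 1e-6 | message-passing controls |
| `corroboration_cap` | 0.49 | probability ceiling for placements with no link to a placed neighbour |
| `sidechain_cutoff` | 0.6 | backbone probability required before side chains are attempted |

All of these live in `ssa_config()` and can be overridden per run or
through a flat `key=value` configuration file.

The tolerance grid is searched exhaustively (carbon × nitrogen) and the
matrix with the highest quality wins, ties toward the smallest values. The
quality score is `sqrt(q_sys * q_link)`: `q_sys` compares the number of
rooted systems against the number of residues with a predecessor
*symmetrically* — both missing systems and ghost inflation (duplicate or
false roots) reduce it — and `q_link` is the fraction of systems with an
outgoing di-peptide link. The symmetric form is this package's choice: a
one-sided ratio capped at 1 goes blind exactly when false-positive peaks
inflate the system count, which is when tolerance selection matters most.

## Numerical and design choices

* **Competitive strip attachment.** A peak attaches only to the root whose
  anchors it matches best, not to every root within tolerance. Backbone
  carbonyls cluster within ~2 ppm, so promiscuous attachment contaminates
  every nearby system; competitive attachment keeps each observation with
  one owner. Single-anchor 2D strips attach only when exactly one system
  matches — with one coordinate there is nothing to arbitrate with.
* **Slot conflicts.** A strip value within tolerance of a slot's current
  value is averaged in (weighted by support). A conflicting value from a
  better-anchored strip replaces a worse-anchored one; a conflict between
  equally-anchored strips demotes both values to the unclassified pool and
  closes the slot — the atom's identity is genuinely ambiguous and
  pretending otherwise propagates a coin flip into the typing. Root-backed
  slots (own N, own CA, preceding CO) are never overwritten.
* **Root ambiguity.** Side-chain carbonyls on CX/CO union axes and
  nitrogen-collision joins create ghost roots that share a true root's
  (N, CA). Ghosts are grouped within a *tight* window (at most
  0.3/0.2 ppm, independent of the matching tolerance — genuinely distinct
  residues must not annihilate each other at wide tolerances) and only the
  best-supported preceding-CO alternative survives, preferring
  direct-experiment evidence.
* **The unassigned state.** Each system's unassigned pseudo-likelihood is
  the probability of its observed values under a noise background
  (`cx_floor` per carbon, `bg_n` per nitrogen). A system whose best
  placement cannot beat "it's all noise" drops out instead of being forced
  somewhere with inflated confidence.
* **Sequential corroboration.** After greedy one-to-one extraction from
  the marginals, a placement with no di-peptide link to a placed
  neighbour is capped below 0.5 probability. On complete data every
  correct placement is corroborated; isolated placements under noise are
  wrong often enough that reporting them confidently is dishonest.
* **Referencing offsets.** Full linear chemical-shift analysis is out of
  scope; two surrogates replace it. (a) For attached experiments, the
  offset is the median leave-one-out residual of the experiment's
  contributions against the other experiments' consensus for the same
  atom — exactly zero on clean data, and exact for an injected uniform
  shift. A residual-versus-database-mean estimator was rejected: residue
  deviations from database means have ~2 ppm scatter, so its median is
  nowhere near a real offset at realistic sample sizes. The median must
  also clear three standard errors (of the median) before a correction is
  applied, otherwise jitter noise masquerades as a referencing error and
  the "correction" degrades the next round. (b) An experiment whose peaks
  mostly fail to attach is scanned over a coarse offset grid for the
  shift maximizing anchor matches — this is what recovers a +0.5 ppm
  mis-referenced experiment whose strips otherwise never match anything.
* **CA/CB arbitration on union axes** uses the open slot when one of the
  two is already named, and reference-statistics plausibility only when
  both are open.
* **Boundary conventions.** The quality gate is a closed lower bound.
  Probability bins: green (0.99, 1], cyan [0.85, 0.99],
  yellow [0.5, 0.85), red [0, 0.5), gray unassigned. Candidate curves use
  `p >= threshold`. Leucine-methyl-style degenerate matchings break ties
  by pairing ascending ppm with ascending atom name.
* **Registry naming.** The supported-experiment table lists an N–CA/CB
  correlation at both 2D and 3D; they are keyed `NCACB-2D` and `NCACB-3D`,
  and plain `NCACB` resolves to the 3D experiment.
* **Tab-separated peak lists** (`.txt`) are read as position columns in
  the profile's axis order followed by an optional height column; `#`
  lines are comments. This is the declared contract for the third
  supported dialect, whose exact layout is not standardized.

## What the synthetic generator does and does not emulate

`generate_peaklists()` instantiates exactly the sequential (i, i−1)
cross-peak templates of each experiment at the values of an assigned shift
table, then degrades them: per-nucleus Gaussian jitter, independent peak
dropout, uniform false positives within each axis's observed range, and
per-experiment referencing offsets — all reproducible from a seed.
`simulate_shift_table()` draws per-residue shifts from the bundled
statistics; with `min_separation` it rejects draws that would collide in
the two ways that actually confuse the algorithm (joint (N, CA) anchor
collisions and full (CA, CB, CO) linking-triplet collisions). Global
per-atom-class separation is deliberately *not* enforced: 56 CA values
cannot be 0.8 ppm apart inside a realistic 20 ppm band, and forcing it
drives the table into statistically absurd territory.

A green recovery test therefore establishes that the pipeline inverts its
own generative model under stated degradation — it does not establish
performance on real spectra, which add correlated lineshape artifacts,
long-range dipolar cross-peaks, inconsistent picking across spectra, and
non-Gaussian shift deviations (paramagnetic centres, ring currents).
The bundled statistics table is itself a hand-compiled snapshot
approximating public database averages, not a live database query, and
typing is not conditioned on secondary structure.

## Known limitations

* The first residue is assignable only through its (N, CA) strips; its
  amide nitrogen is reported but no preceding carbonyl can exist.
* Prolines are treated like any other residue (nitrogen detection does not
  require an amide proton), but sparse proline statistics make them weaker
  typing anchors.
* Aromatic side-chain carbons beyond CG and degenerate pairs
  (CD1/CD2, CE1/CE2, CG1/CG2) are frequently reported with probability
  below the 0.6 cutoff — by design, since swapped matchings are near
  iso-scoring.
* Very high glycine content weakens linking (no CB to compare) and lowers
  correctness, consistent with the method's reliance on CB connectivities.
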