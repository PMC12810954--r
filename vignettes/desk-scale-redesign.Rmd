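---
title: "Desk-scale redesign of four-helix-bundle cytokines: methods and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desk-scale redesign of four-helix-bundle cytokines: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixforge)
```

This vignette records the mathematical models, parameter defaults, and known
limitations of `helixforge`. The package is *desk-scale* by design: every
stage is a small, deterministic, testable model of a step that in practice
would involve heavyweight design software or laboratory instruments. Where a
stage stands in for such software, that is stated explicitly and the stand-in
makes no claim of reproducing the external tool's output.

## 1. Structure model

Structures are tidy atom tables — one row per heavy atom with `chain`,
`resno`, `ins`, `resname`, `atom`, `x`, `y`, `z` — read and written through
`bio3d`. HETATM records, waters, and hydrogens are dropped on input; for
alternate locations the first-encountered altloc is kept with a warning.
Author residue numbering is preserved verbatim, which matters because loop
lengths are computed from numbering gaps.

Helices are declared as inclusive residue ranges, or recovered automatically
by `assign_helices_auto()`: a residue quadruplet is helical when its
Cα(i)→Cα(i+3) distance lies in **4.5–6.0 Å** (ideal helix ≈ 5.2 Å, extended
chain ≈ 10 Å), and maximal consecutive runs of at least **5 residues** become
ranges. A helix's axis is the principal direction (SVD) of its Cα trace,
oriented N→C.

Interface roles use a contact model: a helix is `receptor_binding` when at
least **5** heavy-atom pairs between the helix and a single receptor chain
fall within **4.5 Å**. Both parameters are exposed in `assign_roles()` and
`pipeline_config()`.

## 2. Connector-economy topology design

Helices are rigid bodies in native sequence direction (segments are never
reversed — they are contiguous template sequence). For an order of the $n$
helices, junction $i$ requires a connector of at least

$$L_i = \max\left(1, \lceil g_i / 3.8 \rceil\right) + 1$$

residues, where $g_i$ is the Cα gap between consecutive anchors in Å, 3.8 Å
is the per-residue span of a fully extended chain, and the `+1` slack keeps
the connector closable with non-extended geometry. The *economy* of an order
is $\sum_i L_i$; `design_blueprint()` enumerates all permutations (the
problem size is at most $8! = 40\,320$; the practical case is $4$ helices,
$24$ orders or $6$ with a pinned N-terminal helix) and returns the minimal
economy, breaking ties lexicographically so the result is deterministic. The
acceptance tests verify the optimizer against independent exhaustive scoring.

## 3. CCD loop closure

Connector backbones are grown from the C-terminal anchor with ideal peptide
geometry (bond lengths N–CA 1.458, CA–C 1.525, C–N 1.329, C=O 1.231 Å; bond
angles CA-C-N 116.2°, C-N-CA 121.7°, N-CA-C 111.2°; ω fixed at 180°), with
initial φ drawn uniformly from (−160°, −50°) and ψ from (−70°, 160°). A
scaffold copy of the following residue's N/CA/C is appended and cyclic
coordinate descent rotates each free dihedral by the analytically optimal
angle $\alpha = \operatorname{atan2}(\sum f\cdot(\hat\theta\times r),
\sum f\cdot r)$ until the scaffold superposes onto the true downstream anchor
frame within **0.5 Å** RMSD.

Two details matter in practice:

* **The anchor ψ is the first degree of freedom.** Rotating about the
  anchor's CA→C axis moves no helix atom but sets the loop's exit direction;
  without it, short connectors between antiparallel helices can stall at a
  geometric floor above tolerance.
* **Stall detection.** A trajectory that improves by less than $10^{-7}$ Å
  for 20 consecutive sweeps is abandoned early; up to **10** seeded
  trajectories (**500** sweeps each) are tried and the best kept. The error
  trace of the winner is monotone non-increasing, which the tests assert.

Helix coordinates are copied from the template **bit-for-bit**; only
connector atoms are synthesized. Connector sequence defaults to
glycine/serine alternation. Clash screening reports heavy-atom pairs closer
than **2.6 Å** at sequence separation ≥ **3**.

## 4. Stabilization

* **Disulfide staples**: cross-region Cβ–Cβ distances within **3.0–5.0 Å**
  are candidates, ranked by $|d - 4.0\,\text{Å}|$ (the ideal disulfide Cβ
  separation). Glycine and other residues without a Cβ atom get an ideal
  tetrahedral Cβ reconstructed from backbone N/CA/C. The pipeline applies
  the single best staple between the first and last template helices, giving
  designs with exactly one disulfide.
* **Mutation transfer**: `"Q6P,T45I"`-style edits validate the wild-type
  letter at each position and never touch backbone coordinates; side-chain
  atoms beyond Cβ are dropped for mutated residues.
* **Residue choice stand-in**: `choose_residue()` scores candidates as
  pseudo-sphere clash + burial mismatch (hydrophobic↔buried, using a Cα
  neighbour count within **10 Å** against a threshold of **14**) + a
  **10**-point penalty for proline beyond the second helix position. It is a
  deterministic, alphabetically tie-broken stand-in for fixed-backbone design
  software, not a reproduction of it.

## 5. Acceptance by superposition

`accept_design()` pools the Cα atoms of every template-derived position,
superposes them onto the template with one Kabsch fit (SVD with the
determinant-sign correction, so the rotation is always proper and mirror
images are never matched), and accepts only when the pooled RMSD is
**strictly below 1.0 Å**. Per-helix RMSDs are reported in the same pooled
frame, deliberately without per-segment refitting. The pipeline retries a
rejected build with a shifted connector seed up to a configurable cap and
records the rejection cause.

## 6. Assay models

**SPR (1:1 Langmuir).** Association
$R(t) = R_\mathrm{eq}\,(1 - e^{-(k_a C + k_d)t})$ with
$R_\mathrm{eq} = R_\mathrm{max} k_a C / (k_a C + k_d)$; dissociation decays
with rate $k_d$ from the association endpoint. `fit_kinetics()` fits shared
$(k_a, k_d, R_\mathrm{max})$ across a dilution series (≥ 3 concentrations)
by Levenberg–Marquardt in log-parameter space with a multi-start grid
($k_a \in 10^4..10^8$, $k_d \in 10^{-4}..1$). $K_D$ is **always** reported
as $k_d / k_a$. `kd_consistency()` exists because instrument software
sometimes prints an equilibrium $K_D$ that disagrees with the $k_d/k_a$
ratio of the very same fit; disagreements above 5% are flagged rather than
silently reconciled.

**Thermal shift.** $F(T) = F_{low} + (F_{high} - F_{low}) / (1 +
e^{(T_m - T)/s})$, fitted with the slope as a log parameter. Fits whose $T_m$
lands outside the temperature grid or whose amplitude is within 5× the
residual noise are rejected as "no transition in range".

**Tumor volume.** $V = ((L + W)/2)^3 \times 0.52$ mm³, endpoint flag at
1500 mm³. The second caliper dimension is interpreted as width.

## 7. Synthetic data and its limits

`make_ideal_bundle()` traces parametric ideal helices (rise 1.5 Å/residue,
twist 100°/residue, backbone atoms from fixed cylindrical parameters derived
from an ideal-dihedral helix) on the corners of a regular polygon with
10.5 Å side, consecutive helices antiparallel via a proper rotation. Residue
numbering embeds declared native-loop lengths as gaps, so loop arithmetic
and auto-assignment have exact ground truth. `make_receptor_probe()` adds a
rigid Cα probe at a fixed standoff so role assignment has ground truth too.

These generators are *idealized*: no supercoiling, no sidechains beyond Cβ
reconstruction, no packing optimization, rigid probes instead of real
receptor ectodomains. They exist to give every pipeline stage a
deterministic, assertable input — not to imitate crystal structures.

## 8. Known discrepancies handled explicitly

* In the motivating geometry (helix ranges 8–27, 51–66, 73–91, 127–149), the
  numbering gap between helices 1 and 2 is 23 residues, while the loop
  between them is commonly quoted as 29 residues; the two cannot both be
  right. `loop_lengths()` computes strictly from numbering, and the
  acceptance test for loop arithmetic covers only the two self-consistent
  loops (6 and 35 residues).
* Reported rate constants of the kind $(k_a, k_d) = (1.63\times10^6,
  9.994\times10^{-3})$ alongside an equilibrium $K_D$ of 5.22 nM imply a
  $k_d/k_a$ ratio of 6.13 nM — a 17% disagreement. `kd_consistency()`
  surfaces exactly this situation.

## 9. Determinism

Every stochastic step (connector trajectories, noise injection, perturbation)
runs under an explicit integer seed through an RNG scope that restores the
caller's `.Random.seed`. Sub-seeds are derived arithmetically (per-connector:
`seed + index`; per-assay-curve: `seed*1000 + index`, reduced modulo
$2^{31}-1$), so end-to-end runs are byte-deterministic: the same config and
seed reproduce the same PDB text, stage log, and fitted numbers exactly.
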