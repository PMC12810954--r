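# helixforge

Desk-scale redesign of four-helix-bundle cytokines, with the assay
mathematics used to characterize the designed variants.

Four-helix-bundle cytokines (the interleukin-2/interleukin-7 fold) present
their receptor-binding epitopes on some helices while other helices and long
native loops are purely structural. `helixforge` implements a deliberately
small, fully deterministic version of the redesign idea: keep the
receptor-facing helices exactly where they are, throw away the native loops,
reconnect the helices with the shortest closable connectors, staple the
scaffold with a single disulfide, and accept the design only if the helices
still superpose onto the template. Alongside the design pipeline it
implements the quantitative models behind the characterization assays:
1:1 Langmuir surface plasmon resonance (SPR) kinetics, Boltzmann
thermal-shift melting curves, and the caliper tumor-volume formula.

Everything runs on synthetic inputs with known ground truth, so the whole
pipeline is testable on a laptop without external structures, design
software, or instruments.

## The models

**Connector economy.** Helices are rigid, sequence-ordered segments that are
never flipped. For a candidate helix order, each junction needs a connector
of at least `max(1, ceil(gap / 3.8)) + 1` residues, where `gap` is the
C-anchor-to-N-anchor Cα distance in Å, 3.8 Å is the fully extended
per-residue span, and the extra residue is closability slack. The blueprint
is the order minimizing the summed connector length ("economy") over all
permutations (optionally with a pinned N-terminal helix).

**Loop closure.** Connectors are built with ideal peptide geometry
(N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, trans peptide bonds) and closed by
cyclic coordinate descent (CCD): each backbone dihedral in turn is rotated by
the analytically optimal angle that superposes a scaffold copy of the next
residue's N/CA/C onto its target frame. The anchor residue's ψ is included as
the first degree of freedom (it sets the loop exit direction and moves no
helix atom). Ten seeded trajectories with random initial φ/ψ are attempted;
closure must reach RMSD ≤ 0.5 Å over the three frame atoms.

**Stapling and mutation transfer.** Disulfide sites are scanned as
cross-region residue pairs whose Cβ–Cβ distance (ideal tetrahedral Cβ
reconstructed for glycine) falls in 3–5 Å, ranked by |d − 4 Å|. Point
mutations use `wt-position-mutant` notation (`"Q6P,T45I"`), verify the
wild-type identity, and never move backbone atoms. A small steric/burial
score (pseudo side-chain spheres, Cα neighbour-count burial, mid-helix
proline penalty) stands in for fixed-backbone design; it makes no claim of
reproducing any external design software.

**Acceptance.** The pooled helix Cα atoms of the model are superposed onto
the template with a single Kabsch fit (SVD with determinant correction, so
reflections are never returned); the design is accepted only if the pooled
RMSD is strictly below 1.0 Å.

**Assay models.** SPR sensorgrams follow the closed-form 1:1 Langmuir model
`R(t) = Req (1 − exp(−(ka·C + kd)·t))`, `Req = Rmax·ka·C/(ka·C + kd)`, with
exponential dissociation; `fit_kinetics()` fits shared (ka, kd, Rmax) to a
dilution series by multi-start Levenberg–Marquardt and always reports
`KD = kd/ka`, never an independently fitted value. Melt curves follow the
Boltzmann sigmoid `F(T) = F_low + (F_high − F_low)/(1 + exp((Tm − T)/s))`.
Tumor volume is `((length + width)/2)^3 × 0.52` mm³ with a 1500 mm³ humane
endpoint flag.

## Worked example

```r
library(helixforge)

# A synthetic four-helix bundle with declared helix ranges and native loops
bundle <- make_ideal_bundle()
loop_lengths(bundle$helices)
#> [1] 23  6 35

design_blueprint(bundle$helices, fix_first = "H1")
#> <blueprint> order: H1 > H2 > H3 > H4  economy: 12 residues
#> # A tibble: 3 × 5
#>   from_helix to_helix   gap min_length designed_length
#>   <chr>      <chr>    <dbl>      <int>           <int>
#> 1 H1         H2        7.64          4               4
#> 2 H2         H3        8.62          4               4
#> 3 H3         H4       10.9           4               4

# Full pipeline: annotate -> blueprint -> build -> stabilize -> validate
rec <- run_pipeline(pipeline_config(seed = 1L))
glance(rec)
#> # A tibble: 1 × 8
#>   accepted attempts order       economy n_clashes n_staples     rmsd max_closure_error
#>   <lgl>       <int> <chr>         <int>     <int>     <int>    <dbl>             <dbl>
#> 1 TRUE            1 H1>H2>H3>H4      12         0         1 4.82e-15             0.500

# Assay models with known ground truth
ds <- make_assay_dataset(seed = 42L)   # truth: ka 1.38e6, kd 4.296e-3, Tm 71.12
fit_kinetics(ds$sensorgrams)
#> <kinetic_fit> ka 1.38e+06 1/M/s, kd 0.00429 1/s, KD 3.11 nM, Rmax 30 RU (rms 0.302 RU, 5 curves)
fit_melt_curve(ds$melt)
#> <tm_fit> Tm 71.04 degC (slope 2.11, rms 0.0201 AU)
```

All fitted objects support `tidy()`, `glance()`, and `autoplot()`.

## Scope

The runnable surface of this package is the desk-scale mathematics:
geometry, topology scoring, loop closure, superposition, and assay curve
models on synthetic data. Real design sequences, physics-based energies,
structure-prediction models, expression yields, immune-cell phenotyping,
tumor-growth experiments, and transcriptomics are experimental or
external-software outputs and are explicitly out of scope; nothing here
claims to reproduce them. See the methods vignette
(`vignettes/desk-scale-redesign.Rmd`) for assumptions, parameter defaults,
and known limitations.
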