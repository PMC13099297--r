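---
title: "Methods: structure-based pharmacophore screening and dose-response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based pharmacophore screening and dose-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmscreen)
```

`pharmscreen` implements an integrated receptor-based virtual-screening
pipeline: pharmacophore model construction from receptor–ligand hydrogen
bonds, Güner–Henry (GH) decoy-set validation, hierarchical Lipinski +
pharmacophore screening, and four-parameter logistic (4PL) dose–response
analysis. This vignette documents the underlying models, the tunable
parameters and their defaults, the numerical choices, what the synthetic
data generators emulate, and the package's known limitations.

## 1. Hydrogen-bond detection and the pharmacophore model

A hydrogen bond is accepted between a ligand N/O and a receptor N/O when
the donor–acceptor heavy-atom distance is at most `max_da_distance`
(default **3.5 Å**) and, when an explicit hydrogen is resolved on the
donor, the D–H···A angle is at least `min_dha_angle` (default **120°**).
These defaults are standard crystallographic practice for moderate-
resolution structures. Hydrogens are associated with their heavy atom by a
1.2 Å covalent-distance criterion rather than by a bond table, because PDB
files carry no connectivity. When neither partner carries a hydrogen the
check degrades to distance-only and the contact's angle is recorded as
`NA`; such a contact is classified ligand-acceptor, since ligand-donor
directionality is defined by a ligand-borne hydrogen.

`build_model()` creates **one feature per distinct (ligand atom,
direction) pair**: a DONOR feature where the ligand donates, an ACCEPTOR
feature where it accepts, both positioned at the ligand heavy atom — not
at the hydrogen or the contact midpoint — because the heavy atom is what a
matching library compound must place there. Contacts from one ligand atom
to several residues merge into a single feature whose provenance lists all
partner residues; a hydroxyl that both donates and accepts yields two
co-located features. Labels F1, F2, … are assigned donors-first, in
ligand-atom order. The default tolerance radius of **1.0 Å** per feature
is conventional for receptor-derived queries; it is advisory metadata for
generators and display — acceptance in screening is decided by the global
RMSD cutoff alone.

## 2. Güner–Henry validation

Screening a database of $D$ compounds containing $A$ known actives
retrieves $H_t$ hits of which $H_a$ are active. The GH score

$$GH = \frac{H_a\,(3A + H_t)}{4 H_t A}\Bigl(1 - \frac{H_t - H_a}{D - A}\Bigr)$$

combines the yield of actives ($H_a/H_t$, weighted 3:1 toward precision)
with the decoy false-positive penalty. It is 0 for a model that retrieves
no active and 1 for one that retrieves exactly the actives; values above
0.7 are conventionally read as a reliable model. When $H_t = 0$ the yield
and enrichment factor $E = H_a D/(H_t A)$ are undefined and flagged, and
GH is 0 through $H_a = 0$. Raw values are always retained; the printed
view rounds yield and recall to whole percent, $E$ to the nearest integer
and GH to two decimals, matching the conventional table precision (all
"half" cases round away from zero).

## 3. Feature perception, matching and the funnel

A molecule's feature points are perceived from its explicit-hydrogen
structure: one DONOR per N/O bearing an O–H/N–H, one ACCEPTOR per N or O
except pyrrole-type nitrogens (aromatic N–H), each at the heavy atom. The
same definitions drive the rule-of-five donor/acceptor counts, so the
filter and the matcher cannot disagree about what a donor is.

Matching is **strict all-feature correspondence search**: every injective,
kind-respecting assignment of model features to molecule feature points is
evaluated by optimal rigid superposition (Kabsch algorithm, proper
rotation enforced via the SVD sign correction), and the assignment with
the smallest RMSD is reported. A compound matches when that minimum RMSD
is at most the cutoff (default **0.6 Å**). Surplus molecule features are
ignored; a molecule lacking enough features of either kind is unmatched,
not an error. RMSD is computed *after* superposition, not in the model's
frame — per-compound RMSDs for diverse scaffolds only make sense once the
compound is allowed its rigid placement. Ties between assignments are
broken by the lexicographically smallest atom-index correspondence, which
makes reports reproducible across platforms. The enumeration (with a
rotation-invariant per-point-norm lower bound used to skip hopeless
assignments, and a hard guard at $10^6$ assignments) runs in compiled
code; `superpose_rmsd()` exposes the superposition itself in R.

Multi-conformer records are matched per conformer and the best conformer
is reported. `run_funnel()` fixes the stage order — descriptors → Lipinski
→ perception → matching — so a compound failing the rule of five is never
matched, and ranks hits by ascending best RMSD.

The logP used by the Lipinski stage is a deliberately coarse local
atom-contribution estimate (Crippen-type magnitudes, typed by element,
attached hydrogens and aromatic flags). It is deterministic and adequate
for rule-of-five bucketing of the synthetic chemotypes this package
generates; it is **not** a calibrated replacement for a full SMARTS-typed
logP model, and published per-compound logP values should not be expected
to reproduce.

## 4. Dose–response analysis

`fit_ic50()` fits
$$y = \text{bottom} + \frac{\text{top} - \text{bottom}}{1 + (d/IC_{50})^{h}}$$
to pooled % uptake data by bounded least squares in $\log_{10}$-dose
space. Bounds follow the GraphPad-style convention for normalised uptake
data: top $\in [80, 120]$ %, bottom $\in [-10, 20]$ %, Hill slope
$h \in [0.3, 5]$, $\log_{10} IC_{50}$ within the dose span widened by
three decades. Initialisation is deterministic: a coarse grid over
$\log_{10} IC_{50}$ (0.25-decade steps) × $h \in \{0.5, 1, 2\}$ is scored
by direct residual sum of squares and the best three nodes seed bounded
Levenberg–Marquardt runs (`minpack.lm`); the lowest-RSS fit wins. There is
no randomness anywhere in the fit. Both the 4PL and a 3-parameter variant
(fixed bottom) are offered, the 4PL being the default. Replicates are
fitted pooled with equal weights; per-replicate fits can be summarised
into mean ± SD columns with `summarize_activity()`.

Two flags guard interpretation: data whose per-dose mean response range is
below `noise_floor` (default 10 percentage points) is declared
*no-inhibition* and not fitted; a fitted $IC_{50}$ outside the dose span
± 2 decades is marked *extrapolated*. Selectivity is the raw ratio
$IC_{50}^{SGLT1} / IC_{50}^{SGLT2}$ with an integer view rounded half away
from zero, the convention that reproduces typical published selectivity
columns.

## 5. The synthetic-data generators

The generators stand in for inputs that are not redistributable — an
experimental receptor complex, a proprietary screening library, raw
uptake data — while making every stage's ground truth explicit. Each is a
pure function of its spec (seed included): identical outputs across runs
and platforms at the stored text precision, with the caller's RNG stream
left untouched.

**Complexes.** `generate_complex()` builds a polyol-like ligand (oxygens
on a tilted ring, ~2.5 Å radius) inside a shell of minimal capped
residues drawn from a polar-site vocabulary (Glu/Gln/Asn acceptors,
Lys/Ser donors). Each planted contact is collinear D–H···A (angle
≈ 180°) at heavy-atom distance $3.5 - \text{margin}$ Å, so a positive
margin places it strictly inside both criteria and a negative margin
strictly outside. At generation time the guarantee is *asserted*: every
non-planted ligand/receptor polar pair must lie outside the criteria by at
least the margin, else the spec is rejected as infeasible. This makes the
planted contact list an exact oracle for `detect_hbonds()`.

**Libraries.** Actives realise the model: the (deduplicated) feature
positions are rigidly rotated (uniform over SO(3)) and translated, jittered
with iid per-coordinate Gaussian noise of sd `jitter_sd` (default
**0.1 Å**), and then materialised as hydroxyl/ether oxygens with anchor
carbons and a carbon scaffold. Jitter is applied in feature space, so the
matcher's expected RMSD relates analytically to `jitter_sd` (per-point
displacements are $\chi_3$-distributed; at 0.1 Å per coordinate the
expected match RMSD is ≈ 0.17 Å, far inside the 0.6 Å cutoff — this is
what makes recall statements quantitative). Decoys are built
scaffold-first: a persistent random-walk carbon chain sized to the target
molecular weight, with 0–5 hydroxyls and 0–4 ether oxygens attached to
random chain carbons. An earlier design that confined decoy polar atoms to
a model-sized sphere produced ~1% coincidental geometric matches at
0.6 Å — several-fold more false positives than decoy validations of this
kind actually show — and was replaced by the scaffold-decorated design,
which is both the more molecule-like geometry and yields the near-zero
coincidence rate typical of random decoys against a five-feature query.
Only molecular weight is steered directly (scaffold padding toward a
target drawn in `descriptor_ranges$mw`, default 320–480 Da); donor/
acceptor counts and logP follow structurally from the feature composition.

The default library composition for validation experiments is 25 actives
against 1975 decoys, the conventional decoy-set proportion for GH
validation at $D = 2000$.

**Assays.** `generate_assay()` draws responses from the 4PL plus iid
Gaussian noise (default sd **5%**, 3 replicates) on a 15-level half-log
dose ladder from 0.001 to 10 000 nM — the standard design for cell-based
uptake-inhibition assays.

**What passing tests do and do not show.** The generators emulate the
*geometry* and *noise structure* of the real workflow, not its chemistry:
toy molecules have no stereochemistry, no aromatic systems beyond flags,
no conformational ensembles (each record is one rigid conformer unless
multi-conformer records are supplied), and decoys are random-feature, not
property-matched to the actives. A high GH on synthetic decoys therefore
demonstrates that the matcher discriminates planted geometry from random
geometry at the stated jitter and cutoff — it does not certify enrichment
against property-matched decoys or real screening libraries, which is a
strictly harder problem.

## 6. Problem sizes and numerical choices

The shipped validation experiments use libraries of 2000 compounds
(25 actives / 1975 decoys) over 20 seeds, and simulation studies of 200
assays per condition — sizes chosen so the complete suite re-derives every
oracle from scratch in minutes on a laptop while keeping Monte-Carlo error
well below the decision margins (a GH of ~1.0 vs the 0.7 threshold; median
IC50 recovery within 10%).

Numerical details worth knowing: superposition uses the SVD formulation
with determinant correction, so mirror-image point sets are never matched
by an improper rotation; collinear or coincident point sets are flagged
`degenerate` but still return the optimal proper rotation; SDF coordinates
are written at the format's 4-decimal precision, which bounds round-trip
error at $5 \times 10^{-5}$ Å; rounding for printed tables is half-away-
from-zero throughout; the dose–response fit is deterministic by
construction (grid-seeded, no restarts from random points).

## 7. Limitations

- PDB parsing keeps altloc '' / 'A' only and reads one model; SDF support
  is V2000 only (V3000 blocks are rejected per record with a logged
  reason).
- No aromatic/hydrophobic/ionic pharmacophore feature types, no excluded
  volumes, no complex energy minimisation: the feature vocabulary is
  donor/acceptor, matching the hydrogen-bond-driven sites this pipeline
  targets.
- No docking stage: the funnel's final ranking is by feature RMSD;
  docking scores can be carried as external annotation columns but are
  never computed.
- The logP estimator is coarse (see §3); protonation states and tautomers
  are taken as drawn.
- `evaluate_model()` and `run_funnel()` screen conformers as given; the
  package does not generate conformers.
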