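---
title: "Methods: descriptor-based target fishing and enzyme-assay analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptor-based target fishing and enzyme-assay analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetfish)
```

## Overview

`targetfish` implements a ligand-based target-fishing pipeline — 2-D
pharmacophore descriptors, thresholded neighbor retrieval against an
annotated compound–target library, and inverse-distance-weighted (IDW)
affinity interpolation — together with the enzyme-assay analysis used to
validate a predicted target: kinetic slopes, relative inhibition,
four-parameter logistic (4PL) IC50 fitting, and pIC50 conversion. This
vignette records the model choices, the parameters that matter, and the
places where the design was genuinely open.

## Molecular graphs

Molecules enter as SMILES and are reduced to heavy-atom graphs: element,
formal charge, aromatic flag, implicit-hydrogen count per atom, and the
all-pairs topological distance matrix (shortest-path bond counts, via
igraph). Everything downstream is 2-D; stereochemistry and isotopes are
parsed and discarded.

Conventions worth stating:

* **Salts / mixtures.** A disconnected SMILES keeps only its largest
  connected component. Cross-component topological distances are
  undefined, and the descriptors are path-based, so a single connected
  frame is required; dropping counterions is the conventional
  normalization.
* **Aromaticity.** Lowercase SMILES atoms carry the aromatic flag
  directly. A *default* (unsymbolized) bond between two aromatic atoms is
  aromatic when it lies in a ring and single otherwise, so biphenyl-style
  inter-ring bonds are not misread as aromatic. Every lowercase atom must
  end up with at least two aromatic bonds (i.e. inside a ring) or parsing
  fails.
* **Implicit hydrogens.** Organic-subset atoms receive
  `valence − bond-order sum`, with aromatic bonds counted as single plus
  one valence unit surrendered to the ring system (benzene carbons get one
  H, pyridine nitrogen none). Bracket atoms carry exactly their stated H
  count, per the SMILES standard.

## Pharmacophore features

Each atom receives a subset of the classic four-type alphabet:

| Feature | Rule |
|---|---|
| D (donor) | N or O bearing at least one hydrogen |
| A (acceptor) | any O; any N not positively charged with ≤ 3 heavy neighbors |
| H (hydrophobic) | non-aromatic C with no N/O neighbor; S; halogens |
| R (aromatic) | any atom flagged aromatic |

Atoms may carry several features (a hydroxyl O is both D and A), and
multi-feature atoms contribute combinatorially to pairs and fragments —
collapsing them would make donor/acceptor-rich molecules degenerate.
Aromatic carbons are typed R only: their lipophilic character is carried
by the R channel rather than double-counted as H, which keeps plain
benzene a purely aromatic object.

## The three descriptor families

* **FPD** (feature-pair distributions): for every unordered pair of
  distinct feature-bearing atoms and every combination of features they
  present, one count at their topological distance. Histogram support is
  distances 1–10 with overflow accumulating in bin 10 — bounded vectors
  keep the entropy comparison well-defined; distances beyond 10 bonds
  carry little pharmacophoric signal in drug-sized molecules. Same-atom
  (distance-0) pairings are excluded.
* **SHED**: per feature pair, the Shannon entropy `−Σ p log p` of the
  normalized histogram, in nats (the log base only rescales distances and
  thresholds; it is fixed for reproducibility). Empty distributions score
  0; the ceiling over 10 bins is `log(10) ≈ 2.30`.
* **PHRAG** (pharmacophoric fragments): for every pair of feature-bearing
  atoms 2–6 bonds apart, one fragment string per feature-label choice at
  each endpoint — the two endpoint labels flanking the interior atom
  labels along a shortest path (`.` for featureless interiors,
  multi-feature interiors contribute their full sorted label). The 2–6
  bond window gives fragments long enough to be selective and short
  enough to recur between analogs.

**Canonical paths.** Multiple shortest paths can carry different interior
labels. Fragments are therefore canonicalized twice: each fragment is the
smaller of itself and its label-wise reversal, and among all shortest
paths the lexicographically smallest fragment wins. A fixed-index
tie-break would be cheaper but depends on atom input order; the chosen
rule makes every descriptor invariant under atom permutation (a property
the test suite checks directly), at bounded cost since paths are at most
6 bonds.

## Neighbor retrieval and the applicability domain

Queries are compared to every library compound by

* PHRAG: multiset Dice, `2 Σ min(a, b) / (Σa + Σb)`;
* FPD: mean histogram intersection `Σ min(p, q)` over the feature pairs
  populated in at least one molecule (a pair present in exactly one
  contributes 0);
* SHED: Euclidean distance of the entropy vectors.

Two entirely featureless molecules are treated as indistinguishable
(similarity 1, distance 0) so the identity property holds everywhere.
Dice and histogram intersection were chosen over alternatives (Tanimoto,
χ²) as the standard bounded comparators for multisets and distributions.

The applicability domain is `PHRAG ≥ 0.76`, `FPD ≥ 0.87`, `SHED ≤ 0.52`,
applied jointly (the strictest reading; an any-of mode is available via
`threshold_config(mode = "any")`). These thresholds are carried as
published defaults, not calibrated constants: the commercial descriptors
they were tuned for are proprietary, and this package's descriptor
definitions are stated substitutes, so the thresholds should be treated
as a configuration surface.

## IDW affinity interpolation

Within each (target, activity-type) group of passing neighbors,

$$F = \sum_i W_i f_i, \qquad
W_i = \frac{d_i^{-p}}{\sum_j d_j^{-p}}, \qquad p = 2,$$

where the f are the neighbors' experimental pActivities. Properties that
follow and are tested: weights sum to 1, F lies inside the neighbor
affinity range, and as p grows F converges to the nearest neighbor's
value. Design points:

* **Distance channel.** The default is `d = 1 − PHRAG similarity`; FPD
  (1 − similarity) and SHED (the distance itself) are selectable. A single
  similarity per neighbor is what a prediction report carries, and PHRAG
  heads the similarity discussion, so it is the default evidence channel.
* **Exact matches.** The weight formula diverges at d = 0; distances below
  `zero_eps` (1e-9) switch the estimate to the plain mean over those
  near-zero neighbors. A query identical to a single annotated reference
  therefore predicts exactly that reference's pActivity.
* **Activity types are never pooled.** A pKi is not a pIC50; each group
  interpolates one function. Duplicate (compound, target, activity-type)
  annotations are averaged at library load so each neighbor contributes
  one value.

## Enzyme-assay analysis

Progress curves (RFU vs minutes) are reduced to two-point slopes over the
25–30 min window — inside the linear range of the assay this equals the
initial-rate estimate while being robust to the lag and saturation phases;
window endpoints falling between samples are linearly interpolated.
Relative inhibition is `(slope_EC − slope_S) × 100 / slope_EC`; it is
invariant to RFU rescaling and may legitimately be negative (activation)
or exceed 100. Blank-trace subtraction is available but off by default.

The dose–response model is the 4PL in log10-concentration,

$$y = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + 10^{(\log_{10}\mathrm{IC50} - \log_{10} c)\,\mathrm{hill}}},$$

fitted by bounded Levenberg–Marquardt least squares (minpack.lm) with box
constraints bottom ∈ [−10, 30] %, top ∈ [70, 110] %, hill ∈ [0.2, 5],
and log10(IC50) allowed 2 decades beyond the tested range. Sparse 6–7
point curves need the bounds to stay identified. Initialization is
multi-start over five log-spaced IC50 guesses across the tested range,
keeping the lowest-RSS fit; the procedure is deterministic. The
`converged` flag is honest about degeneracy: a fit whose parameters end
up pinned at a constraint bound (flat data, curves that never reach a
plateau) is reported as not converged rather than silently returned.

## What the synthetic data emulates — and what it does not

`generate_library()` plants analog series: each series grows compounds
from one scaffold by 1–3 seeded decoration edits (methyl, hydroxyl or
amino on a random carbon with a free hydrogen), annotated to its target
with pActivity ~ Normal(target mean, sd). Defaults: 4 targets × 2 series
× 6 analogs, target means spread evenly over 5.5–8 (lead-like potency),
sd 0.4 (within-series spread of a congeneric series). Queries are single
fresh decorations of randomly chosen library members, so every query has
a known true target.

The default scaffolds are twelve elaborated natural-product-like
structures of 26–32 heavy atoms — prenylated and alkylated polyphenols
and fused N-heterocycles — each populating all four feature classes
redundantly. That redundancy is the point: within a real congeneric
series one substituent change perturbs existing feature-pair
distributions; on a bare ring system the same edit creates whole
histograms from nothing and throws the pair outside any sensible
applicability domain. Small single-ring scaffolds therefore do not model
analog series, and the generator deliberately does not use them.

The simulated plates put Gaussian noise in the two places the assay
measures: on the enzyme-control slope (RFU/min, sd 2 against a mean of
100) and on percent inhibition of sample wells (sd 3). Traces are sampled
every 5 min over 0–30 min; two sample wells per concentration, three
enzyme controls, one blank.

What passing tests on this data do **not** show: performance on real
chemical diversity (tautomers, charged states, scaffold hops, activity
cliffs), on noisy heterogeneous annotation databases, or at the scale of
hundreds of thousands of reference compounds. The generator produces
clean, well-separated series by construction; real target fishing is
harder.

## Study problem sizes

The shipped analysis uses a 48-compound library with 100 query analogs,
and 100 simulated plates per assayed compound (seeded 1–100) when
summarizing IC50 recovery — three compounds at their reported potencies
(8.79 µM and 27.2 µM for the two isomeric flavanone inhibitors, 0.047 µM
for the peptidyl positive control) over their published concentration
ranges (10⁻⁹–10⁻³, 10⁻⁹–10⁻⁴ and 10⁻¹⁰–10⁻⁵ M, decade steps). These sizes
exercise every code path while keeping the full analysis in the minutes
range on one CPU.

## Known limitations

* The descriptor definitions are reconstructions of a published descriptor
  *ensemble* whose exact algorithms are proprietary; fragment strings and
  similarity values are internally consistent but not comparable to the
  commercial tool's numbers, and the 0.76/0.87/0.52 domain inherits that
  caveat.
* The 27.2 µM compound's published concentration range tops out at ~3.7×
  its IC50, so the upper asymptote is weakly constrained there; its fitted
  IC50 is the most variable of the three (still within the 15% recovery
  band the tests assert, but with the least margin).
* Feature typing is a minimal 4-type alphabet; no charge-transfer,
  no explicit positive/negative ionizable classes, no ring-system
  fragments.
* The assay module stops at IC50/pIC50: no progress-curve fitting beyond
  two-point slopes and no Ki conversion.
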