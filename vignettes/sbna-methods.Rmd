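---
title: "Structure-based network analysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based network analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the model implemented by `sbnar`, the meaning and
defaults of every tunable parameter, the design of the synthetic
generators, and the numerical choices and their limitations. It makes no
empirical claims beyond what the package's own test suite computes.

## The model

### Contact graph

For one conformer of a prepared structure, the scored residues of the
target chain become graph nodes. Residues $i$ and $j$ are connected when
at least one pair of their heavy atoms lies within the contact cutoff and
$|resno_i - resno_j|$ exceeds the adjacency exclusion. The edge weight is
the *number* of qualifying heavy-atom pairs, so an extensive packed
interface contributes more than a grazing contact.

Assumptions: heavy atoms only (hydrogens are usually absent from crystal
structures and add little contact information); a single distance cutoff
for all atom types; residues identified by `(chain, resno, insert)`.

### Sub-scores

Per residue:

- `local_connectivity` — weighted degree, the immediate packing density;
- `second_order` — sum of neighbours' weighted degrees, a second
  contact shell;
- `bridging` — betweenness centrality with edge length `1/weight`
  (stronger contacts are shorter paths), normalized by
  $(n-1)(n-2)/2$;
- `ligand_proximity` — the count of the residue's heavy atoms with any
  ligand or binding-partner atom within the cutoff.

### Standardization

Each sub-score is z-scored over the protein's scored residues. A
zero-variance sub-score (for example `ligand_proximity` in a structure
without ligands) is set to zero rather than dropped, keeping the
combination length fixed. The unit-weight sum of the four standardized
sub-scores is z-scored again, so the single-conformer network score has
mean 0 and standard deviation 1 per protein by construction. For
multi-model structures each conformer is scored independently and the
network score is averaged per position; after averaging, the per-protein
standard deviation is no longer exactly 1 (the invariant holds per
conformer, not for the average).

### Variant scores

The modified score is `network_score − BLOSUM62(ref, alt)`. Both terms
are on comparable scales — the network score is standardized, and
BLOSUM62 off-diagonal entries for the 20 canonical amino acids span −4 to
3 — which is what makes the plain difference meaningful. Modified scores
are min–max scaled to [0, 1] across the full analysed score set, and the
combined score is `scaled + EVE`, in [0, 2]. Missing EVE values yield a
missing combined score rather than silently falling back.

### Labels

ClinVar significance strings are binned benign / VUS / pathogenic;
entries with fewer review stars than the threshold are left unlabeled.
Variants still unlabeled and carrying at least the gnomAD count threshold
of alternate alleles are labeled benign; a trusted ClinVar label always
wins over the frequency rule.

## Parameters and defaults

All defaults live in `sbna_config()`:

| Parameter | Default | Rationale |
|---|---|---|
| `contact_cutoff` | 4.5 Å | Conventional heavy-atom contact distance: first coordination shell including water-mediated and van der Waals contacts. |
| `exclude_adjacent` | 1 | Peptide-bonded neighbours are in obligatory contact; the edge carries no information about the fold. |
| `subscore_weights` | `c(1, 1, 1, 1)` | No sub-score is privileged a priori; weights are exposed for sensitivity analysis. |
| `solvent_list` | water + common additives | Crystallization components carry no biological contact signal. |
| `threshold_modified` | 1.5 (strict `>`) | Calls roughly the top tail of the modified-score distribution; strictness matters only for exact boundary values. |
| `threshold_eve` | 0.65 (`≥`) | The EVE pathogenic-class boundary as consumed from input. |
| `threshold_combined` | 1.0 (`≥`) | Sum of the scaled minimum pathogenic modified score and the minimum pathogenic EVE score. |
| `min_stars` | 2 | Two ClinVar stars = multiple concordant submitters with assertion criteria. |
| `gnomad_min_count` | 250 | High allele counts are incompatible with a fully penetrant rare disease allele. |

Scoring-side parameters (`probe = 1.4 Å`, `n_points = 960` for
accessibility) follow the water-probe convention and a point count at
which quadrature error is small relative to biological variation.

## Synthetic generators: realism and limits

The generators exist so that the full pipeline — parsing, preparation,
graph construction, scoring, variant evaluation — can be exercised
offline against topologies whose ground truth is known by construction.
They are *not* realistic proteins:

- `ideal_helix` places backbone plus CB atoms on ideal α-helix geometry
  (1.5 Å rise, 100° twist). Real helices bend and have full side chains.
- `two_domain` builds two circular near-clique clusters joined by a
  four-bead extended linker. The linker is the only inter-domain route,
  so it must carry the top bridging scores. Two deliberate artifices:
  the linker beads carry permuted (non-consecutive) residue numbers so
  the adjacency exclusion cannot sever the inter-domain path, and the
  terminal beads sit close enough to each domain to contact several
  residues, so no single "gateway" residue out-bridges the linker.
- `compact_cluster` is one dense circle in which every residue pair is
  within contact range — a degenerate, maximally connected control.

Residue sequences are sampled uniformly from the 19 non-glycine amino
acids; glycine is excluded so every residue has a CB atom and the contact
topology is independent of the sampled sequence. The optional 5-atom
ligand is placed by deterministic search so that exactly three designated
residues touch it. Extra conformers add seeded Gaussian jitter
(sd 0.2 Å), small enough to keep the designed topology.

Variant generation plants pathogenicity as a logistic law on the modified
score, `P(pathogenic) = plogis(qlogis(base_rate) + slope × modified)`,
with optional label noise, and emits labels as two-star ClinVar strings
so the standard labeling path is used. The planted truth is carried in
`planted_prob`/`planted_label` columns for diagnostics. EVE values are a
noisy monotone transform of the planted probability — a stand-in with the
right support and direction, not a simulation of the EVE model.

What the fixtures establish: that the implementation recovers topology it
was designed to have, and that planted signals of known strength are
recovered at the expected discrimination. What they cannot establish: any
claim about real proteins, real ClinVar label quality, or the clinical
AUC of the method.

## Numerical choices

- **Betweenness** uses `igraph` on edge lengths `1/weight`; the test
  suite cross-checks it against an independent Floyd–Warshall
  path-counting oracle on small graphs.
- **AUC** is computed by the rank (Mann–Whitney) formulation with
  average-rank ties, making `auc == U/(n₁n₀)` an identity rather than an
  approximation; tests verify it to 1e-12 against exhaustive pair
  counting.
- **Accessibility** uses deterministic 960-point golden-spiral
  Shrake–Rupley quadrature with Tien et al. (2013) theoretical maxima,
  and RSA is clipped at 1 (exposed termini can exceed the tripeptide
  maxima). The fixed quadrature is exactly translation-invariant but only
  approximately rotation-invariant (~1% drift), which is below any
  threshold the package applies to RSA.
- **Dunn's post hoc** z statistics use the tie-corrected variance
  `(N(N+1)/12 − Σ(t³−t)/(12(N−1)))` and Bonferroni adjustment
  `min(1, m·p)` — written out in full because no suitable dependency was
  available, and verified against direct computation in tests.
- **Zero-intercept logistic regression** is fit by IRLS with a tiny ridge
  (1e-6) so complete separation yields a finite, usable coefficient
  instead of divergence; the fit matches `glm` to 1e-4 on
  well-conditioned data. The split protocol draws all randomness from a
  scoped seed, restoring the caller's RNG state, so results are
  bit-reproducible and composable.
- **Null calibration** of the split protocol is estimated by averaging
  over independent label shuffles: a single permutation retains a
  spurious O(1/√n) signal shared by all of its splits, so one shuffle's
  mean AUC is not itself centred on 0.5 at small n.

## Design decisions on under-specified points

Choices this package had to make where the method description leaves
room, recorded so users can judge them:

- The min–max scale for the combined score is taken over the full variant
  table being scored (which may span several genes); a fixed external
  range can be supplied via `scale_range` when scoring new variants on a
  previously established scale.
- The modified-score call uses a strict inequality, the EVE and combined
  calls inclusive ones; boundary values are exercised in tests.
- Altloc resolution keeps the conformer with the highest mean occupancy
  per residue, breaking ties alphabetically for determinism.
- Modified residues with a known parent (MSE, SEP, TPO, …) are renamed to
  the parent and scored; unknown HET groups become ligands.
- Conformer averaging covers positions missing from some models by
  averaging over the models that contain them (with a warning at
  preparation time when conformer keys disagree).

## Limitations

- Scores are single-chain and single-structure; no ensemble docking, no
  conservation beyond the externally supplied EVE input.
- The contact model ignores atom chemistry: a salt bridge and a van der
  Waals graze at the same distance count equally.
- Fixture-derived performance numbers characterize the implementation,
  not the biology; study-scale evaluation requires the external databases
  and is out of scope here.
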