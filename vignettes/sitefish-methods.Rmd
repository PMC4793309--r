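---
title: "Binding-site similarity search and target fishing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-site similarity search and target fishing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitefish)
```

## The problem

Many drugs act on more than one protein. Inverse target fishing asks, for a
given small molecule with at least one solved protein–ligand complex, which
other proteins in a proteome carry a local arrangement of residues similar
enough to the known binding pocket to plausibly bind the same ligand.
`sitefish` implements this as a four-stage funnel:

1. **Site definition.** The binding site is the set of protein residues with
   at least one heavy atom within 5 Å of any ligand heavy atom.
2. **Local structure search.** Each database structure is scanned for
   residue combinations whose types are substitutable for the site residues
   (BLOSUM62 score ≥ 1) and whose Cα contact pattern matches the query's.
3. **Pose gate.** The query ligand is rigidly transplanted into each match
   and accepted or rejected on steric and contact criteria.
4. **Energy ranking.** Accepted poses receive an interaction enthalpy; a
   fixed entropy correction converts it to a binding free energy, and only
   targets with ΔG < 0 are kept.

Pocket statistics, a structural-similarity network, and hypergeometric
pathway over-representation summarize the surviving targets.

## The search statistic

For a query site of $n$ residues with representative-atom (Cα) coordinates,
the *contact matrix* is the $n \times n$ matrix of pairwise distances
$d^q_{ij}$. For a candidate residue combination in a target structure with
distances $d^c_{ij}$, the contact matrix average deviation is

$$\mathrm{CMAD} = \binom{n}{2}^{-1} \sum_{i<j} \left| d^q_{ij} - d^c_{ij} \right|,$$

in Å. Candidates are generated by an anchor-and-extend enumeration: the
query residue pair with the largest inter-residue distance is matched first
(long distances are rarest in a folded chain, so this pair prunes hardest),
and remaining positions are added one at a time, discarding any partial
mapping with a pairwise deviation above `pair_tol` (default 2 Å).
Enumeration is exact up to a candidate cap (default 50,000, with a
truncation flag); on small instances it is tested against exhaustive
enumeration of all code-compatible subsets.

Candidates with CMAD below `cmad_cutoff` (default 1.5 Å — roughly three
times the deviation produced by 0.3 Å coordinate noise, and far below the
5–10 Å typical of unrelated residue combinations) are superposed onto the
query by the Kabsch algorithm, with the reflection corrected to a proper
rotation. The best (lowest-RMSD) candidate per structure is the structure's
match.

**Significance.** The original contact-matrix search tool reports an
RMSD-based P-value whose analytic form is not public; `sitefish` instead
calibrates an empirical null by sampling random code-compatible residue
combinations from decoy structures and recording their RMSD to the query.
The add-one estimate $p = (1 + \#\{\mathrm{null} \le r\})/(N+1)$ is
conservative and never zero; the E-value is $p$ times the database size,
and hits are significant at E < 0.01. The default of 20,000 null samples
resolves P-values down to $5\times10^{-5}$, small enough for E < 0.01 at
database sizes of a few hundred. The null is a pure function of its seed.

## The docking gate

The original pipeline used a commercial simulated-annealing docking engine
only as a binary per-protein filter ("failed to dock ⇒ removed") plus one
retained pose. `sitefish` preserves exactly that contract with a
deterministic geometric stand-in: the query ligand is carried into the
target frame by the match's rigid transform, and the pose passes iff it has
no protein heavy atom closer than 2.2 Å (a hard-sphere clash) and at least
3 protein heavy atoms within 4.5 Å (the pose actually sits in a pocket).
These defaults were chosen so that self-transplants onto the source complex
always pass while poses overlapping backbone atoms always fail; both
properties are asserted in the test suite. A docking sphere has no analogue
in a transplant scheme and is intentionally omitted. Hydrogen bonds are
detected by a distance-only rule (ligand N/O to protein N/O within 3.5 Å),
since neither deposited nor generated structures carry hydrogens.

## Free-energy bookkeeping

Binding free energy follows end-point bookkeeping,

$$\Delta G = G_\mathrm{complex} - G_\mathrm{receptor} - G_\mathrm{ligand} - T\Delta S,$$

with the enthalpic difference ΔH supplied by a pluggable scorer. The
entropy term is fixed once for all targets, derived from the experimental
binding constant of aspirin to phospholipase A2
($K = 1.56\times10^{5}\,\mathrm{M}^{-1}$) via
$-RT\ln K = \Delta H - T\Delta S$, i.e.
$T\Delta S = \Delta H + RT\ln K = -2.327 + 7.055 = 4.728$ kcal/mol.
Note that the printed $RT\ln K = 7.055$ kcal/mol implies $T \approx 297$ K
rather than 298.15 K; `entropy_from_constant()` therefore accepts the
printed value as an `rt_ln_k` override so the worked example is exact,
while the default constants are $R = 1.9872\times10^{-3}$ kcal/(mol·K),
$T = 298.15$ K. The ΔG < 0 filter is strict: ΔG = 0 is dropped.

Because ΔG = ΔH − TΔS, a larger subtracted TΔS *lowers* ΔG and admits more
targets; the filter's monotonicity test asserts this direction.

The packaged target table (`extdata/table1_targets.tsv`) reproduces the
published funnel output: 23 targets with ΔG < 0, of which 14 fall outside
the primary families (phospholipase A2, prostaglandin G/H synthase,
chitotriosidase), mean ΔG over new targets −18.4 kcal/mol, range −33.0
(EXOSC3) to −6.0 (PLA2G2D). Recomputing the primary-family mean from the
table gives −15.13 kcal/mol where the source text prints −15.3; the
recomputed value is reported and the printed one is not treated as a
reference quantity. The table preserves its source ordering (it is not
sorted by ΔG — e.g. PTGS1 at −27.6 appears after PTGS2 at −20.2) and is
only sorted on request.

**The demo scorer.** Full Poisson–Boltzmann solvation is out of scope; the
default scorer is a pairwise 12-6 Lennard-Jones (rmin form, well depth
0.25 kcal/mol, rmin 3.8 Å, generic per-element parameters) plus a
distance-dependent-dielectric Coulomb term over ligand–protein heavy-atom
pairs within 9 Å. For a rigid transplant the intramolecular energies of
receptor and ligand cancel in the bookkeeping, so the scorer reports
$G_\mathrm{receptor} = G_\mathrm{ligand} = 0$ and ΔH equals the interaction
energy; the Eq-style bookkeeping is exact regardless of the scorer. The
well depth was set so that a formed pocket of 10–17 residues produces
interaction enthalpies on the −5 to −30 kcal/mol scale of the published
targets. The scorer exists to drive the pipeline with finite, ordered
enthalpies; its absolute values are not physical binding energies.

## Redundancy removal and the query set

Database redundancy is removed by greedy longest-first clustering: visiting
structures by decreasing sequence length, each joins the first
representative with global-alignment identity ≥ 0.95, else founds a
cluster. Identity uses Needleman–Wunsch (match +1, mismatch 0, gap −1) and
is normalized by the shorter sequence length — the CD-HIT convention. The
word-filter heuristics of CD-HIT itself are not reproduced; at a 0.95
cutoff the greedy rule collapses the same near-duplicates. Clustering
operates on whole-structure concatenated sequences (whether the original
database clustered full entries or single chains is not stated; this choice
is recorded here). The aligner's traceback tie-break is fixed
(diagonal > up > left) so results are machine-independent.

The query set reduces a configured list of ligand complexes to one per
protein family. Because the published set keeps the *first* member of one
redundant pair (1OXR over 1TGM) but the *second* of another (3GCL over
2QQT), the rule cannot be positional; the configuration carries an explicit
`keep` flag and otherwise keeps the first-listed member. The packaged
configuration reproduces the published five-complex set
(1OXR, 3GCL, 4NSB, 3IAZ, 1PTH).

## Similarity network and enrichment

The published structural comparison used the Combinatorial Extension
aligner; `sitefish` substitutes sequence-alignment-guided superposition
(global alignment under BLOSUM62 with linear gap −5, Kabsch RMSD over
aligned Cα pairs). For homologous or fixture-scale pairs this matches the
intent; for remote homolog-free pairs a sequence-guided alignment can miss
structural equivalences, which is a documented divergence. Network edges
require RMSD strictly below 4 Å; pairs with fewer than 3 aligned residues
are incomparable and get no edge.

Pathway over-representation uses the hypergeometric upper tail against a
user-supplied annotation (GMT format) — no web service is called, so
published enrichment P-values, which depend on a historical annotation
version, are not reproduction targets. Both Benjamini–Hochberg and
Bonferroni adjustments are provided because the source describes both; the
default is BH at α = 0.01. The percentage column divides by the number of
target genes mapped into the background, not the raw target count (the
published table's percentages back-calculate to the mapped denominator).

## What the synthetic generator emulates — and what it does not

Decoys are confined self-avoiding Cα walks: step 3.8 Å, non-adjacent Cα
separation ≥ 4.0 Å, confinement radius $3.0\,n^{1/3}$ Å (protein-like
packing). Each residue carries deterministic stub atoms — backbone-like N
and O at 1.3 Å and a Cβ at 1.5 Å on a local frame (no Cβ for glycine) — so
heavy-atom distance rules, clash screens and polar-pair hydrogen-bond
detection all have atoms to act on. The toy ligand is a fixed 13-heavy-atom
aspirin-like molecule (planar aromatic core, carboxylate, ester-acetyl arm,
4 oxygen acceptors). Query complexes place the ligand at the best of the
eight densest chain neighborhoods and carve a cavity by removing residues
within 3.2 Å (a realistic van der Waals contact floor); this one-time
parameterization puts generated pocket sizes inside the empirically
observed 10–26 residue envelope, which is asserted as a generator test.

Planting copies the site's Cα coordinates into a decoy's densest cluster
under a random rotation, adds per-coordinate Gaussian noise, swaps a chosen
number of residue labels within their BLOSUM62 substitution sets (positions
whose only allowed code is their own — C, G, P — are never chosen), and
carves a cavity around the carried-along ligand. Ground truth (planted ids
and residue mappings) is recorded for sensitivity and specificity
benchmarks.

What this does **not** emulate: real secondary structure, side-chain
rotamers and packing, crystallographic noise models, sequence composition
bias, and genuinely homologous decoys. Passing the planted-site benchmarks
therefore demonstrates the correctness and calibration of the search
machinery — not proteome-scale discovery performance, which depends on a
real structure database. For the same reason the published funnel counts
(79 search hits, 26 post-docking) are not desk-reproducible and are not
test targets.

## Numerical choices and degenerate inputs

* Distances use exact Euclidean arithmetic on double precision; contact
  matrices are symmetric by construction and checked to 1e-6.
* Kabsch handles collinear point sets (rank-1 covariance) naturally; rank-0
  (all points identical) is an error. Reflection is corrected by flipping
  the singular direction with the smallest singular value.
* The empirical P-value is never 0 or inflated by ties (add-one, `<=`).
* Sites need at least 3 residues; smaller extractions are errors, not empty
  sites.
* Residues lacking a Cα are dropped at parse time with a warning; altloc
  records other than blank/'A', waters, and models after the first are
  discarded. Hydrogens are kept but flagged, and excluded from every
  distance rule.
* All randomness flows through explicit integer seeds; reruns with the same
  configuration are byte-identical at the table level.

## Problem sizes used in the test and acceptance runs

The shipped benchmarks run 10 planted structures (noise 0.3 Å, one
substitution) among 100 decoys of 80 residues with a 20,000-sample null —
about one minute end to end on one core. Unit tests use smaller instances
(decoy sets of 6–15 structures, null sizes of 500–5,000) chosen to keep the
whole suite within a few minutes while preserving the discriminating power
of each check; exhaustive oracles run at sizes (≤ 12 residues, N ≤ 12
genes) where enumeration is exact.

## Known limitations

* The enumeration cap can truncate pathological targets with huge numbers
  of compatible combinations; truncation is flagged, and raising the cap
  can only improve the best CMAD (tested).
* The pose gate cannot rescue a correct target whose match transform is
  poor, and has no conformational flexibility.
* The empirical null is calibrated against decoys from the synthetic
  generator; with a real database the decoy set should be drawn from that
  database's own composition.
* The demo scorer has no solvation or entropy model beyond the fixed
  correction; its ΔG values order targets but do not predict affinities.
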