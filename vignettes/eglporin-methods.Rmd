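---
title: "Methods: annotating and testing the TMD5 glycerol-permeability rule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and testing the TMD5 glycerol-permeability rule}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eglporin)
```

## The scientific problem

Aquaporins conduct water through a narrow pore whose selectivity is set by
two elements: the paired Asn-Pro-Ala (NPA) boxes meeting at the channel
centre, and the aromatic/arginine (ar/R) quartet at the outer vestibule.
On the water-selective branch of the superfamily (AQP4-like channels,
including the insect Prip and Drip subfamilies) a histidine contributed by
transmembrane domain 5 (TMD5) sits directly in the ar/R constriction and
sterically excludes glycerol. Insect glycerol transporters
(entomoglyceroporins, Eglps) are AQP4-branch channels in which this single
histidine is replaced by an uncharged residue — most often Ala or Ser —
which opens the constriction enough to pass glycerol. The package encodes
this as a testable residue rule, together with the annotation machinery
needed to read the TMD5 position off arbitrary aquaporin peptides, an
in-silico mutagenesis layer to flip the residue both ways, a geometric pore
profiler, and estimators for the oocyte assays by which glycerol transport
is measured functionally.

## Annotation model

Queries are mapped onto an annotated AQP4-like template by global
Needleman–Wunsch alignment (BLOSUM62, affine gaps 11/1, via
`Biostrings::pairwiseAlignment`), and the template's annotated coordinates
are read through the resulting residue mapping. The template records the
two NPA box positions, the four ar/R positions (labelled `TMD2_aromatic`,
`TMD5`, `LE1`, `LE2`) and a conserved transmembrane core (Thr31–Phe258 in
AQP4 numbering) that anchors coverage: a mapping covering less than 50% of
the core is refused rather than trusted. Only the TMD5 ar/R position is
load-bearing for the permeability rule; the other three quartet positions
are carried as configurable template data. Alignment is used in place of
any hydropathy-based topology prediction; Biostrings' deterministic
traceback supplies a single reproducible optimal alignment, which is the
property the mapping needs.

NPA scanning admits `N-P-[ASTVLIM]` by default (strict `N-P-A` is one
argument away), since third-position variation occurs across the
superfamily; hits are labelled by sequence half because a canonical channel
contributes one box from each pseudo-symmetric half.

### The packaged template and references are synthetic

No database sequences ship with the package. The template and the
six-subfamily reference panel are *synthetic surrogates*: randomly composed
membrane-protein-like scaffolds (built once, fixed seed, by
`tools/make_reference_fixtures.R`) that carry the literature anchor
residues at the literature coordinates — His201 and the Thr31/Phe258 core
in the AQP4 surrogate, His197 in the Prip surrogate (a 4-residue N-terminal
truncation), Ala174 in the Eglp surrogate (a 27-residue truncation), a Glp
surrogate with the glycerol-branch Gly, and Bib/Aqp12-like outliers. Their
filenames and headers say `synthetic` explicitly. This makes every residue
index the package reports positionally faithful to the field's numbering
while keeping the artifact self-contained and honest about provenance.
Water-branch references were placed closer to the AQP4-like scaffold (25%
site divergence) than the Glp/Bib/unorthodox references (35–40%), mirroring
the branch structure of the superfamily, so nearest-reference
classification is well posed.

## Classification and the permeability rule

Tree inference over hundreds of taxa is out of scope; subfamily assignment
is a nearest-reference surrogate: the query is aligned to each reference
and takes the subfamily of the best length-normalised score. The margin
between best and second-best normalised scores is a confidence surrogate;
below 0.05 (default, configurable) the subfamily is `unclassified`, though
the branch is still reported when every reference within the margin agrees
on it. Ties break by panel order and the nearest reference id is always
reported.

The permeability rule is a pure function of (branch, TMD5 residue):

* `glp_branch` → `transporter` (rationale `GLP_BRANCH`);
* water branch, TMD5 ∈ {H, K, R, D, E} → `water_selective`
  (`TMD5_HIS` when His);
* water branch, TMD5 uncharged (all other canonical residues) →
  `transporter` (`TMD5_UNCHARGED`); outside the functionally verified
  {A, S, V} subset the call is additionally flagged `rule_extrapolated`,
  because Gly/Thr/Cys-type channels have not been assayed;
* TMD5 `X` or unmappable → `indeterminate` — the rule refuses to call what
  it cannot see.

For the unorthodox (Aqp12-like) branch the source framework defines no
rule; the package applies the same TMD5 residue logic there as an explicit
extrapolation, on the grounds that the rule is local to the ar/R
constriction.

The packaged seven-channel mutant panel — PvAqp2 wild type and A174H,
BgAqp wild type and H197S, AQP4 wild type, H201A and H201S — runs
annotation → mutation → prediction end to end and reproduces the
experimental flip pattern: every His-bearing wild type or back-mutant is
called water-selective, every uncharged-TMD5 form a transporter.

## Pore geometry

`pore_radius_profile()` reports, at each axial sample, the radius of the
largest sphere that can be centred in the perpendicular plane without
overlapping any atom (van der Waals radii from the packaged Bondi table),
located by a coarse 0.2 Å grid over a 5 Å search disc followed by
pattern-search refinement. The refinement step is driven down to 1e-7 Å by
default: the max–min objective is piecewise linear near its optimum, so
positional accuracy converts one-for-one into radius accuracy, and this
tolerance keeps profiles invariant under rigid motions to ~1e-6 Å while
costing only a few hundred extra evaluations. A fully occluded plane is
radius 0, not an error. Mutants are modelled conservatively by *removing*
side-chain atoms (His→Ala/Ser direction only); no rotamers are placed and
no energies are evaluated, so mutant profiles are upper bounds on pore
widening, which is the direction the comparison needs. The constriction
report labels its quantity explicitly as a radius, avoiding the
radius/diameter ambiguity common in pore-size figures.

## Oocyte assay estimators

Osmotic water permeability follows
$P_f = V_0 \, \frac{d(V/V_0)}{dt} \Big/ \big(S\, V_W\, (\mathrm{Osm}_{in} -
\mathrm{Osm}_{out})\big)$
with $V_W = 18\ \mathrm{cm^3\,mol^{-1}}$, the gradient converted from mOsm
to mol cm⁻³ (1 mOsm = 1e-6 mol cm⁻³), and $S$ nine times the apparent area
(membrane folding; configurable). The slope is ordinary least squares over
the sampled 0–20 s window by default; a shorter window trades precision for
less gradient-dissipation bias (at the default simulated conditions the
full-window estimator is biased low by ~2–3%, well inside the 10% design
tolerance). Radiotracer uptake subtracts the zero-time group mean, converts
counts to moles via specific activity and a counting-efficiency knob
(default 1 — only relative comparisons depend on it), scales by the
total/hot concentration ratio, and clamps negative post-subtraction values
to 0 while counting them. The dose–response plateau is the smallest dose
whose mean is not significantly lower (one-sided Welch test, α = 0.05) than
the maximal-mean dose. Group statistics are one-way ANOVA with Dunnett
many-to-one comparisons against the control (`multcomp`); `method =
"holm"` gives an exactly deterministic fallback (Dunnett p-values use
randomized multivariate-t quadrature and wobble in the fourth decimal).
All-identical inputs short-circuit to F undefined, p = 1.

## Synthetic data: what it emulates and what it does not

The generators exist so every stage is testable offline with known truth.

* **Cohorts** derive sequences from the packaged reference scaffolds by
  seeded per-site substitutions at non-anchor sites (anchors ±2 frozen),
  plant the NPA boxes and ar/R quartet exactly, scrub any
  substitution-created spurious NPA triplet, and emit a truth table. The
  default Eglp TMD5 distribution draws from {Ala, Ser, Val} with weights
  0.40/0.33/0.27 — an expected 73% Ala-or-Ser, the observed
  entomoglyceroporin spectrum; Prip/Drip keep His. What this does *not*
  emulate: indels, domain shuffling, compositional drift, alignment
  ambiguity in loop regions — so passing recovery tests show the
  classifier and extractor are correct *under substitution-only
  divergence*, not that they would survive arbitrary real-sequence
  pathology.
* **Swelling** integrates the two-compartment flux law
  $dV/dt = P_f S V_W (C_{in}(t) - C_{out})$ with internal osmolyte amount
  conserved ($C_{in} = C_{in}(0) V_0 / V$), fixed-step RK4 at 0.1 s,
  sampled every 2 s over 0–20 s with i.i.d. Gaussian noise (σ = 0.002,
  chosen to resemble video-tracking jitter; no noise model is stated in
  the source protocol). The analytic initial slope is recorded as truth.
  Real oocyte artefacts — membrane unfolding, non-instant solution
  exchange, volume-tracking bias — are not modelled.
* **Uptake** draws Poisson counts around `background + truth × conversion`
  with a Poisson zero-time group, emulating scintillation counting noise
  only.
* **Toy channels** are rings of pseudo-atoms with a closed-form minimal
  pore radius, giving the profiler an exact oracle.

All generators are pure functions of (config, seed) and restore the
caller's RNG state.

## Problem sizes and numerical choices

The shipped tests run the quartet-recovery property at 500 replicates (20%
divergence, ≥99% required), classifier recovery at 500 draws (30%
divergence, ≥95%), Pf closed-loop recovery at 100 seeded cohorts of 10
oocytes per true value, the ANOVA null at 1,000 replicates (type-I rate
within [0.03, 0.07]), and the pore profiler against 20 randomized cylinder
closed forms (0.05 Å band) — sizes at which the binomial/Monte-Carlo noise
of each check is comfortably below its acceptance band. Degenerate inputs
are decided, not left to chance: zero-variance groups give p = 1, occluded
pores give radius 0, empty cohorts refuse to summarise, unknown accessions
resolve to an explicit `integration-skipped` status (the resolver is
offline by design and only maps known accessions to the packaged synthetic
surrogates).

## Known limitations

* Subfamily calls are nearest-reference, one representative per subfamily:
  adequate for planted-truth cohorts and the packaged panel, not a
  substitute for phylogenetic placement of novel deep-branching sequences.
* The TMD5 rule is deliberately single-residue; real permeability also
  depends on the rest of the filter and the pore lining, which is why
  uncharged-but-unverified residues are flagged rather than asserted.
* The synthetic references preserve positions, not biochemistry: alignment
  scores against them are internally consistent but not comparable to
  scores against real sequences.
* Pf estimation assumes the stated geometry; errors in $V_0$ or the
  folding factor propagate linearly into $P_f$.
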