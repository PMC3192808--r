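---
title: "Modelling multivalent adaptor-scaffold binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multivalent adaptor-scaffold binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avidity)
```

## The problem

An adaptor protein with two SH3 domains (Grb2 is the packaged example)
binds a scaffold whose disordered tail presents several polyproline
motifs (the Sos1 tail presents five). Each single interaction is weak —
tens of micromolar to low millimolar — yet the complex as a whole is
held at low micromolar affinity, because once one SH3 domain is bound
the remaining motifs are tethered near the second domain at a high
effective local concentration. This vignette explains the model the
package implements, the choices made where the design was open, and what
the synthetic-data generators do and do not emulate.

## Motif grammar and linker architecture

SH3 ligands come in two orientations. `scan_motifs()` uses the field's
standard consensus windows: class I `[RK]-x-x-P-x-x-P` (7 residues) and
class II `P-x-x-P-x-[RK]` (6 residues), with pure wildcards at the `x`
positions. These windows classify all five packaged scaffold peptides
correctly (P1-P4 as class II, RP as class I) and reject the
arginine-to-alanine mutant of P1, the classic negative control. Sites
are reported as minimal windows; overlapping candidate windows of the
same class are merged to the leftmost one so that output never depends
on scan order. Coordinates are 1-based and inclusive, matching how
residue ranges are quoted in the literature. A stricter consensus with
hydrophobic positions would not change the packaged peptides but could
matter on other proteomes; the pure-wildcard form is the deliberate,
more sensitive default.

Linker length between two motifs is counted as the residues strictly
between the two matched windows (`build_layout()`), because in the bound
state the SH3 domains grip the motif residues themselves and only the
intervening chain is free tether. `ceff_table(include_motif_flanks =
TRUE)` adds the motif spans to the contour for users who prefer the
more permissive convention.

Alignment conservation (`column_conservation()`) is majority identity
per column over non-gap rows, with gaps excluded from numerator and
denominator and all-gap columns scored 0 — the simplest rule consistent
with "identity within each column", made explicit about gaps.

## The worm-like chain and its units

The linker is modelled as a worm-like chain in the long-chain limit,
where the end-to-end vector is Gaussian:

$$p(r) = \left(\frac{3}{4\pi l_p L_c}\right)^{3/2}
  \exp\!\left(-\frac{3r^2}{4 l_p L_c}\right),
  \qquad \langle r^2 \rangle = 2\, l_p L_c .$$

Defaults are $l_p = 3.0$ Å, the standard persistence length of unfolded
polypeptides, and $b = 3.8$ Å per residue (the C$\alpha$–C$\alpha$
virtual bond), so $L_c = n b$ for an $n$-residue linker. Both are plain
parameters of `wlc_params()`: measured persistence lengths creep upward
with chain length, so long disordered regions may warrant a larger
$l_p$, and the package takes that as input rather than guessing a
length dependence. The Gaussian limit is appropriate because the
linkers of interest (tens to hundreds of residues, $L_c \gg l_p$) are
far from the rod regime; finite-stiffness corrections and excluded
volume are out of scope.

A classic pitfall in effective-concentration work is confusing the
per-volume density of the end-to-end *vector* with the per-length
density of the scalar distance ($4\pi r^2$ times larger). The package
names the convention in every function: `wlc_vector_density()` is per
Å$^3$ and is what enters the overlap integral; `wlc_radial_density()`
is per Å and is what a histogram of distances estimates.

## Effective local concentration

$C_\mathrm{eff}$ is the overlap of two densities: the WLC density of
the linker end-to-end vector and the density of the vector between the
two bound anchor points of the adaptor. Only scalar anchor distances
are observable in the intended measurement (C$\alpha$–C$\alpha$
distances along a simulation), so the anchor distribution is treated as
isotropic and the overlap collapses to averaging the WLC vector density
at the sampled radii:

$$C_\mathrm{eff} = \frac{1}{N}\sum_k p(r_k)
  \times \frac{10^{27}}{N_A} \;\mathrm{mol/L}.$$

The unit conversion follows from $1$ molecule/Å$^3$ = $10^{27}/N_A$
mol/L; one molecule per $(1000\,\text{Å})^3$ is $1.66$ µM, which the
test suite asserts as the unit-sanity anchor. Three interchangeable
back-ends cover the practical cases: `ceff_hybrid()` for empirical
samples or histograms, `ceff_delta()` for a single representative
separation, and the analytic Gaussian–Gaussian overlap (used as the
test oracle) when the displacement is modelled as an isotropic Gaussian
with mean $\mu$ and per-axis variance $\sigma^2$:

$$C_\mathrm{eff}^{\mathrm{analytic}} =
  \left(\frac{3}{2\pi(2 l_p L_c + 3\sigma^2)}\right)^{3/2}
  \exp\!\left(-\frac{3|\mu|^2}{2(2 l_p L_c + 3\sigma^2)}\right)
  \times \frac{10^{27}}{N_A}.$$

Which anchor pair the distance refers to depends on the classes and
sequence order of the two motifs; the package takes the appropriate
trace as data rather than encoding that structural logic.

## Equilibrium algebra

Free energies and dissociation constants interconvert by
$K_d = \exp(\Delta G / RT)$ with $R = 1.987\times10^{-3}$ kcal/(mol K)
and $T = 298$ K by default; these settings reproduce the paired
columns of the packaged peptide-binding tables to two significant
figures. The doubly bound state has

$$K_{d,\mathrm{eff}}(i, j) = \frac{K_{N,i}\, K_{C,j}}{C_\mathrm{eff}(i,j)},$$

independent of binding order by detailed balance. Units are µM
throughout the algebra; $C_\mathrm{eff}$ enters in mM and is scaled by
$10^3$ on use, which is also how the published effective-constant table
is self-consistent.

With $m$ motifs there are $2m$ singly bound and $m(m-1)$ doubly bound
1:1 configurations ($m = 5$ gives 30). Their associations sum to
$K_{GS}$; the singly bound share of that sum is the predicted fraction
of 1:1 complexes held by one domain (about 10% on the packaged tables,
so ~90% of complexes are doubly bound).

### The 2:1 indistinguishability convention

A 2:1 complex is an unordered pair of 1:1 modes with disjoint motif
sets, and because the two adaptor molecules are identical a symmetry
factor applies. Two conventions are implemented, and they are *not*
numerically equivalent:

- `"strict"`: every unordered pair of distinct modes is weighted by the
  plain product $K_1 K_2$ — the textbook correction of the ordered
  double sum by $1/2$. On the packaged tables this gives a 2:1
  composition of roughly 53% both-doubly / 43% mixed / 4% both-singly.
- `"paper"` (default): doubly–singly cross pairs carry an extra factor
  of $1/2$, i.e. they are counted once in the double sum *before* the
  global halving. This reproduces the published 68/27/5 composition
  (67.6/27.4/5.1 when effective constants are re-derived from
  $C_\mathrm{eff}$; 67.0/27.8/5.2 on the published rounded constants).

The package defaults to `"paper"` because it reproduces the reference
results; whether the extra half is a deliberate counting choice or an
artefact of unrounded inputs cannot be decided from the published
numbers alone, so both conventions are first-class and the tests verify
both against an independent ordered-pair enumeration. $K_{GSG}$ is the
total pair weight divided by $K_{GS}$ — the conditional association of
a second adaptor given an existing complex.

## Speciation

With only 1:1 and 2:1 complexes, mass action plus conservation reduce
to one monotone equation in free adaptor concentration, solved by
`stats::uniroot` bracketed on $[0, G_\mathrm{tot}]$ and polished by a
few Newton steps so that both conservation laws hold to $10^{-9}$
relative (the raw bracket tolerance alone does not guarantee that). The
$K_{GSG} = 0$ limit is checked against the closed-form quadratic of
simple bimolecular binding, and all fractions are invariant under
jointly rescaling concentrations and constants — the natural
dimensional check. Absolute cellular concentrations are inputs, not
constants: the documented example uses 1 µM adaptor against 0.1 µM
scaffold, a 10:1 ratio typical of the cytosolic setting, and
`stoichiometry_sweep()` reproduces titration-style dose curves.

## What the synthetic generators emulate

- `gen_distance_trace()` emulates a simulation-derived anchor-distance
  series as $|\mu + \varepsilon|$ with isotropic Gaussian noise — a
  non-central chi law with 3 degrees of freedom. Real anchor dynamics
  are autocorrelated and multi-modal (four distinct distributions arise
  depending on motif classes and order); the generator makes no attempt
  at either, so passing the parameter-recovery tests shows estimator
  correctness, not simulation realism.
- `gen_sequence()` assembles motif templates and background linkers so
  the realised consensus windows sit exactly the requested number of
  residues apart; the background alphabet excludes P, R and K so no
  unintended motif can form, which makes round-trip tests exact but
  also means the linker composition is not naturalistic. The generator
  re-scans its own output and refuses to return a sequence whose
  recovered layout differs from the request.
- `gen_msa()` draws a consensus residue per column and realises the
  target identity as an independent Bernoulli per sequence — no
  phylogeny, no gaps. Conservation recovery is binomial, so tests
  compare at three standard errors.

## Numerical choices and problem sizes

Quadrature checks of normalisation and $\langle r^2 \rangle$ use
`stats::integrate` at $10^{-9}$ relative tolerance; Monte-Carlo checks
of the hybrid estimator use $2\times10^5$ frames in routine tests and
$10^6$ frames for the 1%-relative comparison with the analytic overlap;
speciation conservation is exercised on 1000 random instances spanning
nanomolar to millimolar totals and association constants over seven
orders of magnitude; sequence round-trips run 100 seeded constructs
with 2-4 motifs and linkers of 12-60 residues. Histogram binning is
equal-width with a caller-chosen bin count (100 by default, matching
the standard analysis); a degenerate all-identical trace is given a
1 Å support so the density remains well-defined.

## Known limitations

- Three cells of the published effective-constant table cannot be
  re-derived from the published single-site constants and
  effective concentrations within the rounding of those inputs (the
  worst cell deviates 9.3% where rounding can explain at most ~4%);
  the corresponding check in the test suite documents this
  inconsistency rather than hiding it. The two-significant-figure
  rounding of the published $C_\mathrm{eff}$ values dominates the
  remaining cells' residuals.
- Single-site affinities come from short isolated peptides; flanking
  sequence in the intact scaffold may shift them, and any allosteric
  coupling between the two SH3 domains is neglected.
- The WLC treatment ignores linker-domain interactions and excluded
  volume; scaffolds with structured interruptions between motifs
  violate the Gaussian-chain assumption.
- The speciation model stops at 2:1 complexes; higher-order assemblies
  (e.g. one adaptor bridging two scaffolds at a membrane) are out of
  scope.
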