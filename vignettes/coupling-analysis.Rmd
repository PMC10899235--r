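---
title: "Dose-response fitting, mutant-cycle coupling and pore geometry for pentameric ligand-gated ion channels"
author: "channelCoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response fitting, mutant-cycle coupling and pore geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(channelCoupling)
```

## Scope and model

This package implements the quantitative pipeline used to dissect how
agonist binding is coupled to channel gating in pentameric ligand-gated ion
channels (pLGICs), with the muscle-type *Torpedo* nicotinic acetylcholine
receptor as the worked system. Four stages are covered:

1. **Dose-response fitting.** Each oocyte's two-electrode voltage-clamp
   (TEVC) peak currents are fit with the variable-slope Hill model
   \[ I(c) = I_{\max}\,\frac{c^{h}}{c^{h} + \mathrm{EC}_{50}^{h}}, \]
   and per-construct summaries are the mean ± sample SD of the individually
   fitted EC50 and Hill values — not a pooled fit. This per-experiment
   protocol is what published EC50 tables in this field aggregate, and it is
   what the `fitHill()` / `summarizeConstruct()` pair reproduces.
2. **Mutant-cycle analysis.** For a cycle of $k$ perturbations with EC50s
   $E_1,\dots,E_k$, combined construct $E_{1\dots k}$ and wild type $E_{wt}$,
   the interaction factor is
   \[ \Omega = \frac{E_{wt}^{\,k-1}\, E_{1\dots k}}{\prod_i E_i}, \]
   which reduces at $k=2$ to the classical double-mutant-cycle ratio
   $E_{wt}E_{12}/(E_1E_2)$. The coupling energy is
   $\Delta\Delta G = RT \ln \Omega$ with $RT = 2.4776$ kJ/mol (298 K).
   $\Omega = 1$ is independence; deviations quantify energetic coupling.
   Because EC50 is a composite functional readout, these energies rank and
   compare couplings; they are not state-specific gating energies.
3. **Group statistics.** One-way ANOVA across construct EC50s and
   Dunnett-style many-to-one comparisons against wild type, computable from
   either raw replicates or published (mean, SD, n) triples.
4. **Structure geometry.** Pore-axis estimation, perpendicular radial
   distances, pore-proximal/pore-distal classification of residues relative
   to a reference (the conserved M2-M3 proline), hydrogen-bond heavy-atom
   distances, and a trans-pore CA–CA collapse metric.

A seeded synthetic-data module emulates both the TEVC recordings and
C5-symmetric pentamer coordinates so that every stage is testable with known
ground truth and no downloads.

## The generalized interaction factor

The classical mutant cycle covers two perturbations. Published coupling
tables for this receptor also contain triple cycles and cycles where one
"perturbation" is a paired mutation applied in the two complementary
subunits (γ and δ copies of the same interface residue). Two design
decisions make the table reproducible:

* **Wild-type exponent $k-1$.** With $k$ singles, the independence
  prediction for the combined EC50 is $E_{wt}\prod_i (E_i/E_{wt})$; dividing
  the observed combined EC50 by this prediction gives the
  $E_{wt}^{\,k-1}$ numerator. This uniquely reproduces the printed Ω of the
  triple and quadruple rows.
* **Paired subunit mutations decompose into singles.** The printed
  independence prediction of, e.g., an αS266A + γG182A/δG188A cycle equals
  the three-way product of the αS266A, γG182A and δG188A single folds, not a
  two-way product using the γ+δ double construct. Cycle definitions
  therefore list single-subunit constructs, and $k$ counts them.

## Error propagation

The published tables print ΔΔG ± SD but no propagation formula. The package
propagates the relative EC50 SDs in quadrature through the logarithm and
scales by $|\Delta\Delta G|$:
\[
\sigma_{\Delta\Delta G} = |\Delta\Delta G| \sqrt{(k-1)\Big(\frac{s_{wt}}{E_{wt}}\Big)^2
 + \sum_i \Big(\frac{s_i}{E_i}\Big)^2 + \Big(\frac{s_{comb}}{E_{comb}}\Big)^2 },
\]
the wild-type term entering $k-1$ times to mirror its exponent. This model
was confirmed against ten published rows before being adopted (±0.24, ±0.82,
±1.57, ±5.7, ±1.90, ±2.51, ±0.88, ±0.11, ±3.49, ±2.95 all reproduce to the
printed digit); one row (αS268A/αS269A + γK218A/δK224A, printed ±0.96 where
the model gives 0.84) deviates, consistently with its Ω also differing in the
last printed digit from printed-mean arithmetic — that row evidently reflects
unrounded internal means. Note that $\sigma_{\Delta\Delta G} \to 0$ as
$\Omega \to 1$: the propagated SD is a scaled relative error, not a
confidence interval, and a coupling of exactly zero is reported as 0.00 ± 0.00
by construction.

Two computation modes are exposed: `mode = "printed"` rounds every EC50 to
the 3 significant figures of a published table before the arithmetic (the
reproduction mode used in the examples below), `mode = "unrounded"` uses
full-precision fitted means (the research mode).

## Worked example: reproducing the published coupling table

```{r cycles}
tab <- readConstructSummaries(couplingExampleFile("summaries"))
cycles <- readCycleDefinitions(couplingExampleFile("cycles"))
res <- buildCycleTable(tab, cycles, mode = "printed")
res[res$cycle_id %in% c("aE45A+aP272G", "aV46A+aI264A+aP265G",
                        "aS266A+gG182A/dG188A"),
    c("cycle_id", "k", "observed_fold", "predicted_fold", "omega",
      "ddg", "ddg_sd")]
```

The αE45A+αP272G double cycle gives Ω = 0.77 and ΔΔG = −0.64 ± 0.24 kJ/mol;
the αV46A+αI264A+αP265G triple collapses to Ω = 0.01 (ΔΔG ≈ −11.1 kJ/mol),
the signature of a strongly coupled residue set; the inter-subunit
αS266A+γG182A/δG188A cycle gives Ω = 0.22 and ΔΔG = −3.77 ± 1.57 kJ/mol.

## The synthetic TEVC generator

`simulateOocyteResponses()` draws, per oocyte, an EC50 from a lognormal
distribution whose *median* is the true EC50 and whose CV is
`inter_oocyte_cv` (default 0.19, the wild-type EC50 CV of the published
table); Hill slope and maximal current are held fixed, because
oocyte-to-oocyte EC50 spread is the quantity the published SDs aggregate.
Peak currents then follow the Hill form times $(1+\varepsilon)$,
$\varepsilon \sim N(0, \texttt{noise\_cv})$ with default CV 7 % (the
published protocol does not state its replicate noise; 7 % makes n = 8
aggregation meaningful without drowning the signal), clipped at zero.
The default concentration series is 8 log-spaced points spanning
EC50/30 … 30·EC50, a standard TEVC bracket; the published grid is not
stated.

What the generator does *not* emulate: desensitization, voltage dependence,
channel block at high agonist, day-to-day normalization drift, and batch
effects between oocyte harvests. Passing parameter-recovery tests therefore
demonstrates correctness of the fitting and aggregation machinery under the
stated noise model, not robustness to every artifact of real recordings.

Two numerical properties of this model are worth knowing. The pooled median
of per-oocyte fitted EC50s recovers the generating EC50 (the lognormal
median) within Monte-Carlo error; the per-panel arithmetic mean instead sits
$\sqrt{1+\mathrm{CV}^2} \approx 1.8\,\%$ high by the lognormal mean/median
relation, plus a further small upward bias from the nonlinearity of the fit
under multiplicative noise (~3 % combined at the default settings). This is
a property of averaging EC50s on the linear scale — exactly what the
published protocol does — and not an implementation defect.

```{r recovery}
truth <- hillTruth(ec50 = 9.40, hill = 1.78, imax = 1)
fits <- unlist(lapply(1:20, function(s) {
  d <- doseDesign(ec50_ref = 9.40, n_oocytes = 8, seed = 3000 + s)
  resp <- simulateOocyteResponses(truth, d)
  vapply(split(resp, resp$oocyte_id), function(x) ec50(fitHill(x)),
         numeric(1))
}))
median(fits) / 9.40
```

(The test suite runs this at 200 panels; 20 keep the vignette quick.)

## Fitting details

`fitHill()` optimizes $(\log \mathrm{EC}_{50}, \log h, I_{\max})$ by
Levenberg-Marquardt on the linear-space residuals, with $h$ bounded to
$[0.2, 10]$ and $\log \mathrm{EC}_{50}$ bounded to the measured
concentration bracket widened by $10^{\pm 2}$ — wide enough never to bind on
reasonable data, tight enough to prevent runaway on flat curves. Start
values: EC50 at the geometric mean of the two concentrations bracketing
half-maximal response, $h_0 = 1.5$, $I_{\max,0} = \max I$. Tolerances are
set near machine precision (`ftol = ptol = 1e-15`), which makes the fitter
an exact interpolator on noise-free data (rss $< 10^{-12} I_{\max}^2$).
Weighting is unweighted least squares, matching the default of the
commercial fitters this protocol is usually run in. All-zero traces
short-circuit to an `NF` (no fittable response) status rather than a fit;
non-convergence retains the best iterate with `converged = FALSE`, and
aggregation uses converged fits only.

## Dunnett comparisons by Monte Carlo

`dunnettVsControl()` computes each group-vs-control t statistic with the
pooled within-group variance of all groups, then adjusts by the family-wise
exceedance probability of the max-|t| statistic under the joint null. The
null distribution is sampled (default $10^5$ seeded draws) from the exact
finite-sample model: group means $\sim N(0, \sigma^2/n_j)$ sharing one
$\chi^2_\nu$ pooled variance, which induces the equicorrelated
multivariate-t structure (correlation ½ for balanced designs, plug-in
correlations otherwise). Monte Carlo rather than closed-form tables keeps
the implementation self-contained and auditable; the test suite pins it
against an independently coded oracle and against the multivariate-t
implementation in `multcomp` to within 3 Monte-Carlo standard errors, and
verifies 5 % family-wise type-I control on 2000 null panels. With a single
comparison the analytic two-sample t p-value is returned exactly.

Tests are run on EC50 values on the linear scale, mirroring the published
protocol. EC50s are closer to lognormal than normal, so a log-scale analysis
is statistically preferable; pass `log(value)` replicates to do so — the
package deliberately does not transform silently.

## Geometry

The pore axis is estimated as the principal axis (largest-variance
eigenvector) of selected CA coordinates, anchored at their centroid — exact
on C5-symmetric fixtures and appropriate for real pentamers when the
selection spans the pore axially, as the five pore-lining M2 segments do.
The default selection (all CA atoms) assumes a roughly axially extended
assembly; for flat ring selections the largest-variance direction would lie
in the plane, so M2 CAs should be selected explicitly when annotations
permit. The direction sign is fixed deterministically; radial distances are
sign-independent.

Pore-proximal/pore-distal calls compare perpendicular radial distances of a
query residue and a reference residue. Aggregation defaults to the
side-chain heavy-atom centroid (CB outward, CA fallback for glycine), since
the published claims concern side-chain positions; `"CA"` and named-atom
modes support sensitivity checks. The tie band defaults to ε = 0.3 Å —
differences below that are reported `indeterminate` rather than overclaimed,
given ~3 Å cryo-EM coordinate precision. Hydrogen-bond distances are
heavy-atom donor–acceptor separations (N···O) with no angle criterion,
matching how the published distances are quoted. Residue numbering follows
deposited author numbering verbatim.

All geometric outputs are invariant under rigid-body transforms to 1e-6 Å
(tested); synthetic pentamer radii are exact to construction in memory and
to 1e-3 Å through PDB files (the format's 3-decimal coordinate field).

```{r geometry}
p <- readStructure(couplingExampleFile("pentamer_pdb"))
ax <- estimatePoreAxis(p)
classifyRadialPosition(p, ax, residueSelector("A", 46),
                       residueSelector("A", 265))
poreCollapseMetric(p, chains = c("A", "C"), resno = 255)
```

On the bundled synthetic bundle the resno-46 ring (11 Å) is pore-distal of
the resno-265 ring (8 Å) — the apo-like arrangement; rebuilding the fixture
with the query ring at 5.5 Å flips every chain's verdict to pore-proximal,
the agonist-bound-like arrangement.

## Known limitations

* Cycles whose single-mutant EC50s were never published cannot be entered in
  reproduction mode; the bundled cycle set omits them.
* The propagation model is a reconstruction: it matches ten published rows
  to the printed digit and is documented where it does not (one row).
* ANOVA/Dunnett assume homoscedastic normal groups; EC50 panels violate this
  mildly (lognormal spread), which the log-scale option addresses.
* `poreCollapseMetric()` summarizes one coordinate set; trajectory analysis
  is out of scope.
* Printed ANOVA DF/F values of the source tables are not reproduction
  targets: the exact construct membership per test is not recoverable from
  the published record.
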