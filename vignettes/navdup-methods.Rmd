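---
title: "Methods and design: detecting neofunctionalization of a duplicated sodium-channel gene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Weakly electric knifefish carry a lineage-specific duplication of a
muscle-expressed voltage-gated sodium-channel gene (an *scn4a*-family
paralog). One of the daughter copies gained expression in the spinal
neurons that form the neurogenic electric organ and, within a short window
after duplication, accumulated amino-acid substitutions concentrated in the
channel's fast-inactivation machinery — the IFM inactivation particle in
the domain III–IV linker and its receptor around the domain IV S4–S5
linker. When engineered into a human cardiac sodium channel, those
substitutions produce a persistent (non-inactivating) sodium current,
`I_NAP`, the biophysical substrate of spontaneous high-frequency firing.

`navdup` implements the computational side of that argument as reusable,
tested components:

1. **Parsimony trio mapping** — assign amino-acid substitutions and indels
   to the three branches connecting two paralogs and an outgroup ortholog.
2. **Hotspot scanning** — weighted kernel substitution densities, a
   relative-density statistic, and a Monte-Carlo null threshold.
3. **Branch codon models** — Goldman–Yang (GY94) likelihoods with F3X4
   frequencies, one-ratio vs two-ratio dN/dS fits, and the likelihood-ratio
   test for positive selection on the post-duplication branch.
4. **Voltage-clamp quantification** — linear leak subtraction, persistent
   current as a percentage of the transient peak, activation and
   steady-state-inactivation (SSI) Boltzmann fits, and recovery from
   inactivation.
5. **Matched synthetic-data generators** for every stage, each emitting a
   ledger of its true parameters, so the whole pipeline is testable with no
   external downloads.

## Parsimony mapping on the trio

For each alignment column of the outgroup/paralog1/paralog2 trio the
minimum-mutation assignment is: identical column, no event; two states
equal and one different, one substitution on the differing branch; all
three states different, one substitution on **each** branch. The
all-different rule slightly inflates totals (by construction,
`n_total = polymorphic + 2 × all-different columns`) but leaves the
relative comparison between branches meaningful; a property test asserts
that identity exactly.

Columns containing an ambiguous residue (`X`) in any sequence are excluded
— parsimony on unknown states is undefined. Gap-versus-residue differences
yield *indel* events. Under the default `per_run` mode a maximal run of
contiguous gap columns in one sequence is a single event at its first
column (one mutational event per indel); `per_column` counts every gapped
column and is kept for sensitivity analysis. Columns gapped in all three
sequences carry no event and do not interrupt a run (a shared deletion is
not evidence about any single lineage). Where two sequences are gapped the
event is credited to the residue-bearing branch as an insertion.
Substitutions are only called where all three sequences bear residues: in
mixed gap/residue columns a residue difference cannot be polarized, so only
the gap event is scored. Density analysis uses substitution events only by
default (`includeIndels = FALSE`), since the clustering statistic is about
amino-acid replacements; indels can be folded in via the flag.

## Densities, relative density, and the permutation null

For branch `b` with events at columns `x_i`, the density at integer column
`x` is a Gaussian kernel sum normalized to unit mass over the real line and
weighted by the branch's share of all events:

    d_b(x) = (1 / n_total) * sum_i phi_h(x - x_i),     w_b = n_b / n_total

with `h = 15` residues. The "binwidth 15" of the original analysis is read
as the Gaussian kernel standard deviation — the bandwidth convention of the
standard kernel density routine — which reproduces smooth profiles with an
effective footprint of roughly ±30 residues. Kernels are evaluated on
integer columns `1..L` with no boundary reflection, so mass is lost at the
termini exactly as in the default estimator; contributions beyond 6
standard deviations are dropped (relative error < 1e-8), identically in
observed and null computations.

The hotspot statistic is the relative density

    R_b(x) = d_b(x) / max(d_b'(x) + d_b''(x), eps),    eps = 1e-8,

one branch's density over the other two combined. The floor `eps` keeps
the ratio finite where the other branches carry no density; because it is
applied identically when the null is simulated, the test remains calibrated
by construction even where the floor binds.

The null distribution redraws each branch's `n_b` events uniformly (with
replacement) on `1..L`, recomputes `R_b`, and records the per-simulation
**maximum** over positions. The per-branch threshold is the empirical 99th
percentile of those maxima, so a profile exceeding it anywhere is a
family-wise 1% event. A `statistic = "pointwise"` switch instead stores
per-column 99th percentiles — the less conservative reading of a
"threshold reached in <99% of simulations", retained because the published
description does not disambiguate the two.

Two behaviors of the family-wise statistic are worth knowing:

* **Sparse denominators.** When the two denominator branches are sparse
  (tens of events over ~1,800 columns), positions near the alignment ends
  can fall outside every kernel's footprint; the floored ratio `d/eps` is
  then enormous, and the null 99th percentile is driven by those boundary
  excursions. Calibration is unaffected (observed and null share the
  statistic), but power against moderate clusters collapses. Real trios —
  with a deeply diverged outgroup contributing hundreds of events — keep
  the denominator dense everywhere, which is the regime the method is
  meant for.
* **Power against diffuse enrichment.** Simulations with a 20-column
  window carrying 10-fold local event density on one branch are detected
  in only ~14–90% of replicates (depending on event counts from
  `n = (300, 180, 180)` up to `n_1 = 450`), because the family-wise
  maximum of the null is comparable to the window's peak. The pointwise
  threshold detects the same window in >90% of replicates. The cluster
  actually observed in the duplicated channel is far stronger — roughly a
  dozen substitutions in a ~20-column window against ~45 branch-wide, a
  ~36-fold local density — and is called under the family-wise threshold,
  as the acceptance script demonstrates.

Thresholds use the default (type 7) empirical quantile; with 1,000 null
draws the expected family-wise exceedance of a fresh profile is ~1.1%, the
small finite-null bias of an empirical percentile.

## The codon model and branch tests

The GY94 rate matrix over the 61 sense codons sets the rate from codon `c`
to `d` to zero unless they differ at exactly one nucleotide, and otherwise
to `pi_d`, times `kappa` for transitions, times `omega` (dN/dS) when the
change is nonsynonymous; the matrix is rescaled so branch lengths are
expected substitutions per codon. Equilibrium frequencies are F3X4:
empirical nucleotide frequencies at the three codon positions (gaps
excluded), multiplied per codon, zeroed on stops and renormalized.
Frequencies are estimated once from the alignment and held fixed during
optimisation, the convention of the standard codon-model software.

Likelihoods use Felsenstein pruning over site patterns (identical columns
are collapsed with weights). Transition matrices come from the
eigendecomposition of the model in the `pi^{1/2}`-symmetrized basis — GY94
is time-reversible, so the symmetrized generator has real eigenvalues and
the decomposition is stable; frequencies are floored at 1e-10 and
renormalized inside this path to keep the basis well-defined when a codon
is absent from the data. Gap or ambiguous codons are missing data (partial
likelihood 1 over all states); `dropGapped = TRUE` removes gapped columns
instead. The pruning implementation is verified against exhaustive
enumeration of ancestral states on small trees to 1e-8 relative tolerance.

Fits maximize the likelihood jointly over `kappa`, the per-class `omega`
and (by default) all branch lengths, by bounded quasi-Newton iterations on
log-transformed parameters (convergence tolerance ~1e-6 log-likelihood
units; boxes `kappa` in [0.01, 100], `omega` in [1e-4, 50], `t` in
[1e-6, 20]). Three starts are used by default: the supplied or heuristic
start, plus two random log-scale perturbations run with a reduced
iteration cap, the best of which is polished. Eigendecompositions are
cached on (`kappa`, `omega`) so branch-length moves only pay for the
transition matrices. Two-ratio fits are conveniently warm-started from the
one-ratio optimum (with `omega_fg = omega_bg`), which also guarantees the
nesting inequality `lnL_2 >= lnL_1` that the likelihood-ratio test
`2dL ~ chi-square(df = 1)` relies on; the statistic is clipped at zero and
a negative excursion beyond tolerance triggers a refit warning.

`profileForegroundOmega()` inverts the likelihood-ratio statistic: the
foreground dN/dS is fixed on a moving multiplicative grid, all nuisance
parameters are re-optimized with continuation (each profile point
warm-starts from the previous one), and the 95% bound is found by
bisection of the profile deviance against the chi-square(1) quantile.

**Finite-sample behavior.** On 3-taxon trios the LRT and profile intervals
are close to nominal when the foreground branch carries a few hundred
substitutions (measured: 3.3% rejection at the 5% level over 150 null
replicates at `L = 500`, foreground length 0.25; profile deviance at the
generating values has mean 0.96). With only ~50 foreground events the test
is visibly liberal (~7%), an expected small-sample property of
likelihood-ratio inference, so the package's simulation-based checks use
trees whose foreground branch is deep enough for the asymptotic regime
(lengths 0.5/0.25/0.1 at 1,800 codons; 0.3/0.25/0.2 at 500).

## Voltage-clamp quantification

Trace sets hold a samples-by-sweeps current matrix, per-sweep metadata
(step voltage, protocol tag, recovery role/interval) and a protocol
descriptor (pre-pulse baseline and pulse durations); they round-trip
through a long-format CSV plus a JSON sidecar.

* **Leak subtraction** fits `I = g_leak V + b` to the steady-state current
  of subthreshold steps and subtracts the predicted leak per sample using
  each sweep's command voltage. The default window is steps at or below
  −100 mV: with an exactly Boltzmann conductance curve (midpoint −40 mV,
  slope 7 mV), steps at −95/−90 mV still carry ~0.5% of maximal
  conductance, enough to tilt the fitted leak line by ~0.5 percentage
  points of `%I_NAP`; at ≤ −100 mV the residual bias is ~0.2 points. SSI
  and recovery families contain no subthreshold steps, so the step
  family's fitted coefficients can be applied to them directly
  (`leakSubtract(x, coefficients = ...)`).
* **Persistent current** is `100 × I_late / I_peak` per sweep: the mean of
  the last 0.5 ms of the 30-ms pulse over the extremum of the
  low-pass-filtered (10 kHz Butterworth, zero-phase) current within the
  pulse, both inward-negative so the ratio is positive. Sweeps whose peak
  is below 3 baseline standard deviations are excluded with a warning.
  Note the estimand is the trace's true late/peak ratio: because the
  transient peak is itself partially inactivated by the time activation
  completes, a channel with persistent floor `p` shows `%I_NAP` slightly
  above `100 p` (about 7% for `p = 0.06` with the generator's default
  kinetics) — the same property the experimental measure has.
* **Activation (G–V)** converts step-family peaks to conductances
  `G = I_peak / (V − E_rev)`, normalizes, and fits
  `1 / (1 + exp((V50 − V)/k))` with no pedestal.
* **SSI** normalizes test-pulse peaks indexed by conditioning voltage and
  fits `a + (1 − a) / (1 + exp((V − V50)/k))` with the pedestal `a` free
  in [0, 1]; a persistent, non-inactivating channel fraction appears as
  `a > 0`.
* **Recovery** is the ratio of test-pulse to conditioning-pulse peaks per
  recovery interval, reported at all intervals including 0.5 and 1.0 ms.

Fits use Levenberg–Marquardt least squares with box constraints;
non-convergence is flagged on the returned object rather than raised.

## Synthetic-data generators

* **Codon trio with ledger** (`simulateCodonTrio`): the root is drawn from
  `pi` (uniform over the 61 sense codons by default, or a supplied
  composition); each branch evolves every site by a GY94 jump process with
  its own dN/dS, the nonsynonymous rate multiplied inside hotspot windows.
  Every realized substitution is recorded (branch, column, codons, amino
  acids, synonymous or not), so parsimony-mapping accuracy can be audited
  against truth rather than only against another estimator.
* **Multi-taxon alignments** (`simulateMultitaxonCodon`): endpoint sampling
  with per-branch transition matrices, foreground branches using the
  foreground dN/dS.
* **Event maps** (`simulateEventMap`): direct uniform placement with an
  optional hotspot window whose local density is multiplied — the exact
  null model of the scan, used for calibration and power studies.
* **Voltage-clamp traces** (`simulateTraces`): Hodgkin–Huxley-style
  `g_max m(t)^3 [(1 − p) h(t) + p] (V − E_rev) + g_leak V + noise`, with
  first-order gate relaxations (`tau_m = 0.1` ms, `tau_h = 3` ms by
  default, 50 kHz sampling, −120 mV holding). The activation parameters
  describe the steady-state *conductance* curve — the `m` gate is the cube
  root of the Boltzmann — so a G–V analysis recovers `vHalfAct`/`kAct`
  directly. For SSI the test pulse starts from the conditioning voltage's
  equilibrium availability; the brief 1-ms pre-test gap of the experimental
  protocol is not modelled (its only role here would be partial recovery
  that redistributes the curve slightly). For recovery, availability
  re-primes toward its holding value with `tau_rec`, giving the closed
  form `f(dt) = 1 − (1 − h_end) exp(−dt / tau_rec)` that the tests check.
  Default amplitudes (`g_max = 0.2` µA/mV, noise SD 0.02 µA) give
  oocyte-scale currents of ~10 µA peak at high signal-to-noise.
* **Expression tables** (`simulateExpressionTable`): log-normal abundances
  with mean-preserving noise (`exp(sigma Z − sigma²/2)`), transfrags as
  independent estimates of their gene and isoforms splitting each
  transfrag evenly, so zero dispersion returns the specified means exactly.

What the generators do **not** emulate: alignment error and filtered
columns (real alignments were guidance-filtered before analysis),
rate-heterogeneity across sites, locally depressed substitution rates in
conserved regions (which in the real protein *boost* the relative-density
signal by thinning the denominator), capacitance transients,
series-resistance artefacts and voltage-dependent time constants in
recordings. Passing tests therefore demonstrate correctness of the
statistics under their own assumptions, not field realism of every input.

## Problem sizes used by the test suite

The statistical checks run at: 1,000 uniform trios × 1,000 null
simulations (threshold calibration; `L = 1800`, `n = (100, 60, 60)`);
200 hotspot replicates at `n = (300, 180, 180)`; 50 selection-recovery
replicates at 1,800 codons (dN/dS 0.090 background / 1.58 foreground);
500 null-calibration replicates at 500 codons with single-start,
warm-chained fits; 100 Boltzmann-recovery replicates; and a persistent
fraction sweep over {0, 1, 3, 6, 10}%. The full null of 10,000 simulations
remains the analysis default (`readRunConfig()`), with the smaller counts
used where many independent replicates are needed.

## Known limitations

* The relative-density scan assumes shared alignment coordinates across
  the trio; per-protein coordinates would break the cross-branch ratio.
* The family-wise threshold is conservative against diffuse moderate
  clusters (see above); use `statistic = "pointwise"` for sensitivity.
* Branch models here are one- and two-ratio only; site and branch-site
  models, tree search, and random-effects branch methods are out of scope.
* qPCR quantification fixes amplification efficiency at 2 (a per-assay
  override exists); efficiency estimation from amplification curves is out
  of scope.
* Two-gap/one-residue parsimony columns are credited to the residue
  branch; with only three taxa the alternative (independent deletions)
  cannot be distinguished.
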