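---
title: "Targeted lipidomics with lipidmrm: transition chemistry, TG composition resolution and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted lipidomics with lipidmrm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmrm)
```

## The problem

Targeted lipidomics on a triple-quadrupole instrument monitors each lipid
molecular species as a fixed precursor/product m/z pair (an MRM
transition). Designing those transitions, and interpreting the resulting
chromatograms, requires a chain of chemical bookkeeping that this package
automates:

1. **Transition chemistry** — from a shorthand species name
   (`"TG 58:5"`, `"PC 34:2 (18:2_16:0)"`, `"LPC-15:0[D5]"`) to elemental
   formulas, monoisotopic masses, class-specific adducts and fragment
   ions.
2. **Isobar enumeration** — a TG sum composition such as TG 58:5 can
   arise from several acyl triplets; the acquisition panel must monitor
   the acyl-loss channel of every fatty acid that could contribute.
3. **Composition resolution** — after acquisition, the overlaid extracted
   ion chromatograms (XICs) of those channels reveal which triplet(s) are
   actually present, and with what chain multiplicities.
4. **Quantification** — single-point normalization against a per-class
   internal standard, scaled by tissue mass, with class totals and
   fatty-acid mol% derived from the resolved triplets.
5. **Method validation** — calibration linearity, LOD/LOQ from
   signal-to-noise, recovery efficiency and matrix effect.

A synthetic-data generator reproduces the co-elution structure the
resolver depends on, so the full pipeline is testable without an
instrument.

## Transition chemistry

Every supported class is built as *backbone + acyl free acids − one water
per ester bond*. The backbones are fixed elemental constants (glycerol
for the neutral classes; glycerophosphocholine, -ethanolamine, -glycerol,
-inositol, -serine for the phospholipids; glycerol plus one or two
anhydrogalactose units for the galactolipids). Deuterated internal
standards carry a glycerol-D5 label: five backbone hydrogens replaced by
deuterium, tracked as a distinct element so only the mass shifts.

Adducts follow the class rule observed in electrospray: the neutral
classes (MG/DG/TG) ionize as ammonium adducts in positive mode; choline
lipids (PC/LPC) as acetate adducts in negative mode; every other polar
class as \[M−H\]−. Product channels are class-specific: acyl loss
(precursor − NH3 − fatty acid) for DG/TG, the acylium cation or the
NH3+H2O-loss for MG, the deprotonated fatty-acid (carboxylate) for polar
classes, and a glycerophosphate-derived headgroup fragment (C3HD5O5P−)
for D5-labelled LPS.

```{r}
build_transition("MG 17:0", "acylium")[, c("species", "q1_mz", "q3_mz")]
build_transition("DG 44:2 (22:1_22:1)", "loss:22:1")[, c("q1_mz", "q3_mz")]
```

Masses use standard monoisotopic atomic values with electron-mass
correction per charge; internal arithmetic is exact to well below 1e-4 Da
and only the export layer rounds, half-up, to the one decimal an
acquisition list carries. The packaged standards panel
(`standards_panel()`) stores operator-entered one-decimal values for 74
transitions across all 15 classes; `check_standards_panel()` recomputes
each one and flags rows whose printed values drift from theory by more
than 0.15 Da (unit-resolution entry error). Fifteen rows — mostly
long-chain and deuterated TG entries — carry such drift; they are
reported, not silently accepted, and two MG standards are annotated to
the water-loss channel their printed product ion actually corresponds to,
although the panel's formula column suggests the acylium.

## Enumerating and resolving TG compositions

`enumerate_tg_compositions(total_c, total_db, pool)` returns every
multiset of three pool fatty acids matching the sum composition. The
default pool — 16:0, 18:0, 18:1, 18:2, 18:3, 20:0, 20:1, 22:1, 24:1 —
covers the fatty acids of pennycress (*Thlaspi arvense*) seed
glycerolipids, whose defining feature is the very-long-chain erucic acid
(22:1); override it for other tissues, because every downstream
composition call is conditional on the pool.

```{r}
sapply(enumerate_tg_compositions(58, 5), composition_string)
```

The resolver works per precursor:

* `detect_peaks()` finds local maxima above `max(min_height, min_snr ×
  noise SD)`, with noise estimated from first differences of the trace,
  integration bounds at the return-to-baseline or the valley toward a
  neighbouring peak, and a baseline-corrected trapezoidal area.
* `group_by_coelution()` single-links peak apexes within `rt_tol`
  (default 0.05 min, about half a peak width; the tolerance is a
  configuration decision, not a measured constant).
* `call_compositions()` tests each candidate triplet against a group. A
  candidate is *supported* when every distinct FA of the triplet has a
  co-eluting peak. Multiplicity is then inferred from heights: the three
  chains of one precursor are spread across all co-eluting channels, so
  the unit (multiplicity-1) height is the group's summed channel height
  divided by three, and each channel's height/unit ratio is matched to
  the nearest integer with an acceptance band of `[0.7m, 1.4m]`. Inferred
  multiplicities equal to the candidate's chain counts give a
  `confirmed` call; presence without ratio agreement gives `tentative`.
  Heights, not areas, drive this inference because they are insensitive
  to integration-boundary choices. Equal detector response across FA
  channels is assumed throughout — a caveat inherited from the
  experimental workflow, since acyl-loss efficiencies do differ somewhat
  between chains.
* `select_quantifiers()` keeps exactly one transition per confirmed
  composition and divides its area by the chain multiplicity of that FA,
  so a triplet like 18:1_18:1_18:1 is counted once (divisor 3), and a
  channel shared between two co-eluting species (the classic 22:1 case
  for the two TG 58:5 species) is never used to quantify either of them
  while unshared alternatives exist. Preference: unshared channels
  first, then lowest multiplicity, ties broken deterministically by
  lowest product m/z. If two calls can only be quantified by the same
  peak, both are demoted to tentative — shared-channel area is never
  split, because any split ratio would be an invention.

```{r}
smp <- synthetic_sample(data.frame(
  name = c("TG 58:5 (18:2_18:2_22:1)", "TG 58:5 (18:1_18:3_22:1)",
           "TG 54:3 (18:1_18:1_18:1)"),
  nmol = c(2, 1, 3)), seed = 7)
res <- resolve_tg_xics(simulate_xics(smp, noise = NULL))
res$calls[, c("tg_species", "composition", "confidence",
              "quantifier_fa", "divisor")]
```

## The synthetic-data generator

`simulate_xics()` emulates the reverse-phase (C30) separation of neutral
lipids. Retention is an equivalent-carbon-number model: per class,
`rt = intercept + coef_c·ΣC − coef_db·ΣDB`, clipped to the class elution
window, plus two small chain-dispersion terms
(`+0.15·(Cmax−Cmin) − 0.30·(DBmax−DBmin)` minutes) that separate isobaric
triplets of one sum composition the way the C30 phase does. The purely
additive part is calibrated to observed standards (TG 41:0 at 11.4 min,
TG 54:9 at 9.7 min, TG 72:3 at 26.7 min; analogous anchors for DG and
MG); the dispersion coefficients are a design choice sized to a few peak
widths so that resolvable isomer pairs — the situation the resolver
exists for — actually occur in simulation. Real isomer spacing on a C30
column is not tabulated anywhere we could calibrate against; treat these
two coefficients as qualitative.

Peaks are Gaussian with SD 0.08 min (consistent with a sharp core-shell
separation). Each acyl-loss channel of a species receives height
`nmol × multiplicity × response` (default response 1e5 counts/nmol), so
the channel-multiplicity law holds exactly at zero noise. Noise is an
additive baseline (0.5% of the tallest simulated peak) plus a Gaussian
term with CV 2% of signal; channel RT jitter defaults to 0 (ideal
co-elution) and can be raised to stress `rt_tol`. `random_tg_sample()`
draws distinct triplets from the pool with log-uniform abundances over a
20-fold range, chosen so every simulated channel stays above the LOQ
implied by the default noise — the regime in which the experimental
workflow quantifies at all.

What the generator does *not* emulate: tailing/fronting peak shapes,
ion suppression dynamics, response-factor differences between channels,
isotope envelopes, and retention drift between runs. Passing the
simulation suite therefore demonstrates the logic of the resolver and
quantifier under the workflow's own assumptions, not instrument-grade
robustness.

## Quantification

`quantify_areas()` implements single-point internal-standard
normalization: `area × is_nmol ÷ is_area ÷ tissue_mg`, one spiked
standard per class. No calibration-curve quantification is attempted —
curves live in the validation module only. Class totals are per-sample
sums, averaged over replicates with the sample (n−1) SD. Fatty-acid mol%
weights each resolved triplet's amount by the chain count of the FA:

```{r}
fa_mol_percent(c("18:3_22:1_22:1", "18:1_18:3_22:1"), c(1, 1))
```

`export_stats_table()` writes the samples × features layout (with a group
label column) consumed by downstream multivariate statistics tools;
statistics themselves are out of scope.

## Method validation

`fit_calibration()` fits a serial-dilution series by OLS. The linear
range is determined by anchoring on the lowest third of the series and
extending upward while each next point stays within 15% of the
extrapolated line; this catches detector saturation, which a global fit
hides through leverage. LOD and LOQ are `3·noise/slope` and
`10·noise/slope`, so LOQ/LOD ≡ 10/3; the noise SD is taken from a
signal-free region of a blank, an estimator the operator must designate
because no universal definition exists. Recovery efficiency
(`before/after × 100`) and matrix effect (`after/alone × 100 − 100`) are
computed as ratios of replicate means — the equations operate on
aggregate intensities and no per-replicate pairing is defined. Flags use
inclusive boundaries: ME of exactly ±25% and RE of exactly 75% are
acceptable; beyond them `suppressed`/`enhanced`/`low_recovery`.

## Numerical and design decisions

* **Masses**: CODATA/IUPAC monoisotopic values; electron mass corrected
  per charge; instrument export rounds half-up to one decimal (R's
  default rounding is banker's, which an acquisition list never uses).
* **Acyl chains** are unordered multisets; `"_"` is the canonical
  separator, `/`-separated input is accepted but sn-position information
  is discarded. Canonical composition strings sort chains ascending by
  carbons then double bonds.
* **Degenerate inputs**: subtraction of formulas refuses negative
  element counts; empty enumeration results are valid; a TG precursor
  with no candidate under the pool is kept in the panel with a warning
  and no product channel; a co-elution group supporting no candidate
  warns and yields no call; zero IS area or zero tissue mass are errors
  naming the sample and class.
* **Tie-breaks** are deterministic everywhere (canonical ordering of
  compositions, lowest-q3 quantifier ties), so identical inputs give
  byte-identical outputs.
* **Problem sizes**: the simulation-based checks in the test suite use
  20 seeded samples of 10 TG compositions each at default noise — a
  scale at which the co-elution structure is fully exercised while the
  suite stays fast.

## Known limitations

* Double-bond positions, sn-positions, ether/oxidized lipids and
  isotope patterns are out of scope; PA and LPA are not modelled (their
  chromatography is unreliable on uncoated LC hardware).
* Composition calls are conditional on the FA pool: an absent FA can
  silently re-attribute a precursor to a different triplet.
* Overlapping peaks are not deconvolved by curve fitting; the resolver
  refuses shared-channel splits instead of guessing them.
* Equal channel response factors are assumed; relative TG species
  distributions are therefore semi-quantitative, as in the experimental
  method itself.
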