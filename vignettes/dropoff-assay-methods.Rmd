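---
title: "Methods: drop-off LNA assays for quantifying CRISPR editing"
author: "dropoffr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drop-off LNA assays for quantifying CRISPR editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropoffr)
```

## The measurement problem

CRISPR-Cas9 editing in zygotes produces *mosaic* founder animals: a single
DNA sample can contain up to five distinct alleles — unedited (wt) sequence,
the designed homology-directed-repair (HDR) allele, partial HDR
incorporations, NHEJ indels, point mutations, and combinations of these.
Sanger sequencing of plasmid-cloned PCR products resolves the alleles but is
slow and quantitatively limited by the number of clones. `dropoffr`
implements the probe-based alternative: a *drop-off assay* places an
LNA-substituted "target" probe across the Cas9 cut site and an internal
"reference" probe elsewhere in the same short amplicon. Any edit under the
target probe abolishes its binding ("drops off") while the reference probe
still signals, so the target/reference signal ratio measures the unedited
fraction. The package covers the whole workflow: probe thermodynamics and
assay design, ΔΔCq quantification from qPCR, Poisson statistics for chip
dPCR, clone-sequence classification, endpoint-fluorescence genotyping of
recombinant alleles, and seeded simulators that tie everything together.

## Hybridization model

Duplex stability is computed by the two-state nearest-neighbor model:
ΔH and ΔS are summed over dinucleotide stacks using the unified DNA/DNA
parameter set, with the published internal single-mismatch parameters at
mismatched positions. The melting temperature at the 1 M Na⁺ reference is

$$T_m = \frac{\Delta H \times 1000}{\Delta S + R\,\ln(C_T/4)}$$

and is then corrected for divalent cations with the standard empirical Mg²⁺
correction, using free Mg²⁺ = [Mg²⁺] − [dNTP] because dNTPs chelate
magnesium roughly stoichiometrically. Defaults reproduce multiplex qPCR
chemistry: 3.0 mM Mg²⁺, 0.8 mM dNTPs, 50 mM monovalent, 250 nM probe, 60 °C
annealing.

Locked nucleic acids are handled as per-locked-base perturbation terms: each
matched stack adjacent to a locked base receives a stabilizing ΔΔH/ΔΔS
increment (≈ −0.6 to −0.9 kcal/mol ΔG₃₇ per stack, strongest for locked
G/C), while a mismatch at or next to a locked position receives an extra
destabilization. This compact parameterization — rather than a full 64-entry
LNA table — reproduces the two properties the rest of the toolkit consumes:
LNA substitutions raise the perfect-match Tm, and a mismatch under a locked
triplet costs at least as much as the same mismatch in an unmodified probe.
Bulges (insertions/deletions under the probe) get a fixed configurable
penalty per bulged base (default 3 kcal/mol ΔG₃₇), since no complete
nearest-neighbor bulge table exists; only *relative* discrimination is used
downstream. The bound fraction at the annealing temperature follows the
two-state definition and equals 0.5 exactly at `T = Tm` at the reference
strand concentration. No secondary-structure partition function is
attempted: probes are ≤ 40 nt, where the two-state approximation is standard
practice.

Because the model is a re-implementation of what is usually delegated to
vendor tools, its absolute Tm values are validated against an independently
coded re-summation of the same parameter tables (agreement well within
1.5 °C on random duplexes), and its relative behavior against the LNA
properties above.

## Assay design rules

`design_dropoff_assay()` enumerates amplicon geometries around the cut site
and keeps candidates that satisfy, in order:

* amplicon length in a window whose default (110–160 bp, target 134 bp)
  centers on the short-amplicon regime that keeps both probes on one
  molecule;
* primers with Tm in 57–63 °C, GC 30–70%, homopolymers ≤ 4;
* a target probe whose footprint straddles the cut site (the blunt DSB is
  stored as a 0-based inter-base coordinate, 3 nt 5′ of the PAM — standard
  SpCas9 biochemistry) and which carries **three consecutive locked bases**
  centered on the cut, shifted minimally away from G-runs;
* an internal reference probe in the same amplicon but *distal* to the cut
  (≥ 10 nt by default), on the other fluorophore channel;
* both probes melting 3–6 °C **above** the hotter primer — so probes are
  bound before primer extension — and within 2 °C of each other.

Candidates are ranked by a composite penalty (Tm-window centering, probe Tm
balance, GC extremes, amplicon-length deviation) with coordinate-based tie
breaks, so design is deterministic. `validate_assay()` re-measures every
rule and is the contract: the designer only emits assays that pass it, and
the test suite re-checks the geometry independently. Allele-discrimination
probe pairs (`design_allele_probes()`) share one footprint, differ only at
the variant base, and carry a locked doublet on the discriminating site;
variants within 2 nt of a probe end are rejected (no terminal
discrimination).

## ΔΔCq quantification

`ddcq_wt_fraction()` implements relative quantification with an assumed
amplification efficiency of 2.0 on both channels:

$$\Delta C_q = \bar{C_q}^{target} - \bar{C_q}^{ref},\qquad
\Delta\Delta C_q = \Delta C_q^{sample} - \Delta C_q^{calibrator},\qquad
\%wt = 100 \times 2^{-\Delta\Delta C_q}.$$

The calibrator is a designated wild-type control. Replicates (three, as is
standard) are summarized with a 0.5-cycle median-distance outlier rule; SEM
is propagated to the percentage scale at first order. Values above 100% are
reported clipped to [0, 100] with the raw value retained — noise pushes
$2^{-\Delta\Delta C_q}$ above 1 near the calibrator. Wells that never
amplify are flagged, never imputed to a fixed Cq. The `trans_multiplex` mode
(external single-copy reference assay) shares the arithmetic; only the well
layout differs. `calibration_slope()` guards the efficiency assumption: ΔCq
regressed on log₁₀ input must be flat (default |slope| ≤ 0.1 per decade).

The efficiency-2 assumption and the equal-efficiency guard are the reasons
the estimator is *unbiased only for fully discriminating probes*: if the
target probe still binds edited templates at partial efficiency *b*, the
apparent wt fraction is $f + b(1-f) > f$ — an overestimate for every
mosaic sample. The simulator exposes exactly this knob, which is how the
package reproduces the oligo-vs-LNA bias structure (see below).

## dPCR quantification

Partitions are classified into four two-channel classes. With raw
fluorescence, per-channel thresholds default to the deepest density valley
between the two dominant modes; a channel whose distribution is not
convincingly bimodal (secondary mode < 5% of the main peak, or valley less
than half the smaller mode) is refused with an instruction to threshold
manually — silent misthresholding is worse than an error. Occupancy follows
Poisson statistics, $\lambda = -\ln(1-p)$, with a Wilson interval on *p*
transformed through the same map (well-behaved at *p* near 0 and 1).

Because both probe sites sit on one 134-bp amplicon, site occupancies are
perfectly linked, and the wt fraction is a ratio of occupancies rather than
of independent concentrations:

$$\%wt = 100\,\frac{\lambda_{target}}{\lambda_{ref}},\qquad
\lambda_{target}: \text{double-pos} + \text{target-only},\quad
\lambda_{ref}: \text{double-pos} + \text{ref-only}.$$

Target-only partitions should not occur biologically; they are counted
toward $\lambda_{target}$ but flagged as anomalies. The 95% CI is a
delta-method interval on $\log(\lambda_t/\lambda_r)$ using the full
multinomial covariance of the two positive fractions. The covariance term
matters: the shared double-positive class makes the two proportions strongly
correlated (at high wt the ratio estimator has almost no variance), and
treating the channels as independent would roughly double the interval and
push empirical coverage above 98%. With the covariance included, coverage on
simulated 20,000-partition chips sits at ≈ 93–95%.

## Clone classification

`align_to_reference()` is a global affine-gap Needleman–Wunsch aligner
(match +1, mismatch −2, gap open −5, gap extend −1 per base including the
first; the scoring favors parsimonious indel calls at amplicon scale) with
a fully specified tie-breaking order, implemented in C++ and mirrored by a
pure-R exhaustive oracle in the test suite. Clone orientation is
auto-detected by aligning both strands. Indels are normalized by
left-shifting within repeat context, so allele identity ("exact variant-set
equality") is well-defined. Clones under 60% identity are rejected as
off-target amplicons or vector sequence.

Within a 70-nt analysis window centered on the cut site (the width of the
genomic window used in this kind of founder survey; configurable), each
clone is assigned exactly one category:

| category | rule |
|---|---|
| `wt` | no variants in window |
| `HDR` | all HDR components present, nothing else |
| `partial_HDR` | a nonempty proper subset of components, nothing else |
| `deletion` / `insertion` / `point_mutation` | a single variant class, no components |
| `mixed` | ≥ 2 variant classes, or components plus other edits |

An HDR *component* (target codon, PAM mutation, silent restriction site) may
span several substitutions and counts as present only when complete.
Variants outside the window never affect the category but are recorded, and
distinct-allele counting uses the full variant set — whether out-of-window
edits should count toward "mixed" is genuinely ambiguous in this assay
family, so the package reports both tallies instead of deciding silently.
`hdr_component_venn()` decomposes records over the 2³−1 component subsets;
`summarize_founder()` reports per-animal category fractions (summing to 1)
and the distinct-allele count.

## Endpoint genotyping

`call_genotypes()` normalizes each channel by the NTC-subtracted control
maxima, maps samples to (signal angle, amplitude), estimates control
centroids and the pooled within-control spread, and assigns the nearest
centroid. The classification is invariant to common-mode gain by
construction. Two non-calls protect against silent errors: samples at the
no-template noise floor are `indeterminate`, and samples farther than 3
within-control SDs from every centroid — where mosaic founders fall, since
their allele mixtures interpolate between the discrete control clusters —
are `founder_mosaic_candidate`. These flags route a sample to review; they
are deliberately not genotype assignments, and the package's error metric
counts only wrong definite genotypes. `linearity_check()` verifies the
dose response of the competitive pair (default pass at r² ≥ 0.98).

## The simulator and what it does (not) show

The generators are the package's test fixture and define its study
conditions; all are bit-reproducible given (configuration, seed), with the
RNG namespaced per operation so partial pipeline reruns reproduce exactly.

* **Locus.** A frozen synthetic 300-nt amplicon with protospacer, AGG PAM,
  cut site at inter-base coordinate 150, and an HDR template of four
  substitutions in three components (codon change, PAM kill, two silent
  bases creating an EcoRI site). It is labelled synthetic: the real assay's
  primer/probe sequences live in a supplementary table that is not part of
  this package.
* **Founders.** 1–5 distinct alleles (uniform count — the observed range in
  founder surveys; the true distribution is unpublished), categories drawn
  from configurable probabilities (defaults loosely matched to published
  aggregate counts: HDR ≈ 7%, partial HDR ≈ 10%, deletions dominating NHEJ),
  Dirichlet(1) fractions. Indels are placed at the cut site; generated
  point mutations avoid recreating HDR component bases, and mixed alleles
  separate their two events by ≥ 8 nt so the generating variant set is the
  unique parsimonious alignment — this is what makes the 100% classification
  round trip a meaningful test of the aligner rather than a coin flip over
  equivalent alignments.
* **qPCR.** Channel signal = binding-weighted allele-fraction sum;
  `Cq = Cq₀ − log₂(signal)` plus independent Gaussian noise per replicate
  and channel (σ = 0.1 default). Binding efficiencies come from a
  per-category override table (wt = 1; `edited_binding` = 0 for the
  idealized LNA probe, 0.5 for an oligo-probe regime) or from the
  thermodynamic bound fractions.
* **dPCR.** Poisson(0.8) copies per partition by default — chip dPCR
  practice targets mean occupancies of roughly 0.6–1.6 — with per-copy
  Bernoulli probe binding and optional two-cluster fluorescence rendering.
* **Endpoint.** Gaussian clusters; the HET centroid is the WT/HOMO midpoint
  and mosaic centroids interpolate along that axis by mutant fraction.

What passing these simulations does *not* show: real founder data add
pipetting structure correlated within wells (which multiplexing partly
cancels), amplification-efficiency differences between long-indel alleles,
chip-loading artifacts, and Sanger base-calling noise — none of which the
generators emulate (clone draws are error-free, consistent with
plasmid-derived sequencing). Recovery numbers here validate the estimators'
statistics, not instrument behavior.

## Numerical and validation choices

* **Noise-free bias check.** The oligo-bias property ("estimated wt exceeds
  true wt for every mosaic sample when edited templates half-bind") is an
  exact inequality of the signal model, so it is verified at σ = 0; any
  nonzero noise would make a strict per-sample inequality fail with positive
  probability at high wt without saying anything about the bias.
* **Clipped scale.** Recovery error is measured on the reported (clipped)
  percentage, which is the estimator's actual output.
* **Genotyping separation.** The misclassification benchmark uses adjacent
  clusters 6 within-cluster SDs apart (the discrimination-plot regime the
  control-anchored design targets), 500 unknowns per class.
* **Problem sizes.** Validation uses 500 simulated plates per wt fraction
  for qPCR, 200 chips × 20,000 partitions per fraction for dPCR, 1,000
  clones for the round trip, 200 random alignment cases and 100 random
  duplexes/references for the oracle and design checks — sizes at which the
  Monte-Carlo error of each summary is far below its acceptance margin.
* **Determinism.** The full simulate→analyze→report pipeline writes no
  timestamps and records provenance with relative paths, so reruns with one
  seed are byte-identical; this is asserted file-by-file.

## Known limitations

Thermodynamics: the LNA increments are a summarized parameterization, so
absolute Tm of heavily locked probes carries more uncertainty than relative
comparisons; terminal mismatches reuse internal parameters. Design: a
single amplicon per reaction; no genome-wide off-target scan of candidate
primers. qPCR: no Pfaffl-style multi-efficiency correction (the slope check
is the guard). dPCR: no chip-image QC and no absolute copies/µL calibration
(the deliverable is a relative fraction). Classification: no chromatogram
parsing or mixed-trace deconvolution; heterozygous traces must be cloned or
deconvolved upstream.
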