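---
title: "Deconvolving DIA runs into pseudo-tandem spectra: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving DIA runs into pseudo-tandem spectra: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In data-independent acquisition (DIA/SWATH) proteomics, every duty cycle
fragments *all* precursor ions inside a sequence of wide isolation windows.
The resulting MS2 spectra are mixtures: fragments of many co-isolated
peptides appear in the same scan, so the precursor–fragment relationships
that database search engines rely on are lost. `DIAdeconv` reconstructs
those relationships directly from a single run, without a DDA spectral
library, and emits pseudo-tandem spectra (MGF) that any conventional search
engine can process.

The guiding physical assumption is co-elution: fragments of one peptide
share the chromatographic elution profile of their precursor (same apex,
same width), while fragments of different peptides generally do not. All
stages of the pipeline exploit this signal in one way or another.

## Pipeline overview

For each isolation window the run is cut into fixed-width retention-time
**sliders** (20 duty cycles wide, stride 1 — the slider width is also the
length of every extracted ion chromatogram, XIC). Within a slider:

1. **Preprocessing.** Spectra are binned on a truncated m/z grid
   (30 bins per Th; at the 1,200 Th default ceiling a spectrum is a
   36,000-length vector). Candidate precursors are found in MS1 by peak
   finding plus isotope-envelope deisotoping (charge 1–5, spacing
   1.003355/z Th, correlated isotope XICs); candidate fragments are MS2
   XICs passing two background filters — more than 5 nonzero points and a
   max/min-nonzero ratio above 4, both strict.
2. **Embedding.** Each fragment XIC is min-max normalized and encoded by
   the mean head of a 4-branch fully connected variational autoencoder
   (VAE) into a 16-dimensional latent vector.
3. **Clustering.** k-means (Lloyd, k-means++ seeding) groups the
   embeddings; k is set to the number of candidate precursors detected in
   the slider, clamped to the fragment count.
4. **Peptide assignment.** An inverted index over the in-silico tryptic
   digest of the FASTA database maps (precursor m/z bin, charge) and
   fragment m/z bins to peptide index sets; their intersection gives the
   candidate peptides of a cluster, ranked by an X!Tandem-style
   hyperscore, `log10(Nb! * Ny! * sum(matched intensities))`.
5. **Co-elution gate.** The top-6 matched fragment XICs (rows min-max
   normalized, zero-padded to 6) form a 6x20 matrix scored in [0, 1] by an
   inception-style CNN; a group is accepted when the score strictly
   exceeds θ (default 0.5).
6. **Second pass.** Fragments of accepted groups are removed and the
   remainder re-clustered (k2 = unmatched precursors) and matched once
   more, recovering peptides whose fragments were buried in mixed
   first-pass clusters.
7. **Consolidation and recalibration.** Groups repeating across
   overlapping sliders (same peptide entry, apex within half a slider
   width) are merged keeping the best hyperscore. Accepted groups serve as
   internal calibrants for a least-squares m/z recalibration curve, then
   every pseudo-spectrum is written as one MGF block.

## The VAE and its losses

Encoder branches are fully connected stacks of widths 384 | 192–384 |
48–128 | 128 (concatenation 1024), followed by two linear 16-dimensional
heads for the latent mean and log-variance. The decoder mirrors them
(384 | 384–192 | 128–48 | 128, concatenation 752 = 384+192+48+128) and maps
back to the 20-point XIC. Hidden activations are ReLU; dropout 0.2 is
applied on branch outputs of the first three branches during training.

Training minimizes, per anchor/positive/negative triplet,

    total = (vae(a) + vae(p) + vae(n)) / 3 + triplet(mu_a, mu_p, mu_n)

with `vae(x) = KL + MSE`, `KL = -1/2 sum_d(log s2 - mu^2 - s2 + 1)` and the
triplet hinge `max(||mu_a-mu_p||^2 - ||mu_a-mu_n||^2 + 1, 0)`. Two
interpretation choices deserve a note:

* **Sign of the KL term.** A formulation in which the KL term is
  *subtracted* from the objective rewards posterior divergence — its value
  decreases without bound as the posterior mean grows — so the package
  trains on the standard ELBO form (KL added). The subtractive variant
  remains available as `literalEq2` in `vaeLoss()` for comparison.
* **Second encoder head.** Whether the head stores σ or σ² is genuinely
  ambiguous in descriptions of this architecture family; the package
  stores log σ² and samples `Z = mu + eps * exp(log s2 / 2)` by default,
  with the variance-scaled form `Z = mu + eps * s2` available via
  `sampleLatent(..., literal = TRUE)`.

Optimization is a from-scratch Adam (η = 0.001, β₁ = 0.9, β₂ = 0.999,
ε = 1e-8) verified against an independent scalar implementation to 1e-12,
and all backward passes are verified against central finite differences to
1e-4 on reduced architectures. Inputs are min-max normalized per XIC so the
reconstruction error is comparable across fragment abundances and the
embedding is scale-invariant by construction. Defaults: batch 256, 5–10
epochs, Glorot-uniform initialization, all seeded.

## The CNN co-elution classifier

The 6x20 group matrix passes through four branches (16 channels each):
1x1 conv | 1x1→3x3 | 1x1→5x5 | 3x3 pooling→1x1, concatenated along
channels, flattened, a 512-unit FC layer and a sigmoid score unit, trained
with binary cross-entropy (label 1 = fragments of one peptide, 0 = mixed)
and Adam at its default parameters. Two unspecified details were fixed as
follows: the pooling branch uses 3x3 *average* pooling (linear, hence an
exactly checkable backward pass), and matrix rows are ordered by
descending apex intensity and min-max normalized per row. Training on
2,000 labeled synthetic groups for 12 epochs takes a few CPU minutes and
reaches ≈0.9 held-out accuracy.

## The inverted peptide index

Tryptic digestion (cleave after K/R except before P, ≤1 missed cleavage,
length 7–50, charges enumerated), fixed carbamidomethyl on C, variable
oxidation on the first M and protein N-terminal acetylation. Entries are
registered under precursor (m/z bin, charge) keys and fragment m/z bin
keys with ±1 neighbor bins; queries scan the bin range of mz ± tolerance
and post-filter exactly, so the index is provably equivalent to a linear
scan (property-tested on 10,000-entry digests). Monoisotopic masses, proton
1.00727646688 Th.

A note on tolerances: candidate precursor m/z is read off the binned grid,
whose centers are up to half a bin (≈0.017 Th ≈ 35 ppm at 500 Th) from the
true value. A 20 ppm query against grid-derived values would therefore
reject true matches by construction; the pipeline uses an absolute
one-bin tolerance for precursors (and 0.03 Th for fragments), while 20 ppm
remains the default for queries on unbinned input.

## MS1 recalibration

Accepted groups (deduplicated by peptide, hyperscore ≥ 2 by default, or an
engine expectation value < 0.001 when supplied) provide
(observed, theoretical) precursor pairs. A least-squares curve is fitted
per instrument family: `m' = A m + B sqrt(m) + C` for TOF and the
two-parameter `m' = A m + B sqrt(m)` for Orbitrap — the published
rendering of the Orbitrap formula is typographically garbled, so the
package keeps the same √m basis with the constant dropped and documents
this choice rather than guessing further. The fit is global per run;
post-fit RMS (ppm) never exceeds the pre-fit RMS, and recalibration is
skipped (identity) below 5 calibrants.

## The synthetic run generator

`simulateRun()` emulates SWATH acquisition so the entire pipeline can be
trained and validated with known ground truth and no external data:
interleaved duty cycles (one MS1 scan plus one MS2 scan per isolation
window), three 200-Th windows over 400–1000 Th and 60 cycles by default;
peptides are random tryptic-like sequences (or draws from a supplied FASTA
digest), charge 2–3, eluting as Gaussians with σ ∈ [1.5, 4] cycles so one
peak fits within a 20-cycle slider; precursors carry 3-isotope envelopes
with Poisson(λ = M/1800) abundance ratios; each peptide exposes 6–10
fragments with log-normal relative intensities (floor 0.15) sharing the
precursor's elution profile; apex signal-to-noise is drawn from [10, 100]
against log-normal(log 50, 0.5) background intensities, with Poisson
background ion counts of 30 (MS1) and 50 (MS2) per scan and 5% log-normal
per-peak jitter for shot noise.

What the generator does *not* emulate: peptide detectability and
ionization-efficiency models, chimeric co-elution beyond what random apex
placement produces, profile-mode peak shapes in m/z (peaks are centroids;
the binning step absorbs the difference), retention-time drift between
runs, and ion mobility. Passing tests on generator data therefore
demonstrate the correctness and internal consistency of the machinery and
its behaviour under the stated noise model — not performance on real
instrument data.

## Numerical and design choices

* **Peak-finding SNR baseline.** The local baseline of a candidate MS1
  peak is the median of nonzero profile values within ±15 bins, excluding
  the apex ±1 *and any value above half the apex*. Without the second
  exclusion, the isotope companions of the same envelope dominate the
  median and mask genuine precursors (sensitivity on generator runs
  collapsed to ≈35%); with it, the ≥90% recovery property holds. Default
  threshold 3.
* **Deisotoping.** Charge is the value in 1..5 maximizing the count of
  consecutive isotopes whose XICs correlate (Pearson ≥ 0.6) with the
  monoisotopic trace and whose envelope is plausible (next apex ≤ 2x
  previous); at least 2 isotopes are required, otherwise the ion is
  dropped. The monoisotopic XIC must additionally span ≥3 nonzero cycles:
  a chromatographic peak elutes over several cycles, whereas two
  background spikes landing in the same scan at an isotope spacing
  correlate perfectly and would otherwise pass as a phantom precursor.
* **k for k-means** is never stated for this problem; the package uses the
  number of candidate precursors in the slider (each cluster ideally maps
  to one precursor), clamped to [1, n fragments], configurable. Ties in
  assignment go to the lowest-index centroid; empty clusters are re-seeded
  at the point farthest from its centroid; inertia is asserted
  non-increasing every Lloyd iteration.
* **Group acceptance** additionally requires ≥3 matched fragments
  (`minMatched`), preventing single-fragment coincidences from reaching
  the CNN gate.
* **Slider consolidation.** With stride 1 the same elution appears in up
  to 20 consecutive sliders; whether the original emits one spectrum per
  occurrence or consolidates is undocumented, so the package merges groups
  with the same peptide entry and apex within half a slider width, keeping
  the best hyperscore — some rule is mandatory to avoid ~20-fold duplicate
  output.
* **Degenerate inputs.** Runs with fewer cycles than the slider width
  yield an empty slider list with a warning; empty clusters, empty
  Index1∩Index2 intersections and calibrant shortfalls all degrade to
  explicit empty results or the identity calibration, never to errors.

## Problem sizes used in the checks

The test suite trains the VAE on 20,000 triplets for 5 epochs and the CNN
on 2,000 labeled groups for 12 epochs, both from a 60-peptide synthetic
run, and evaluates end-to-end recovery on a 20-peptide run against a
30-protein database — sizes chosen so a complete validation runs on a
single CPU in minutes while still exercising every stage at realistic
cluster multiplicities. The same models are reused across test files via a
session cache.

## Known limitations

* Only b/y singly charged fragment ions are indexed; modified fragment
  series beyond carbamidomethyl/oxidation/N-terminal acetylation are out
  of scope, and phosphorylation in particular is not supported.
* Calibration is global per run; slow drift within a run is not modeled.
* The two-stage clustering runs the re-clustering exactly once.
* Decoy generation, FDR control, library building and quantification are
  deliberately left to downstream tools operating on the MGF output.
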