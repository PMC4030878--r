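---
title: "Spectral transcript analysis: models, parameters and design notes"
author: "SpectraQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral transcript analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpectraQuant)
```

# The problem

Multiplexed RNA FISH labels five or six transcript species in the same
cell with spectrally distinct fluorochromes. Because the target RNAs live
largely in the same cytoplasmic volume, their signals overlap spatially and
cannot be separated by bandpass filters alone. Interferometric spectral
imaging records a full emission spectrum (450–800 nm at roughly 10 nm
resolution) at every pixel; linear spectral un-mixing then splits each
pixel's spectrum into per-dye abundances, and per-cell integration of those
abundances yields a gene-expression profile for every single cell — enough
to classify cell populations and to find rare cells with an aberrant
profile.

SpectraQuant implements this analysis chain together with a synthetic-data
generator that provides exact ground truth, so every stage can be validated
quantitatively. This vignette records the models, the defaults and the
reasoning behind the design decisions.

# Acquisition model

## Forward interferometry

A Sagnac interferometer splits the emission light into two beams with a
stepped optical path difference (OPD) $d$. For band spectrum $S(\lambda_b)$
the recorded frame intensity is modeled as

$$ I(d) \;=\; \sum_b S(\lambda_b)\,\frac{1 + \cos(2\pi d/\lambda_b)}{2}, $$

so $I(0)$ equals the total intensity. The default `opdSchedule()` takes 128
one-sided, evenly spaced OPD samples (the modeled instrument records 80–130
frames per object) with a 220 nm step — just under the 225 nm Nyquist limit
for the shortest band of the default grid. Schedules violating Nyquist are
rejected with an aliasing error.

## Reconstruction and the line-shape correction

Reconstruction mean-subtracts the interferogram, apodizes it with a
half-Hann window (unity at zero path difference, zero at maximum OPD — the
one-sided interferogram carries its information density near $d = 0$) and
evaluates a direct windowed cosine transform at the exact band wavenumbers
$1/\lambda_b$, with no FFT-grid interpolation.

At 128 frames the maximum OPD is about 28 µm, and the corresponding
spectral resolution is coarser than the 10 nm band spacing at the red end
of the grid: the raw transform smears neighboring red bands into each
other, and we measured 28–34 % relative L2 round-trip error on 30 nm-FWHM
dye spectra — far too much for quantitative work. The transform of the
forward model is, however, a fixed linear operator for a given schedule and
grid. `reconstructSpectrum()` therefore builds that band-response
(instrument line shape) matrix once per schedule, caches it, and applies
its inverse (condition number ≈ 93 at the defaults). This makes the
noise-free round trip exact to machine precision and keeps reconstruction
exactly linear; with shot noise at realistic signal levels the per-pixel
round-trip error is a few percent, and ROI totals are far tighter. The raw
uncorrected transform remains available (`correct = FALSE`).

Two details follow the conventions of the modeled software: reconstructed
negatives are clamped to zero, and the spectrum is rescaled so its total
equals $I(0)$. We use the signed cosine transform rather than the DFT
magnitude precisely so that clamping is meaningful and the pre-clamp core
stays linear; both clamping and rescaling are no-ops on clean data. The
whole acquisition step is optional — every downstream stage accepts the
rendered cube directly, and results are invariant to the bypass within the
reconstruction tolerance.

# The synthetic-data generator

`renderScene()` composes, per pixel, a flat background (total counts spread
evenly over bands), an optional autofluorescence spectrum, and uniform
disks (beads) or nucleus+cytoplasm disk pairs (cells) whose per-dye
brightness multiplies a unit-area Gaussian emission spectrum. Defaults and
what they represent:

* **Emission shape** — single Gaussian per dye, FWHM 30 nm (configurable).
  Dye catalogs give only excitation/emission peaks; 30 nm gives the smooth,
  distinct but overlapping spectra typical of organic dye panels.
  Excitation and filter physics are collapsed into the per-object
  brightness scalars, since the analysis consumes emission cubes only.
* **Peak signal** — 5000 counts per bead pixel (10000 for the brighter
  red/infrared standards). No numeric noise levels are published for the
  modeled experiments; these values make shot-noise-limited replicate CVs
  land below the few-percent reproducibility reported for physical beads,
  which also contains focus and ROI-placement variability that the
  simulation deliberately omits.
* **Noise** — `"shot"` (Poisson) by default; optional Gaussian read noise.
* **Photobleaching** — geometric decay $(1-r)^{b-1}$ applied per band plane
  in band order, modeling signal fading over the band-sequential recording
  of a full spectrum. Off by default; beads (the calibration standard)
  bleach far less than hybridized cells.
* **Cells** — cytoplasm disk radius 5 px carrying the transcript signal,
  concentric nucleus disk radius 3 px appearing only in the separately
  recorded DAPI reference image (the DAPI channel is acquired through its
  own filter set and is not part of the spectral cube). Per-cell, per-dye
  amplitudes are log-normal around population means with CV 20 % by
  default, standing in for cell-cycle-dependent expression variation whose
  magnitude is not quantified in the source experiments.
* **Bead panel** — one fixed four-bead layout re-rendered per replicate
  with independent noise and a global integer translation of at most 2 px,
  emulating manual stage repositioning between recordings.
* **Cell mixtures** — `round(nCells × rareFraction)` rare cells
  (deterministic, so a 1 % fraction of 100 cells is exactly one cell) whose
  target-dye mean is the baseline times $(1 + \text{elevation}/100)$; with
  zero elevation and equal baselines the populations are exchangeable.

Ground truth records, per object, the exact pixel set and the noiseless,
pre-bleach per-dye sums — conservation is asserted to $10^{-9}$ in the
tests. What passing these benchmarks does *not* show: robustness to optical
blur (no PSF is modeled), to chromatic aberration, to 3-D defocus, to
irregular cell morphology, or to the clumping that makes physical mixture
ratios drift; the generator's cells are clean disks on a flat background.

# Spectral un-mixing

References are unit-area normalized (area rather than peak normalization,
so a fitted coefficient carries total-signal meaning; the modeled
software's convention is not documented). `unmixPixel()` fits
$s \approx \sum_k a_k R_k$ two ways:

* `mode = "clamp"` (default) — unconstrained least squares with negative
  coefficients reported as zeros, mirroring the deployed software, which
  documents occasional negative contributions and zeroes them.
* `mode = "nnls"` — KKT-optimal nonnegative least squares (via the
  active-set solver in `pracma`), the statistically preferable option. The
  test suite checks it against an independent brute-force nonnegative
  grid search refined to a 0.001 step.

A library background spectrum, when present, joins the fit as an extra
component whose coefficient is excluded from the reported abundances.
Background may instead be subtracted beforehand (`subtractBackground()`,
clamped at zero); applying both is allowed but warned about, since it
double-corrects. The per-pixel residual L2 norm is kept so downstream QC
can flag unmodeled autofluorescence. A library whose column-normalized
matrix has condition number above $10^6$ is rejected naming the most
similar pair of references — un-mixing against near-duplicate references
is meaningless. Clamp mode is a single linear operator and runs on whole
cubes as one matrix product; `nnls` iterates per pixel.

# Segmentation

Seeded region growing admits connected pixels (8-connectivity by default)
whose total intensity is within a fractional tolerance of the seed pixel's
and whose spectral angle to the seed spectrum is below `spectralTol`.
Spectral angle was chosen as the similarity metric because it is invariant
to brightness, separating "same dye mixture, different amount" from
"different dye mixture".

DAPI-guided segmentation thresholds the max-normalized DAPI image with
Otsu's method (normalization makes the result invariant to global intensity
rescaling), labels connected components, discards nuclei under 20 px, and
orders labels by centroid raster position so labeling is deterministic.
Each cell is its nucleus dilated by 6 px (Euclidean distance via per-nucleus
distance transforms), contested pixels going to the nearest nucleus with
ties to the lower label — a compact, deterministic stand-in for a watershed
that is adequate for disk-shaped fixtures. Declumping beyond
nearest-nucleus assignment is out of scope.

# Quantification, classification, rare cells

Per-ROI reports follow the instrument's reporting convention: area, average
intensity per pixel (`int`), total = area × average (exact by
construction), and per-dye relative percent of the ROI's total reporter
signal. Background coefficients and residuals are excluded from the
relative-percent denominator, matching the convention of reporting percent
of total *cellular reporter* fluorescence. Replicate CVs use the sample
standard deviation (n − 1), appropriate at nine replicates, and are
computed on totals. Cross-replicate object matching uses nearest centroids
after removing the optimal global translation, with a 10 px radius and
hard errors for unmatched objects.

The rare-cell detector takes the median of the target dye's per-cell totals
as the majority baseline — robust to the rare cells themselves — and flags
cells at or above baseline × (1 + threshold/100). It is deterministic and
monotone in the threshold.

One statistical boundary deserves a note. If the rare population's true
mean elevation *equals* the detector threshold, the rare cell's measured
total is centered exactly on the cutoff: with any symmetric per-cell
variability its flagging probability is 1/2, independent of the noise
level, so "always detected at threshold = true elevation" is not
achievable by this (or any median-baseline) rule. Reliable detection of an
X %-elevated cell requires running the detector with a threshold
sufficiently below X for the gap to exceed the biological CV; at CV 10 %,
a 50 % elevation is flagged essentially always by a 25 % threshold at the
cost of roughly one false positive per hundred cells. The acceptance
experiments report this boundary honestly rather than tuning around it.

# Problem sizes and runtime choices

The shipped tests and the acceptance script were sized to run comfortably
on a single CPU: bead fields are 64 × 64 px with four 8 px beads, cell
mixtures place up to 100 cells on a ~160 × 160 px grid, acquisition uses
128 frames, and the replicate/seed counts (9 replicates, 20 seeds, 50-seed
noise-robustness sweeps) match the corresponding experimental protocols.
All heavy steps are matrix products, so larger fields scale linearly in
pixel count.

# Known limitations

* No optical PSF, 3-D stacks, or realistic chromatin texture; segmentation
  performance on real images will be worse than on the disk fixtures.
* The line-shape-corrected reconstruction assumes the schedule is known
  exactly; OPD calibration error is not modeled.
* Absolute transcript-copy-number calibration, ratio imaging and internal
  standards are out of scope; all quantities are relative.
* The wavelength grid is band-center based; no within-band spectral
  response is modeled.
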