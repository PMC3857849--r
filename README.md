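# nzplDICS

Coherence between EEG/MEG sensors is contaminated by volume conduction (VC)
and magnetic field spread (MFS): a single source projects instantaneously to
many sensors, so sensor pairs appear "connected" even when no neural
interaction exists, and source-level connectivity maps inherit those false
positives. `nzplDICS` implements a cross-spectral density (CSD) estimator and
beamformer pipeline that suppress these artefacts by keeping only the
**non-zero-phase-lagged (NZPL)** part of the signal, for researchers who want
to reconstruct coherent source networks from scalp recordings.

## The method

For sensor Fourier coefficients `p` (one epoch, one frequency bin), the
sensor CSD is the epoch- and band-averaged outer product

    C = < p p^H >,        coherency  K_ij = C_ij / sqrt(C_ii C_jj).

Purely instantaneous (VC/MFS) interactions are confined to `Re C`, so the
imaginary part `Im C` carries only phase-lagged interactions (the imaginary
coherency of Nolte and colleagues). The NZPL construction goes one step
further: for each sample, the anti-symmetric matrix `Im C` is
eigendecomposed; its two non-zero eigenvalues form a conjugate pair
`±i·s` whose eigenvectors, weighted by `|λ|` and squared element-wise, give
the per-sensor power that participates in the lagged interaction. The NZPL
CSD keeps `i·Im C` off the diagonal and places this eigen-derived power on
the diagonal:

    C_nzpl = i·Im C  +  diag(nzpl power).

Unlike the imaginary coherency, whose magnitude is biased by `|sin Δφ|`, the
NZPL coherence of a noiseless lagged pair is 1 for **every** lag in
`(0, π)`.

The DICS (dynamic imaging of coherent sources) stage builds one
minimum-variance unit-gain spatial filter per source,

    W_k = (L_k^H C_r^-1 L_k)^-1 L_k^H C_r^-1,    C_r = C + α‖C‖·I,

from either the full or the NZPL sensor CSD, projects that CSD to every
source pair (`W_k C W_l^H`), and normalises to pairwise source coherences.
Subtracting the pre-stimulus reconstruction from the post-stimulus one
removes filter leakage and systematic bias. A coherent two-node network
simulator (von Mises phase jitter, SNP-controlled noise, analytic
spherical-head EEG/MEG forward models) and a log-ROC evaluation harness make
the whole pipeline testable end-to-end with no external data.

## Worked example

Simulate the coherent two-node protocol on a reduced spherical-head grid and
compare the NZPL and full-CSD reconstructions:

```r
library(nzplDICS)

grid <- sourceGridSphere(spacing = 15, rMin = 57, rMax = 72, zMin = -40)
lead <- sphericalEegLeadfield(grid, eegLayout64())
cfg  <- simulationConfig(gridSpacing = 15,
                         nSourcesTarget = nSources(grid), seed = 1L)
ds   <- simulateDataset(cfg, lead, grid)

nz <- reconstructNetwork(ds, lead, grid, "nzpl")
fu <- reconstructNetwork(ds, lead, grid, "full")
```

which prints (180 sources, 16110 scored pairs):

```
NZPL  log-ROC AUC: 4.207
full  log-ROC AUC: 0.047
critical AUC:      3.855
```

The NZPL reconstruction is at the AUC ceiling for this grid
(`-log10(1/16110) = 4.207`): the true node pair outranks every one of the
16k candidate pairs, and the AUC exceeds the critical benchmark of 3.855
(the AUC at which the score distributions behind the true- and
false-positive rates overlap by 5%). The full-CSD reconstruction collapses —
the minimum-variance filter cancels the two correlated sources, so the
contrast at the true pair is no larger than background. The strongest
contrast edge lands within one grid spacing of the true node centres:

```r
exportTopPairs(nz$contrast, q = 1e-4)[1, ]
#    kx  ky kz lx  ly lz    value
#   -42 -57  3 33 -57  3 24.5
# true nodes (head frame): (-40.5 -52.5 2), (42 -52.5 2)
```

A phase-lag tolerance sweep quantifies how much coherence the estimator
retains as the lag and the signal-to-noise proportion (SNP) shrink;
at SNP 0.5 a lag of 0.025π (4.5°) still retains over 90%:

```r
phaseSweep(0.5, 0.025 * pi, "nzpl", seed = 1)$coherence
# [1] 0.976
```

## Command line

`inst/cli/nzpl-dics.R` exposes `simulate`, `csd`, `dics`, `evaluate` and
`phase-sweep` subcommands over the same functions, staged through on-disk
containers so externally computed CSDs or lead fields can enter the pipeline
at any point.
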