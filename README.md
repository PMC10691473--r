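# chromdyn

Quantify a nuclear protein's chromatin engagement from live-cell imaging:
fast single-molecule tracking (fast-SMT) and 3D fluorescence recovery after
photobleaching (FRAP), with a synthetic-data module so the whole pipeline is
testable by parameter recovery without any microscopy data.

The package is written for quantitative cell biologists analyzing
single-molecule imaging of DNA-binding proteins — the motivating system is
MeCP2 at the chromocenters of mouse neurons, where methyl-binding-domain
mutations such as G118E weaken chromatin binding — and for method developers
who need a fully simulated, ground-truthed test bed for SMT/FRAP analysis
code.

## What it computes

**Diffusion spectra and bound fractions.** Trajectories are modeled as
regular Brownian motion with localization error (RBME): the vector of $n$
consecutive one-axis jumps is zero-mean multivariate normal with tridiagonal
covariance

$$C_{ii} = 2D\,\Delta t + 2\sigma^2, \qquad C_{i,i\pm1} = -\sigma^2 .$$

A state array — a fixed log-spaced grid of diffusion coefficients $D_k$
(100 points, 0.01–100 µm²/s) — is fitted per cell by an EM-style fixed
point on the grid occupations $\pi_k$, with each state deweighted by its
expected number of observed jumps per activated molecule (defocalization
through the 0.7 µm focal slab plus geometric photobleaching). The
**bound fraction** is the occupation with $D < 0.1$ µm²/s.

**Spot detection, localization, linking.** A generalized
log-likelihood-ratio detector (kernel σ 1.3 px, 15 px window, threshold 18),
damped least-squares fitting of a pixel-integrated Gaussian (9 px window,
σ 1 px, ridge 0.001, damping 0.3), and euclidean linking within a 1 µm
search radius with no gap closing. Movies averaging more than three
detections per frame are excluded.

**FRAP summaries.** Background subtraction, pre-bleach normalization,
frame-by-frame division by the normalized nuclear signal (which cancels
acquisition photobleaching exactly), then the bleach depth $I_{\min}$,
maximal recovery $I_{\max}$ (3-frame moving-average maximum) and time to
half-recovery $t_{1/2}$ (first crossing of
$I_{\min} + (I_{\max}-I_{\min})/2$, by linear interpolation).

**Expression coupling.** Detections per cell as a protein-level proxy,
Pearson correlation with the bound fraction, a seeded random-pairing null,
high/low-expression FRAP stratification, and per-animal Mann–Whitney
comparisons.

## Worked example

Simulate the wild-type preset (64% bound, free state 3 µm²/s) at 5 cells ×
250 photoactivated molecules and infer the spectrum:

```r
library(chromdyn)

cfg <- imaging_config()              # 0.16 um/px, 7.48 ms frames, 0.7 um slab
wt  <- preset("WT")
sim <- simulate_trajectories(wt$two_state, cfg,
                             n_cells = 5, traj_per_cell = 250, seed = 11)
fit <- state_array(sim$trajectories)
fit
#> State-array diffusion spectrum: 5 cells (0 skipped), 100 grid points
#>   total trajectories 972, total jumps 5887
#>   aggregate bound fraction (D < 0.1 um^2/s): 0.678
```

The aggregate bound fraction (0.678) is the jump-count-weighted mean of the
per-cell posterior occupations below 0.1 µm²/s; at this small cell count it
sits within a few points of the generating 0.64, and at the study scale of
20 cells it recovers 63–65% across seeds. `summary(fit)` gives the per-cell
table (`cell_id`, `n_trajectories`, `n_jumps`, `n_detections`,
`bound_fraction`) and `plot(fit)` the occupation spectrum.

FRAP at the wild-type preset ($t_{1/2} = 26$ s, plateau 0.92, with 20%
acquisition photobleaching over 10 min injected and corrected away):

```r
frap <- simulate_frap(wt$frap, n_cells = 23, seed = 11)
average_and_summarize(lapply(frap$series, correct_series))
#> FRAP recovery (23 cells, 0 excluded)
#>   I_min  0.455
#>   I_max  0.930
#>   t_1/2  26.5 s
```

$I_{\min}$ is the corrected bleach depth (truth 0.45), $I_{\max}$ the
maximal recovery (truth 0.92) and $t_{1/2}$ the half-recovery time (truth
26 s).

A thin command-line wrapper for the CSV-level steps (`track`, `infer`,
`frap`, `couple`) is installed at `inst/cli/chromdyn`.

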