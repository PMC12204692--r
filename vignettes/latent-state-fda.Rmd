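---
title: "Latent-state functional data analysis: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-state functional data analysis: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statefda)
```

## The problem

Many longitudinal measurements are best viewed as a time series of *curves*:
each observation is a whole function on a shared grid rather than a scalar.
The motivating case is resting-state EEG, where every second of recording
yields a power spectral density (PSD) over frequency. Two questions arise
naturally at different levels: *between* time points — which discrete
regimes ("latent states") does an individual's spectrum move through, and
how often? — and *within* a regime — once individuals are in a matched
state, what modes of spectral variation distinguish them? `statefda`
answers both with a nested design: a functional hidden Markov model (FHMM)
over curves, followed by functional principal component analysis (FPCA)
inside each decoded state.

## The functional hidden Markov model

An individual's sequence of curves $x_1, \dots, x_K$ is modelled as
emissions of a hidden Markov chain $Q_k$ on states $\{1, \dots, N\}$ with
initial distribution $\nu$ and transition matrix $A = \{a_{ij}\}$. Each
state $i$ owns a centroid curve $\mu_i$, and the emission term is a
*pseudo-likelihood* built from distance rather than a density:

$$ b_i(x) \;=\; h\!\big(d(x, \mu_i)\big), \qquad h(y) = \frac{1}{y^2 + \varepsilon}, $$

with $d$ the $L^2$ distance $\sqrt{\int (x - \mu_i)^2\,dt}$ approximated by
trapezoidal quadrature on the grid. Curves near a centroid are "likely"
under that state; $\varepsilon$ (default $10^{-12}$ times the grid range)
regularises the otherwise-undefined value at $d = 0$, which genuinely
occurs for noiseless synthetic data. Because emissions are unnormalised
similarities, the objective maximised by estimation is a log
*pseudo*-likelihood (the sum of log scaling normalisers of the scaled
forward recursion); posteriors $\gamma_k(i)$ and $\xi_k(i,j)$ from the
forward–backward pass are proper distributions regardless, which is all
the M-step needs.

### Estimation and the centroid update

`baum_welch()` pools multiple individuals under one shared model: $\nu$ is
re-estimated as the average first-step posterior, $A$ from responsibilities
pooled over all sequences. The centroid update deserves a note, because the
obvious choice is wrong. The k-means-style update — the
$\gamma$-weighted pointwise mean — minimises $\sum_k \gamma_k d^2(x_k, \mu)$,
but the M-step objective here is $\sum_k \gamma_k \log b(x_k;\mu) =
-\sum_k \gamma_k \log(d_k^2 + \varepsilon)$, and the weighted mean does not
maximise it; in experiments it visibly *decreased* the objective on noisy
data. Since $-\log u$ is convex, its tangent at the current value $u^0_k =
d_k^2(\mu^{0}) + \varepsilon$ minorises it, and maximising the minorant is
a weighted least-squares problem whose solution is the mean reweighted by
$\gamma_k / u^0_k$ — that is, by `gamma * emission`. This
minorise–maximise step restores the EM monotonicity guarantee, which the
test suite asserts on every run (slack $10^{-9}$ per step). Observations
far from a centroid are naturally down-weighted, a mild robustness bonus.

Other conventions: convergence is declared when the relative objective
change drops below `tol` ($10^{-6}$ by default, 200 iteration cap); a state
whose total responsibility falls below $10^{-8}$ has its centroid frozen
with a warning rather than producing 0/0; Viterbi decoding breaks ties
toward the lowest state index so output is deterministic; each individual's
sequence is treated as a single unbroken chain (segment boundaries, e.g.
between eyes-closed blocks, are retained in the metadata so a user can
split sequences beforehand if they prefer chains that restart at
boundaries).

### Initialisation by consensus over subsamples

Functional k-means with random restarts initialises centroids, but on
high-dimensional curves it is notoriously unstable: clusters collapse onto
near-identical centroids. `subsample_initialise()` therefore fits several
FHMMs (default 10) to random 80% subsamples of the individuals, each
deliberately over-provisioned with states (default 8) so redundant
duplicates are allowed to occur, and pools all fitted centroids.
Centroids that recur across subsamples mark the stable states;
`group_centroids()` clusters the pool by average-linkage agglomeration on
pairwise $L^2$ distances (cut at a requested group count or distance
threshold, or grouped manually from the diagnostic distance matrix), and
each group's pointwise mean becomes an initial centroid for the final
full-data fit. The subsampled fits use looser convergence settings
(`tol = 1e-5`, 50 iterations) than the final fit, since only their
centroids are harvested.

## Occupancy dynamics

From each decoded path, `summarise_path()` reports the number of distinct
states visited, the number of transitions (adjacent unequal pairs), the
proportion of time per state over all $K$ steps, and the dominant state
(ties broken toward the lowest label, with a flag). Individuals with
dominant-state share at or above the threshold — 0.8 by default, and the
comparison is inclusive — form dominant-state groups; the rest are
"mixed". `visited_combinations()` counts individuals by the exact subset
of states they visit; the counts partition the sample (the cells of a Venn
diagram over states).

## FPCA within states

Curves decoded into one state are pooled across individuals and expanded
in a cubic B-spline basis (order 4, interior knots at every other grid
point by default) by penalised least squares with a second-derivative
roughness penalty ($\lambda = 10^{-4}$ on the grid scale by default — PSD
peak curves are already smooth, so only gentle regularisation is wanted;
both knot density and $\lambda$ are arguments). The eigenproblem of the
coefficient covariance is solved in the basis metric — symmetrised through
the Gram matrix $J^{1/2} V J^{1/2}$ — so eigenfunctions come out
orthonormal in $L^2$. One deliberate consistency choice: the Gram matrix
uses the same trapezoidal quadrature on the evaluation grid as every other
inner product in the package, rather than exact continuum integrals. This
makes orthonormality exact under the quadrature scores are computed with,
and gives a clean discrete limit: with a saturated basis, zero penalty and
a uniform grid, eigenvalues and scores coincide with classical PCA of the
quadrature-scaled curve matrix to $10^{-6}$, which the tests verify
against `prcomp` as an independent route.

Scores are quadrature inner products of the *raw* centred curves with the
eigenfunctions, so projecting the training curves reproduces the stored
scores exactly, and new curves can be scored with `project_scores()`.
Eigenvalues are clipped at zero; each eigenfunction's sign is fixed by
making its largest-magnitude entry positive. Component retention follows
the smallest $C$ whose cumulative variance fraction strictly exceeds 70%,
with the scree table returned for visual inspection of the elbow —
retention is a human judgement the rule only approximates. Per-individual
scores for regression are the arithmetic mean of that individual's
within-state observation scores; the mean (rather than a median or single
representative observation) keeps the aggregation linear and
order-invariant, but it is a choice, and the observation-level scores are
exported for users who prefer another.

## The spectral parameteriser

EEG applications feed the FHMM not raw spectra but their *periodic*
content. `fit_spectral_model()` separates a log10-power spectrum into an
aperiodic background $\text{offset} - \text{exponent}\cdot\log_{10} f$
plus Gaussian oscillatory peaks, in the spirit of established
spectral-parameterisation tools, with the settings: peak width limits
1–12 Hz, no cap on the number of peaks, minimum peak height 0.05,
relative peak threshold 2.0 residual standard deviations, fixed aperiodic
mode (no knee), fit range 1.5–30 Hz. This is a re-implementation
built for parameter recovery, not a bit-compatible clone of any existing
tool. Width limits are read as bounds on the full bandwidth ($2\sigma$),
so $\sigma \in [0.5, 6]$ Hz.

The procedure: a robust aperiodic fit (ordinary least squares, refit after
dropping the top 2.5% of residuals so peaks do not drag the background
up); iterative peak extraction from the flattened residual, where each
seed Gaussian is refined alone by bounded least squares before
subtraction — refining before subtracting avoids leaving artifacts that
would seed spurious further peaks — stopping when the tallest remaining
point falls below $\max(0.05,\; 2.0 \times \mathrm{sd}(\text{residual}))$;
joint bounded refinement of all Gaussians, each centre confined within
$\pm 1.5$ guessed widths of its seed so overlapping peaks cannot merge or
split; three alternations of peak refinement with aperiodic refit on the
peak-subtracted curve, which removes the bias tall peaks induce in the
initial background estimate; and finally $R^2 = 1 - SSE/SST$ in
log10-power space. Peaks that end below the height floor or outside the
width bounds are dropped, so every returned peak satisfies the declared
constraints. Peak-only curves stay in log10-power units.

## The synthetic-data generator

Because the framework is validated without any external dataset, the
generator is first-class code. `make_psd_centroids()` builds state
centroids as sums of Gaussian peaks; the built-in 4-state preset mimics
four qualitatively distinct resting-state EEG profiles (delta-dominant
with a beta-2 shoulder; theta with a 9 Hz alpha peak; 11 Hz alpha with
beta-1; strong 10 Hz alpha) on the default 1.5–30 Hz grid at 0.5 Hz
spacing (58 points). `simulate_fhmm_dataset()` draws state paths from
$(\nu, A)$ and emits the centroid plus smooth functional noise: about ten
evenly spaced cubic B-spline basis functions with i.i.d. Gaussian
coefficients, rescaled per grid point so the marginal standard deviation
equals `noise_sd` exactly. Emissions of a functional model must be random
*functions* — i.i.d. pointwise jitter would be unsmooth in a way no
spectral estimate is — but this Gaussian smooth-noise model is a
stand-in: the distance-based emission model has no generative noise
distribution of its own, so any generator is a modelling choice, and
recovery results under this noise do not certify behaviour under, say,
heavy-tailed or multiplicative spectral noise. One master seed is split
into per-individual seeds, so an individual's draw is reproducible in
isolation. `simulate_raw_psd()` generates raw log10-power spectra
(aperiodic plus peaks plus i.i.d. noise) for exercising the spectral
parameteriser.

## Validation set-up and problem sizes

The test suite validates exact inference against brute-force path
enumeration (100 random instances with $N \le 3$, $K \le 6$, agreement to
$10^{-10}$), EM monotonicity on every run, and full-pipeline parameter
recovery: 4 preset states, 50 individuals with 100 observations each,
noise standard deviation set to one-twelfth of the minimum pairwise
centroid distance (comfortably within the well-separated regime of at
least ten noise standard deviations between centroids), consensus
initialisation with its defaults, for ten seeds of which at least nine
must recover all centroids within a tenth of the minimum true pairwise
distance and all transition entries within 0.05. Spectral recovery is
checked at observation noise 0.01–0.02 with batch mean $R^2$ above 0.95.
These sizes keep the whole suite under a couple of minutes on one core
while leaving the Monte-Carlo margins far from the tolerances.

## Known limitations

* Emissions are pseudo-likelihoods; information criteria computed from the
  objective are not comparable across emission choices, so the number of
  states is chosen via the consensus-initialisation diagnostics, not AIC/BIC.
* The hidden chain is first-order Markov with geometric dwell times;
  semi-Markov or autoregressive dynamics are out of scope.
* One shared model across individuals: heterogeneity appears only through
  state occupancy, not individual-specific centroids or transitions.
* The spectral parameteriser has no aperiodic "knee" mode and does not fit
  outside 1.5–30 Hz.
* FPCA is unrotated; interpretation of higher components inherits the
  usual ambiguity of variance-ordered bases.
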