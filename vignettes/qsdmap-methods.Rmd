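---
title: "Diffusion maps, quasi-stationary distributions and committors on point clouds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qsdmap methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsdmap)
```

## The model

`qsdmap` analyses point clouds sampled by overdamped Langevin dynamics

$$dx_t = -\nabla V(x_t)\,dt + \sqrt{2\beta^{-1}}\,dW_t,$$

whose invariant law is the Boltzmann–Gibbs measure
$\mu \propto e^{-\beta V}$ and whose infinitesimal generator is
$L_\beta = -\nabla V\cdot\nabla + \beta^{-1}\Delta$.  The central
object is the graph-Laplacian (diffusion-map) approximation of that
generator built from samples alone: with the Gaussian kernel
$K_{ij} = \exp(-\|x_i-x_j\|^2/(4\epsilon))$, the density estimate
$q_i = \sum_j K_{ij}$, the two-step $\alpha$-normalization
$K^{(\alpha)}_{ij} = K_{ij}/(q_i^\alpha q_j^\alpha)$ followed by row
normalization into a Markov matrix $P_\epsilon$, the matrix

$$L_\epsilon = \epsilon^{-1}(P_\epsilon - I)$$

converges point-wise (as $m \to \infty$, $\epsilon \to 0$) to
$\Delta + (2-2\alpha)\,\nabla\log\pi\cdot\nabla$ where $\pi$ is the
sampling density.  For $\alpha = 1/2$ and Boltzmann-distributed samples
this is $\beta L_\beta$, the *time-rescaled* generator; every solver in
the package, including the pseudo-spectral reference, uses this same
time scale so that eigenvalues are directly comparable across routes.

A note on conventions: a compressed one-step notation
$P_\epsilon = D_\alpha^{-1} K_\epsilon$ circulates for this
construction, but read literally it is neither row-stochastic nor does
it have the stated limit; `buildGenerator` implements the standard
two-step construction throughout.  Because the row normalization
divides by the row sums of $K^{(\alpha)}$, constant rescalings of $q$
cancel; the package therefore uses raw kernel row sums and asserts the
scale invariance by test.

The target-measure variant (`buildTMDmap`) right-normalizes the kernel
with $\mathrm{diag}(\pi^{1/2}/q)$ using *known* (possibly unnormalized)
target-density values, so that clouds sampled from any surrogate
distribution — for instance a metadynamics-biased trajectory — still
approximate the target generator $\nabla\log\pi\cdot\nabla + \Delta$.

Both flavours are reversible Markov generators: $\mathrm{diag}(\mu)
P_\epsilon$ is symmetric for a known positive weight $\mu$ (the
$K^{(\alpha)}$ row sums for the $\alpha$-map; $\pi^{1/2}q^{-1}\tilde D$
for the TMDmap).  `spectralDecompose` exploits this and solves an
exactly symmetric eigenproblem (dense LAPACK below ~1200 points, ARPACK
with a fixed deterministic start vector above), so eigenvalues are real
by construction, the trivial mode is resolved to machine precision, and
every returned pair is checked against the residual bound
$\|Lv-\lambda v\| \le 10^{-8}\|L\|_\infty$.

## Dirichlet problems, committors and the QSD

Dirichlet boundary conditions are realized on the point cloud by
restriction to the principal submatrix $L_\epsilon[\Omega,\Omega]$
(`solveDirichletEigen`).  Zeroing the exterior rows of the full matrix
gives identical eigenpairs for vectors supported in $\Omega$; the
submatrix form keeps the matrix well-conditioned and symmetric under
the same weight.

The committor $q(x) = \mathbb P(\tau_B < \tau_A \mid x_0 = x)$ solves
$Lq = 0$ off $A \cup B$ with $q|_A = 0$, $q|_B = 1$; on the cloud this
is the linear system $L_\epsilon[c,c]\,q[c] = -L_\epsilon[c,b]\mathbf 1$
(`solveCommittor`), solved by a direct factorization (dense or sparse
LU; the problem sizes in this package never require an iterative
fallback).  Finite-$\epsilon$, finite-$m$ committors can leave $[0,1]$
slightly; values outside $[-0.05, 1.05]$ are flagged and counted, never
clamped.

The quasi-stationary distribution of a domain $\Omega$ has density
$\nu \propto v\,e^{-\beta V}$ with $v$ the first Dirichlet
eigenfunction of the generator on $\Omega$.  The package's reference
solver (`chebyshevDirichlet`, `chebyshevQSD`) discretizes the
time-rescaled generator with Chebyshev collocation on Gauss–Lobatto
nodes.  Internally it solves the Schrödinger-conjugated form

$$H = \partial^2 - W, \qquad W = \tfrac{1}{4}(\beta V')^2 -
\tfrac{1}{2}\beta V'',$$

which has the same spectrum as the drift form but only mild
non-normality.  This choice is essential, not cosmetic: on large
domains the drift form's non-normality grows like $e^{\beta\Delta V/2}$
and the computed first eigenvector visibly mixes the two near-null well
modes (we observed $v(1) = 0.91$ instead of $1.000$ for the shifted
double well on $[-8,8]$), while the conjugated form resolves it to ten
digits.  The back-conversion $v = e^{\beta V/2}\phi$ is only performed
on nodes where $\phi$ is above its round-off floor; elsewhere $v$ is
set to zero — those regions carry Boltzmann mass $e^{-\beta V}
\approx 0$ and enter no downstream quantity.  For evaluating $v$ at
interior points, `qsdEigenfunctionAt` interpolates through the smooth
product $\nu = v e^{-\beta V}$ rather than $v$ itself, avoiding noise
amplification in the tails.

$v$ is normalized so that its mean against the Boltzmann measure
restricted to $\Omega$ equals one.  With this convention the
convergence of the QSD to the Boltzmann measure as the domain grows
becomes the directly testable statement $v(x)\to 1$ on compacts: for
$V = ((x-1)^2-1)^2$ at $\beta = 1$ the deviation $|v(1)-1|$ falls from
$0.126$ at $L=2$ to $4.7\times10^{-4}$ at $L=3$ and reaches the
numerical floor ($<10^{-8}$) by $L=5$ — the true deviations beyond that
are of order $e^{-\beta\,\Delta V_{boundary}}$ and are not representable
in double precision, so the domain-growth check treats "below the
spectral floor" as converged rather than insisting on strict
monotonicity between two numerical zeros.

## Local versus global spectra

Inside a metastable state the sampled distribution is the QSD, and the
diffusion map approximates the QSD-weighted operator
$\Delta + \nabla f\cdot(\nabla\log v - \beta\nabla V)$ (for
$\alpha = 1/2$).  Two consequences are verified quantitatively:

* **What the trapped spectrum measures.**  The conditioned (never
  absorbed) cloud knows nothing about the exit rate; its first nonzero
  eigenvalue is the relaxation rate *within* the QSD.  Where
  $v \approx 1$ (everywhere except a boundary layer) the QSD-weighted
  operator coincides with the full generator, so that eigenvalue must
  match the full-line generator's intra-well mode — the eigenvalue
  *above* the slow interwell one.  For the 1D double well at
  $\beta = 1$ the package finds $-6.03$ from the conditioned cloud
  versus $-6.004$ pseudo-spectrally (0.5%); the Dirichlet exit rate
  ($-0.75$) is a different quantity and no spectral estimate from an
  unabsorbed cloud can approximate it.

* **Local and global coordinates.**  For the two-dimensional double
  well (parameters $h = 2$, $w = 1$; minima near $(\pm1.18, 0)$ with
  $V = 0.4$, saddles at $(0,\pm1)$ with $V = 8/3$) at $\beta = 10$, a
  trapped cloud's first diffusion coordinate parametrizes the
  transverse $y$ mode ($|\rho(\phi_1, y)| > 0.99$), while a cloud
  covering both wells parametrizes the reaction coordinate $x$
  ($|\rho(\phi_1, x)| > 0.99$).  The second local coordinate
  parametrizes $x$ ($|\rho(\phi_2, x)| > 0.99$) — used below.

Metastable sets are identified from the extrema of $\phi_1$ and grown
by diffusion distance (`identifyMetastableSets`).  Raw eigenvector
coordinates are used (no $e^{\lambda t}$ weighting): the threshold is
user-set, so any weighting would be absorbed into it.  Ambiguous points
join the nearer centre, exact ties going to the argmax set.

## Exit detection

`spectrumMonitor` recomputes the $\alpha = 1/2$ spectrum on successive
trajectory windows and `flagSpectrumExit` flags the first window whose
mean eigenvalue jumps by more than `jumpFactor` (default 5) trailing
standard deviations of the preceding window means.  No numeric trigger
is canonical for this detector, so both the raw eigenvalue series and
the per-window mean/max-difference summaries are returned for users who
prefer their own rule.  Under metadynamics the detector fires when the
accumulated bias has distorted the local state by roughly its own
scale; matching the deposition rate to about one barrier-unit per
window makes the flag and the first barrier crossing coincide to within
one window, which is how the acceptance check runs it.

## The adaptive CV-learning loop

`runAdaptiveSampling` implements the enhanced-sampling loop — published
only as a narrative outline, so this implementation is a labelled
reconstruction: (1) sample the local state (plain Langevin or
Fleming–Viot) while monitoring the window spectra until the mean
eigenvalue is stable (relative change below 5% across 3 consecutive
windows; a run that never stabilizes is reported as inconclusive, not
an error); (2) decompose the pooled local cloud; (3) rank candidate
CVs by absolute Pearson correlation against the leading diffusion
coordinates and choose the best distinct candidate per coordinate;
(4) run standard Gaussian-hill metadynamics along the chosen CVs,
keeping the accumulated bias across iterations; (5) count transitions
and record a TMDmap diagnostic that targets the *unbiased* Boltzmann
density on the biased samples, so the unbiased relaxation rate is
recovered from biased data (verified within 20% on the 1D double
well).

For the toy systems the candidate list is coordinate projections and
their linear combinations plus a pure-noise control
(`toyCandidateCVs`).  The noise candidate is a seeded nearest-neighbour
lookup into an i.i.d. Gaussian table — a deterministic function of the
configuration that reproduces its stored values exactly, decorrelates
from every smooth coordinate, and has zero gradient almost everywhere,
so metadynamics along it exerts no systematic force.  The negative
control (`selectionRule = "least"`) biases the *jointly*
least-correlated candidate — the one minimizing the largest $|\rho|$
across the served diffusion coordinates.  The joint criterion matters
in the toy geometry: against $\phi_1$ alone, $x$ and the noise control
are statistically tied near zero inside a well, yet $x$ is secretly the
perfect global reaction coordinate; $\phi_2$ resolves the tie
($|\rho(\phi_2, x)| > 0.99$), leaving the noise control as the
unambiguous bottom candidate in every seed we tested.

## Simulators

`simulateOverdamped` offers Euler–Maruyama and the Leimkuhler–Matthews
postprocessed step (`scheme = "lm"`), which averages consecutive noise
increments and samples the configurational marginal with higher-order
accuracy — for the quadratic well its stationary variance is exactly
$1/\beta$ at any stable step size.  All study fixtures use the LM
scheme with $\Delta t = 0.1$ (1D) or as stated.  Noise conventions:
increment $\sqrt{2\Delta t/\beta}\,\xi$; one root seed spawns
sub-streams by the fixed affine rule in `deriveSeed`, so Fleming–Viot
replicas with an always-true indicator are bit-identical to independent
`simulateOverdamped` runs at the derived seeds.

`flemingViot` checks the domain indicator after each full step and
restarts violators, in replica-index order, from a uniformly chosen
replica currently inside the domain (the classical construction; the
published description leaves these details to footnotes unavailable to
us, so the bookkeeping is documented here rather than attributed).  The
ensemble's empirical density for free diffusion on $(-1,1)$ matches the
pseudo-spectral QSD to $L^1$ distance $< 0.1$ with 600 replicas pooled
over late snapshots.

`simulateMetadynamics` deposits standard (non-well-tempered) Gaussian
hills every `stride` steps; height, width and stride are required
arguments with no silent defaults.  With `hillHeight = 0` the
trajectory is bit-identical to the unbiased one at the same seed.
Stability note: the 2D double well at $\beta = 10$ needs
$\Delta t \lesssim 0.05$ once the bias approaches the barrier scale;
the study configurations use $\Delta t = 0.02$.

## Numerical choices and problem sizes

* **Bandwidth $\epsilon$.**  There is no automatic tuner; $\epsilon$ is
  required wherever a kernel is built, and `kernelSumDiagnostic`
  provides the standard log–log data to guide the choice.  The studies
  in this package use: $0.05$ for the quadratic-well spectrum (ratio
  $\lambda_2/\lambda_1 = 2$ recovered within the stated 10%), $0.1$ for
  the 2D committor and correlation studies, and $2\times10^{-4}$ for
  the Dirichlet error-decay study — small enough that the sampling
  error, not the $O(\sqrt\epsilon)$ absorbing-boundary-layer bias,
  dominates over the whole sample range, which is the regime in which
  the $N^{-1/2}$ statistical decay is measurable (fitted log–log slope
  $-0.55$ over $N \in \{500, 1000, 2000, 4000, 8000\}$ averaged over
  three seeds).
* **Dirichlet boundary layers.**  The principal-submatrix Dirichlet
  realization carries an $O(\sqrt\epsilon)$ absorbing layer: at
  $\epsilon = 0.05$ the first OU Dirichlet eigenvalue is 40% off; at
  $10^{-3}$ it is within 3%.  Point-cloud Dirichlet studies therefore
  use much smaller bandwidths than spectral ones, and the classical
  free-diffusion spectrum test uses $\epsilon = 10^{-3}$ with an
  absorbing shell of width $0.03$ (kernel width $\sqrt{4\epsilon}
  \approx 0.06$, commensurate with the shell).
* **Committor bandwidth bias.**  The point-cloud committor carries a
  broad $O(\epsilon)$ bias peaking at the absorbing-set edges
  ($L^\infty$ against the pseudo-spectral reference on the 1D double
  well: $0.16$ at $\epsilon = 0.1$, $0.05$ at $0.02$, $0.03$ at
  $0.01$, at $m = 10^4$).  The convergence in $\epsilon$ is asserted by
  test; users who need committors accurate to better than a few percent
  should work at $\epsilon \le 0.05$ for problems of this scale.
* **Sparsity.**  `cutoff = 0` (dense) is the default and is used up to
  $m = 10^4$; a positive cutoff switches to sparse storage, applied
  symmetrically, with a connectivity check that errors listing the
  component sizes.
* **Problem sizes.**  The published studies of this methodology used
  clouds of $10^5$–$10^6$ points.  This package's studies run at
  desk scale: $m = 2000$–$10^4$ for spectra and committors, $N \le
  8000$ for the error-decay study, $1500$-point windows for monitoring.
  Power-law slopes, spectral ratios, correlations and committor levels
  are scale-free diagnostics, so the conclusions carry; absolute errors
  are correspondingly larger than at $10^6$ points.
* **Degenerate inputs.**  Duplicate points are allowed everywhere
  (kernel rows handle them); zero kernel rows after a cutoff, empty or
  overlapping committor sets, non-positive target densities, constant
  $\phi_1$, and all-replica Fleming–Viot extinction raise informative
  errors.

## What the synthetic systems do and do not show

The toy potentials (quadratic well, two 1D double wells, the 2D double
well with a slow transverse mode) exercise every code path — biased and
unbiased sampling, local and global spectra, committors with known
references, QSD limits, exit detection, CV learning — with oracles
available for each.  They are low-dimensional, smooth, and sampled at
modest metastability ($\beta\Delta V \le 23$), so passing tests show
the estimators converge to the right operators and rates under these
conditions.  They do not probe: high ambient dimension with
low-dimensional structure (where $\epsilon$ selection and variable
bandwidths become delicate), rugged landscapes with many states beyond
the two-centre partition scheme, molecular force fields, or sampling
schemes other than overdamped Langevin.  The two-centre metastable-set
scheme is deliberately limited to two sets; multi-state clustering
(PCCA-style) is out of scope.

## Assumptions inherited from the source problems

The inverse temperature for the 1D committor study is not stated in
its source; $\beta = 1$ is adopted.  The 2D committor study needs the
transition region populated, so its cloud is generated at $\beta = 2$
(walkers started in both wells, $\Delta t = 0.1$, subsampled to
$10^4$); the local/global correlation study keeps $\beta = 10$, where
each walker stays in its well.  The Nyström extension divides by the
Markov-matrix eigenvalue $1 + \epsilon\lambda_j$, which makes the
extension exact at the training points; the alternative reading
(dividing by $\lambda_j$ itself) does not have that property.
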