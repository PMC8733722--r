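---
title: "Diagrammatic self-energies for molecular ionization potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagrammatic self-energies for molecular ionization potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbptip)
```

## The model

`mbptip` computes electron-removal energies of closed-shell systems from
many-body perturbation theory on top of a mean-field reference. The
central object is the diagonal self-energy difference
$\Delta\Sigma_{pp}(\omega)$ that connects the non-interacting Green's
function $G_0$ (defined by orbital energies $\epsilon_p$ and occupations
0/2) to the interacting one through the Dyson equation. With the common
diagonal approximation, the poles of the interacting Green's function are
the solutions of the quasiparticle equation

$$\omega - \epsilon_p = \mathrm{Re}\,\Delta\Sigma_{pp}(\omega),$$

and the ionization potential is minus the highest such solution over the
occupied states. Each crossing carries a spectral weight
$Z = [1 - \partial\Delta\Sigma/\partial\omega]^{-1}$, which must lie in
$(0, 1]$ for a physically meaningful quasiparticle.

Implemented self-energies, all with strict single-pole structure:

* **PT2** — all second-order diagrams in the bare Coulomb interaction:
  the direct (ring) term with factor-2 spin-adapted numerators plus the
  second-order exchange (SOX) with crossed numerators. 2p1h poles sit at
  $\epsilon_a + \epsilon_b - \epsilon_i$, 2h1p poles at
  $\epsilon_i + \epsilon_j - \epsilon_a$.
* **GW** — first order in the screened interaction $W$, with
  $\Sigma^c_{pp}(\omega) = \sum_s \left[\sum_i (w^s_{pi})^2/(\omega -
  \epsilon_i + \Omega_s - i\eta) + \sum_a (w^s_{pa})^2/(\omega -
  \epsilon_a - \Omega_s + i\eta)\right]$. The residues are squares, so
  the slope of $\mathrm{Re}\,\Sigma^c$ is negative between poles by
  construction — the correct analytic structure.
* **GW + SOSEX** — the second-order-exchange topology with one screened
  line, added to GW.
* **GW + $\gamma^{GW}$** — GW plus the static Hartree/exchange shift
  generated by the linearized first-order-in-$W$ correction to the
  one-particle density matrix.

## The screened interaction

$W$ is built from a Casida-type linear-response eigenproblem over
occupied–virtual pairs,

$$A_{ia,jb} = \delta_{ij}\delta_{ab}(\epsilon_a - \epsilon_i)
  + 2(ia|jb) - k\,(ij|ab), \qquad
  B_{ia,jb} = 2(ia|jb) - k\,(ib|aj),$$

with $k = 0$ (RPA), $k = 1$ (TDHF) or $k = \alpha$ (exchange-scaled
hybrid kernel). The solver uses the symmetrized form
$(A-B)^{1/2}(A+B)(A-B)^{1/2}$ and refuses to continue whenever $A-B$ or
the symmetrized product has a non-positive eigenvalue, raising an
`mbpt_instability_error` that names the offending eigenvalue. This is
deliberate: a negative excitation energy means the underlying mean-field
solution is not a stable minimum, and silently producing complex
excitation energies would poison every downstream quantity.

The pole residues are
$w^s_{pq} = \sqrt{2}\,\sum_{ia}(pq|ia)(X+Y)^s_{ia}$. The $\sqrt 2$ is
not a free constant: replacing the amplitudes by unit vectors and the
excitation energies by bare orbital gaps (`bare_screening()`) must make
the GW self-energy collapse onto the PT2 ring term exactly, and the test
suite enforces this identity to $10^{-10}$ at every grid frequency.

**SOSEX convention.** The frequency structure of screened second-order
exchange differs between literature formulations. Here the collective
mode replaces the bare electron–hole pair in *both* numerator factors of
each SOX channel, e.g. for the 2p1h channel

$$\Sigma^{\rm SOSEX}_{pp}(\omega) = -\sum_{s,a}
  \Big[\textstyle\sum_{ib}(pa|ib)(X+Y)^s_{ib}\Big]
  \Big[\textstyle\sum_{kc}(pc|ka)(X+Y)^s_{kc}\Big]
  \big/ (\omega - \epsilon_a - \Omega_s + i\eta),$$

and analogously on the 2h1p side. This is the only reading consistent
with the defining limit used throughout the package: with truncated
screening the expression collapses to bare SOX term by term. A wiring
that attaches only the correlation part of $W$ to the SOX topology does
*not* have this limit (it produces a third-order object instead) and is
not what is meant here.

**$\gamma^{GW}$ working equations.** The density-matrix correction is
the energy-integrated $G_0\Sigma^c G_0$ evaluated by closed-form residue
sums. The occupied–occupied and virtual–virtual blocks are

$$\Delta\gamma_{ij} = -\sum_{s,a}
  \frac{w^s_{ia} w^s_{ja}}
  {(\epsilon_i - \epsilon_a - \Omega_s)(\epsilon_j - \epsilon_a - \Omega_s)},
  \qquad
  \Delta\gamma_{ab} = +\sum_{s,i}
  \frac{w^s_{ai} w^s_{bi}}
  {(\epsilon_i - \epsilon_a - \Omega_s)(\epsilon_i - \epsilon_b - \Omega_s)},$$

in which the $\epsilon_p \to \epsilon_q$ degenerate limits have already
been taken analytically — the cancellations between the Green's-function
residues and the self-energy pole sums are carried out symbolically, so
no divided differences or small-denominator thresholds appear anywhere
(this is stronger than a switch-over to a derivative formula at a
threshold, which an earlier design sketch suggested). The
occupied–virtual block uses the same analytically combined form. Two
identities pin the construction and its spin factors: with truncated
screening the oo/vv blocks equal the direct part of the unrelaxed MP2
density matrix, and contracting the *full* mean-field density matrix
through the same static Hartree + exchange map reproduces the
Hartree-plus-exchange diagonal of the Fock operator exactly. A pleasant
by-product of the combined forms is exact trace conservation: the hole
and particle sums cancel to machine precision, so the reported
`trace_deviation` is zero on every fixture.

## Reference conventions

For a native Hartree–Fock reference the static part of
$\Delta\Sigma$ vanishes identically: the model stores the full diagonal
of the mean-field exchange-correlation potential (`vxc_diag`), which for
HF equals the exchange diagonal, and the one-shot construction is
$\Delta\Sigma_{pp}(\omega) = \Sigma^x_{pp} - v^{xc}_{pp} +
\Sigma^c_{pp}(\omega)$. Imported references (e.g. global hybrids with
boosted exact exchange, serialized as JSON containers) enter through the
same formula; a container exported from a native HF solution reproduces
the native results to $10^{-10}$.

**PT1.** On a non-HF reference, Brillouin's theorem no longer removes
the first-order terms, but their algebraic content is
convention-dependent. Two readings are available behind a default-off
flag: the diagonal static potential difference
$\Sigma^x - v^{xc}$, and additionally a static single-excitation shift
built from the off-diagonal elements of the HF Fock operator in the
reference basis. Both vanish identically at HF, and neither is asserted
to be *the* canonical PT1; for the PT2 family the strict order-by-order
default includes no static term unless the flag is set, while GW-family
methods always carry the one-shot static part.

## The quasiparticle solver

`solve_graphical()` walks a frequency grid (default spacing
$2\times 10^{-3}$ Ha over $\epsilon_p \pm 1$ Ha), brackets every sign
change of $f(\omega) = \omega - \epsilon_p -
\mathrm{Re}\,\Delta\Sigma_{pp}(\omega)$, and refines by bisection to
$10^{-8}$ Ha. Sign changes across a bare pole (where $|f|$ stays large)
are discarded; crossings with spectral weight outside $(0,1]$ are
reported but never selected. Among the valid crossings the solver
selects the **largest-$Z$** root — the principal quasiparticle peak.
The "highest zero" rule of the graphical method disambiguates the choice
*among states* (the HOMO among occupied levels), not among multiple
crossings of one state; the energetically highest root is also reported
so the selection is auditable. `compute_ip()` scans the four highest
occupied states by default, which cures cases where the mean-field
ordering differs from the quasiparticle ordering.

Numerical choices: broadening $\eta = 10^{-3}$ Ha attached with the
correct sign per pole side (only the real part enters the quasiparticle
equation); the pole-skipping warning fires when the grid step exceeds
$2\eta$, which keeps the documented defaults quiet; spectral functions
add $\eta$ to $|\mathrm{Im}\,\Sigma|$ so every peak is a normalized
Lorentzian of width $\geq \eta$.

## Exact references and the synthetic generator

`fci_ground_state()` performs dense full configuration interaction in a
fixed $S_z$ sector using Slater–Condon rules over ordered spin-orbital
determinants, and `fci_ip()` takes the $N-1$ vs $N$ total-energy
difference — the same definition used by coupled-cluster reference sets.
Dense diagonalization only is provided, with a hard cap at determinant
dimension 4000: every system in the package's scope (model dimers and
random Hamiltonians up to about six orbitals) stays orders of magnitude
below the cap, so an iterative path would be dead code here.

`build_random_hamiltonian()` generates the desk-scale stand-ins for real
molecules: a well-spread one-electron spectrum (level spacing of order 1
Ha over $[-2, 2]$ plus a small random symmetric perturbation) and an ERI
tensor assembled as $\sum_m L^{(m)} \otimes L^{(m)}$ from
$n(n+1)/2$ random symmetric factors, which guarantees positive
semidefiniteness, full 8-fold symmetry, and full Cholesky rank. The
default `interaction_scale = 0.2` Ha keeps correlation perturbative
(self-energies a few percent of the gaps), emulating the weakly to
moderately correlated regime where single-reference perturbation theory
is meaningful. What the generator does **not** emulate: realistic
Coulomb decay and cusp structure, point-group symmetry, basis-set
incompleteness, and near-degenerate (strongly correlated) regimes —
conclusions about those features cannot be drawn from passing tests on
these fixtures.

The Hubbard dimer (hopping $t$, on-site $U$) is the exactly solvable
anchor: its ground state $U/2 - \sqrt{(U/2)^2 + 4t^2}$, its cation
energy $-t$, and hand-contractable integrals pin many conventions
(e.g. $\Sigma^x_{\rm HOMO} = -U/2$, verified against the Fock-matrix
decomposition $\epsilon_p = h_{pp} + v^H_{pp} + \Sigma^x_{pp}$).

## Resolution of the identity

`cholesky_eri()` provides a pivoted Cholesky factorization of the
$(pq) \times (rs)$ ERI matrix with a guaranteed maximum reconstruction
error, playing the role that fitted auxiliary bases play in
Gaussian-orbital production codes but with a controllable bound. The
test suite checks that screened-interaction residues and self-energies
built from truncated factors track the exact ones to ten times the
achieved reconstruction bound.

## Problem sizes and determinism

All shipped calculations are desk-scale by design: dense linear algebra
on 2–6 orbital systems, where every quantity can be cross-checked
against literal spin-orbital nested-loop sums (`sos_selfenergy()`) and
exact diagonalization. The full test suite runs in a few seconds on one
CPU. Every constructor is pure — identical inputs give bitwise-identical
outputs — and the only randomness anywhere is the explicit seed of the
fixture generator, so complete pipelines (SCF → screening → self-energy
→ quasiparticle scan) are reproducible bit for bit.

## Benchmark bookkeeping

`mae()` computes the mean absolute HOMO-energy error against a reference
set (signed errors are method-minus-reference HOMO energies, i.e.
negative IP differences); `box_stats()` reports median and quartiles by
linear interpolation between order statistics (quantile type 7 — the
common box-plot convention; no universal convention exists, so the
choice is recorded in every result), whiskers at the most extreme points
within 1.5 IQR of the box, and everything beyond as named outliers.
Reference sets are JSON with a fixed three-field schema; unknown extra
fields are accepted with a warning so that future schema revisions
remain readable.

## Known limitations

* Closed-shell (restricted) references only; open-shell inputs are
  rejected, not spin-averaged.
* No third-order (PT3) self-energy and no outer-valence rescaling: those
  working equations span pages in the original literature and their
  double-pole structure is exactly the pathology the slope scanner
  (`selfenergy_slope_scan()`) exists to detect.
* The hybrid response kernel is exchange-scaled TDHF only; semilocal
  kernels would need integration grids that model Hamiltonians do not
  define. DFT quantities themselves are never computed — hybrid starting
  points are imported as data.
* No self-consistency in $G$ or $W$; the one-shot philosophy is the
  point, with improved starting points entering through the import
  adapter.
* The SCF uses DIIS without stability analysis; on strongly correlated
  model parameters it can fail to converge, and the error says so rather
  than silently accepting a stationary point.
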