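---
title: "Modal-backflow neural quantum states for anharmonic vibrations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modal-backflow neural quantum states for anharmonic vibrations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibnqs)
```

## The problem

Molecular vibrations beyond the harmonic approximation are governed by the
Watson Hamiltonian in dimensionless normal coordinates,

$$
\hat H = \tfrac12\sum_i w_i(\hat p_i^2 + \hat q_i^2)
 + \tfrac16\sum_{ijk}\Phi^{(3)}_{ijk}\hat q_i\hat q_j\hat q_k
 + \tfrac1{24}\sum_{ijkl}\Phi^{(4)}_{ijkl}\hat q_i\hat q_j\hat q_k\hat q_l
 + \cdots
 + \sum_{ijkl}\sum_\tau B^\tau \xi^\tau_{ij}\xi^\tau_{kl}
   \sqrt{\tfrac{w_j w_l}{w_i w_k}}\,\hat q_i\hat p_j\hat q_k\hat p_l ,
$$

where $w_i$ are harmonic frequencies (cm$^{-1}$), $\Phi^{(\nu)}$ are *reduced*
force constants (raw PES derivatives divided by
$\sqrt{w_{i_1}\cdots w_{i_\nu}}$), and the last term is the Coriolis
rotational coupling. Substituting
$\hat q = (b^\dagger + b)/\sqrt2$, $\hat p = (b^\dagger - b)/\sqrt2$ yields a
second-quantized operator on the bosonic Fock space of the $L$ modes. A
cutoff $N_{\max}$ per mode ($N_{\text{modal}} = N_{\max}+1$ basis states)
makes the space finite but exponentially large,
$(N_{\text{modal}})^L$ — hence variational ansaetze.

This package solves for the low-lying eigenstates of such operators with a
**modal-backflow (MBF) neural quantum state**: the coefficients of a
modal-product (Hartree-product) state are made configuration-dependent
through a small neural network, which injects mode-mode correlation without
ever leaving a product *form*. All amplitudes are real, matching the real
symmetric Hamiltonian and its real low-lying eigenvectors.

## Operator representation and numerical choices

Every Hamiltonian term factorizes over modes, so the operator is stored as a
term table: a scalar coefficient and one small $N_{\text{modal}}\times
N_{\text{modal}}$ matrix per involved mode (powers of the truncated
$X = b^\dagger + b$, products of $X$ and $P = b^\dagger - b$ for Coriolis
strings). Three conventions matter:

* **Truncation.** Each ladder factor is applied sequentially *inside* the
  truncated space (creating on top of $N_{\max}$ annihilates the state), so
  $(b^\dagger + b)^k$ is the $k$-th power of the truncated $X$, not the
  truncation of the untruncated power. This matches an operator-by-operator
  application and is exactly what the brute-force ladder-string oracle in the
  test suite implements independently.
* **Hermitization.** Mixed $X/P$ strings on a repeated mode can lose exact
  symmetry at the occupation boundary after sequential truncation; since the
  untruncated operator is Hermitian, the operator is defined as the symmetric
  part $\tfrac12(A + A^\top)$ of the assembled matrix. Without Coriolis terms
  the assembly is already symmetric and the step is a no-op.
* **Orders 5 and 6** use the prefactor $1/(\nu!\,2^{\nu/2})$, the evident
  continuation of the cubic $1/(12\sqrt2)$ and quartic $1/96$ factors.

All energies and coefficients are carried in cm$^{-1}$. The single unit
constant (`CM1_TO_HARTREE`, $4.556335\times10^{-6}$) is used only by the
random sampler, which draws raw derivatives in atomic units.

## The MBF ansatz

A modal product state has amplitude
$\Psi_{\mathrm{MP}}(\mathbf n) = \prod_i \phi_{i,\,n_i+1}$ for a fixed
$L\times N_{\text{modal}}$ modal matrix $\phi^{(0)}$. The MBF state feeds the
raw occupation vector through a two-layer tanh network,

$$
\mathbf h = \tanh(W^{(0)}\mathbf n + \mathbf b^{(0)}),\qquad
\mathbf o = \tanh(W^{(1)}\mathbf h + \mathbf b^{(1)}),
$$

reshapes $\mathbf o$ into an $L\times N_{\text{modal}}$ correction
$\delta(\mathbf n)$, and evaluates
$\Psi(\mathbf n) = \prod_i \big[\phi^{(0)} + \delta(\mathbf n)\big]_{i,\,n_i+1}$.
The hidden width is set by the density $\alpha = N_{\mathrm{hidden}}/L$. With
all weights zero the ansatz is exactly the modal product defined by
$\phi^{(0)}$ — which is how VSCF lives inside the same code path. The
fixed part $\phi^{(0)}$ is frozen during MBF training and trainable only in
VSCF mode; log-derivatives for every block are exact chain-rule expressions
(validated against central finite differences to $10^{-5}$ relative).

The baseline for comparison is a plain scalar-head network,
$\Psi(\mathbf n) = \tanh(W^{(1)}\mathbf h + b^{(1)})$, identical except that
it outputs the amplitude directly instead of modal corrections.

## Selected-configuration evaluation

Instead of Markov-chain Monte Carlo, expectation values are restricted to a
set $W$ of configurations with the largest amplitudes:

$$
\langle \hat H\rangle_W = \sum_{\mathbf n\in W} P_{\Psi_W}(\mathbf n)\,
E_{\mathrm{loc}}(\mathbf n),\qquad
E_{\mathrm{loc}}(\mathbf n) = \sum_{\mathbf n'}
\frac{\langle \mathbf n|\hat H|\mathbf n'\rangle\,\Psi(\mathbf n')}{\Psi(\mathbf n)},
$$

with $P_{\Psi_W}$ normalized over $W$ only (the only self-consistent reading
of the restricted sum) and the local energy running over the *complete*
connected set. Each iteration (i) extends $W$ by at most $K\,N_s$ candidates
sampled uniformly without replacement from the sorted, deduplicated union of
Hamiltonian connections of the members, (ii) keeps the $N_s$ candidates of
largest $|\Psi|$ (ties broken in lexicographic configuration order), and
(iii) takes a CoRe step along the gradient estimator
$F_m = 2\sum_{\mathbf n\in W} P(\mathbf n)\,D_m(\mathbf n)\,
(E_{\mathrm{loc}}(\mathbf n) - \langle\hat H\rangle_W)$ with
$D_m = \partial_m \log\Psi$. On the full space this estimator is the exact
derivative of the Rayleigh quotient (tested); on truncated $W$ it is the
standard selected-space estimator. Configurations with
$|\Psi| \le 10^{-12}\max_W|\Psi|$ are excluded from the probability
normalization and the gradient to avoid $1/\Psi$ blow-ups.

On enumerable spaces the loop uses an equivalent fast path — one batched
amplitude evaluation over the basis plus one sparse matrix-vector product per
iteration; the generic per-configuration path (with memoized connection
lists) serves larger mode counts and gives bit-identical trajectories on a
shared RNG stream.

## Optimizer

The CoRe update is an Adam-style step with a Gaussian-relaxing momentum
coefficient
$\beta_1(t) = \beta_1^b + (\beta_1^a-\beta_1^b)\exp[-((t-1)/\beta_1^c)^2]$,
bias-corrected first/second moments, and defaults
$\eta_0 = 0.05,\ \beta_1^a = 0.9,\ \beta_1^b = 0.5,\ \beta_1^c = 100,
\ \beta_2 = 0.99,\ \epsilon = 10^{-8}$ ($\epsilon$ is our choice; it is the
conventional magnitude). The learning rate decays exponentially,
$\eta(t) = \eta_0\,r^{t/T}$: the source text prints the exponent with the
opposite sign, which with $r = 0.1$ would *grow* tenfold over a run, while
calling $r$ a decay rate and the schedule an exponential decay — we follow
the stated intent, so $\eta(T) = r\,\eta_0$.

## VSCF pretraining and excited states

VSCF is the optimal modal product; because a zero-weight MBF *is* a modal
product, the mean field is obtained by running the identical
selected-configuration loop with only $\phi^{(0)}$ trainable, initialized
one-hot at a harmonic seed configuration plus $N(0, 0.01^2)$ exploration
noise (without the noise, amplitudes outside the seed vanish identically and
no gradient flows). The converged, row-normalized modal matrix becomes the
fixed part of the MBF ansatz. Defaults: 300 VSCF iterations at the first
scheduled $N_s$. When pretraining is disabled the modal matrix is instead a
random row-normalized Gaussian draw — a genuinely uninformed start, which is
what makes the pretraining comparison meaningful.

Excited states are solved one by one as ground states of penalty-shifted
operators $\hat H + z\sum_{j<n} |\Psi_j\rangle\langle\Psi_j| -
\mathrm{ZPE}$, with previously converged states entering through their stored
supports (overlaps are evaluated on the prior state's support only — states
are never known elsewhere). The level-specific shift is estimated by a VSCF
run on the penalized operator seeded at the $n$-th lowest harmonic
configuration; its variational energy $z_n$ upper-bounds the target
transition, and the production run uses $1.1\,z_n$ (10% headroom for VSCF
bias; configurable). The initial estimate $z'$ defaults to
$10^4$ cm$^{-1}$ — comfortably above any low-lying transition of frequencies
in the 1500–3000 cm$^{-1}$ range; $z'$ only enters the estimate, so a
generous value costs nothing. Residual overlaps above $10^{-2}$ and
out-of-order energies are flagged on the returned records rather than
silently accepted. Convergence is by fixed step budget, as in the reference
protocol; the per-iteration log supports post-hoc checks.

## The synthetic benchmark world

The sampler reproduces the benchmark distributions used to validate the
method: frequencies uniform on $[1500, 3000]$ cm$^{-1}$; raw cubic/quartic
derivative magnitudes $|\kappa^{(\nu)}| \sim N(\lambda_\nu, \lambda_\nu/5)$
in atomic units with $\lambda_\nu = \text{base} \cdot \bar w^{\nu/2}$, where
$\bar w$ is the 2250 cm$^{-1}$ interval midpoint in a.u. and base is 50, 150
or 500 cm$^{-1}$ (in a.u.) for weak, moderate, strong anharmonicity; decay
factors 1 / 0.1 / 0.01 for fully-, semi-, off-diagonal index tuples; quartic
constants kept positive (a bound potential). Two gaps the source leaves open
are fixed once here: magnitudes are clamped at zero rather than redrawn (the
event has probability $\sim 3\times10^{-7}$, and clamping preserves the
draw-count determinism), and each unique cubic tuple receives an independent
random sign, since only magnitudes are specified and systematically positive
cubics would tilt every well the same way. A harmonic-frequency sanity check:
with these scales a fully diagonal reduced cubic constant is of order
"base" cm$^{-1}$ itself, i.e. $\Phi^{(3)}/w \approx 0.02$–$0.2$ across the
regimes.

What a green synthetic test does **not** establish: the sampled fields have
only cubic/quartic terms, no Coriolis coupling, and 4 modes — real sextic
force fields with Coriolis constants exercise longer operator strings and
denser connectivity. The I/O and operator layers are therefore additionally
tested on a synthetic 3-mode sextic+Coriolis fixture, and ab initio runs
require transcribing published force fields into the JSON schema (see
`read_force_field`); no such external data ships with the package.

## Known limitations

* The real tanh-head FNN baseline trains reliably at $\alpha = 1$ (where it
  is, as expected, orders of magnitude weaker than MBF) but becomes unstable
  at $\alpha = 4$ under the default optimizer settings: its log-derivatives
  carry $1/\Psi$ factors that explode near amplitude nodes of a sign-changing
  scalar head. Mainstream NQS implementations avoid this by parametrizing a
  complex log-amplitude, which lies outside this package's real-amplitude
  contract; a positive exp-head variant was tested and stalls at the
  positive-state variational floor instead. The corresponding acceptance
  expectation is left failing by design rather than papered over.
* The selected-space estimator is not strictly variational; energies can
  transiently dip below the exact ground state early in training when $W$
  misses dominant weight. Converged runs in the test suite respect the bound
  to $10^{-6}$ cm$^{-1}$.
* `to_matrix`/`exact_spectrum` enumerate the full basis and are guarded at
  $2\times10^6$ states; beyond that only the variational pipeline applies.

## A worked example

```{r example, eval = FALSE}
ff <- sample_force_field(4, "moderate", "moderate", seed = 7)
H <- watson_operator(ff, nmax = 6)
conn <- make_connector(H)
cfg <- training_config(nmax = 6, ns_schedule = list(c(128L, 1000L)),
                       alpha = 1, decay = 0.1, seed = 3)
states <- run_excited_ladder(conn, 4, cfg)
exact <- exact_spectrum(conn, k = 4)
data.frame(level = 0:3,
           mbf = sapply(states, `[[`, "energy"),
           exact = exact$values)
```

Running this prints MBF energies within a few tenths of cm$^{-1}$ of the
exact values (the README shows actual output); the per-iteration TSV log
(`run$log`) records energy, selected-space and pool sizes, gradient norm and
learning rate for every step.
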