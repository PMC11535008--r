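---
title: "Matched asymptotics for diffusion among small compartments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched asymptotics for diffusion among small compartments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how `singtrap` computes what it computes: the model
assumptions, the parameter conventions, the numerical machinery and its
tolerances, the design decisions that were genuinely open, and the known
limitations.  Everything quantitative stated here is recomputed by the test
suite or by `scripts/acceptance.R`; nothing is asserted from memory.

## The singularly perturbed diffusion problem

The bulk concentration `u(x, t)` obeys

$$\partial_t u = D\nabla^2 u - \gamma_0 u + \mathcal I_0,
\qquad x \in \Omega\setminus\mathcal U,$$

with a reflecting outer boundary, and a Robin exchange condition
$D\nabla u\cdot n_j = \kappa_j(u - c_j)$ on each small interior compartment
of radius $\epsilon\ell_j$.  The three compartment models differ only in
what fixes $c_j$: a constant (model I), the interior concentration across a
semi-permeable interface (model II), or the exchanged species of a
well-mixed reaction network (model III).

Assumptions inherited by every solver:

* $\max_j \ell_j = 1$ — this *defines* $\epsilon$ and is enforced by
  `compartment_configuration()`;
* centres are mutually and boundary separated by at least
  `separation` (default $10\epsilon$); violations are errors, not warnings,
  because the matched expansions silently lose accuracy otherwise;
* parameters are the *post-rescaling*, $O(1)$ values: the reactivity enters
  the unscaled problem as $\kappa_j/\epsilon$, the model-II interior source
  and degradation as $\bar I_j/\epsilon^2$, $\bar\gamma_j/\epsilon^2$.
  This convention makes every matching formula literal.  (A uniform bulk
  source $\mathcal I_0>0$ with $\gamma_0>0$ is removed by the shift
  $u\to u-\mathcal I_0/\gamma_0$ and restored on output; with
  $\gamma_0=0$ it admits no steady state and is refused.)

## Green's functions

All solvers consume a `greens_provider`, which must satisfy (and is tested
against) four contracts: symmetry; the free-space singular decomposition
($-\log|x-x'|/2\pi D$ in 2D, $1/4\pi D|x-x'|$ in 3D); the normalisations
$\int_\Omega G = 1/(\gamma_0+s)$ and $\int_\Omega G_0 = 0$; and agreement
with a direct finite-difference solve of the defining PDE.

Concrete representations, chosen for exponential convergence at desk scale:

* **disk / sphere** ($\gamma_0+s>0$): screened free-space kernel plus an
  addition-theorem correction series whose coefficients
  $-K_n'(\beta)/I_n'(\beta)$ (resp. the spherical analogues) cancel the
  boundary flux.  The correction decays like $(r r')^n$, so it is truncated
  when the term bound drops below `tol` (default `1e-12`) of the running
  sum.  Coefficients are assembled in log space because $K_n$ overflows and
  $I_n$ underflows individually at large order while their products stay
  $O(1)$.
* **rectangle / box** ($\gamma_0+s>0$): method of images.  In 2D the
  $K_0$ kernel is summed over reflection images within a radius where the
  kernel falls below `tol`.  In 3D the same sum is Ewald-split (real-space
  `erfc`-screened part plus a separable cosine reciprocal sum), which keeps
  the image count bounded for arbitrarily small $\beta=\sqrt{(\gamma_0+s)/D}$.
* **pseudo-Green's functions** ($\gamma_0=0$): closed forms for the unit
  disk and unit ball; for the rectangle, a cosine-mode expansion across the
  short side whose oscillatory part is resummed exactly into image
  logarithms via $\sum_n q^n\cos n\phi/n = -\tfrac12\log(1-2q\cos\phi+q^2)$;
  for the box, Ewald summation of the zero-mean periodic Coulomb potential
  on the doubled torus.  The zero-integral condition is satisfied by
  construction in every case and re-verified by quadrature.

The Laplace-variable derivative $H=\partial_s G|_{s=0}$ is differentiated
term-by-term for the image representations and obtained by
Richardson-extrapolated central differences (step $0.01\gamma_0$) for the
disk/sphere series; the two routes agree to better than `1e-6` in tests.

Regular-part evaluation within `boundary_margin` (default 0.02) of the
outer boundary is refused: the image singularities approach coincidence
there and the asymptotics assume compartments $O(1)$ from the wall anyway.

**Normalisation quadrature.**  The identity checks integrate the Green's
function with the singularity handled in closed form: polar rules centred
on the source (with angular splits at rectangle corners), an axisymmetric
spherical rule in the ball, and a tensor rule plus the closed-form box
Newtonian potential in the box.  These choices make the checks accurate to
roughly `1e-8` relative, an order of magnitude tighter than the `1e-6`
contract.

## Steady states

2D solves the matching system $(I+\nu M)a=-c_0$ directly.  The
zero-degradation branch determines $(a, u_\infty)$ from the bordered
$(N+1)$-dimensional system with the solvability constraint $\sum_j A_j=0$
appended; this is better conditioned than eliminating $u_\infty$ first, and
the two constructions are verified to agree to `1e-10`
(`solve_model1_2d_twostep()` retains the elimination route purely as a
cross-check).  3D defaults to the two-term expansion (the $-\epsilon\chi_k$
correction); one-term is available for order studies.  The zero-degradation
3D far-field constant is the solution of a scalar linear equation because
$\chi$ depends affinely on $u_\infty$.

`evaluate_field()` uses the inner representation within
$5\epsilon\ell_j$ of a centre (configurable).  The factor 5 keeps the
switch radius well inside the matching overlap for $\epsilon \le 0.05$
while staying a few compartment radii out; tests confirm the inner/outer
mismatch at the switch circle shrinks with $\epsilon$.  Interior queries
return the model-II radial profile where one exists and `NA` for
models I/III, whose interiors the theory does not model.

Model II enters the 2D matching through the effective parameters
$c_{j,0}=\bar I_j/\bar\gamma_j$ and
$\Psi_j = D/(\kappa_j\ell_j) + D/(\bar D_j F(\bar\beta_j\ell_j))$,
$F(x)=xI_1(x)/I_0(x)$.  Note the fast-interior-diffusion limit
$\bar D_j\to\infty$ at fixed $\bar\gamma_j$ leaves the residual
$2D/(\bar\gamma_j\ell_j^2)$ in $\Psi_j$; recovering model I requires
$\bar\gamma_j\ell_j^2 \gg D$ as well, which is why no test asserts the bare
limit.  Dirichlet compartments are represented exactly
($\kappa_j=\infty \Rightarrow \Psi_j=0$, $\Lambda_j=\ell_j$) rather than by
a large number.

Model III balances the extensive kinetics $\hat f_a = |U_j| f_a$ against
the exchange flux of the exchanged species, which the package fixes to
species index 1 (the first row of the state).  The sign convention is
physical: positive kinetics production balances positive outflux, and the
3D exchange is written in the form $4\pi D\Lambda_j(w_{j,0}^*-u_\infty-
\epsilon\chi_j)$, which is exact in $\kappa$ including the Dirichlet limit.
The multistart uses the kinetics' own well-mixed fixed points plus a seeded
random sample; converged roots are deduplicated at relative distance
`1e-6`, and a failure of every start returns an empty list with a message
rather than an error, so scans can proceed past infeasible parameters.

## Ripening

The radius ODEs conserve $\sum\ell^2$ (2D) resp. $\sum\ell^3$ (3D)
*algebraically*, so the integrator tolerance (`rtol 1e-10`) is the only
drift source.  The equations are singular as $\ell_j\to 0$; droplets are
removed when they cross `extinction_threshold` (default $10^{-3}$ of the
initial mean radius) using the integrator's root-finding, and the removed
mass (at most threshold³) is reported as `leaked_mass` rather than silently
redistributed — the leading-order theory does not specify redistribution.
A caveat worth stating: between extinction events the alive-set mean radius
*decreases* (the shrinking droplet dominates the average); the critical
radius grows through the extinction jumps, which is what the tests assert.
An optional `greens-corrected` 2D mode recomputes the far-field constant
from the full non-perturbative solve at every step, restoring the
configuration-dependent corrections to the mean-field rule at the cost of a
linear solve per right-hand side.

## Accumulation times

Defined for $\gamma_0>0$ only; at $\gamma_0=0$ the Laplace-space Green's
function has a pole at $s=0$ and the machinery is refused with an explicit
error.  The sign convention is an explicit `direction` argument: `drain`
(bulk initial data, compartments are sinks, $T=+\mathrm d_s[s\tilde u]/u$)
and `fill` (zero initial data, compartment sources,
$T=-\mathrm d_s[s\tilde u]/u$); both reduce to the textbook 1D closed form,
and no silent sign flips occur.  The full 2D expression uses the matrix
derivative $\Theta=(I+\nu M)^{-1}M'(0)(I+\nu M)^{-1}$ with $M'(0)$
assembled from $H$; the leading-order variant ($\propto 1/\nu$) is always
returned alongside for comparison.  $\Gamma_0(x,s)=\int G\,u_0$ is computed
by a polar Gauss rule over the (compactly supported, smooth) bump; supports
overlapping a compartment are refused.

## Quorum-sensing reduction and Kuramoto analogue

With $D=D_0/\nu$ the model-III system reduces to ODEs for the bulk mean and
the cell states, coupled through the quasi-static matching solve
$[1+D_0/(\kappa_j\ell_j)]A_j + 2\pi D_0\nu\sum_k\mathcal G_{0,jk}A_k
= \bar u - w_{j,0}$, re-solved at every right-hand-side evaluation
(correctness over speed at these sizes).  The pseudo-Green's matrix is
evaluated with diffusivity $D_0$, which is what makes
$W=(I+\nu Q)^{-1}\to I$ as $D_0\to\infty$; the identical-cell $Q$ carries
the $2\pi$ factor required by the matching equation (some compact
statements of $Q$ absorb it into the Green's matrix).  Cells with
$\kappa_j=0$ are sealed and drop out of the coupling solve exactly.  In the
well-mixed limit the reduction reproduces the non-spatial model with
$\hat\kappa = 2\pi N\kappa\ell/|\mathcal U|$ up to an $O(\epsilon^2)$
volume-fraction difference ($|\Omega|$ versus $|\Omega|-|\mathcal U|$ in
the bulk balance), which bounds how far the $1/D_0$ convergence can be
followed; the acceptance run uses $\epsilon=0.005$, where the $1/D_0$ decay
is cleanly resolved over $D_0\in\{10,10^2,10^3\}$.

The Sel'kov form $f_0=\alpha_s w_1 + w_1w_0^2 - w_0$,
$f_1=\epsilon_s(\mu_s-\alpha_s w_1 - w_1w_0^2)$ ships as the worked
kinetics (isolated fixed point $w_0^*=\mu_s$,
$w_1^*=\mu_s/(\alpha_s+\mu_s^2)$, closed-form Hopf threshold in
$\epsilon_s$); any mass-action law can be substituted through
`make_kinetics()`.  The Hopf scanner locates sign changes of the leading
complex eigenvalue pair of the reduced Jacobian at the fixed point and
refines them by bisection; tests compare the crossing against the onset of
sustained oscillation in direct simulation at the scan's grid resolution.

The Kuramoto variant couples phases to a complex medium amplitude, with an
optional matrix $W$ inherited from the reduction; $W=I$ recovers the
classical medium-coupled model, verified against an independent RK4
integrator to `1e-10`.  All random draws (frequencies, initial phases) are
seeded in the system constructor.

## Switching volume transmission

Varicosities release neurotransmitter at flux density $J_j$ while the
(synchronously firing) source neurons are active and absorb it
($u=0$) while quiescent; switching is a two-state Markov chain with rates
$\beta$ (quiescent to firing) and $\alpha$ (back).  The stationary
conditional means are built from two nested model-I solves — the
zero-degradation Dirichlet problem for the sum field, then a
rate-$(\alpha+\beta)$ problem for the firing-conditioned field — and the
unknown interface constants $\phi_j$ are closed by the firing-state flux
condition, with the conditional flux weighted by the stationary firing
occupancy $\beta/(\alpha+\beta)$ (the expectation of a state-indicator
times a pathwise flux).  Two implementation points deserve note:

* the convolution of the rate-$s$ Green's function with the sum field has
  a closed resolvent form,
  $\int G_s(x,x')\bar u(x')dx' = [\bar u(x) + 2\pi D\nu\sum_k A_k
  G_s(x,x_k)]/s$ after using $\sum_k A_k=0$, so the nested solve involves
  no quadrature at all and its flux residuals sit at machine precision;
* the far-field constant of the Dirichlet step is carried as an unknown
  inside the same linear closure rather than fixed a priori.

The Monte-Carlo oracle simulates the switching PDE on a cell-centred grid:
Shortley–Weller Dirichlet in the quiescent state, and in the firing state
the release flux distributed over the interface-cut cells with the *total*
influx per varicosity exact ($2\pi\epsilon\ell_j J_j$) — a first-order
boundary treatment whose conserved total is what the far field sees at
leading order.  Backward-Euler stepping with both operators factorised once
is unconditionally stable, so no step-size (CFL) restriction applies;
exponential holding times are rounded to whole steps (bias
$\ll$ Monte-Carlo error at `dt = 0.02` and $O(1)$ rates).

## Validation harness and the synthetic configuration generator

`generate_configuration()` rejection-samples well-separated centres with
seeded, reproducible output; radius heterogeneity is rescaled so
$\max\ell_j=1$ always holds.  It emulates exactly the geometric assumptions
of the theory — small, well-separated, circular compartments in a clean
geometry — and deliberately nothing else: real membranes and cytoplasm have
irregular compartment shapes, crowding, advection and finite-compartment
effects that are out of scope here, so a passing test certifies the
asymptotic machinery, not any particular biological dataset.

Oracles are paired with every solver: the concentric annulus/shell closed
forms (which also certify the finite-κ Robin discretisation of the radial
FD scheme, verified second-order by Richardson triples); a polar
finite-volume solve of the Green's PDE with a mollified source (relative
agreement `1e-3` away from the source); the embedded-boundary rectangle
solver (Shortley–Weller Dirichlet, globally second order) for
multi-compartment steady states and Crank–Nicolson relaxation; the
Monte-Carlo switching oracle; fixed-step RK4 for ripening extinction times;
and the eigenfunction sum for the 1D accumulation time.  Non-spherical
traps enter through electrostatic capacitances (sphere, hemisphere,
prolate/oblate spheroids; the oblate formula uses the principal
$\cos^{-1}(b/a)$ branch, the standard electrostatics result).

## Problem sizes

The shipped tests run 1–5 compartments at $\epsilon\in[0.005, 0.05]$,
finite-difference grids up to $400\times 400$, 200 Monte-Carlo replicates,
and integration horizons of 10–400 time units — sizes chosen so the whole
validation cycle completes on a laptop in minutes while every comparison
still has an order of magnitude of headroom against its tolerance.

## Known limitations

* Geometry is restricted to the four shipped domains; there is no
  general-purpose boundary-element Green's function.
* Time dependence is handled only through Laplace-space asymptotics
  (accumulation times) and the quasi-static reductions; the package does
  not integrate the full PDE except as an oracle.
* The switching model assumes synchronous firing (a single two-state
  chain); independent varicosity switching would need the $2^N$ chain and
  second-moment equations, which are not implemented.
* Zero-degradation accumulation times are out of scope (Laplace-space pole).
* Linear stability of the full PDE–ODE model III system is not computed;
  the Hopf scanner works on the reduced ODEs.
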