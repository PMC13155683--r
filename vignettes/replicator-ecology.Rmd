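---
title: "Models and methods: sub-exponential replicator communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: sub-exponential replicator communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subrep)
```

## The mechanistic model and its assumptions

`subrep` models communities of template-directed replicators whose single
strands reversibly pair into replication-inert duplexes. For species $i$,
three reactions occur: association of two single strands into a duplex
(rate constant $a_i$), duplex dissociation (rate $b_i$), and templated
copying from the shared resource $R$ (rate $c_i$), after which the fresh
copy stays bound to its template. The model deliberately simplifies in
three ways: replication yields an exact copy (no complement strands), only
strands of the same species pair (no cross-hybridization, so the
self-inhibition is strictly species-specific), and replication consumes a
single resource. These are the assumptions under which self-inhibition
translates one-to-one into one regulating factor per species, the
mechanism that permits multispecies coexistence.

In the **mass-regulated** setting the resource concentration $r$ is held
constant and strands wash out at the *normalized production*
$\phi = (r/m)\sum_j c_j x_j$, so the total strand concentration
$\mu = \sum_i (x_i + 2 y_i)$ obeys the logistic identity
$d\mu/dt = \phi\,(m - \mu)$ and equilibrates at the target concentration
$m$ exactly. The package also implements the **chemostat** variant (fixed
dilution $\phi$, dynamic resource with inflow $\rho$; at equilibrium
$\rho - \hat r = \hat\mu$) and the **phenomenological** power-law model
$dz_i/dt = k_i z_i^{p_i} - \phi z_i$, both used for framework contrasts.

Once a species' single/double-strand ratio settles, its growth rate is

$$\Lambda_i(x_i) = \tfrac12\Big[-(2a_i x_i + b_i + c_i r) +
\sqrt{(2a_i x_i + b_i + c_i r)^2 + 4 b_i c_i r}\Big],$$

decreasing in $x_i$ for $a_i > 0$ (S-species). Its value at zero density,
$\lambda_i = \Lambda_i(0)$, is the intrinsic growth rate; it is independent
of $a_i$, and a species with $a_i = 0$ (E-species) grows at $\lambda_i$
regardless of density. For a single S-species at large $m$, the equilibrium
production $\hat\phi\, m$ grows like $\sqrt m$ — the defining square-root
law of parabolic replication. (One could misread the model as predicting
production proportional to $m$; the quadratic-in-time growth of a free
parabolic replicator forces the $\sqrt m$ scaling, and the package's tests
verify $\hat\phi(4m)/\hat\phi(m) \to 1/2$ numerically.)

## Analytic equilibria

Equilibrium hinges on two exact ratio identities, for S- and E-species
alike: $\hat x_i/\hat\mu_i = \hat\phi/(r c_i)$ and
$\hat y_i/\hat x_i = (c_i r - \hat\phi)/(2\hat\phi)$. Inverting
$\Lambda_i$ gives the closed-form single-strand concentration at which a
species' growth matches a prescribed production,
$\hat x_i(\phi) = [b_i c_i r - (b_i + c_i r)\phi - \phi^2]/(2 a_i \phi)$,
and hence its equilibrium mass $\hat\mu_i(\phi) = r c_i \hat x_i/\phi$ — a
continuous function of $\phi$, decreasing from $+\infty$ at $\phi \to 0^+$
to $0$ at $\phi = \lambda_i$ and zero beyond.

*Pure-S communities.* $\sum_i \hat\mu_i(\phi)$ inherits these properties,
so $\sum_i \hat\mu_i(\phi) = m$ has exactly one root on
$(0, \max_i\lambda_i)$ for every $m > 0$. `equilibrium_state()` finds it
with a bracketed scalar root-finder (`stats::uniroot`, relative tolerance
$10^{-14}$); survivors are the species with $\lambda_i > \hat\phi$.
Species whose $\lambda_i$ lies within a relative band of $10^{-9}$ of
$\hat\phi$ are reported as *marginal* rather than silently classified.

*E-species.* An E-species can only be stationary when $\phi$ equals its own
$\lambda$, so at most one — the one with the largest intrinsic rate
$\lambda_0$ — can persist, pinning $\hat\phi = \lambda_0$ and absorbing the
residual mass $m - \sum_S \hat\mu_i(\lambda_0)$ (tested against an absolute
tolerance of $10^{-12}$). If the residual is non-positive the E-species is
excluded and the pure-S branch applies. Two E-species tied at the maximal
$\lambda$ are rejected as degenerate input: the theory says they cannot
coexist, and no tie-breaking rule exists.

The critical target concentration at which the first extinction occurs as
$m$ shrinks solves $\hat\phi(m^*) = \lambda_{\min}$, which reduces to the
explicit sum $m^* = \sum_{i \neq \arg\min} \hat\mu_i(\lambda_{\min})$
because the exiting species carries no mass at the boundary.

Uniqueness of the interior equilibrium is not proven here; the root
bracketing argument makes the *analytic* equilibrium unique, and the suite
verifies empirically (multiple starting points, random communities) that
the ODE flow converges to it.

## Invasion and assembly

A rare invader grows at $\lambda'$ and washes out at $\hat\phi_{res}$, so
it enters iff $\lambda' > \hat\phi_{res}$ — independent of its association
rate. `invade()` works equilibrium-to-equilibrium (adiabatic assembly),
reporting extinct residents both as species with zero mass in the new
equilibrium and as species whose $\lambda$ falls in the zone of exclusion
$(\hat\phi_{res}, \hat\phi_{new}]$; the two classifications are
cross-checked on every call. A trajectory-based `invade_dynamic()`
(introduction at $x = 10^{-5}$, long integration) is provided for
cross-validation. Because $\hat\phi$ never decreases along an assembly
sequence, a rejected species stays rejected, and `assemble()` returns the
same survivor set and $\hat\phi$ for every introduction order — identical
to solving the full-pool equilibrium at once, which is the default path.

Sensitivity of residents to production changes is quantified as the
response of the equilibrium mass: for fixed $b, c$ the absolute response
$|d\hat\mu_i/d\hat\phi|$ scales exactly as $1/a_i$, so weakly associating
species suffer the largest concentration drops after an invasion, and an
E-species ($a = 0$) cannot re-equilibrate at all at a shifted production.
Note the *relative* drop is $a$-independent (since
$\hat\mu_i \propto 1/a_i$ at fixed $b, c$), which is why the package frames
sensitivity in absolute terms.

## Numerical choices

* **Integrator.** Adaptive BDF (`deSolve::ode(method = "bdf")`) with
  `rtol = 1e-10`, `atol = 1e-12`. The tolerances are tight because
  extinction decisions hinge on concentrations four to six orders of
  magnitude below the community total. The horizon defaults to $10^6$ time
  units, integrated over log-spaced checkpoints.
* **Steady-state detection.** Early stop when
  $\max_i |d\mu_i/dt| / \max(\mu, 10^{-12}) < 10^{-12}$. The threshold
  sits far below the $10^{-6}$ state accuracy the package aims for: near an
  exclusion boundary the slowest mode decays at rate
  $|\lambda_i - \hat\phi|$, and the derivative criterion under-reports the
  remaining distance to equilibrium by exactly that factor. At a looser
  $10^{-10}$ we observed a random community stopping with a near-marginal
  species still $6\times10^{-6}$ away from its equilibrium mass.
* **Negative concentrations.** Values that undershoot zero by less than
  $\sqrt{\texttt{atol}}$ are clipped to zero (an unavoidable by-product of
  finite solver tolerances as species decay); anything more negative
  aborts, signalling solver misconfiguration rather than round-off.
* **Cancellation-free growth rates.** $\Lambda$ and $\lambda$ are evaluated
  as $2bcr/(s + \sqrt{s^2 + 4bcr})$ with $s = 2ax + b + cr$, exact and
  stable when $bcr \ll s^2$.
* **Extinction thresholds.** Long deterministic runs count a species
  extinct below $\mu_i = 10^{-7}$; the fluctuating-environment protocol
  uses its own establishment threshold of $3\times10^{-5}$.
* **Default initial condition.** Where none is supplied: $x_i = 10^{-3}$,
  $y_i = 0$ for every species (resource at $\rho$ for the chemostat),
  configurable. All runs from alternative positive starts converged to the
  same equilibrium in testing.

## Experiments and their defaults

**Parameter sweeps** (`sweep_m`, `sweep_r`, `sweep_grid`) evaluate the
analytic equilibrium per grid cell; defaults are log-spaced,
$m \in 10^{[-2,2]}$ and $r \in 10^{[-1,1.5]}$, 81 points each, matching
the regimes where the model's qualitative transitions happen. Sweep cells
are spot-checked against ODE integration in the test suite.

**Fluctuating environment** (`fluctuating_run`). All species share one
association rate that oscillates slowly — emulating temperature cycles,
since cooler environments mean stronger pairing — while the resource
oscillates ten times faster. Defaults:
$a(t) = 75 + 25\sin(2\pi t/10^4)$, spanning the kinetic grid's 50–100
range with a slow period of $10^4$ time units, and
$\log r(t) = \log(4)\sin(2\pi t/10^3)$, spanning 0.25–4. Every 100 time
units a new species enters at $x = 10^{-5}$ with $b$ and $c$ drawn
uniformly from the kinetic grids ($b \in \{5, 5.25, \ldots, 10\}$,
$c \in \{1, 1.2, \ldots, 5\}$); at each introduction, species below the
establishment threshold $3\times10^{-5}$ are removed. The removal applies
to *all* sub-threshold species by default — a deterministic proxy for
stochastic extinction at low copy number — with `removal = "newest"`
available for the narrower reading in which only the latest entrant is
culled. The run lasts six slow periods: the community assembles from empty
over roughly the first half, and `fluctuation_association()` measures the
diversity–waveform association on the saturated second half (window means
at $a$-extrema, detrended correlation with $a(t)$, and the fast phase
profile against the resource cycle). Expect diversity to rise with the
association rate — higher common $a$ lowers $\hat\phi$ at fixed $m$, just
as a larger $m$ would — and to peak shortly after resource scarcity, with
a lag of a few hundred time units reflecting the finite exclusion
dynamics. These segments integrate at `rtol = 1e-8`: the quantities of
interest are species counts against a $3\times10^{-5}$ threshold, not
$10^{-6}$-accurate concentrations, and the piecewise run re-starts the
solver 600 times.

**Framework comparison** (`model_comparison`). (i) In the phenomenological
model the per-capita growth $k z^{p-1}$ diverges at low density, so a
sub-exponential invader introduced at $z = 10^{-8}$ establishes against an
exponential resident regardless of rate constants; the mechanistic model
gates the same scenario by $\lambda' > \hat\phi_{res}$ and rejects it. (ii)
In the chemostat, sweeping the inflow $\rho$ at fixed dilution raises the
number of coexisting species just as raising $m$ does; the default sweep
($\rho \in \{1,2,4,8,16\}$ at dilution 1) shows the correspondence while
keeping every cell a short integration. Default contrast species: an
exponential resident with $k = 2$ ($p = 1$, matching the reference
E-species' $\lambda_0 = 2$ at $r = 1$) against a sub-exponential invader
with $k = 0.5$, $p = 0.5$; the mechanistic counterpart uses the reference
community with species 3 exponential and an invader with
$\lambda' = 1.217 < 2$.

## What the synthetic communities do and do not show

Test communities are drawn from the kinetic grids
$a \in \{50, 52.5, \ldots, 100\}$, $b \in \{5, 5.25, \ldots, 10\}$,
$c \in \{1, 1.2, \ldots, 5\}$ (the regime where association is the fastest
process and replication the slowest at order-one concentrations), with
environments $m \in [0.1, 10]$, $r \in [0.25, 4]$. Within this regime the
suite verifies the analytic theory against brute-force integration to
$10^{-6}$ relative accuracy. What passing these tests does *not* show:
behavior under cross-hybridization between species, complement-strand
bookkeeping, multi-resource (ligation) chemistry, or demographic noise —
all outside the model class — nor anything about kinetic regimes far from
the grids (e.g. association slower than replication), where the
square-root law's "large concentration" approximation and the numerical
tolerances were not exercised.

## Problem sizes used by the shipped checks

The test suite and acceptance script run communities of at most ten
species: 50 random communities for the oracle-equivalence property, 200
random invasions for production monotonicity, 20 permutations for assembly
order-invariance, 81-point sweep grids, and one six-slow-period
fluctuating run (600 introductions). These sizes give stable, minutes-long
runs while exercising every code path; all scale linearly in community
size and grid length if larger studies are needed.
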