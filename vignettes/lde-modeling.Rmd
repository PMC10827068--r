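---
title: "Logic-based differential equation modeling of signaling networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logic-based differential equation modeling of signaling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldenet)
```

## The model

A network model consists of *species* — genes, proteins or processes, each
carrying a continuous, dimensionless activity $y_i \in [0, y_{max,i}]$ —
and *reactions*, directed activating or inhibiting influences of zero or
more source species on one target. Each species obeys a relaxation
equation:

$$\frac{dy_i}{dt} = \frac{\phi_i(y)\, y_{max,i} - y_i}{\tau_i}$$

where $\phi_i \in [0,1]$ is the total regulatory drive on species $i$ and
$\tau_i$ its time constant. Compared with a Boolean network, the state is
continuous and the dynamics are smooth, so graded and transient responses
can be represented; compared with a mass-action kinetic model, no rate
constants need be measured — the sigmoidal logic is normalized.

**Normalized Hill terms.** An activating influence of source activity $x$
enters through $f_{act}(x) = \beta x^n / (K^n + x^n)$ with the two derived
constants chosen so that $f_{act}(0)=0$, $f_{act}(EC_{50})=\tfrac12$ and
$f_{act}(1)=1$. These three anchors have the closed-form solution

$$\beta = \frac{EC_{50}^{\,n} - 1}{2\,EC_{50}^{\,n} - 1}, \qquad
  K = (\beta - 1)^{1/n},$$

which exists exactly when $0 < EC_{50} < 1$ and $EC_{50}^{\,n} < \tfrac12$
(`validateModel()` reports violations). An inhibiting influence is the
complement $f_{inh}(x) = 1 - f_{act}(x)$: a fully active repressor
silences its target, an absent repressor permits full drive. With the
default parameters $n = 1.4$, $EC_{50} = 0.5$ this gives
$\beta \approx 2.5649$, $K \approx 1.3770$:

```{r}
hillShape(1.4, 0.5)
```

**Combining reactions.** Within one rule, terms combine by AND — the
product of their Hill terms — so `A & !B => E` contributes
$w \cdot f_{act}(y_A)\, f_{inh}(y_B)$. A rule with no sources (`=> A`) is
an *input reaction* modeling a constitutive environmental stimulus; it
contributes its weight $w$ regardless of state. When several reactions
converge on one target they combine by the continuous fuzzy OR
$a \oplus b = a + b - ab$, folded associatively, which is smooth
(integrator-friendly), order-invariant, and reduces to Boolean OR at the
extremes. A species with no incoming reactions has zero drive and decays;
one regulated only by inhibitors receives full drive until a repressor
rises — that is why ISL1 in the cardiac model starts and stays at 1 until
NKX25 appears. OR-as-probabilistic-sum rather than `max` was a design
choice: `max` introduces derivative discontinuities that degrade
adaptive-step integration, and the two agree when one branch dominates.

## Parameters

| parameter | meaning | domain | default |
|---|---|---|---|
| `yinit` | activity at simulation start | $[0, y_{max}]$ | 0 |
| `ymax`  | maximal activity; 0 models a knockout | $\ge 0$ | 1 |
| `tau`   | relaxation time constant (time is unitless, in $\tau$-units) | $> 0$ | 1 |
| `weight` (`w`) | reaction strength; 0 disables | $[0, 1]$ | 1 |
| `n`     | Hill steepness | $> 0$ | 1.4 |
| `ec50`  | half-maximal source activity | $(0,1)$, $EC_{50}^n<\tfrac12$ | 0.5 |

Weights outside $[0,1]$ are rejected: the flux is interpreted as a logic
level, and the defaults keep every flux in $[0,1]$. Activation inputs are
clamped into $[0,1]$ before the sigmoid is applied, which keeps fluxes
interpretable when a species with $y_{max} > 1$ feeds a rule.

## Simulation

`simulateSegment()` integrates with `deSolve`'s adaptive `lsoda` at
relative tolerance $10^{-6}$ and absolute tolerance $10^{-8}$. The
dynamics are smooth, bounded and non-stiff for valid models, so any
conforming adaptive explicit method would do. Staged protocols
(`runProtocol()`) mirror the interactive change-a-weight-then-simulate
workflow: parameter changes are step functions at segment boundaries, each
segment continues from the exact final integrator state of the previous
one (not a grid-interpolated value, so no interpolation error compounds
across many segments), and changes persist until changed again. The
default segment duration of 10 $\tau$-units matches the staged tutorial
runs, which read out at timepoints 10, 20, ...; 101 output points per
segment resolves the fastest default transient ($\tau = 1$) more than
adequately.

```{r}
tc <- runProtocol(exampleNet(), simulationProtocol(list(
  protocolStep(10),                      # all inputs off
  protocolStep(10, weights = c(r1 = 1))  # stimulus A on
)))
round(finalState(tc), 4)
```

`steadyState()` integrates to convergence
($\max_i |dy_i/dt|\,\tau_i < 10^{-6}$, capped at $500 \max_i \tau_i$)
rather than solving the algebraic fixed-point system. Integration follows
the trajectory from the given initial state, which picks the dynamically
relevant branch in multistable networks and cannot converge to an
unstable root; non-convergence (e.g. oscillatory networks) is flagged,
not raised.

## Knockouts and screening

A knockout sets $y_{max} = 0$: the production term vanishes and the
species decays exponentially with its own $\tau$. `knockoutScreen()`
computes a stimulated baseline steady state (by default every input
reaction at $w = 1$ — a defensible "all stimuli present" reference,
configurable via `inputs`), then re-solves with each target knocked out
and reports activity deltas:

```{r}
scr <- knockoutScreen(cardiacDevNet(), targets = "NKX25")
round(screenDeltas(scr), 3)
```

The NKX25 row shows the de-repression of ISL1 (delta $+1$): removing the
repressor leaves the progenitor marker fully active, matching the
experimentally observed ISL1 increase when NKX2-5 is reduced.

## Degenerate inputs and numerical edges

* `ec50^n = 1/2` exactly (e.g. $n = 1$, $EC_{50} = 0.5$) makes the
  normalization singular and is rejected at validation.
* Duplicate reactions with identical rules are permitted and OR-combine
  like any other pair; self-loops are permitted.
* A rule referencing an undeclared species is collected by
  `validateModel()` (with sheet/row coordinates when read from a
  workbook) rather than raised piecemeal.
* `yinit > ymax` is a warning, not an error: the trajectory simply decays
  into range.
* The all-off model has an exactly zero vector field at the origin, so a
  null simulation returns activities that are exactly 0, not merely small.

## The random-network generator

`randomNetwork()` produces property-test models: `S1..Sn` with default
species parameters, rules with 1–3 source terms, inhibition marked with
probability `pInhib`, input reactions with probability `pInput` (at least
one input is always present so the network can be driven), and uniform
weights. It emulates the *structural* variety of curated models —
crosstalk, repression, fan-in — under the default kinetic parameters;
it does not emulate measured kinetics, heterogeneous $\tau$/$EC_{50}$
values, or the modular organization of large published networks. Tests
passing on these models therefore establish the correctness of the
simulation machinery, not the biological adequacy of any particular
parameterization. Isolated species are allowed; they exercise zero-drive
decay.

## Problem sizes used in the test suite

The bundled models have 5 species and 6–7 reactions; property suites use
100 random models of up to ~8 species for right-hand-side equivalence
against a naive oracle, and a dozen 50-$\tau$-unit integrations for
boundedness. These sizes fully exercise every code path (AND, NOT, OR
fan-in, inputs, knockouts) while keeping the whole suite around ten
seconds.

## Known limitations

* One rule supports only AND and NOT; OR between regulators is expressed
  as separate reactions sharing a target. Multi-valued logic, delays,
  stochastic semantics and stiff solvers are out of scope.
* Whether the weighted flux should be clamped at $w$ or the unweighted
  activation at 1 is indistinguishable for the $w \in \{0, 1\}$ settings
  used throughout the bundled models; this package clamps the unweighted
  activation.
* Workbook reading interprets only the documented column set; unknown
  columns ride along untyped.
* Steady states are found by integration, so an unstable fixed point will
  not be reported even if it exists algebraically.
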