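---
title: "Models and methods: structure and dynamics of chromatin domains"
author: "chromodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: structure and dynamics of chromatin domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

chromodyn connects two complementary views of subchromosomal chromatin
domains (TADs): the *topological* view from chromosome-conformation-capture
contact maps, and the *dynamic* view from fluorescence correlation
spectroscopy (FCS) of chromatin-bound labels. The package provides

* closed-form polymer models of a domain (loop rosette in theta or good
  solvent, crumpled globule, blob) linking contour length `L`, persistence
  length `l_p` and loop count `f` to the gyration radius `R_g`;
* a relaxation-mode description (Rouse–Zimm type) that maps `R_g` onto a
  spectrum of mode times `tau_p` and amplitudes `a_p`, and back;
* a self-avoiding lattice Monte Carlo model of loop-cluster chains,
  contact-map computation, and a projection/parabolic-peak pipeline that
  calls loop-base pairs from contact maps;
* a windowed intensity correlator and model fitting that converts
  fluctuation traces into domain relaxation times, gyration radii and
  genomic content;
* FRAP/continuous-photobleaching (CP) analysis of a sequential two-state
  chromatin-binding scheme, and an accessible-volume model of domains;
* synthetic-data generators with stored ground truth for every input.

## Polymer model of a domain

A domain is a topologically independent subchain characterized by
`(topology, L, l_p, f)`. The four gyration-radius branches are

* theta-solvent loop rosette: `R_g^2 = (L l_p / 6) (2f - 1) / f^2`
* good-solvent loop rosette:
  `R_g^2 = (L^{6/5} l_p^{4/5} / 9.59) (1.92 f - 0.92) / f^{11/5}`
* globule: `R_g^2 = L^{2/3} l_p^{4/3} / 1.76`
* blob: `R_g^2 = L l_p / 3`

Internal motion is decomposed into independent relaxation modes with

* `tau_1 = c_tau * eta_s R_g^3 / (kB T)`, with `c_tau` = 6.111 (theta
  rosette), 4.114 (good-solvent rosette), 7.151 (globule), 5.849 (blob);
* `tau_p = tau_1 / p^x` with `x` = 3/2, 17/20, 1, 3/2 respectively;
* `a_p = c_a R_g^2 / p^y` with `c_a` = 0.152, 0.172, 0.236, 0.152 and `y`
  = 2, 9/4, 5/3, 2.

Each mode is an Ornstein–Uhlenbeck (OU) process: per-axis variance
`a_p / 3`, correlation time `tau_p`. The segment mean-squared displacement
is confined diffusion, `msd(t) = 2 sum_p a_p (1 - exp(-t/tau_p))`, with
plateau `2 sum_p a_p` (twice the stationary segment variance; for the
theta rosette the full series gives `0.500 R_g^2`). This per-mode form is
the package's stand-in for extracting MSDs from correlation data; the
factor 2 is fixed by requiring equality with the stationary variance of
the OU generator, which the tests verify by simulation.

### Key constants and calibrations

| parameter | default | units | rationale |
|---|---|---|---|
| `eta_s` | 4.306e-3 | Pa s | calibrated so the theta spectrum maps 161 ms onto 297 nm at 310.15 K; an independent viscosity measurement is out of scope |
| `T` | 310.15 | K | live-cell temperature |
| `NRL` | 191 | bp | nucleosomal repeat length |
| `c_nuc` | 100–140 | uM | mean nuclear nucleosome concentration interval |
| `rel_density` | 0.91 / 1.56 | – | euchromatin / heterochromatin density relative to the nuclear mean |
| `chi_V` | 0.724 | – | prefactor of the effective domain volume `V = chi_V (4/3) pi R_g^3`, calibrated once so that the dense-chromatin (245 nm) gyration radius maps onto its 0.80–1.12 Mb genomic-content interval; it then transfers to the open-chromatin row within 1% |

Genomic content follows by counting nucleosomes:
`gc = rel_density * c_nuc * N_A-scaled density * V * NRL`, evaluated at
both concentration endpoints.

`parameter_surface()` inverts the gyration-radius branch for the
persistence length over a grid of linear mass densities (nucleosomes per
11 nm) and loop counts, flagging the plausibility box (0.5–6 nuc/11 nm,
`l_p` 10–200 nm, `f <= 20`). For the open-chromatin geometry
(`R_g` = 297 nm, 1 Mb) at 4.5 nuc/11 nm and `f = 9` the closed-form
inversion gives `l_p ≈ 197 nm`. Published parameter-surface figures for
the same combination quote ~110 nm; the main-text branch alone does not
reproduce that number, and the package deliberately reports the
closed-form value rather than forcing agreement.

## Lattice Monte Carlo of loop-cluster chains

Chains live on a cubic lattice with grid constant `a = 30 nm` (the assumed
fiber diameter); consecutive beads occupy one of the 26 surrounding sites,
so bond lengths are `a`, `sqrt(2) a`, `sqrt(3) a` with mean close to
`b = sqrt(2) a = 42.4 nm`, one bond corresponding to 2500 bp. Double
occupancy is forbidden (self-avoidance).

Configurations are written in a domain grammar: `lin(x)` for linear
stretches, `dom(y)[loop(z1) - loop(z2) - ...]` for loop clusters,
`dom(y)[glob(y)]` for globular domains (lengths in kb). Slash-separated
loop lengths are synchronous variants; expansion uses their mean by
default. The declared `dom` size is nominal — bead counts always derive
from the element lengths, and a mismatch beyond 2.5% is rejected. Loop
closure is first/last-bead adjacency; the first bead of the next loop is
the chain successor of the previous loop's last bead, so consecutive loop
bases sit within one lattice step of each other, giving a rosette center
without shared beads (this keeps the bead count equal to total kb / 2.5
exactly).

The Monte Carlo move set satisfies detailed balance with respect to the
uniform measure on valid conformations:

* *single-bead moves*: symmetric proposals to one of the 26 surrounding
  sites, rejected on occupancy, bond overstretch, or confinement
  violations;
* *tail regrowth* (probability `p_tail = 0.2` where legal): one chain
  bond outside all loops is resampled uniformly and the downstream chain
  translated rigidly. This accelerates the relaxation of long linear
  stretches from the deterministic initial layout, whose slowest mode
  would otherwise decay over a number of sweeps that grows with the
  square of the bead count.

Globular stretches are equilibrated inside a confining sphere whose radius
sets a volume fraction `phi = 0.1` (configurable); no globule construction
algorithm is prescribed by the source material, so this is the package's
documented choice.

Defaults: equilibration 100 sweeps per bead (one sweep = one attempted
move per bead), 10 sweeps per bead between recorded conformations, seed
mandatory. For loop clusters the slow degrees of freedom are loop-scale,
so this envelope is comfortable; for long *linear* chains the tests use
explicitly longer schedules scaled to the chain's relaxation time.

Contact maps count, per genomic bin pair, the fraction of conformations
with any bead pair within the capture radius. The default capture radius
is `sqrt(3) a` — the bonded-neighbour scale of the 26-neighbour lattice —
so chain-adjacent beads always register as contacts. (A tighter
`sqrt(2) a` would exclude the lattice's own diagonal bonds.)

## Loop-base detection from contact maps

The analysis mirrors the projection approach: after masking the diagonal
±30 kb (configurable within the ±30–75 kb range), the global profile of a
domain is, per column, the average of the maximum and the mean of
non-missing entries. Peaks are detected by sliding 12-point (30 kb)
parabolic fits; a candidate requires (i) a concave fit whose vertex lies
inside the window, (ii) fitted curvature significantly negative (2.5
standard errors — this significance gate is the package's reading of
"parabolic fitting", and is what rejects spurious maxima on flat noisy
profiles), and (iii) fitted height above 80% of the profile mean.
Candidates closer than one window merge (highest fitted value wins, ties
to the left). Global peaks anchor local projections (mean over a ±27.5 kb
row band), whose peaks are the partner sites; a pair recovered from both
of its anchors within one window is a high-confidence call, one direction
only is low confidence. Domain intervals are user-supplied, as in the
source analysis.

## FCS: correlator and model fitting

The local-average correlator tiles the trace into non-overlapping windows
of length `Theta`, computes `G(tau) = <dF_k dF_l> / (<F_k><F_l>)` with
window-local means, and averages over windows; lags are quasi-logarithmic
(8 per octave) up to `Theta/5`. Window-local normalization suppresses
fluctuations slower than the window (bulk photobleaching, cell movement).
Two estimator details matter numerically:

* *window bias*: estimating the mean from the same window shifts the
  correlator by approximately `-(2/Theta) int_0^Theta (1 - t/Theta) G(t)
  dt`. The relaxation fitter subtracts exactly this quantity, computed
  from the model itself, during fitting (`baseline = "window"`); a purely
  data-driven tail anchor and no correction are available as options.
* *weights*: inverse variance across windows, floored at one third of the
  median standard error so a few accidentally tiny window-to-window SEs
  cannot dominate; uniform fallback when SEs are unavailable.

Free diffusion is fitted with the standard anomalous-diffusion/blinking
autocorrelation; `D = w_0^2 / (4 tau_D)` with the focus calibration
(`w_0` = 200 nm, `kappa = z_0/w_0` = 5 by default). Polymer relaxation is
fitted as a composite: a fast free-diffusion term (normal diffusion,
capped at 10 ms so the two components cannot trade places) plus the mode
sum in which each mode contributes

`a_p [ (1 + u/ups_p)^{-1} (1 + u/(kappa^2 ups_p))^{-1/2} - (const) ]`,
`u = 1 - exp(-tau/tau_p)`,

with the diffusion-to-relaxation ratio closed per mode through the OU
mapping `ups_p = 3 w_0^2 / (4 a_p)` (per-axis mode variance `a_p/3` and
`D_p = a_p / (3 tau_p)`). This closure removes one free parameter per
mode; the whole relaxation component is parameterized by `tau_1` alone
(plus a free scale), since `R_g` follows from `tau_1` hydrodynamically
and fixes all amplitudes. Fits use Levenberg–Marquardt with multiple
`tau_1` starts (20–500 ms) and keep the best weighted residual norm.

Window-size scanning fits the model at every window of a grid spanning at
least a decade and looks for a plateau — the longest run of consecutive
windows whose fitted time changes by less than 10% between neighbours
(runs of at least two). The smallest window of the longest plateau is
selected; a trace without a plateau is flagged invalid and excluded, and
the bleaching test shows why: with a 50-s bleaching envelope the
full-trace estimate is biased more than twofold while plateau-selected
windows recover the truth within 15%.

## Synthetic data and what passing tests mean

Bound-emitter traces place anchors uniformly in a box of half-widths
`1.5 (w_0, w_0, z_0)` around the focus and move emitters by exactly
discretized OU displacements. Two compositions are available:

* `"quasiparticle"` (default): each emitter carries a single mode, with
  mode populations proportional to `a_p`. The ensemble ACF is then
  *exactly* the amplitude-weighted mode sum the fitter assumes, so
  recovery tests are well-posed model-class round trips.
* `"summed"`: each emitter carries the sum of all modes (the physically
  collective picture). The resulting correlator is a multiplicative form
  in the combined variance; at chromatin-like amplitudes
  (`4 sum_p a_p / (3 w_0^2) ≈ 0.7`) it is *not* a mode sum, and fitting
  it with the mode-sum model biases `tau_1` downward by roughly 20%.

This distinction is a genuine approximation gap of mode-sum FCS fitting of
collective polymer motion; the package exposes both so users can measure
the gap. Defaults (2000 emitters, 4000 counts/s peak brightness) emulate an
abundant, transiently bound label such as a linker histone at micromolar
bound concentration: the estimator averages over anchors, and sparser
populations add a finite-sample bias of order one over the number of
emitters in the focus. Shot noise is Poisson on binned counts; blinking is
a two-state telegraph with dark fraction and lifetime; bulk bleaching is a
multiplicative exponential envelope — each independently switchable.

Free-diffusion traces are Gaussian random walks in a periodic box.
FRAP/CP generators share their closed forms with the fitters (Gaussian
profile broadening `sigma^2(t) = sigma_0^2 + 2 D_app t`; erf-kernel strip
recovery with instantaneous free fraction and slow exponential
dissociation; reaction-dominant CP with focal bleach rate `k_b`), so
recovery tests are exact at zero noise. The binding scheme is strictly
sequential (free -> short-lived -> long-lived -> free): the steady-state
algebra `k_switch = f_long k_off2 / f_short`,
`k_on = f_short (k_off1 + k_switch) / f_free` is the exact stationary
solution, which the tests confirm against direct ODE integration.

None of the generators emulate detector afterpulsing or dead time,
chromatic aberration, real 3C library biases, or the collective coupling
of modes along one chain; passing tests therefore demonstrate estimator
and inversion correctness within the stated model classes, not end-to-end
fidelity to any particular microscope or sequencing pipeline.

## Accessibility model

A domain of volume `V` containing fiber length `L` of diameter
`d_f = 14 nm` excludes, for a probe of radius `r_p`, the dilated cylinder
`L pi (d_f/2 + r_p)^2`; the accessible fraction is clipped at zero and
the 50% limit is `r_50 = sqrt(V_mode / (2 pi L)) - d_f/2`. The dynamic
mode uses `V_dyn = 2 V` by default, motivated by volume fluctuations of
the same order as the volume itself. When comparing chromatin states, the
fiber content is that of a ~1-Mb domain at 1.6 nucleosomes/11 nm for
every state while the volume follows each state's gyration radius; under
this reading the model reproduces both the ordering (heterochromatin <
euchromatin < TSA-treated) and the magnitude (~5–30 nm) of the published
accessibility limits. (Taking instead each state's own genomic content
makes volume and fiber length grow proportionally and washes the ordering
out — a diagnostic that the published limits compare equal-content
domains.) Only ordering and order of magnitude are asserted, not exact
published values — the source formulas for accessible volume are not
reproducible from the main text and this cylinder-dilation model is the
package's documented stand-in.

## Problem sizes

The shipped tests and the acceptance script use: 50 conformations of the
516-bead ten-loop rosette (about 10 s of CPU); 60-conformation ensembles
of a four-loop test rosette for loop calling; 600 phantom-chain samples
for the ideal-chain check; 60-s FCS traces (3–5 per scenario, averaged as
repeated measurements of one condition); and 100 seeded strip-FRAP
regressions. These sizes put Monte Carlo standard errors comfortably
inside the tolerances being asserted while keeping the default run on a
single CPU within minutes.

## Known limitations

* The mode-sum relaxation model is an approximation for collective chain
  motion (see above); the quasi-particle generator matches it by
  construction.
* The Monte Carlo schedule (move set, equilibration length, globule
  construction) is not prescribed by the source material; defaults are
  documented choices, validated against closed-form ideal-chain and
  swelling properties.
* Contact capture is a proximity threshold on ensembles; no analytic
  (Gaussian-closure) contact probability is implemented.
* `dom` sizes in shipped model configurations are nominal: the ten-loop
  1300-kb domain's printed loop lengths sum to 1290 kb at the variant
  mean, and the first 1000-kb domain alternates 166/167-kb loops (six of
  them, 999 kb).
* Experimental 5C/T2C data handling stops at dense text matrices;
  normalization and bias correction of raw captures are out of scope.
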