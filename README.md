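# chromodyn

Structure and dynamics of topologically independent chromatin domains.

Mammalian genomes fold into subchromosomal domains (TADs) of roughly a
megabase. Contact-probability maps from 3C-derived assays (5C, T2C, Hi-C)
show these domains as squares of enriched internal contacts, but say
nothing about how they move. Fluorescence correlation spectroscopy (FCS)
of transiently chromatin-bound labels (such as linker histone H1.0)
measures exactly that: intensity fluctuations in a confocal focus carry
the relaxation spectrum of the chromatin fiber. `chromodyn` implements
the polymer theory, the simulation machinery and the fluorescence
analysis that connect the two views, for biophysicists who want to turn
correlation curves and contact maps into domain sizes, genomic content,
loop topology, binding kinetics and accessibility.

## What is inside

* **Polymer core** — closed-form gyration radii of four domain
  conformations (`gyration_radius`):

      R_g^2 = (L l_p / 6) (2f-1)/f^2            loop rosette, theta solvent
      R_g^2 = L^{6/5} l_p^{4/5}/9.59 (1.92f-0.92)/f^{11/5}   loop rosette, good solvent
      R_g^2 = L^{2/3} l_p^{4/3} / 1.76           globule
      R_g^2 = L l_p / 3                          blob

  and the relaxation-mode spectra `tau_1 = c eta_s R_g^3 / (kB T)`,
  `tau_p = tau_1/p^x`, `a_p = c_a R_g^2/p^y` per conformation
  (`mode_spectrum`), invertible from a measured relaxation time to domain
  geometry and genomic content (`rg_from_relaxation`, `genomic_content`),
  plus confined-diffusion segment MSDs (`segment_msd`) and
  density/persistence-length/loop-number parameter surfaces
  (`parameter_surface`).
* **Lattice Monte Carlo** (`parse_domain_config`, `sample_ensemble`) —
  self-avoiding chains on a 30-nm cubic lattice with 26-neighbour bonds
  (2500 bp per bond), built from a domain grammar
  (`lin(x)`, `dom(y)[loop(z) - ...]`, `dom(y)[glob(y)]`), with
  contact-map computation (`contact_map_from_ensemble`).
* **Map analysis** (`extract_domain`, `call_loop_bases`) — diagonal
  masking, max/mean projections, sliding parabolic peak fits and
  two-direction loop-base calling with high/low confidence.
* **FCS engine** (`correlate`, `window_scan`, `fit_diffusion`,
  `fit_relaxation`) — windowed local-average correlator, window-size
  stability scanning, anomalous-diffusion/blinking fits, and the
  composite polymer-relaxation model whose per-mode focus ratio is closed
  by the Ornstein-Uhlenbeck mapping `ups_p = 3 w_0^2/(4 a_p)`.
* **Binding kinetics** (`steady_state_rates`, `residence_times`,
  `fit_strip_profiles`, `fit_recovery`, `fit_cp`, `fit_point_frap`) —
  strip-FRAP broadening, three-population recovery, two-state continuous
  photobleaching and global point-FRAP fitting of the sequential
  free -> short-lived -> long-lived binding scheme.
* **Accessibility** (`accessible_fraction`, `accessibility_limit`) —
  static versus fluctuation-expanded accessible volume of a domain for
  probes of given radius.
* **Synthetic data** (`simulate_ou_trace`, `simulate_diffusion_trace`,
  `simulate_frap`, `simulate_cp`, `simulate_contact_map`) — seeded
  generators with stored ground truth for every pipeline input.
* **Pipelines** (`run_structure_pipeline`, `run_dynamics_pipeline`) —
  YAML-configured end-to-end workflows with JSON reports.

## Worked example

Convert a measured euchromatin relaxation time into domain geometry, then
check it against a Monte Carlo ensemble of a ten-loop rosette:

```r
library(chromodyn)

# 161 ms first-mode time, theta-solvent loop rosette
geom <- rg_from_relaxation(0.161, "loop_rosette", "theta",
                           calib = chromatin_calibration(rel_density = 0.91))
geom
#> Domain geometry (loop_rosette/theta)
#>   R_g = 297 nm, V = 0.07946 um^3
#>   genomic content 0.832 - 1.16 Mb

# Monte Carlo ensemble of the 1300-kb ten-loop rosette domain
ens <- sample_ensemble(rosette_1300_config(), n_conformations = 50,
                       seed = 42)
chain_statistics(ens)$rg_mean
#> [1] 251.7607
```

The inversion says a 161-ms domain is a ~297-nm object holding about
0.8–1.2 Mb of chromatin; the self-avoiding lattice ensemble of the
1300-kb ten-loop model domain equilibrates to a ~250-nm gyration radius,
the same ~240–300 nm scale measured for interphase domains.

Loop-base detection on a synthetic rosette with known truth:

```r
map <- simulate_contact_map(
  "lin(100) - dom(600)[loop(150) - loop(150) - loop(150) - loop(150)] - lin(100)",
  n_conformations = 60, seed = 11)
calls <- call_loop_bases(extract_domain(map, diag_mask_halfwidth = 30000))
generator_truth(map)$loop_bases    # planted boundaries (bp)
#> [1] 100000 250000 400000 550000 700000
subset(calls, confidence == "high")
#>     site_i   site_j confidence
#> 6 248577.7 548059.1       high
#> 8 398501.5 546382.3       high
```

The boundary sites at 250, 400 and 550 kb pair up in both projection
directions (high confidence); counting the additional single-direction
(low-confidence) calls, all five planted boundaries are recovered within
one 30-kb fit window.

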