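# abmorph

Quantitative analysis of amyloid-beta (Abeta42) prefibrillar
assemblies — the oligomers, curvilinear protofibrils and annular
(ring) assemblies that dominate the lag phase of amyloid fibril
formation and are the species most strongly linked to toxicity in
Alzheimer's disease.

The package is aimed at structural biologists and biophysicists who
image these assemblies (AFM, cryo-EM/ET) or record their ion-channel
activity (patch clamp) and want a tested, scriptable measurement
chain. It provides:

* **Morphometry** — automatic tracing of elongated assemblies in
  height maps and density fields (robust threshold, skeleton, longest
  geodesic path), cross-sectional diameters at a threshold above
  baseline (default 15%), annular ring geometry (outer/inner diameter,
  channel length), and length-distribution statistics (median,
  Freedman-Diaconis modal length).
* **Assembly kinetics** — ThT lag-phase timing (first crossing of 10%
  of maximal signal) and real-time bidirectional elongation rates from
  AFM time series, with the conversion to monomers added per minute
  through the 0.48-nm cross-beta strand rise.
* **Electrophysiology** — single-channel idealization (half-amplitude
  thresholds between conductance levels), windowed modal conductance
  (2500-ms windows, 10-pS bins), and the access-resistance (Hille)
  pore model linking conductance *g* to pore diameter *d* at pore
  length *l* and solution resistivity *rho*:

  $$\frac{1}{g} \;=\; \frac{4\rho l}{\pi d^{2}} \;+\; \frac{\rho}{d}$$

  With *l* = 5.4 nm and *rho* = 80 ohm cm, a 320-pS channel maps to a
  1.46-nm pore and 540 pS to 1.95 nm.
* **Stoichiometry** — map volume to mass (825 Da/nm^3), mass and
  filament length to Abeta42 monomer counts (average monomer mass
  4514.04 Da; 48 nm of filament = 100 monomers ~ 450 kDa).
* **Synthetic data generators** for every modality (AFM series with a
  spherical-tip contact model, 2D/3D density fields, two-state Markov
  channel traces, logistic ThT curves, lognormal length populations)
  with exact ground truth, so the entire chain is testable without
  external data.

## Worked example

Simulate a 320-pS channel under a ±80 mV step protocol, idealize it,
and convert the modal conductance to a pore diameter:

```r
library(abmorph)

sim <- gen_current_trace(channel_sim_params(), duration_ms = 100000, seed = 20260925)
id  <- idealize(sim$trace)
w   <- windowed_modal_conductance(sim$trace, window_ms = 2500, ideal = id)
s   <- ephys_summary(w, pore_model(l_nm = 5.4, rho_ohm_cm = 80))
```

This prints, via the bundled driver script
(`Rscript analysis/04_electrophysiology.R`):

```
detected level(s): 321 pS; open probability 0.502
idealization accuracy vs ground truth: 100.0%
median modal conductance: 320 pS over 40 windows
pore diameter at the median: 1.46 nm (range 1.45-1.47)
```

The detected open level (321 pS) and per-window modal conductances
recover the simulated 320-pS channel to within one histogram bin; the
access-resistance model then converts the median modal conductance to
a 1.46-nm pore — the diameter of the central channel that annular
Abeta42 assemblies would need to carry such a conductance across a
5.4-nm membrane span.

The full analysis workflow is a sequence of driver scripts over the
package functions:

```sh
Rscript analysis/01_simulate_inputs.R     # all modalities + ground truth
Rscript analysis/02_morphometry.R         # diameters, rings, length modes
Rscript analysis/03_growth_kinetics.R     # ThT lag, elongation rates
Rscript analysis/04_electrophysiology.R   # idealization, modal conductance
Rscript analysis/05_stoichiometry.R       # volumes/lengths -> monomer counts
```

Each writes its tables and a summary JSON (with the resolved
configuration embedded) under `results/`. Typical headline numbers:
tube diameters 2.87 ± 0.04 nm at the 15%-above-baseline convention;
ring geometry recovered within one voxel; elongation ~7.5-8 nm/min per
end, i.e. ~16 monomers added per minute per growing end; lag end at
~28 h for the default ThT geometry.

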