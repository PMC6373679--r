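# Packaged data

- `tumor_d0_morphometry.csv` — published reference measurements for five
  experimental tumour lines: boron-neutron D0 (Gy) extracted from mixed-beam
  clonogenic survival under BPA and BSH, together with the slide-derived
  N/C ratio (`xnc`) and cell-size index (`xcs`, um^2). The default
  D0-prediction models are fitted to this table. The B16-BL6 N/C ratio is
  stored as 0.3.
- `tumor_total_dose_d0.csv` — D0 of the total dose (Gy) for the same lines
  under beam-only, BPA + beam and BSH + beam conditions.
- `tumor_diameters_in_vitro.csv` — estimated in-vivo (slide morphometry) and
  measured in-vitro cell and nucleus diameters (um) for the same lines.
- `example_survival_experiment.csv` — a SYNTHETIC two-curve colony-survival
  example (beam-only control plus BPA at 25 ppm) generated from an
  exponential survival model with boron-neutron D0 = 0.35 Gy and a beam-only
  slope of 1e-12 per n/cm^2, surviving fractions rounded to 4 decimals. Used
  in examples and format tests; not experimental data.

Access from R with `tumor_reference_data()` or
`system.file("extdata", ..., package = "abebnct")`.
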