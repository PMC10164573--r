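synthetic_rh_measurements.csv -- synthetic example input for calibrate_dh()
and the `hydro --mode calibrate` CLI subcommand: hydrodynamic radii
(Angstrom) of two open-circular loops generated from the torus closed form
at thickness 29 A with 1% multiplicative noise (seed 42). Synthetic data,
not measurements; fitting recovers dh = 28.97 A.
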