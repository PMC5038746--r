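# Synthetic terrestrial solar spectral power density at the earth surface,
# approximating the AM1.5-global shape (coarse nodes, including the ~0.94 and
# ~1.14 um water-vapour troughs). Used only for relative spectral weighting.
# Units: wavelength um; density W/m^2/um.
wavelength_um,power_density_W_m2_um
0.3,20
0.35,600
0.4,1100
0.45,1600
0.5,1550
0.55,1550
0.6,1500
0.65,1450
0.7,1350
0.75,1230
0.8,1100
0.85,950
0.9,800
0.95,450
1,700
1.05,650
1.1,400
1.15,100
1.2,350
1.3,300
1.4,50
1.5,200
1.6,250
1.7,150
1.8,100
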