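# Wavelength-resolved optical properties of the four-layer human skin model,
# compiled from standard tissue-optics literature values (melanin power law for
# epidermis, blood+water for dermis, lipid bands for fat, myoglobin+water for
# muscle; reduced-scattering power laws converted to mu_s with the stated g).
# Units: mu_a, mu_s in 1/cm; g, n dimensionless; wavelength in um.
wavelength_um,layer,mu_a_per_cm,mu_s_per_cm,g,n
0.5,epidermis,26.25,400,0.85,1.44
0.55,epidermis,18.889,350,0.85,1.44
0.6,epidermis,14.009,309.9,0.85,1.44
0.65,epidermis,10.659,277,0.85,1.44
0.7,epidermis,8.293,249.7,0.85,1.44
0.75,epidermis,6.578,226.7,0.85,1.44
0.8,epidermis,5.309,207.2,0.85,1.44
0.85,epidermis,4.351,190.3,0.85,1.44
0.9,epidermis,3.617,175.7,0.85,1.44
0.95,epidermis,3.045,162.9,0.85,1.44
1,epidermis,2.594,151.6,0.85,1.44
0.5,dermis,2.2,450,0.9,1.4
0.55,dermis,2.7,397.6,0.9,1.4
0.6,dermis,1,355,0.9,1.4
0.65,dermis,0.55,320,0.9,1.4
0.7,dermis,0.4,290.6,0.9,1.4
0.75,dermis,0.38,265.6,0.9,1.4
0.8,dermis,0.4,244.3,0.9,1.4
0.85,dermis,0.43,225.8,0.9,1.4
0.9,dermis,0.48,209.6,0.9,1.4
0.95,dermis,0.6,195.4,0.9,1.4
1,dermis,0.55,182.8,0.9,1.4
0.5,fat,0.13,160,0.9,1.44
0.55,fat,0.12,151.8,0.9,1.44
0.6,fat,0.11,144.7,0.9,1.44
0.65,fat,0.1,138.5,0.9,1.44
0.7,fat,0.1,133,0.9,1.44
0.75,fat,0.1,128,0.9,1.44
0.8,fat,0.1,123.6,0.9,1.44
0.85,fat,0.11,119.5,0.9,1.44
0.9,fat,0.13,115.8,0.9,1.44
0.95,fat,0.16,112.4,0.9,1.44
1,fat,0.13,109.3,0.9,1.44
0.5,muscle,1.2,95,0.9,1.37
0.55,muscle,1,90.3,0.9,1.37
0.6,muscle,0.55,86.2,0.9,1.37
0.65,muscle,0.4,82.7,0.9,1.37
0.7,muscle,0.32,79.5,0.9,1.37
0.75,muscle,0.3,76.6,0.9,1.37
0.8,muscle,0.3,74.1,0.9,1.37
0.85,muscle,0.32,71.7,0.9,1.37
0.9,muscle,0.36,69.6,0.9,1.37
0.95,muscle,0.48,67.6,0.9,1.37
1,muscle,0.45,65.8,0.9,1.37
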