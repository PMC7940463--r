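# Elemental mass attenuation coefficients (cm^2/g) for H, C, O, 0.1-1.0 MeV,
# split into photoelectric, incoherent (Compton) and coherent (Rayleigh) components.
# Transcribed from the standard Hubbell/Seltzer-style compilations (NIST-published
# photon cross sections; photoelectric from the un-renormalized Scofield values).
# With-coherent totals cross-checked against published water and PMMA mixture values.
# Interpolate log-log in energy within each element and component. v1
element	Z	atomic_weight	energy_MeV	photoelectric	incoherent	coherent
H	1	1.008	0.1	4e-06	0.294096	3e-04
H	1	1.008	0.15	1.138e-06	0.264962	0.0001366
H	1	1.008	0.2	4.665e-07	0.242821	7.818e-05
H	1	1.008	0.3	1.327e-07	0.211164	3.56e-05
H	1	1.008	0.4	5.441e-08	0.18928	2.038e-05
H	1	1.008	0.5	2.724e-08	0.172887	1.322e-05
H	1	1.008	0.6	1.548e-08	0.159891	9.279e-06
H	1	1.008	0.8	6.346e-09	0.140495	5.31e-06
H	1	1.008	1	3.177e-09	0.126297	3.444e-06
C	6	12.011	0.1	0.00022	0.14678	0.0044
C	6	12.011	0.15	6.26e-05	0.132634	0.002004
C	6	12.011	0.2	2.566e-05	0.121728	0.001147
C	6	12.011	0.3	7.3e-06	0.10607	0.0005222
C	6	12.011	0.4	2.993e-06	0.0951582	0.0002989
C	6	12.011	0.5	1.498e-06	0.0869547	0.0001938
C	6	12.011	0.6	8.514e-07	0.0804431	0.0001361
C	6	12.011	0.8	3.49e-07	0.0706818	7.789e-05
C	6	12.011	1	1.748e-07	0.0635593	5.052e-05
O	8	15.999	0.1	0.00064	0.14786	0.0066
O	8	15.999	0.15	0.0001821	0.132912	0.003006
O	8	15.999	0.2	7.464e-05	0.121905	0.00172
O	8	15.999	0.3	2.124e-05	0.106195	0.0007833
O	8	15.999	0.4	8.706e-06	0.095203	0.0004483
O	8	15.999	0.5	4.359e-06	0.0869949	0.0002908
O	8	15.999	0.6	2.477e-06	0.0804934	0.0002041
O	8	15.999	0.8	1.015e-06	0.0707522	0.0001168
O	8	15.999	1	5.084e-07	0.0636437	7.578e-05
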