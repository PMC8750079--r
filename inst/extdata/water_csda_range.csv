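# Continuous-slowing-down-approximation (CSDA) ranges of protons in liquid
# water (unit density), PSTAR-style stopping-power tabulation, rounded to
# ~0.1%. Ranges are in mm of water; energies in MeV.
energy_mev,range_mm
10,1.23
20,4.26
30,8.85
40,14.89
50,22.27
60,30.93
70,40.80
80,51.84
90,63.98
100,77.18
110,91.39
120,106.5
130,122.6
140,139.5
150,157.7
160,176.6
170,196.4
180,217.0
190,238.6
200,260.8
210,283.9
220,307.7
230,332.4
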