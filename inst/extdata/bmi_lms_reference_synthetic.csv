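# SYNTHETIC healthy BMI-for-age LMS reference (kg/m^2).
# Constructed stand-in with plausible magnitudes for a healthy population,
# NOT a published growth standard; substitute a published LMS table (same
# schema: sex,age_years,L,M,S) such as the WHO 2007 coefficients for real use.
# L: Box-Cox power, M: median, S: coefficient of variation.
sex,age_years,L,M,S
M,0,-1.2,13.6,0.08
M,0.5,-1.2,16.6,0.0808
M,1,-1.2,17.661,0.0816
M,2,-1.2,16.1,0.0832
M,3,-1.2,14.728,0.0848
M,4,-1.2,14.457,0.0864
M,5,-1.2,14.833,0.088
M,6,-1.2,15.4,0.0896
M,7,-1.2,15.797,0.0912
M,8,-1.2,16.049,0.0928
M,9,-1.2,16.277,0.0944
M,10,-1.2,16.6,0.096
M,11,-1.2,17.107,0.0976
M,12,-1.2,17.758,0.0992
M,13,-1.2,18.48,0.1008
M,14,-1.2,19.2,0.1024
M,15,-1.2,19.857,0.104
M,16,-1.2,20.431,0.1056
M,17,-1.2,20.915,0.1072
M,18,-1.2,21.3,0.1088
M,20,-1.2,21.8,0.112
M,22,-1.2,22.116,0.1152
M,24,-1.2,22.322,0.1184
M,26,-1.2,22.45,0.12
M,28,-1.2,22.532,0.12
M,30,-1.2,22.6,0.12
M,32,-1.2,22.679,0.12
M,34,-1.2,22.772,0.12
M,36,-1.2,22.876,0.12
M,38,-1.2,22.986,0.12
M,40,-1.2,23.1,0.12
F,0,-1.2,13.4,0.08
F,0.5,-1.2,16.3,0.0808
F,1,-1.2,17.344,0.0816
F,2,-1.2,15.9,0.0832
F,3,-1.2,14.618,0.0848
F,4,-1.2,14.377,0.0864
F,5,-1.2,14.747,0.088
F,6,-1.2,15.3,0.0896
F,7,-1.2,15.698,0.0912
F,8,-1.2,15.968,0.0928
F,9,-1.2,16.229,0.0944
F,10,-1.2,16.6,0.096
F,11,-1.2,17.164,0.0976
F,12,-1.2,17.863,0.0992
F,13,-1.2,18.606,0.1008
F,14,-1.2,19.3,0.1024
F,15,-1.2,19.871,0.104
F,16,-1.2,20.317,0.1056
F,17,-1.2,20.654,0.1072
F,18,-1.2,20.9,0.1088
F,20,-1.2,21.2,0.112
F,22,-1.2,21.405,0.1152
F,24,-1.2,21.566,0.1184
F,26,-1.2,21.695,0.12
F,28,-1.2,21.802,0.12
F,30,-1.2,21.9,0.12
F,32,-1.2,21.998,0.12
F,34,-1.2,22.097,0.12
F,36,-1.2,22.197,0.12
F,38,-1.2,22.298,0.12
F,40,-1.2,22.4,0.12
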