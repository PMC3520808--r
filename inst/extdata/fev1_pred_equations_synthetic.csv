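# SYNTHETIC healthy-reference FEV1 prediction equations (liters; height in cm).
# These coefficients are a constructed stand-in with plausible magnitudes for a
# healthy population, shipped so the percent-predicted machinery runs out of the
# box.  They are NOT a published equation set; substitute a published table
# (same schema) for clinical or comparative use.
# Predicted FEV1 = intercept + age_coef*age_years + height_coef*height_cm
# within each [age_lo, age_hi) stratum (last stratum closed above).
sex,age_lo,age_hi,intercept,age_coef,height_coef
M,6,12,-2.81,0.000,0.0350
M,12,25,-6.12,0.0640,0.0520
M,25,80,-6.52,-0.0292,0.0665
F,6,11,-2.76,0.000,0.0336
F,11,20,-3.76,0.0690,0.0351
F,20,80,-1.41,-0.0201,0.0309
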