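# Relative-risk coefficient configuration (synthetic values unless replaced)
# SYNTHETIC demonstration coefficients: NOT the proprietary FRAX beta set.
prior_fracture.fracture_hr = 1.8
parent_hip_fracture.fracture_hr = 1.5
current_smoking.fracture_hr = 1.3
glucocorticoids.fracture_hr = 1.7
rheumatoid_arthritis.fracture_hr = 1.4
alcohol_3plus_units.fracture_hr = 1.4
prior_fracture.death_hr = 1
parent_hip_fracture.death_hr = 1
current_smoking.death_hr = 1
glucocorticoids.death_hr = 1
rheumatoid_arthritis.death_hr = 1
alcohol_3plus_units.death_hr = 1
bmd.gradient_per_sd = 1.6
bmd.tscore_ref = 0
calibration.divisor = 1
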