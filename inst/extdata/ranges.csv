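indicator,low,high,units,grid_step,span_factor
serum_alanine_aminotransferase,9,50,IU/L,,
serum_aspartate_aminotransferase,15,40,IU/L,,
albumin,40.0,55.0,g/L,,
total_bilirubin,2.0,20.0,umol/L,,
blood_urea_nitrogen,3.6,9.5,mmol/L,,
total_cholesterol,2.86,6.10,mmol/L,,
triglycerides,0.45,1.81,mmol/L,,
low_density_lipoprotein,0.00,3.37,mmol/L,,
high_density_lipoprotein,1.16,1.42,mmol/L,,
fasting_blood_glucose,3.9,6.1,mmol/L,,
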