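code,code_system,component,category_map
22K..,ReadV2,bmi_value,
229..,ReadV2,height,
22A..,ReadV2,weight,
22K1.,ReadV2,bmi_category,underweight
22K2.,ReadV2,bmi_category,normal
22K4.,ReadV2,bmi_category,overweight
22K5.,ReadV2,bmi_category,obese
E66,ICD10,obesity_dx,obese
E660,ICD10,obesity_dx,obese
E661,ICD10,obesity_dx,obese
E668,ICD10,obesity_dx,obese
E669,ICD10,obesity_dx,obese
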