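ward_id,ward_label,class,pharmacy_ddd,ward_ddd
pulmonary,Pulmonary diseases,2nd generation cephalosporins,445.0,432.5
pulmonary,Pulmonary diseases,3rd generation cephalosporins,328.8,360.3
pulmonary,Pulmonary diseases,Carbapenems,180.0,171.0
pulmonary,Pulmonary diseases,Ciprofloxacin parenteral,16.0,26.4
pulmonary,Pulmonary diseases,Ciprofloxacin oral,175.0,204.0
gastro_inf,Gastrointestinal/infectious diseases,2nd generation cephalosporins,205.0,231.0
gastro_inf,Gastrointestinal/infectious diseases,3rd generation cephalosporins,161.3,152.5
gastro_inf,Gastrointestinal/infectious diseases,Carbapenems,103.0,96.3
gastro_inf,Gastrointestinal/infectious diseases,Ciprofloxacin parenteral,128.0,130.0
gastro_inf,Gastrointestinal/infectious diseases,Ciprofloxacin oral,280.0,288.3
endo_haem,Endocrinology/haematology,2nd generation cephalosporins,125.0,128.0
endo_haem,Endocrinology/haematology,3rd generation cephalosporins,101.3,111.3
endo_haem,Endocrinology/haematology,Carbapenems,80.0,76.0
endo_haem,Endocrinology/haematology,Ciprofloxacin parenteral,52.0,46.8
endo_haem,Endocrinology/haematology,Ciprofloxacin oral,310.0,314.0
urology_1,Urology 1,2nd generation cephalosporins,70.0,62.5
urology_1,Urology 1,3rd generation cephalosporins,46.3,32.8
urology_1,Urology 1,Carbapenems,0,0
urology_1,Urology 1,Ciprofloxacin parenteral,124.0,131.2
urology_1,Urology 1,Ciprofloxacin oral,375.0,346.3
urology_2,Urology 2,2nd generation cephalosporins,72.5,63.0
urology_2,Urology 2,3rd generation cephalosporins,30.0,19.0
urology_2,Urology 2,Carbapenems,0,0
urology_2,Urology 2,Ciprofloxacin parenteral,144.0,144.4
urology_2,Urology 2,Ciprofloxacin oral,425.0,402.3
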