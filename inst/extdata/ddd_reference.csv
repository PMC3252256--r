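agent_id,atc_code,name,route,ddd_mg,pack_strength_mg,is_bsa
cefuroxime,J01DC02,Cefuroxime,parenteral,3000,1500,TRUE
cefotaxime,J01DD01,Cefotaxime,parenteral,4000,2000,TRUE
ceftazidime,J01DD02,Ceftazidime,parenteral,4000,2000,TRUE
ceftriaxone,J01DD04,Ceftriaxone,parenteral,2000,2000,TRUE
meropenem,J01DH02,Meropenem,parenteral,3000,1000,TRUE
imipenem_cilastatin,J01DH51,Imipenem/cilastatin,parenteral,2000,500,TRUE
ciprofloxacin_iv,J01MA02,Ciprofloxacin,parenteral,800,400,TRUE
ciprofloxacin_oral,J01MA02,Ciprofloxacin,oral,1000,500,TRUE
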