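vocabulary,code,category
SNOMED,SN_LIVEBIRTH,livebirth_singleton
SNOMED,SN_DELIVERY,livebirth_singleton
SNOMED,SN_MULTIPLE_BIRTH,livebirth_multiple
SNOMED,SN_STILLBIRTH,stillbirth
SNOMED,SN_MISCARRIAGE,miscarriage
SNOMED,SN_TERMINATION,termination
SNOMED,SN_PROBABLE_TERMINATION,probable_termination
SNOMED,SN_ECTOPIC,ectopic
SNOMED,SN_MOLAR,molar
SNOMED,SN_UNSPECIFIED_LOSS,unspecified_loss
SNOMED,SN_BLIGHTED_OVUM,blighted_ovum
SNOMED,SN_EDD,edd
SNOMED,SN_LMP,lmp
SNOMED,SN_SCAN,antenatal_scan
SNOMED,SN_POSTNATAL_VISIT,postnatal
ICD10,Z370,livebirth_singleton
ICD10,O80,livebirth_singleton
ICD10,Z372,livebirth_multiple
ICD10,O84,livebirth_multiple
ICD10,Z371,stillbirth
ICD10,O03,miscarriage
ICD10,O04,termination
ICD10,O05,probable_termination
ICD10,O00,ectopic
ICD10,O01,molar
ICD10,O06,unspecified_loss
ICD10,O021,blighted_ovum
ICD10,O601,preterm_indicator
ICD10,O603,preterm_indicator
ICD10,Z36,antenatal_scan
ICD10,Z39,postnatal
OPCS4,R17,livebirth_singleton
OPCS4,R18,livebirth_singleton
OPCS4,R24,livebirth_singleton
OPCS4,R19,livebirth_multiple
OPCS4,R20,stillbirth
OPCS4,Q10,termination
OPCS4,Q11,miscarriage
OPCS4,Q12,probable_termination
OPCS4,Q13,molar
OPCS4,Q14,blighted_ovum
OPCS4,Q15,unspecified_loss
OPCS4,R03,ectopic
OPCS4,R36,antenatal_scan
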