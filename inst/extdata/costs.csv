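"block","label","n_visits","units_per_visit","unit_cost"
"assessment","referral_audiologist",1,1,84
"assessment","removing_earwax",1,1,106
"assessment","initial_assessment_audiologist",1,1.5,84
"assessment","initial_assessment_slt",1,1.5,96
"assessment","vestibular_assessment",1,1.5,86
"assessment","radiologist",1,1,74
"assessment","mri_scan",1,1,138
"assessment","ct_scan",1,1,88
"assessment","audioscientist",1,1,84
"assessment","electrophysiology_assessment",1,1,70
"assessment","preop_audiologist",1,1.5,84
"assessment","ent_surgeon_consultation",1,1,104
"assessment","anaesthetist_consultation",1,1,130
"assessment","multidisciplinary_team_meeting",1,1,284
"assessment","gp_meningitis_consultation",1,1,31
"assessment","meningitis_vaccination",1,1,60
"assessment","surgery_coordinator",1,1,44
"surgery","uci_operation_surgical",1,1,5956
"surgery","uci_operation_device",1,1,16964
"hearing_aid","one_hearing_aid",1,1,166
"hearing_aid","pair_of_hearing_aids",1,1,332
"year1","gp_medical_check",1,1,31
"year1","programming_audiologist",6,1.5,84
"year1","aural_training_slt",4.5,1.5,96
"maintenance","tuning_audiologist",1,1,84
"maintenance","tuning_slt",1,1,96
"maintenance","equipment_maintenance",1,1,328
"maintenance","annual_administration",1,1,44
"processor","external_component",1,1,5000
"processor","tuning_audiologist",1,1.5,84
"processor","tuning_slt",1,1.5,96
"explant","assessment_audiologist",1,1.5,84
"explant","explant_operation",1,1,4253
"reimplant","preop_audiologist",1,1.5,84
"reimplant","ent_surgeon_consultation",1,1,104
"reimplant","anaesthetist_consultation",1,1,130
"reimplant","multidisciplinary_team_meeting",1,1,284
"reimplant","surgery_coordinator",1,1,44
"reimplant","uci_operation_surgical",1,1,5956
"reimplant","gp_medical_check",1,1,31
"ae_short_term","dysgeusia_gp_visit",1,1,31
"ae_short_term","vertigo_gp_visit",1,1,31
"ae_short_term","tinnitus_gp_visit",1,1,31
"ae_short_term","infection_gp_visit",1,1,31
"ae_short_term","infection_antibiotics",1,1,10
"ae_long_term","vertigo_gp_visit",1,1,31
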