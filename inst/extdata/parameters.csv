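"name","mean","ci_low","ci_high","family","units","ci_assumed"
"average_age",52.8,NA,NA,"fixed","years",FALSE
"discount_rate",0.035,NA,NA,"fixed","per year",FALSE
"prop_eligible",0.7,0.372,0.938,"beta","proportion",FALSE
"p_internal_failure",0.025,0.011,0.04,"beta","probability",FALSE
"p_external_failure",0.004,0.002,0.018,"beta","probability",FALSE
"p_discontinue",0.077,0.009,0.206,"beta","probability",FALSE
"prop_benefit_ha",0.5,0.061,0.939,"beta","proportion",FALSE
"ha_lifetime_years",5,1.3,11,"gamma","years",FALSE
"upgrade_time_months",106,29,232,"gamma","months",FALSE
"p_ha_compliant",0.5,0.061,0.939,"beta","proportion",FALSE
"u_base_traditional",0.41,0.328,0.492,"beta","utility",TRUE
"u_base_marginal",0.494,0.3952,0.5928,"beta","utility",TRUE
"u_gain_traditional",0.214,0.1712,0.2568,"beta","utility",TRUE
"u_gain_marginal",0.151,0.1208,0.1812,"beta","utility",TRUE
"norm_decrement_traditional",0.439,NA,NA,"fixed","utility",FALSE
"norm_decrement_marginal",0.374,NA,NA,"fixed","utility",FALSE
"du_dysgeusia",0.02,0.016,0.024,"beta","utility",TRUE
"du_st_vertigo",0.033,0.0264,0.0396,"beta","utility",TRUE
"du_tinnitus",0.05,0.04,0.06,"beta","utility",TRUE
"du_infection",0.042,0.0336,0.0504,"beta","utility",TRUE
"du_lt_vertigo",0.033,0.0264,0.0396,"beta","utility",TRUE
"p_dysgeusia",0.065,0.052,0.078,"beta","probability",TRUE
"p_st_vertigo",0.194,0.1552,0.2328,"beta","probability",TRUE
"p_infection",0.015,0.012,0.018,"beta","probability",TRUE
"p_tinnitus",0.036,0.0288,0.0432,"beta","probability",TRUE
"p_lt_vertigo",0.014,0.0112,0.0168,"beta","probability",TRUE
"c_assessment",1,0.8,1.2,"gamma","multiplier",TRUE
"c_surgery_device",1,0.8,1.2,"gamma","multiplier",TRUE
"c_hearing_aid",1,0.8,1.2,"gamma","multiplier",TRUE
"c_year1",1,0.8,1.2,"gamma","multiplier",TRUE
"c_maintenance",1,0.8,1.2,"gamma","multiplier",TRUE
"c_processor",1,0.8,1.2,"gamma","multiplier",TRUE
"c_explant",1,0.8,1.2,"gamma","multiplier",TRUE
"c_reimplant",1,0.8,1.2,"gamma","multiplier",TRUE
"c_adverse_event",1,0.8,1.2,"gamma","multiplier",TRUE
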