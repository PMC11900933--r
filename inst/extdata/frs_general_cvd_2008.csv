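# 2008 Framingham general cardiovascular disease risk function, lipid-based,
# sex-specific Cox model. Transcribed from D'Agostino RB Sr et al., "General
# cardiovascular risk profile for use in primary care: the Framingham Heart
# Study", Circulation 2008;117(6):743-753, Table (Cox model coefficients).
# risk_10yr = 1 - s0_10 ^ exp(lp - lp_mean), where
# lp = b_ln_age*ln(age) + b_ln_tc*ln(TC) + b_ln_hdl*ln(HDL)
#    + b_ln_sbp_untreated*ln(SBP) [if untreated] or b_ln_sbp_treated*ln(SBP)
#    + b_smoker*smoker + b_diabetes*diabetic
# Units: age years; TC, HDL mg/dL; SBP mmHg. Version: 1 (do not edit; the
# vascular-age inversion and its tests assume these exact values).
sex,term,value
female,b_ln_age,2.32888
female,b_ln_tc,1.20904
female,b_ln_hdl,-0.70833
female,b_ln_sbp_untreated,2.76157
female,b_ln_sbp_treated,2.82263
female,b_smoker,0.52873
female,b_diabetes,0.69154
female,lp_mean,26.1931
female,s0_10,0.95012
male,b_ln_age,3.06117
male,b_ln_tc,1.12370
male,b_ln_hdl,-0.93263
male,b_ln_sbp_untreated,1.93303
male,b_ln_sbp_treated,1.99881
male,b_smoker,0.65451
male,b_diabetes,0.57367
male,lp_mean,23.9802
male,s0_10,0.88936
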