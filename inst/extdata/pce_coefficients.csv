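# Pooled Cohort Equations coefficients, transcribed from the 2013 ACC/AHA
# cardiovascular risk assessment guideline (Goff et al., Circulation 2014;
# 129:S49-S73, Appendix 7, Table A). Natural-log terms; lipids in mg/dL,
# SBP in mmHg. mean_lp is the race/sex-group mean of the coefficient-by-value
# products; baseline_survival is survival at 10 years for that group.
stratum,term,value
female_white,ln_age,-29.799
female_white,ln_age_sq,4.884
female_white,ln_tc,13.540
female_white,ln_age_ln_tc,-3.114
female_white,ln_hdl,-13.578
female_white,ln_age_ln_hdl,3.149
female_white,ln_sbp_treated,2.019
female_white,ln_sbp_untreated,1.957
female_white,smoker,7.574
female_white,ln_age_smoker,-1.665
female_white,diabetes,0.661
female_white,mean_lp,-29.18
female_white,baseline_survival,0.9665
female_black,ln_age,17.114
female_black,ln_tc,0.940
female_black,ln_hdl,-18.920
female_black,ln_age_ln_hdl,4.475
female_black,ln_sbp_treated,29.291
female_black,ln_age_ln_sbp_treated,-6.432
female_black,ln_sbp_untreated,27.820
female_black,ln_age_ln_sbp_untreated,-6.087
female_black,smoker,0.691
female_black,diabetes,0.874
female_black,mean_lp,86.61
female_black,baseline_survival,0.9533
male_white,ln_age,12.344
male_white,ln_tc,11.853
male_white,ln_age_ln_tc,-2.664
male_white,ln_hdl,-7.990
male_white,ln_age_ln_hdl,1.769
male_white,ln_sbp_treated,1.797
male_white,ln_sbp_untreated,1.764
male_white,smoker,7.837
male_white,ln_age_smoker,-1.795
male_white,diabetes,0.658
male_white,mean_lp,61.18
male_white,baseline_survival,0.9144
male_black,ln_age,2.469
male_black,ln_tc,0.302
male_black,ln_hdl,-0.307
male_black,ln_sbp_treated,1.916
male_black,ln_sbp_untreated,1.809
male_black,smoker,0.549
male_black,diabetes,0.645
male_black,mean_lp,19.54
male_black,baseline_survival,0.8954
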