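parameter,group,mean,sd,n
age_years,ASD,3.3,1.0,66
age_years,TD,3.3,1.2,47
ADOS_total_SS,ASD,7.7,1.8,66
ADOS_total_SS,TD,1.0,0.0,47
ADOS_SA_SS,ASD,6.7,2.1,66
ADOS_SA_SS,TD,1.0,0.0,47
ADOS_RRB_SS,ASD,8.7,1.8,66
ADOS_RRB_SS,TD,2.2,1.9,47
MSEL_total_DQ,ASD,73.4,24.5,55
MSEL_total_DQ,TD,110.4,13.7,35
MSEL_FM_DQ,ASD,79.7,21.3,55
MSEL_FM_DQ,TD,104.0,12.6,35
MSEL_VR_DQ,ASD,86.4,26.1,55
MSEL_VR_DQ,TD,122.7,23.8,35
MSEL_EL_DQ,ASD,60.4,28.5,55
MSEL_EL_DQ,TD,104.2,21.2,35
MSEL_RL_DQ,ASD,67.0,31.7,55
MSEL_RL_DQ,TD,113.8,16.5,35
CBCL_AffP_T,ASD,58.7,8.1,49
CBCL_AffP_T,TD,53.0,5.4,34
CBCL_AnxP_T,ASD,56.9,9.7,49
CBCL_AnxP_T,TD,52.4,4.9,34
CBCL_ADHP_T,ASD,55.9,5.9,49
CBCL_ADHP_T,TD,51.9,3.3,34
CBCL_ODP_T,ASD,54.9,6.9,49
CBCL_ODP_T,TD,53.7,7.1,34
CBCL_PDP_T,ASD,68.7,12.0,49
CBCL_PDP_T,TD,51.4,4.1,34
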