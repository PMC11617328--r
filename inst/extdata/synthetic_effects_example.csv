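effect_id,study_id,species,stat_type,stat_value,df,n_total,n1,n0,m1,m0,sd_pooled,direction,color_class,plasticity,sex,aggression_measure,study_design,condition_control,rank_control,age_control
e01,smith2001,Parus_major,pearson_r,0.42,,34,,,,,,,eumelanin,fixed,male,direct,observational,statistical,uncontrolled,uncontrolled
e02,smith2001,Parus_major,pearson_r,0.31,,34,,,,,,,eumelanin,fixed,male,indirect,observational,statistical,uncontrolled,uncontrolled
e03,jones2004,Taeniopygia_guttata,t_test,2.10,28,30,,,,,,,carotenoid,plastic,male,direct,experimental,uncontrolled,unfamiliar,uncontrolled
e04,lee2010,Anolis_sagrei,F_test,5.60,22,24,,,,,,1,structural,fixed,both,direct,experimental,statistical,uncontrolled,statistical
e05,garcia2012,Poecilia_reticulata,chisq,4.10,,52,,,,,,1,carotenoid,plastic,male,indirect,observational,uncontrolled,mirror_or_video,uncontrolled
e06,wang2015,Gallus_gallus,group_means,,,40,20,20,1.30,0.60,1.10,,pheomelanin,fixed,female,direct,experimental,statistical,unfamiliar,uncontrolled
e07,wang2015,Gallus_gallus,group_means,,,40,22,18,0.90,0.80,1.00,,pheomelanin,fixed,female,indirect,experimental,statistical,unfamiliar,uncontrolled
e08,okafor2018,Crocuta_crocuta,pearson_r,-0.12,,26,,,,,,,unknown,fixed,both,direct,observational,uncontrolled,uncontrolled,uncontrolled
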