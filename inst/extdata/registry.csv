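indicator_id,name,topic,direction,transform,target_type,target_value,baseline_year,target_year,units,assumption
2.2.1,Child stunting prevalence under 5 years,child_nutrition,lower_better,logit,relative_reduction,0.4,2015,2025,proportion,FALSE
2.2.2a,Child wasting prevalence under 5 years,child_nutrition,lower_better,logit,absolute,0.05,NA,2025,proportion,FALSE
2.2.2b,Child overweight prevalence ages 2-4 years,child_nutrition,lower_better,logit,no_increase,NA,2015,2025,proportion,FALSE
3.1.1,Maternal mortality ratio,mchrh,lower_better,log,absolute,70,NA,2030,per 100000 live births,FALSE
3.1.2,Births attended by skilled health personnel,mchrh,higher_better,logit,absolute,0.99,NA,2030,proportion,TRUE
3.2.1,Under-5 mortality rate,mchrh,lower_better,log,absolute,25,NA,2030,per 1000 live births,FALSE
3.2.2,Neonatal mortality rate,mchrh,lower_better,log,absolute,12,NA,2030,per 1000 live births,FALSE
3.b.1,Coverage of eight vaccines (geometric mean),mchrh,higher_better,logit,absolute,0.99,NA,2030,proportion,TRUE
3.7.1,Family planning need met with modern methods,mchrh,higher_better,logit,absolute,0.99,NA,2030,proportion,TRUE
3.3.1,HIV incidence,infectious,lower_better,log,relative_reduction,0.9,2010,2030,per 1000,FALSE
3.3.2,Tuberculosis incidence,infectious,lower_better,log,relative_reduction,0.8,2015,2030,per 100000,FALSE
3.3.3,Malaria incidence,infectious,lower_better,log,relative_reduction,0.9,2015,2030,per 1000,FALSE
3.3.4,Hepatitis B incidence,infectious,lower_better,log,relative_reduction,0.95,2015,2030,per 100000,FALSE
3.3.5,Neglected tropical disease prevalence (sum of 15),infectious,lower_better,log,relative_reduction,0.9,2015,2030,percent,TRUE
3.4.1,Premature NCD mortality ages 30-70,ncd_mortality,lower_better,log,relative_reduction,0.333333333333,2015,2030,per 100000,FALSE
3.4.2,Suicide mortality,ncd_mortality,lower_better,log,relative_reduction,0.333333333333,2015,2030,per 100000,FALSE
3.5.2,Alcohol use summary exposure value,ncd_risk,lower_better,logit,relative_reduction,0.1,2015,2025,proportion,TRUE
3.a.1,Daily smoking prevalence ages 10 and over,ncd_risk,lower_better,logit,relative_reduction,0.3,2015,2025,proportion,FALSE
3.6.1,Road injury mortality,road_injury,lower_better,log,relative_reduction,0.5,2015,2020,per 100000,TRUE
3.9.1,Air pollution attributable mortality,env_outcome,lower_better,log,relative_reduction,0.5,2015,2030,per 100000,TRUE
3.9.2,Unsafe WaSH attributable mortality,env_outcome,lower_better,log,relative_reduction,0.5,2015,2030,per 100000,TRUE
3.9.3,Unintentional poisoning mortality,env_outcome,lower_better,log,relative_reduction,0.5,2015,2030,per 100000,TRUE
11.6.2,Population-weighted mean PM2.5,env_exposure,lower_better,linear,absolute,10,NA,2030,ug/m3,FALSE
7.1.2,Household air pollution summary exposure value,env_exposure,lower_better,logit,elimination,NA,NA,2030,proportion,TRUE
6.1.1,Unsafe water summary exposure value,env_exposure,lower_better,logit,elimination,NA,NA,2030,proportion,TRUE
6.2.1a,Unsafe sanitation summary exposure value,env_exposure,lower_better,logit,elimination,NA,NA,2030,proportion,TRUE
6.2.1b,Unsafe hygiene summary exposure value,env_exposure,lower_better,logit,elimination,NA,NA,2030,proportion,TRUE
3.8.1,UHC essential service coverage index,uhc,higher_better,linear,absolute,100,NA,2030,index 0-100,TRUE
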